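test_that("short-timescale noise is zero for perfectly smooth traces", {
  tr <- ephys_trace(rep(-60, 1000), 10000)
  filt <- moving_average(tr$samples, 10000, 3)
  empty_spikes <- detect_spikes(tr)
  nt <- short_timescale_noise(tr, filt, empty_spikes)
  expect_true(all(nt[is.finite(nt)] == 0))
  # edges (half filter width) are undefined
  expect_true(all(is.na(nt[1:15])))
})

test_that("noise estimator recovers the sd of iid Gaussian residuals", {
  set.seed(21)
  tr <- ephys_trace(-60 + rnorm(50000, 0, 0.5), 10000)
  filt <- moving_average(tr$samples, 10000, 3)
  nt <- short_timescale_noise(tr, filt, detect_spikes(tr))
  expect_gt(mean(nt, na.rm = TRUE), 0.45)
  expect_lt(mean(nt, na.rm = TRUE), 0.55)
})

test_that("noise is masked within 3 ms of accepted spikes", {
  out <- generate_trace(generator_profile(noise_sd = 0.3), seed = 3)
  sp <- detect_spikes(out$trace)
  filt <- moving_average(out$trace$samples, out$trace$sampling_rate, 3)
  nt <- short_timescale_noise(out$trace, filt, sp)
  centre <- round(sp$t_spike[1] * out$trace$sampling_rate) + 1
  expect_true(all(is.na(nt[(centre - 30):(centre + 30)])))
})

test_that("linear drift matches an independent OLS oracle", {
  expect_equal(linear_drift(c(1, 2, 3), c(0, 1, 2)), 1)
  expect_equal(linear_drift(rep(4, 10), 1:10), 0)
  set.seed(5)
  v <- rnorm(10); tt <- sort(runif(10, 0, 5))
  expect_equal(linear_drift(v, tt),
               unname(stats::coef(stats::lm(v ~ tt))[2]), tolerance = 1e-10)
  expect_equal(linear_drift(3, 1), 0)  # fill for < 2 points
})

test_that("spike summary features follow hand calculations", {
  set.seed(2)
  tr <- ephys_trace(-60 + rnorm(20000, 0, 0.1), 10000)
  spikes <- data.frame(t_spike = c(1.0, 1.1), v_max = 0, baseline = 0,
                       height = c(8, 12), width = c(2, 2),
                       max_slope = c(5, 7), min_slope = c(-6, -4),
                       onset_index = 1, offset_index = 2, peak_index = c(10001, 11001))
  fv <- extract_features(tr, spikes)
  expect_equal(unname(fv["f01_mean_spike_height"]), 10)
  expect_equal(unname(fv["f03_cv_spike_height"]), 0.2)  # population sd 2 / 10
  expect_equal(unname(fv["f02_mean_spike_width"]), 2)
  expect_equal(unname(fv["f04_cv_spike_width"]), 0)
  expect_equal(unname(fv["f12_min_isi"]), 0.1)
  expect_equal(unname(fv["f13_max_spike_slope"]), 6)
  expect_equal(unname(fv["f15_std_max_spike_slope"]), 1)  # population sd
})

test_that("degenerate traces take the documented fill values", {
  tr <- ephys_trace(rep(-60, 5000), 1000)
  sp <- detect_spikes(tr)
  expect_equal(nrow(sp), 0L)
  fv <- extract_features(tr, sp)
  expect_equal(unname(fv["f01_mean_spike_height"]), 0)
  expect_equal(unname(fv["f12_min_isi"]), 5)    # trace duration in seconds
  expect_equal(unname(fv["f05_mean_baseline_voltage"]), -60)
  expect_true(all(is.finite(fv)))
})

test_that("features transform correctly under scaling and shifts", {
  out <- generate_trace(generator_profile(noise_sd = 0.3), seed = 14)
  tr <- out$trace
  f0 <- extract_features(tr, detect_spikes(tr))
  k <- 3
  trk <- ephys_trace(tr$samples * k, tr$sampling_rate)
  fk <- extract_features(trk, detect_spikes(trk))
  expect_equal(unname(fk["f01_mean_spike_height"]),
               unname(k * f0["f01_mean_spike_height"]), tolerance = 1e-8)
  expect_equal(unname(fk["f03_cv_spike_height"]),
               unname(f0["f03_cv_spike_height"]), tolerance = 1e-8)
  trc <- ephys_trace(tr$samples + 25, tr$sampling_rate)
  fc <- extract_features(trc, detect_spikes(trc))
  expect_equal(unname(fc["f05_mean_baseline_voltage"]),
               unname(f0["f05_mean_baseline_voltage"] + 25), tolerance = 1e-8)
  expect_equal(unname(fc["f06_std_baseline"]),
               unname(f0["f06_std_baseline"]), tolerance = 1e-8)
})

test_that("estimated height and noise match the generator", {
  hs <- sig <- numeric(20)
  for (s in 1:20) {
    out <- generate_trace(generator_profile(noise_sd = 0.3), seed = 300 + s)
    sp <- detect_spikes(out$trace)
    fv <- extract_features(out$trace, sp)
    hs[s] <- fv["f01_mean_spike_height"]
    sig[s] <- fv["f07_short_timescale_noise"]
  }
  expect_lt(abs(mean(hs) - 25) / 25, 0.05)
  expect_lt(abs(mean(sig) - 0.3) / 0.3, 0.10)
})

test_that("the feature table is a deterministic per-trace map", {
  corpus <- generate_dataset(counts = c(good = 2, intermediate = 2, bad = 2),
                             seed = 8)
  tab1 <- extract_feature_table(corpus$traces)
  tab2 <- extract_feature_table(corpus$traces)
  expect_identical(tab1, tab2)
  expect_equal(dim(tab1), c(6L, 17L))
  expect_true(all(vapply(tab1[, -1], function(col) all(is.finite(col)), TRUE)))
  one <- extract_features(corpus$traces[[3]],
                          detect_spikes(corpus$traces[[3]]))
  expect_equal(unlist(tab1[3, -1]), one)
})
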