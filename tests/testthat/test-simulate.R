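test_that("the corpus matches requested counts and is reproducible", {
  corpus <- generate_dataset(counts = c(good = 5, intermediate = 4, bad = 3),
                             seed = 3)
  expect_length(corpus$traces, 12L)
  expect_equal(unname(table(corpus$labels)[c("good", "intermediate", "bad")]),
               c(5L, 4L, 3L), ignore_attr = TRUE)
  expect_equal(names(corpus$traces), names(corpus$labels))
  corpus2 <- generate_dataset(counts = c(good = 5, intermediate = 4, bad = 3),
                              seed = 3)
  expect_identical(corpus$traces[[1]]$samples, corpus2$traces[[1]]$samples)
  expect_identical(corpus$ground_truth, corpus2$ground_truth)
})

test_that("traces are bit-identical under a fixed seed", {
  pr <- generator_profile()
  a <- generate_trace(pr, seed = 77)
  b <- generate_trace(pr, seed = 77)
  expect_identical(a$trace$samples, b$trace$samples)
  expect_identical(a$ground_truth, b$ground_truth)
  c <- generate_trace(pr, seed = 78)
  expect_false(identical(a$trace$samples, c$trace$samples))
})

test_that("empirical firing rate matches the profile rate", {
  pr <- generator_profile(firing_rate = 8, refractory_ms = 8,
                          stim_rate_multiplier = 1)
  rates <- vapply(1:100, function(s)
    length(generate_trace(pr, seed = 2000 + s)$ground_truth$spike_times) / 5,
    numeric(1))
  se <- sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - 8), 3 * se + 1e-9)
})

test_that("spike time and height statistics honour the profile", {
  pr <- generator_profile(spike_height_mean = 20, spike_height_cv = 0.2,
                          firing_rate = 10, refractory_ms = 8,
                          stim_rate_multiplier = 1)
  hs <- unlist(lapply(1:10, function(s)
    generate_trace(pr, seed = 400 + s)$ground_truth$heights))
  expect_gt(length(hs), 50)
  cv <- sd(hs) / mean(hs)
  expect_lt(abs(cv - 0.2) / 0.2, 0.2)
  gts <- generate_trace(pr, seed = 1)$ground_truth$spike_times
  expect_true(all(diff(gts) >= 0.008))     # refractory respected
})

test_that("rate zero gives a spikeless trace", {
  out <- generate_trace(generator_profile(firing_rate = 0), seed = 5)
  expect_length(out$ground_truth$spike_times, 0L)
  expect_equal(nrow(detect_spikes(out$trace)), 0L)
})

test_that("the rendered waveform has the drawn height and half-height width", {
  pr <- clean_profile(firing_rate = 2, spike_height_mean = 20,
                      spike_width_mean = 1.6)
  out <- generate_trace(pr, seed = 6)
  sp <- detect_spikes(out$trace)
  gt <- out$ground_truth
  expect_equal(nrow(sp), length(gt$spike_times))
  expect_lt(max(abs(sp$height - gt$heights) / gt$heights), 0.05)
  expect_lt(mean(abs(sp$width - gt$widths)), 0.25)   # quantised to 0.1 ms
})

test_that("planted feature datasets have informative structure", {
  ds <- planted_feature_dataset(n = 90, seed = 2)
  expect_equal(dim(ds$x), c(90L, 16L))
  expect_equal(attr(ds, "informative"), 1:3)
  # informative features separate their class from the rest
  m1 <- mean(ds$x[ds$y == "bad", 1]) - mean(ds$x[ds$y != "bad", 1])
  expect_gt(m1, 1.5)
  expect_lt(abs(mean(ds$x[, 10])), 0.5)
})

test_that("degenerate identical profiles give chance-level classification", {
  pr <- default_profiles()
  pr$intermediate <- pr$good; pr$bad <- pr$good
  pr$intermediate$label <- "intermediate"; pr$bad$label <- "bad"
  corpus <- generate_dataset(pr, counts = c(good = 20, intermediate = 20,
                                            bad = 20), seed = 17)
  tab <- extract_feature_table(corpus$traces)
  ds <- labeled_dataset(tab, corpus$labels)
  cv <- repeated_kfold_cv(ds, k = 10, repeats = 5, seed = 3)
  expect_lt(abs(cv$mean - 1 / 3), 0.15)
})
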