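test_that("moving average preserves constants and affine interiors", {
  expect_equal(moving_average(rep(3.2, 50), 1000, 3), rep(3.2, 50))
  # 3-point mean with edge shrink (window_ms = 2 at 1 kHz -> L = 1)
  expect_equal(moving_average(c(0, 0, 3, 0, 0), 1000, 2), c(0, 1, 1, 1, 0))
  ramp <- seq(0, 10, length.out = 101)
  sm <- moving_average(ramp, 1000, 3)
  expect_equal(sm[3:99], ramp[3:99])
  expect_error(moving_average(1:3, 10000, 3), "shorter than the filter")
})

test_that("derivative is the forward difference in mV/ms", {
  expect_equal(trace_derivative(c(0, 1), 1000), 1)
  expect_equal(trace_derivative(rep(5, 10), 20000), rep(0, 9))
  expect_equal(trace_derivative(seq(0, 38, by = 2), 10000), rep(20, 19))
  expect_error(trace_derivative(1, 1000), "at least 2")
})

test_that("thresholds use 3x the interpolated 80th/20th percentiles", {
  th <- detection_thresholds(seq(-1, 1, length.out = 201))
  expect_equal(th$up, 1.8)
  expect_equal(th$down, -1.8)
  expect_false(th$degenerate)
  # brute-force linear-interpolation percentile: h = (n-1)p + 1 = 80.2
  th2 <- detection_thresholds(as.numeric(1:100))
  expect_equal(th2$up, 3 * (80 + 0.2 * (81 - 80)))
  expect_true(detection_thresholds(rep(0, 50))$degenerate)
  # monotone decreasing trace: wrong-signed thresholds
  expect_true(detection_thresholds(rep(-1, 50))$degenerate)
})

test_that("candidate events need an up run and a nearby down run", {
  # 1 kHz => t_spike_max window is 3 derivative samples past the up run
  th <- list(up = 0.5, down = -0.5, degenerate = FALSE)
  d <- rep(0, 30)
  d[10:12] <- 1; d[14:16] <- -1
  ev <- find_candidate_events(d, th, 1000)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$onset, 10L)
  expect_equal(ev$offset, 15L)   # last sub-threshold derivative in window
  # down run too late (> 3 ms after the up run ends)
  d2 <- rep(0, 40); d2[10:12] <- 1; d2[18:20] <- -1
  expect_equal(nrow(find_candidate_events(d2, th, 1000)), 0L)
  # two events stay separate and ordered
  d3 <- rep(0, 60); d3[10:12] <- 1; d3[13:15] <- -1
  d3[40:42] <- 1; d3[43:45] <- -1
  ev3 <- find_candidate_events(d3, th, 1000)
  expect_equal(ev3$onset, c(10L, 40L))
  expect_true(all(ev3$offset[-nrow(ev3)] < ev3$onset[-1]))
})

test_that("event characterisation measures height, width and slopes", {
  # sharp triangle: rise 2 samples at 1 kHz, amplitude 10 over baseline -60
  tr <- triangle_trace(n = 200, peaks = 100, rise = 2, amp = 10,
                       baseline = -60)
  filt <- moving_average(tr$samples, 1000, 3)
  der <- trace_derivative(filt, 1000)
  ev <- characterize_event(tr, filt, der, onset = 96L, offset = 104L)
  expect_equal(ev$v_max, -50)
  expect_equal(ev$baseline, -60)        # baseline windows on the flat segment
  expect_equal(ev$height, 10)
  # half height -50 - 5 = -55; nearest samples strictly below are at +/-2 ms
  expect_equal(ev$width, 4)
  expect_equal(ev$t_spike, 99 / 1000)
})

test_that("eligibility keeps tall spikes with half-height dips", {
  # two-pass 95th-percentile rule on constructed candidate heights
  cand <- data.frame(
    t_spike = seq(0.1, 1.5, length.out = 15),
    v_max = 0, baseline = 0,
    height = c(rep(20, 10), rep(1, 5)),
    width = 2, max_slope = 5, min_slope = -5,
    onset_index = 1, offset_index = 10,
    peak_index = round(seq(0.1, 1.5, length.out = 15) * 1000),
    j_before = round(seq(0.1, 1.5, length.out = 15) * 1000) - 2,
    j_after = round(seq(0.1, 1.5, length.out = 15) * 1000) + 2)
  kept <- eligibility_filter(cand, 1000)
  expect_equal(nrow(kept), 10L)
  expect_true(all(kept$height == 20))
  # a single candidate passes rule (ii) against its own percentile
  expect_equal(nrow(eligibility_filter(cand[1, ], 1000)), 1L)
  # rule (i): no return below half height after the peak
  cand$j_after[1:10] <- NA
  expect_equal(nrow(eligibility_filter(cand, 1000)), 0L)
})

test_that("detector finds a clean regular train and nothing on flats", {
  set.seed(123)
  flat <- ephys_trace(rep(-60, 5000) + rnorm(5000, 0, 1e-3), 10000)
  expect_equal(nrow(detect_spikes(flat)), 0L)

  pr <- clean_profile(firing_rate = 4, duration_s = 5)
  out <- generate_trace(pr, seed = 42)
  sp <- detect_spikes(out$trace)
  gt <- out$ground_truth$spike_times
  expect_equal(nrow(sp), length(gt))
  expect_equal(match_spikes(sp$t_spike, gt), length(gt))
})

test_that("secondary small spikes below half the height percentile are dropped", {
  pr <- bad_scenario_profile("few_large_with_secondary")
  out <- generate_trace(pr, seed = 5)
  sp <- detect_spikes(out$trace)
  expect_gt(nrow(sp), 0)
  # only the 30 mV population survives the height rule
  expect_true(all(sp$height > 15))
  expect_equal(match_spikes(sp$t_spike, out$ground_truth$spike_times),
               nrow(sp))
})

test_that("detection is scale- and shift-invariant", {
  out <- generate_trace(generator_profile(noise_sd = 0.3), seed = 9)
  tr <- out$trace
  base <- detect_spikes(tr)
  for (k in c(0.25, 5)) {
    scaled <- ephys_trace(tr$samples * k, tr$sampling_rate)
    sp <- detect_spikes(scaled)
    expect_equal(sp$peak_index, base$peak_index)
    expect_equal(sp$height, base$height * k)
    expect_equal(sp$width, base$width)
  }
  shifted <- ephys_trace(tr$samples + 17.3, tr$sampling_rate)
  sh <- detect_spikes(shifted)
  expect_equal(sh$t_spike, base$t_spike)
  expect_equal(sh$height, base$height)
  expect_equal(sh$width, base$width)
  expect_equal(sh$max_slope, base$max_slope)
  # determinism
  expect_identical(detect_spikes(tr), base)
})
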