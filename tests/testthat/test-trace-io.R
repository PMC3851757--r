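test_that("one-column traces apply the gain and read the header rate", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# id: t1", "# sampling_rate: 10000", "voltage_mV",
               "0.0", "1.0", "2.0"), path)
  tr <- read_trace(path, gain = 2)
  expect_equal(tr$samples, c(0, 2, 4))
  expect_equal(tr$sampling_rate, 10000)
  expect_equal(tr$id, "t1")
})

test_that("two-column traces infer the rate from the median time step", {
  path <- withr::local_tempfile(fileext = ".csv")
  tt <- seq(0, 0.0019, by = 1e-4)
  writeLines(c("time_s,voltage_mV",
               sprintf("%.6f,%.3f", tt, sin(tt * 100))), path)
  tr <- read_trace(path)
  expect_equal(tr$sampling_rate, 10000, tolerance = 1e-9)
})

test_that("malformed and non-uniform files raise informative errors", {
  p1 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# sampling_rate: 1000", "voltage_mV", "1.0", "oops", "2.0"), p1)
  expect_error(read_trace(p1), "parse error.*line 4")
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,voltage_mV", "0.0,1", "0.001,2", "0.0021,3",
               "0.004,4"), p2)
  expect_error(read_trace(p2), "sampling error")
  expect_error(read_trace(withr::local_tempfile(fileext = ".csv")),
               "not found")
})

test_that("traces round-trip through write_trace/read_trace", {
  set.seed(7)
  tr <- ephys_trace(round(rnorm(20, -60, 5), 6), 5000, id = "rt",
                    stim_onset = 1.5, stim_duration = 0.5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  back <- read_trace(path)
  expect_equal(back$samples, tr$samples, tolerance = 1e-9)
  expect_equal(back$sampling_rate, tr$sampling_rate)
  expect_equal(back$id, "rt")
  expect_equal(back$stim_onset, 1.5)
  # writing the re-read trace reproduces the file byte for byte
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_trace(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("gain application is linear", {
  path <- withr::local_tempfile(fileext = ".csv")
  set.seed(11)
  write_trace(ephys_trace(rnorm(30), 1000), path)
  g1 <- read_trace(path, gain = 1)
  g3 <- read_trace(path, gain = 3.5)
  expect_equal(g3$samples, g1$samples * 3.5)
})

test_that("label tables encode, validate and round-trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,label", "r1,GOOD"), path)
  labs <- read_labels(path)
  expect_equal(unname(attr(labs, "encoded")["r1"]), 1)

  writeLines(c("id,label", "r1,good", "r1,bad"), path)
  expect_error(read_labels(path), "duplicate")
  writeLines(c("id,label", "r1,great"), path)
  expect_error(read_labels(path), "unknown quality label")

  writeLines(c("id,label", "r1,bad", "r2,intermediate", "r3,good"), path)
  labs <- read_labels(path)
  expect_equal(unname(attr(labs, "encoded")), c(-1, 0, 1))
  expect_equal(decode_labels(c(-1, 0, 1)), c("bad", "intermediate", "good"))

  p2 <- withr::local_tempfile(fileext = ".csv")
  write_labels(labs, p2)
  expect_equal(read_labels(p2), read_labels(path))
})

test_that("feature tables round-trip with the canonical 16 columns", {
  set.seed(3)
  tab <- data.frame(id = sprintf("r%d", 1:5))
  for (f in feature_names()) tab[[f]] <- round(rnorm(5), 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_features(tab, path)
  back <- read_features(path)
  expect_equal(back, tab, tolerance = 1e-10)
  expect_error(write_features(tab[, -3], path), "lacks column")
})
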