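test_that("canonical subset ranks match the lexicographic enumeration", {
  # oracle: position within utils::combn, which enumerates lexicographically
  for (k in c(2, 3)) {
    subs <- utils::combn(6, k)
    for (j in seq_len(ncol(subs)))
      expect_equal(subset_rank(subs[, j], p = 6), j - 1L)
  }
  expect_equal(subset_rank(1:6, p = 16), 0L)
  expect_equal(subset_rank(11:16, p = 16), choose(16, 6) - 1L)
  expect_equal(subset_name(11:16, p = 16), "6-8007")
  # spot check against the full size-6 enumeration of 16 features
  subs6 <- utils::combn(16, 6)
  expect_equal(subs6[, subset_rank(c(1, 4, 8, 12, 13, 16), 16) + 1L],
               c(1, 4, 8, 12, 13, 16))
})

test_that("the top10 rule takes the 10 best or the best 10%, at least one", {
  set.seed(31)
  expect_length(top10_group(runif(8008)), 10L)
  expect_length(top10_group(runif(16)), 1L)
  expect_length(top10_group(runif(120)), 10L)
  expect_length(top10_group(runif(35)), 3L)
  # ties broken by the lower canonical rank (m = 3 for N = 30)
  means <- c(rep(0.9, 4), runif(26, 0, 0.5))
  expect_equal(top10_group(means), c(1L, 2L, 3L))
})

test_that("wrapper search satisfies its ordering and counting invariants", {
  set.seed(41)
  x <- cbind(matrix(rnorm(60 * 2), 60, 2) +
               2.5 * c(rep(0, 20), rep(1, 20), rep(2, 20)),
             matrix(rnorm(60 * 2), 60, 2))
  rownames(x) <- sprintf("w%02d", 1:60)
  y <- setNames(rep(c("bad", "intermediate", "good"), each = 20), rownames(x))
  ds <- labeled_dataset(x, y)
  wr <- wrapper_search(ds, sizes = 1:4, seed = 5, repeats = 3)
  for (s in 1:4) {
    ps <- wr$per_size[[as.character(s)]]
    expect_equal(nrow(ps$results), choose(4, s))
    expect_lte(ps$worst$mean, ps$median)
    expect_lte(ps$median, ps$best$mean)
    expect_lte(ps$top10$mean, ps$best$mean)
    expect_true(all(diff(ps$top10$means) <= 0))
  }
  wr2 <- wrapper_search(ds, sizes = 1:4, seed = 5, repeats = 3)
  expect_equal(wr$per_size, wr2$per_size)

  # informative pair (features 1:2) dominates the noise features
  use <- feature_use_statistics(wr)
  expect_gt(sum(use["2", 1:2]), sum(use["2", 3:4]))
})

test_that("wrapper results survive a JSON round trip", {
  ds <- blob_dataset(n_per = 10, sep = 6, seed = 8)
  wr <- wrapper_search(ds, sizes = 1:2, seed = 2, repeats = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_wrapper_result(wr, path)
  back <- read_wrapper_result(path)
  expect_equal(back$per_size[["2"]]$best$subset,
               wr$per_size[["2"]]$best$subset)
  expect_equal(back$per_size[["1"]]$top10$mean, wr$per_size[["1"]]$top10$mean)
})

test_that("majority voting follows plurality with best-rank tie-breaks", {
  x <- matrix(0, 1, 2)
  ten_good <- replicate(10, fake_model("good"), simplify = FALSE)
  expect_equal(vote_predict(ten_good, x), "good")
  mixed <- c(replicate(6, fake_model("good"), simplify = FALSE),
             replicate(4, fake_model("bad"), simplify = FALSE))
  expect_equal(vote_predict(mixed, x), "good")
  # 5-5 tie: the best-ranked member votes good
  tie <- c(list(fake_model("good")), replicate(5, fake_model("bad"), simplify = FALSE),
           replicate(4, fake_model("good"), simplify = FALSE))
  expect_equal(vote_predict(tie, x), "good")
})

test_that("feature-use statistics count top10 membership", {
  ds <- blob_dataset(n_per = 10, sep = 6, seed = 9)
  wr <- wrapper_search(ds, sizes = c(1, 4), seed = 3, repeats = 2)
  use <- feature_use_statistics(wr)
  expect_equal(unname(use["4", ]), rep(1L, 4))  # single full set
  expect_equal(sum(use["1", ]), 1L)             # m = 1 for 4 size-1 choices
})
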