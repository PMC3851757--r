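#' Canonical rank and name of a feature set
#'
#' Feature sets are non-empty sorted subsets of `1..p`.  The canonical rank
#' is the 0-based position of the subset in lexicographic order among all
#' subsets of its size (the order produced by `utils::combn`), and the
#' canonical name is `"<size>-<rank>"`, e.g. the 2134th 6-feature choice of
#' 16 is `"6-2133"`.
#'
#' @param subset integer vector of feature indices.
#' @param p total number of features.
#' @return `subset_rank`: 0-based integer rank; `subset_name`: character.
#' @export
subset_rank <- function(subset, p = 16) {
  s <- sort(unique(as.integer(subset)))
  k <- length(s)
  stopifnot(k >= 1L, s[1L] >= 1L, s[k] <= p)
  rank <- 0
  prev <- 0L
  for (i in seq_len(k)) {
    lo <- prev + 1L
    if (s[i] > lo) {
      for (v in lo:(s[i] - 1L)) rank <- rank + choose(p - v, k - i)
    }
    prev <- s[i]
  }
  as.integer(rank)
}

#' @rdname subset_rank
#' @export
subset_name <- function(subset, p = 16) {
  sprintf("%d-%d", length(unique(subset)), subset_rank(subset, p))
}

#' The top10 group of feature sets
#'
#' The 10 best-performing feature sets of one size, or, when fewer than 100
#' sets exist, the best 10% of them -- but always at least one:
#' `m = min(10, max(1, floor(0.1 * N)))`.  Ties in the mean CV fraction are
#' broken by the lower canonical rank.
#'
#' @param means numeric vector of mean CV fractions, one per feature set.
#' @param ranks canonical ranks (used as the deterministic tie-break).
#' @return integer indices of the selected sets, best first.
#' @export
top10_group <- function(means, ranks = seq_along(means) - 1L) {
  n <- length(means)
  stopifnot(n >= 1L, length(ranks) == n)
  m <- min(10L, max(1L, floor(0.1 * n)))
  utils::head(order(-means, ranks), m)
}

#' Exhaustive wrapper feature selection
#'
#' Evaluates every feature subset of each requested size with repeated
#' k-fold cross-validation and records, per size, the full results together
#' with the best, worst and median performance and the top10 group.  With
#' `sizes = 1:16` this enumerates all `2^16 - 1 = 65535` subsets; desk-scale
#' runs reduce `repeats` and/or `sizes`.
#'
#' @param dataset a [labeled_dataset()].
#' @param sizes subset sizes to explore.
#' @param config [svm_config()].
#' @param seed RNG seed; the CV splits of successive subsets are drawn from
#'   one seeded stream, so the whole search is reproducible.
#' @param repeats CV repeats per subset (the full-scale setting is 50).
#' @param k CV folds.
#' @param verbose log progress per size.
#' @return object of class `wrapper_result`: per size a data.frame
#'   (`rank`, `name`, `subset`, `mean`) plus `best`, `worst`, `median`,
#'   `top10` summaries.
#' @export
wrapper_search <- function(dataset, sizes = 1:16, config = svm_config(),
                           seed = 1, repeats = 5, k = 10, verbose = FALSE) {
  p <- ncol(dataset$x)
  y <- dataset$y
  cc <- class_codes(y)
  n <- nrow(dataset$x)
  per_size <- list()
  with_seed(seed, {
    for (s in sizes) {
      subs <- utils::combn(p, s)
      nsub <- ncol(subs)
      means <- numeric(nsub)
      for (j in seq_len(nsub)) {
        folds <- make_folds(n, k, repeats)
        preds <- cv_predict_folds(dataset$x[, subs[, j], drop = FALSE],
                                  y, folds, config)
        means[j] <- mean(colMeans(preds == y))
      }
      ranks <- seq_len(nsub) - 1L   # combn enumerates in lexicographic order
      top_idx <- top10_group(means, ranks)
      best_idx <- top_idx[1L]
      worst_idx <- order(means, ranks)[1L]
      res <- data.frame(rank = ranks,
                        name = sprintf("%d-%d", s, ranks),
                        subset = apply(subs, 2L, paste, collapse = ","),
                        mean = means, stringsAsFactors = FALSE)
      per_size[[as.character(s)]] <- list(
        size = s, results = res,
        best = list(subset = subs[, best_idx], mean = means[best_idx],
                    name = res$name[best_idx]),
        worst = list(subset = subs[, worst_idx], mean = means[worst_idx]),
        median = stats::median(means),
        top10 = list(members = lapply(top_idx, function(i) subs[, i]),
                     names = res$name[top_idx],
                     means = means[top_idx],
                     mean = mean(means[top_idx])))
      if (verbose)
        qc_log("wrapper size ", s, ": ", nsub, " subsets, best ",
               round(means[best_idx], 3), verbose = TRUE)
    }
  })
  structure(list(sizes = sizes, per_size = per_size, repeats = repeats,
                 k = k, seed = seed, p = p),
            class = "wrapper_result")
}

#' @export
print.wrapper_result <- function(x, ...) {
  cat("<wrapper_result>\n size  n_subsets   worst  median    best   top10\n")
  for (s in x$sizes) {
    ps <- x$per_size[[as.character(s)]]
    cat(sprintf(" %4d %10d  %6.3f  %6.3f  %6.3f  %6.3f\n", s,
                nrow(ps$results), ps$worst$mean, ps$median, ps$best$mean,
                ps$top10$mean))
  }
  invisible(x)
}

#' Save / load a wrapper result as JSON
#' @param wr a `wrapper_result`.
#' @param path JSON path.
#' @param full store the complete per-subset score tables (can be large).
#' @return `write_wrapper_result`: `path` invisibly; `read_wrapper_result`:
#'   a list mirroring the `wrapper_result` summaries.
#' @export
write_wrapper_result <- function(wr, path, full = FALSE) {
  doc <- list(sizes = wr$sizes, repeats = wr$repeats, k = wr$k,
              seed = wr$seed, p = wr$p,
              per_size = lapply(wr$per_size, function(ps) {
                out <- list(size = ps$size,
                            best = ps$best, worst = ps$worst,
                            median = ps$median, top10 = ps$top10)
                if (full) out$results <- ps$results
                out
              }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_wrapper_result
#' @export
read_wrapper_result <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  doc$per_size <- lapply(doc$per_size, function(ps) {
    ps$top10$members <- lapply(ps$top10$members, as.integer)
    ps$best$subset <- as.integer(ps$best$subset)
    ps$worst$subset <- as.integer(ps$worst$subset)
    ps
  })
  class(doc) <- "wrapper_result"
  doc
}

#' Majority-vote prediction over an ensemble of classifiers
#'
#' Each member predicts every row; the plurality label wins.  Vote ties are
#' broken in favour of the member with the best cross-validation rank
#' (position in `models`, best first) among those voting for a tied label.
#'
#' @param models list of `qc_svm` models ordered best first.
#' @param newdata feature matrix (full 16 columns; each member applies its
#'   own feature subset).
#' @return character vector of voted labels.
#' @export
vote_predict <- function(models, newdata) {
  stopifnot(length(models) >= 1L)
  newdata <- as.matrix(newdata)
  votes <- vapply(models, function(m) predict(m, newdata),
                  character(nrow(newdata)))
  votes <- matrix(votes, nrow = nrow(newdata))
  apply_vote <- function(row) {
    tab <- table(row)
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1L) return(top)
    # earliest (= best-ranked) member that voted for one of the tied labels
    row[match(TRUE, row %in% top)]
  }
  apply(votes, 1L, apply_vote)
}

# evaluate every subset of the given sizes by (deterministic) k-fold CV on
# (x, y); returns data.frame(size, rank, mean) plus a list of subsets
evaluate_all_subsets <- function(x, y, sizes, config, inner_k, inner_repeats,
                                 seed) {
  p <- ncol(x)
  n <- nrow(x)
  rows <- list(); subsets <- list(); ii <- 0L
  with_seed(seed, {
    for (s in sizes) {
      subs <- utils::combn(p, s)
      for (j in seq_len(ncol(subs))) {
        folds <- if (inner_k >= n) matrix(seq_len(n), n, 1L)
                 else make_folds(n, inner_k, inner_repeats)
        preds <- cv_predict_folds(x[, subs[, j], drop = FALSE], y, folds, config)
        ii <- ii + 1L
        subsets[[ii]] <- subs[, j]
        rows[[ii]] <- data.frame(size = s, rank = j - 1L,
                                 mean = mean(colMeans(preds == y)))
      }
    }
  })
  list(table = do.call(rbind, rows), subsets = subsets)
}

#' Two-stage leave-one-out evaluation with inner wrapper selection
#'
#' The outer loop leaves one recording out; on the remaining `n - 1`
#' recordings a full wrapper search (leave-one-out CV by default) ranks all
#' feature subsets of the requested sizes, the `m` best subsets are selected
#' -- either regardless of size (`mode = "overall"`) or per size -- and a
#' classifier per subset is trained on all `n - 1` recordings.  The held-out
#' recording is then predicted by each member and by majority vote.  The
#' held-out recording never influences feature choice or training, so the
#' resulting accuracy is free of wrapper selection bias.
#'
#' @param dataset a [labeled_dataset()].
#' @param config [svm_config()].
#' @param sizes subset sizes explored in the inner wrapper, or `"all"` for
#'   `1:p` ("reduced scale" defaults; the full procedure uses all sizes).
#' @param m ensemble size (the 10 best subsets).
#' @param mode `"overall"` selects the `m` best subsets regardless of size
#'   (the default); `"per_size"` repeats the whole procedure once per size
#'   with the ensemble drawn from that size only, returning one result per
#'   size.
#' @param inner_k inner CV folds; `Inf` (default) means leave-one-out.
#' @param inner_repeats inner CV repeats (only used when `inner_k < n - 1`).
#' @param seed seed for any randomised inner splits.
#' @param verbose log progress.
#' @return list of class `loo2_result`: per-recording data.frame
#'   (`id`, `truth`, `voted`, `member_correct`), overall `accuracy`, the
#'   consistency histogram counts (`consistency`, 11 bins 0..100%), the
#'   selected subsets per outer fold and the inner training ids per fold.
#' @export
two_stage_loo <- function(dataset, config = svm_config(), sizes = 1:2,
                          m = 10, mode = c("overall", "per_size"),
                          inner_k = Inf, inner_repeats = 1,
                          seed = 1, verbose = FALSE) {
  mode <- match.arg(mode)
  if (identical(sizes, "all")) sizes <- seq_len(ncol(dataset$x))
  if (mode == "per_size") {
    out <- lapply(sizes, function(s)
      two_stage_loo(dataset, config, sizes = s, m = m, mode = "overall",
                    inner_k = inner_k, inner_repeats = inner_repeats,
                    seed = seed, verbose = verbose))
    names(out) <- as.character(sizes)
    return(out)
  }
  x <- dataset$x; y <- dataset$y; n <- nrow(x)
  stopifnot(n >= 3L)
  ids <- dataset$ids
  res <- vector("list", n)
  chosen <- vector("list", n)
  inner_ids <- vector("list", n)
  for (i in seq_len(n)) {
    xt <- x[-i, , drop = FALSE]; yt <- y[-i]
    inner_ids[[i]] <- ids[-i]
    ev <- evaluate_all_subsets(xt, yt, sizes, config,
                               inner_k = min(inner_k, nrow(xt)),
                               inner_repeats = inner_repeats,
                               seed = derive_seed(seed, i))
    tab <- ev$table
    # rank regardless of size: mean desc, then smaller size, then lower rank
    ord <- order(-tab$mean, tab$size, tab$rank)
    sel <- utils::head(ord, max(1L, min(m, length(ord))))
    members <- ev$subsets[sel]
    chosen[[i]] <- lapply(seq_along(sel), function(j)
      list(subset = members[[j]], mean = tab$mean[sel[j]],
           name = sprintf("%d-%d", tab$size[sel[j]], tab$rank[sel[j]])))
    models <- lapply(members, function(fs)
      train_svm(xt, yt, config, features = fs))
    newx <- x[i, , drop = FALSE]
    member_preds <- vapply(models, function(mo) predict(mo, newx), character(1L))
    voted <- vote_predict(models, newx)
    res[[i]] <- data.frame(id = ids[i], truth = y[i], voted = voted,
                           member_correct = mean(member_preds == y[i]),
                           stringsAsFactors = FALSE)
    if (verbose && i %% 10L == 0L)
      qc_log("two_stage_loo: ", i, "/", n, verbose = TRUE)
  }
  pred <- do.call(rbind, res)
  rownames(pred) <- NULL
  # 10 bins [0,10)% ... [90,100]% of per-recording member agreement
  breaks <- seq(0, 1, by = 0.1)
  bin <- pmin(floor(pred$member_correct * 10) + 1L, 10L)
  structure(list(predictions = pred,
                 accuracy = mean(pred$voted == pred$truth),
                 consistency = stats::setNames(tabulate(bin, 10L),
                   sprintf("[%g,%g%s", breaks[-11] * 100, breaks[-1] * 100,
                           c(rep(")", 9), "]"))),
                 chosen_subsets = chosen, inner_ids = inner_ids,
                 sizes = sizes, m = m, seed = seed),
            class = "loo2_result")
}

#' Cross-dataset evaluation of wrapper-selected classifiers
#'
#' For every subset size of a wrapper result obtained on the training
#' dataset: train on the full training set with the best subset and with
#' every top10 member, then score on the untouched test set -- individually
#' ("best across", "top10 across" mean) and as a majority-voting ensemble
#' ("top10 voting").
#'
#' @param train_dataset,test_dataset [labeled_dataset()]s sharing the
#'   feature schema.
#' @param wrapper_result a [wrapper_search()] result on `train_dataset`.
#' @param config [svm_config()].
#' @param merge also report 2-class (good vs unacceptable) fractions.
#' @return data.frame with one row per size: `cv_best`, `cv_top10`,
#'   `across_best`, `across_top10`, `across_voting` (and `_2class` variants
#'   when `merge`).
#' @export
cross_dataset_eval <- function(train_dataset, test_dataset, wrapper_result,
                               config = svm_config(), merge = TRUE) {
  if (ncol(train_dataset$x) != ncol(test_dataset$x))
    stop("train and test datasets have different feature schemas")
  yte <- test_dataset$y
  rows <- lapply(wrapper_result$sizes, function(s) {
    ps <- wrapper_result$per_size[[as.character(s)]]
    best_model <- train_svm(train_dataset$x, train_dataset$y, config,
                            features = ps$best$subset)
    best_pred <- predict(best_model, test_dataset$x)
    members <- lapply(ps$top10$members, function(fs)
      train_svm(train_dataset$x, train_dataset$y, config, features = fs))
    member_preds <- vapply(members, function(m) predict(m, test_dataset$x),
                           character(nrow(test_dataset$x)))
    member_preds <- matrix(member_preds, nrow = nrow(test_dataset$x))
    voted <- vote_predict(members, test_dataset$x)
    out <- data.frame(
      size = s,
      cv_best = ps$best$mean,
      cv_top10 = ps$top10$mean,
      across_best = mean(best_pred == yte),
      across_top10 = mean(colMeans(member_preds == yte)),
      across_voting = mean(voted == yte))
    if (merge) {
      ym <- merge_classes(yte)
      out$across_best_2class <- mean(merge_classes(best_pred) == ym)
      out$across_voting_2class <- mean(merge_classes(voted) == ym)
    }
    out
  })
  do.call(rbind, rows)
}
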