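#' Per-class feature histograms
#'
#' For each feature, 20 equal bins spanning the pooled 5th-95th percentile
#' range (extreme outliers are excluded from binning); counts are normalised
#' within each class so each class histogram reports relative occurrence and
#' sums to 1.
#'
#' @param features feature data.frame (with `id`) or matrix.
#' @param labels labels aligned with the rows.
#' @param bins number of bins.
#' @return list per feature with `breaks` and a class x bins matrix
#'   `density` of relative occurrences.
#' @export
feature_histograms <- function(features, labels, bins = 20) {
  ds <- labeled_dataset(features, labels)
  out <- list()
  for (j in seq_len(ncol(ds$x))) {
    v <- ds$x[, j]
    rng <- pctl(v, c(0.05, 0.95))
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
    breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
    classes <- sort(unique(ds$y))
    dens <- matrix(0, length(classes), bins,
                   dimnames = list(classes, NULL))
    for (cl in classes) {
      vv <- v[ds$y == cl]
      vv <- vv[vv >= rng[1] & vv <= rng[2]]
      if (!length(vv)) next
      bin <- pmin(pmax(findInterval(vv, breaks, rightmost.closed = TRUE), 1L),
                  bins)
      dens[cl, ] <- tabulate(bin, bins) / length(vv)
    }
    out[[colnames(ds$x)[j]]] <- list(breaks = breaks, density = dens)
  }
  out
}

#' Pairwise Kolmogorov-Smirnov tests with Bonferroni correction
#'
#' Two-sample KS tests for every feature and class pair; the Bonferroni
#' family is all features x pairs tests (48 for 16 features and 3 classes).
#' Class pairs with fewer than 2 observations on either side are skipped and
#' reported as `NA`.
#'
#' @param features feature data.frame or matrix.
#' @param labels labels aligned with the rows.
#' @param alpha significance levels to flag.
#' @return data.frame with `feature`, `pair`, `statistic`, `p_value`,
#'   `p_bonferroni` and one logical flag column per `alpha`.
#' @export
ks_bonferroni <- function(features, labels, alpha = c(0.05, 0.01)) {
  ds <- labeled_dataset(features, labels)
  classes <- sort(unique(ds$y))
  pairs <- utils::combn(classes, 2L)
  rows <- list()
  for (j in seq_len(ncol(ds$x))) {
    for (q in seq_len(ncol(pairs))) {
      a <- ds$x[ds$y == pairs[1L, q], j]
      b <- ds$x[ds$y == pairs[2L, q], j]
      if (length(a) < 2L || length(b) < 2L) {
        rows[[length(rows) + 1L]] <- data.frame(
          feature = colnames(ds$x)[j],
          pair = paste(pairs[, q], collapse = " vs "),
          statistic = NA_real_, p_value = NA_real_)
        next
      }
      kt <- suppressWarnings(stats::ks.test(a, b))
      rows[[length(rows) + 1L]] <- data.frame(
        feature = colnames(ds$x)[j],
        pair = paste(pairs[, q], collapse = " vs "),
        statistic = unname(kt$statistic), p_value = kt$p.value)
    }
  }
  out <- do.call(rbind, rows)
  family <- sum(!is.na(out$p_value))
  out$p_bonferroni <- pmin(out$p_value * family, 1)
  for (a in alpha)
    out[[sprintf("sig_%g", a)]] <- !is.na(out$p_bonferroni) & out$p_bonferroni < a
  attr(out, "family_size") <- family
  out
}

#' PCA projection of the feature table
#'
#' Features are standardised (eigen-decomposition of the correlation
#' matrix, appropriate for incommensurate units); returns the scores on the
#' first two principal components and all variance fractions.
#'
#' @param features feature data.frame or matrix (>= 3 rows, >= 2 columns).
#' @return list with `scores` (n x 2), `variance_fractions` and the full
#'   `rotation` of the two leading components.
#' @export
pca_projection <- function(features) {
  x <- if (is.data.frame(features))
    as.matrix(features[, setdiff(names(features), "id"), drop = FALSE])
  else as.matrix(features)
  if (nrow(x) < 3L) stop("PCA needs at least 3 recordings")
  if (ncol(x) < 2L) stop("PCA needs at least 2 features")
  sds <- apply(x, 2L, stats::sd)
  sds[!is.finite(sds) | sds <= 0] <- 1
  pc <- stats::prcomp(x, center = TRUE, scale. = sds)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, 1:2, drop = FALSE],
       variance_fractions = vf,
       rotation = pc$rotation[, 1:2, drop = FALSE])
}

#' Chance levels of a labelled dataset
#'
#' Random guessing (`1/k`), guessing proportional to class abundance
#' (`sum p_i^2`) and always guessing the majority class (`max p_i`).
#'
#' @param labels label vector.
#' @return list with the raw fractions (`random`, `proportional`,
#'   `majority`) and `percent`, the same values in percent rounded to one
#'   decimal (proportional/random) or the nearest integer (majority), the
#'   convention used in reports.
#' @export
chance_levels <- function(labels) {
  y <- decode_labels(labels)
  p <- as.numeric(table(y)) / length(y)
  out <- list(random = 1 / length(p),
              proportional = sum(p^2),
              majority = max(p))
  out$percent <- c(random = round(100 * out$random, 1),
                   proportional = round(100 * out$proportional, 1),
                   majority = round(100 * out$majority))
  out
}

#' Feature-use statistics of the top10 groups
#'
#' How often each feature occurs in the top10 member sets, per subset size.
#'
#' @param wrapper_result a [wrapper_search()] result.
#' @return sizes x features integer matrix of occurrence counts.
#' @export
feature_use_statistics <- function(wrapper_result) {
  p <- wrapper_result$p
  sizes <- wrapper_result$sizes
  counts <- matrix(0L, length(sizes), p,
                   dimnames = list(as.character(sizes),
                                   sprintf("f%02d", seq_len(p))))
  for (i in seq_along(sizes)) {
    members <- wrapper_result$per_size[[as.character(sizes[i])]]$top10$members
    tab <- tabulate(unlist(members), p)
    counts[i, ] <- tab
  }
  counts
}

#' Agreement matrix between prediction sources
#'
#' Pairwise [prediction_correlation()] between two or more aligned label
#' vectors (e.g. different experts and classifiers); diagonal 1.
#'
#' @param predictions named list of label vectors over the same recordings.
#' @return symmetric correlation matrix.
#' @export
agreement_table <- function(predictions) {
  stopifnot(is.list(predictions), length(predictions) >= 2L)
  k <- length(predictions)
  nm <- names(predictions)
  if (is.null(nm)) nm <- paste0("source", seq_len(k))
  n <- unique(vapply(predictions, length, 1L))
  if (length(n) != 1L) stop("prediction vectors must be aligned (equal length)")
  out <- matrix(1, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    out[i, j] <- out[j, i] <-
      prediction_correlation(predictions[[i]], predictions[[j]])
  }
  out
}
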