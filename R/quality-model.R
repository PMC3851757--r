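#' Linear-SVM configuration
#'
#' Cost `C = 512` and a cap of `1e4` learning iterations (coordinate update
#' steps, the iteration unit of the LIBSVM-family solvers) are the package
#' defaults; the dual coordinate-descent solver also takes a stopping
#' tolerance on the projected-gradient spread (0.1, the customary value for
#' dual linear-SVM solvers).  Multiclass problems use one-vs-one voting, and
#' per-feature standardisation is always fitted on training data only.
#'
#' @param C cost parameter, positive.
#' @param max_iter cap on learning iterations (coordinate steps) per
#'   pairwise problem; hitting the cap is logged, the model is still used.
#' @param tol stopping tolerance on the maximal projected gradient.
#' @return list of class `svm_config`.
#' @export
svm_config <- function(C = 512, max_iter = 1e4, tol = 0.1) {
  stopifnot(C > 0, max_iter >= 1, tol > 0)
  structure(list(C = C, max_iter = as.integer(max_iter), tol = tol),
            class = "svm_config")
}

#' Labelled feature dataset
#'
#' Couples a recordings-by-features matrix with quality labels.
#'
#' @param features numeric matrix or a feature data.frame (with `id` column)
#'   as produced by [extract_feature_table()].
#' @param labels labels, named by recording id (character `bad` /
#'   `intermediate` / `good`, or -1/0/+1 numeric); matched to the feature
#'   rows by id when both carry ids.
#' @return list of class `labeled_dataset` with elements `x` (matrix,
#'   rownames = ids), `y` (character labels) and `ids`.
#' @export
labeled_dataset <- function(features, labels) {
  if (is.data.frame(features)) {
    ids <- as.character(features$id)
    x <- as.matrix(features[, setdiff(names(features), "id"), drop = FALSE])
    rownames(x) <- ids
  } else {
    x <- as.matrix(features)
    ids <- rownames(x)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
    rownames(x) <- ids
  }
  y <- decode_labels(labels)
  if (!is.null(names(y))) {
    miss <- setdiff(ids, names(y))
    if (length(miss)) stop("no label for recording(s): ", paste(miss, collapse = ", "))
    y <- y[ids]
  } else if (length(y) != nrow(x)) {
    stop("labels length does not match the number of recordings")
  }
  names(y) <- ids
  structure(list(x = x, y = y, ids = ids), class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset: %d recordings x %d features; %s>\n",
              nrow(x$x), ncol(x$x),
              paste(sprintf("%s=%d", names(table(x$y)), table(x$y)), collapse = ", ")))
  invisible(x)
}

# class codes 0..k-1 ordered by numeric encoding (-1, 0, +1)
class_codes <- function(y) {
  enc <- encode_labels(y)
  classes <- sort(unique(enc))
  list(idx = match(enc, classes) - 1L, classes = classes,
       labels = decode_labels(classes))
}

#' Fit / apply per-feature standardisation
#'
#' Z-scoring with mean and population standard deviation computed on the
#' training matrix; zero-variance features pass through with scale 1.
#'
#' @param x numeric training matrix.
#' @return `standardize_fit`: list of class `qc_scaler` with `center` and
#'   `scale`; `standardize_apply`: the transformed matrix.
#' @export
standardize_fit <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2L, pop_sd)
  scale[!is.finite(scale) | scale <= 0] <- 1
  structure(list(center = center, scale = scale), class = "qc_scaler")
}

#' @rdname standardize_fit
#' @param scaler a `qc_scaler`.
#' @param newx matrix to transform.
#' @export
standardize_apply <- function(scaler, newx) {
  sweep(sweep(as.matrix(newx), 2L, scaler$center, "-"), 2L, scaler$scale, "/")
}

#' Train a linear one-vs-one SVM quality classifier
#'
#' Standardises the training matrix (training statistics only), then fits one
#' linear SVM per class pair with the deterministic dual coordinate-descent
#' solver.  A single-class training set yields a constant model (with a
#' message).
#'
#' @param x numeric matrix (recordings x features) or a `labeled_dataset`.
#' @param y labels (ignored when `x` is a `labeled_dataset`).
#' @param config [svm_config()].
#' @param features optional integer vector of feature columns to use.
#' @return object of class `qc_svm`.
#' @export
train_svm <- function(x, y = NULL, config = svm_config(), features = NULL) {
  if (inherits(x, "labeled_dataset")) { y <- x$y; x <- x$x }
  x <- as.matrix(x)
  if (!is.null(features)) x <- x[, features, drop = FALSE]
  cc <- class_codes(y)
  scaler <- standardize_fit(x)
  xs <- standardize_apply(scaler, x)
  if (length(cc$classes) < 2L) {
    message("single-class training set: constant model for '", cc$labels, "'")
    model <- list(constant = cc$labels[1L])
  } else {
    fit <- .ovo_train_cpp(xs, cc$idx, length(cc$classes),
                          config$C, config$max_iter, config$tol)
    capped <- sum(fit$iterations >= config$max_iter)
    if (capped > 0L)
      qc_log(capped, " pairwise problem(s) hit the iteration cap of ",
             config$max_iter, level = "WARN")
    model <- fit
  }
  structure(list(model = model, scaler = scaler, classes = cc$classes,
                 class_labels = cc$labels, features = features,
                 config = config),
            class = "qc_svm")
}

#' Predict quality labels
#'
#' @param object a `qc_svm` model.
#' @param newdata matrix of feature vectors (all 16 columns, or already
#'   restricted to the model's features when `restrict = FALSE`).
#' @param restrict apply the model's stored feature subset to `newdata`.
#' @param ... unused.
#' @return character vector of predicted labels.
#' @export
predict.qc_svm <- function(object, newdata, restrict = TRUE, ...) {
  x <- as.matrix(newdata)
  if (restrict && !is.null(object$features)) {
    if (ncol(x) >= max(object$features)) x <- x[, object$features, drop = FALSE]
  }
  if (!is.null(object$model$constant))
    return(rep(object$model$constant, nrow(x)))
  xs <- standardize_apply(object$scaler, x)
  idx <- .ovo_predict_cpp(object$model$W, object$model$pairs,
                          object$model$const_vote, length(object$classes), xs)
  object$class_labels[idx + 1L]
}

# fold assignment matrix (n x repeats), fold ids 1..k; every sample left out
# exactly once per repeat
make_folds <- function(n, k, repeats, stratify_y = NULL) {
  stopifnot(n >= k)
  folds <- matrix(0L, n, repeats)
  for (r in seq_len(repeats)) {
    if (is.null(stratify_y)) {
      folds[, r] <- sample(rep(seq_len(k), length.out = n))
    } else {
      f <- integer(n)
      for (cl in unique(stratify_y)) {
        rows <- which(stratify_y == cl)
        f[rows] <- sample(rep(seq_len(k), length.out = length(rows)))
      }
      folds[, r] <- f
    }
  }
  folds
}

# core CV on a prebuilt fold matrix; returns n x repeats predicted labels
cv_predict_folds <- function(x, y, folds, config) {
  cc <- class_codes(y)
  if (length(cc$classes) < 2L) {
    return(matrix(cc$labels[1L], nrow(x), ncol(folds)))
  }
  preds <- .cv_predict_cpp(as.matrix(x), cc$idx, folds, length(cc$classes),
                           config$C, config$max_iter, config$tol)
  matrix(cc$labels[preds + 1L], nrow(preds), ncol(preds))
}

#' Repeated k-fold cross-validation of the quality classifier
#'
#' Random, exhaustive splits: each repeat partitions the recordings into `k`
#' near-equal folds so that every recording is left out exactly once; the
#' fraction of correct predictions is pooled over folds and averaged over
#' repeats.  Standardisation is refitted on every training fold.  Fully
#' reproducible under `seed`.
#'
#' @param dataset a [labeled_dataset()].
#' @param feature_set integer vector of feature indices (default all).
#' @param k number of folds.
#' @param repeats number of independent repetitions.
#' @param config [svm_config()].
#' @param seed RNG seed for the splits.
#' @param stratified use class-stratified splits (off by default).
#' @return list of class `cv_result`: `feature_set`, `per_repeat` fractions,
#'   `mean`, and the n x repeats `predictions` matrix.
#' @export
repeated_kfold_cv <- function(dataset, feature_set = NULL, k = 10,
                              repeats = 50, config = svm_config(),
                              seed = 1, stratified = FALSE) {
  x <- dataset$x
  if (!is.null(feature_set)) x <- x[, feature_set, drop = FALSE]
  n <- nrow(x)
  folds <- with_seed(seed, make_folds(n, k, repeats,
                                      if (stratified) dataset$y else NULL))
  preds <- cv_predict_folds(x, dataset$y, folds, config)
  per_repeat <- colMeans(preds == dataset$y)
  structure(list(feature_set = feature_set, per_repeat = per_repeat,
                 mean = mean(per_repeat), predictions = preds,
                 k = k, repeats = repeats, seed = seed),
            class = "cv_result")
}

#' Merge the three quality classes into two
#'
#' `good` stays `good`; `intermediate` and `bad` become `unacceptable`.
#'
#' @param labels character or -1/0/+1 numeric labels.
#' @return character vector over \{"good", "unacceptable"\}.
#' @export
merge_classes <- function(labels) {
  l <- if (is.numeric(labels)) decode_labels(labels) else tolower(labels)
  out <- ifelse(l == "good", "good", "unacceptable")
  names(out) <- names(labels)
  out
}

#' Correlation between two prediction vectors
#'
#' Pearson correlation of the numeric encodings (bad = -1, intermediate = 0,
#' good = +1).  `NA` (with a warning) when either vector is constant.
#'
#' @param labels_a,labels_b label vectors of equal length (character or
#'   numeric encoding).
#' @return correlation coefficient.
#' @export
prediction_correlation <- function(labels_a, labels_b) {
  a <- encode_labels(labels_a); b <- encode_labels(labels_b)
  stopifnot(length(a) == length(b), length(a) >= 2L)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant prediction vector: correlation undefined")
    return(NA_real_)
  }
  stats::cor(a, b)
}

#' Save / load a trained model as JSON
#'
#' The JSON document records the feature subset, scaler parameters, class
#' list and pairwise SVM weights, so published models are fully transparent.
#'
#' @param model a `qc_svm`.
#' @param path JSON path.
#' @return `write_model`: `path` invisibly; `read_model`: the `qc_svm`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "qc_svm"))
  doc <- list(
    type = "ephysqc_linear_svm_ovo",
    features = model$features,
    classes = model$classes,
    class_labels = model$class_labels,
    scaler = list(center = unname(model$scaler$center),
                  scale = unname(model$scaler$scale)),
    config = unclass(model$config),
    constant = model$model$constant,
    W = if (!is.null(model$model$W)) unclass(model$model$W),
    pairs = if (!is.null(model$model$pairs)) unclass(model$model$pairs),
    const_vote = model$model$const_vote)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- if (!is.null(doc$constant)) list(constant = doc$constant) else
    list(W = as.matrix(doc$W),
         pairs = matrix(as.integer(as.matrix(doc$pairs)), nrow = 2L),
         const_vote = as.integer(doc$const_vote))
  structure(list(model = model,
                 scaler = structure(list(center = doc$scaler$center,
                                         scale = doc$scaler$scale),
                                    class = "qc_scaler"),
                 classes = doc$classes, class_labels = doc$class_labels,
                 features = doc$features,
                 config = do.call(svm_config, as.list(doc$config))),
            class = "qc_svm")
}
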