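#' Recording container
#'
#' An `ephys_trace` holds one intracellular recording: gain-corrected
#' membrane-potential samples (mV), the sampling rate (Hz) and optional
#' stimulus metadata.  Time is measured in seconds from the first sample;
#' samples are indexed 1-based.
#'
#' @param samples numeric vector of membrane potential values in mV (already
#'   gain-corrected), at least 2 samples, all finite.
#' @param sampling_rate sampling rate in Hz, positive.
#' @param id recording identifier.
#' @param gain gain factor that was applied to the raw samples.
#' @param stim_onset,stim_duration optional stimulus metadata, seconds.
#' @return an object of class `ephys_trace`.
#' @export
ephys_trace <- function(samples, sampling_rate, id = "trace", gain = 1,
                        stim_onset = NA_real_, stim_duration = NA_real_) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    stop("a trace needs at least 2 samples")
  if (!all(is.finite(samples)))
    stop("trace '", id, "': non-finite samples after gain correction")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be a single positive number")
  structure(list(id = as.character(id), samples = samples,
                 sampling_rate = as.numeric(sampling_rate),
                 gain = as.numeric(gain),
                 stim_onset = as.numeric(stim_onset),
                 stim_duration = as.numeric(stim_duration)),
            class = "ephys_trace")
}

#' @export
print.ephys_trace <- function(x, ...) {
  cat(sprintf("<ephys_trace '%s': %d samples @ %g Hz (%.3f s), gain %g>\n",
              x$id, length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate, x$gain))
  invisible(x)
}

#' Trace duration in seconds
#' @param trace an [ephys_trace()].
#' @return duration in seconds.
#' @export
trace_duration <- function(trace) length(trace$samples) / trace$sampling_rate

parse_meta <- function(lines) {
  meta <- list()
  for (ln in lines) {
    body <- sub("^#\\s*", "", ln)
    kv <- regmatches(body, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*[:=]\\s*(.*)$", body))[[1]]
    if (length(kv) == 3L) meta[[kv[2]]] <- trimws(kv[3])
  }
  meta
}

#' Read a recording from a plain-text trace file
#'
#' The format is CSV with an optional `#`-prefixed metadata header
#' (`# key: value` lines for `id`, `sampling_rate`, `gain`, `stim_onset`,
#' `stim_duration`), followed by a column-name line and either one column
#' (voltage) or two columns (`time_s,voltage`).  One-column files must carry
#' `sampling_rate` in the header; for two-column files the rate is inferred
#' from the median time step, which must be uniform to within 1%.
#'
#' @param path path of the trace file.
#' @param gain gain factor multiplied into the raw voltages to bring all
#'   recordings to a common mV scale; `NULL` (default) uses the file's
#'   `gain` metadata, falling back to 1.
#' @return an [ephys_trace()].
#' @export
read_trace <- function(path, gain = NULL) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_meta <- grepl("^\\s*#", lines)
  meta <- parse_meta(lines[is_meta])
  body <- lines[!is_meta]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L) stop("malformed trace file (no data rows): ", path)
  # first body line is the column header
  header <- strsplit(body[1L], ",", fixed = TRUE)[[1]]
  ncol_ <- length(header)
  data_lines <- body[-1L]
  parts <- strsplit(data_lines, ",", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) != ncol_)
  if (length(bad))
    stop(sprintf("parse error in '%s' at line %d: expected %d fields",
                 path, which(!is_meta)[bad[1L] + 1L], ncol_))
  mat <- suppressWarnings(
    matrix(as.numeric(unlist(parts)), ncol = ncol_, byrow = TRUE))
  if (anyNA(mat)) {
    bad_row <- which(apply(is.na(mat), 1L, any))[1L]
    stop(sprintf("parse error in '%s' at line %d: non-numeric value",
                 path, which(!is_meta)[bad_row + 1L]))
  }
  if (is.null(gain)) {
    gain <- if (!is.null(meta$gain)) as.numeric(meta$gain) else 1
  }
  if (ncol_ == 1L) {
    if (is.null(meta$sampling_rate))
      stop("one-column trace file '", path, "' lacks a sampling_rate header")
    rate <- as.numeric(meta$sampling_rate)
    volt <- mat[, 1L]
  } else if (ncol_ == 2L) {
    tt <- mat[, 1L]
    dt <- diff(tt)
    if (any(dt <= 0)) stop("sampling error in '", path, "': non-increasing time column")
    mdt <- stats::median(dt)
    if (max(abs(dt - mdt)) / mdt > 0.01)
      stop("sampling error in '", path, "': time step varies by more than 1%")
    rate <- 1 / mdt
    volt <- mat[, 2L]
  } else {
    stop("trace file '", path, "' must have 1 or 2 columns, found ", ncol_)
  }
  ephys_trace(volt * gain, rate,
              id = if (!is.null(meta$id)) meta$id
                   else tools::file_path_sans_ext(basename(path)),
              gain = gain,
              stim_onset = if (!is.null(meta$stim_onset)) as.numeric(meta$stim_onset) else NA_real_,
              stim_duration = if (!is.null(meta$stim_duration)) as.numeric(meta$stim_duration) else NA_real_)
}

#' Write a recording to a plain-text trace file
#'
#' Writes the one-column format understood by [read_trace()]: metadata header
#' followed by the (already gain-corrected) voltages, `gain: 1` so a re-read
#' reproduces the object.
#'
#' @param trace an [ephys_trace()].
#' @param path output path.
#' @param digits significant digits used for the voltages.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, digits = 10) {
  stopifnot(inherits(trace, "ephys_trace"))
  meta <- c(sprintf("# id: %s", trace$id),
            sprintf("# sampling_rate: %.10g", trace$sampling_rate),
            "# gain: 1")
  if (is.finite(trace$stim_onset))
    meta <- c(meta, sprintf("# stim_onset: %.10g", trace$stim_onset))
  if (is.finite(trace$stim_duration))
    meta <- c(meta, sprintf("# stim_duration: %.10g", trace$stim_duration))
  writeLines(c(meta, "voltage_mV",
               formatC(trace$samples, digits = digits, format = "g")), path)
  invisible(path)
}

quality_levels <- c("bad", "intermediate", "good")

#' Encode and decode quality labels
#'
#' Quality labels use the numeric convention bad = -1, intermediate = 0,
#' good = +1.
#'
#' @param labels character vector of labels (`"bad"`, `"intermediate"`,
#'   `"good"`, case-insensitive) for `encode_labels`, or a numeric vector in
#'   \{-1, 0, 1\} for `decode_labels`.
#' @return `encode_labels`: numeric vector in \{-1, 0, 1\};
#'   `decode_labels`: character vector of label names.
#' @export
encode_labels <- function(labels) {
  if (is.numeric(labels)) {
    if (!all(labels %in% c(-1, 0, 1))) stop("numeric labels must be -1, 0 or 1")
    return(as.numeric(labels))
  }
  lv <- tolower(trimws(as.character(labels)))
  unknown <- setdiff(unique(lv), quality_levels)
  if (length(unknown))
    stop("unknown quality label(s): ", paste(unknown, collapse = ", "))
  enc <- unname(c(bad = -1, intermediate = 0, good = 1)[lv])
  names(enc) <- names(labels)
  enc
}

#' @rdname encode_labels
#' @export
decode_labels <- function(labels) {
  if (is.character(labels)) return(tolower(labels))
  if (!all(labels %in% c(-1, 0, 1))) stop("numeric labels must be -1, 0 or 1")
  out <- quality_levels[match(labels, c(-1, 0, 1))]
  names(out) <- names(labels)
  out
}

#' Read a label table
#'
#' CSV with columns `id,label`; labels are case-insensitive `bad`,
#' `intermediate` or `good`.  Duplicate ids and unknown labels are errors.
#'
#' @param path CSV path.
#' @return named character vector of labels (names are recording ids), with
#'   attribute `encoded` holding the -1/0/+1 numeric encoding.
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "label") %in% names(df)))
    stop("label table '", path, "' must have columns id,label")
  ids <- as.character(df$id)
  if (anyDuplicated(ids))
    stop("duplicate recording id(s) in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  enc <- encode_labels(df$label)   # validates the vocabulary
  labels <- decode_labels(enc)
  names(labels) <- ids
  attr(labels, "encoded") <- stats::setNames(enc, ids)
  labels
}

#' Write a label table
#' @param labels named character (or -1/0/+1 numeric) vector of labels.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  df <- data.frame(id = names(labels), label = decode_labels(unname(labels)),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Names of the 16 recording features, in canonical order
#' @return character vector of length 16.
#' @export
feature_names <- function() {
  c("f01_mean_spike_height", "f02_mean_spike_width",
    "f03_cv_spike_height", "f04_cv_spike_width",
    "f05_mean_baseline_voltage", "f06_std_baseline",
    "f07_short_timescale_noise", "f08_std_noise_level",
    "f09_drift_spike_height", "f10_drift_spike_width",
    "f11_drift_noise_amplitude", "f12_min_isi",
    "f13_max_spike_slope", "f14_min_spike_slope",
    "f15_std_max_spike_slope", "f16_std_min_spike_slope")
}

#' Read / write a feature table
#'
#' Feature tables are CSV files with an `id` column followed by the 16
#' feature columns in the order of [feature_names()].
#'
#' @param table data.frame with columns `id` and the 16 features.
#' @param path CSV path.
#' @return `read_features`: the feature data.frame; `write_features`:
#'   `path`, invisibly.
#' @export
write_features <- function(table, path) {
  miss <- setdiff(c("id", feature_names()), names(table))
  if (length(miss)) stop("feature table lacks column(s): ", paste(miss, collapse = ", "))
  utils::write.csv(table[, c("id", feature_names())], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("id", feature_names()), names(df))
  if (length(miss)) stop("feature table '", path, "' lacks column(s): ",
                         paste(miss, collapse = ", "))
  df$id <- as.character(df$id)
  df[, c("id", feature_names())]
}
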