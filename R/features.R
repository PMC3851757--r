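#' Short-timescale noise trace
#'
#' The local noise level is the RMS deviation of the raw trace from its
#' moving average over a window of two filter half-widths,
#' `n(t) = sqrt( sum_{|t'-t| <= L} (V(t') - V_avg(t'))^2 / (2L + 1) )`,
#' where `L` is the filter half-width in samples.  The value is undefined
#' (`NA`) where the window does not fit inside the trace and within
#' `exclude_ms` of any accepted spike time (a 2 x 3 ms exclusion zone, i.e.
#' two maximal spike widths).
#'
#' @param trace an [ephys_trace()].
#' @param filtered moving-average filtered samples (same length).
#' @param spikes accepted `spike_events` for this trace.
#' @param params [detection_params()].
#' @param exclude_ms half-width of the exclusion zone around each spike, ms.
#' @return numeric vector of per-sample noise levels (mV), `NA` where
#'   undefined.
#' @export
short_timescale_noise <- function(trace, filtered, spikes,
                                  params = detection_params(),
                                  exclude_ms = 3) {
  v <- trace$samples
  stopifnot(length(filtered) == length(v))
  n <- length(v)
  rate <- trace$sampling_rate
  L <- filter_halfwidth(rate, params)
  resid2 <- (v - filtered)^2
  out <- rep(NA_real_, n)
  if (n >= 2L * L + 1L) {
    cs <- c(0, cumsum(resid2))
    idx <- (L + 1L):(n - L)
    out[idx] <- sqrt((cs[idx + L + 1L] - cs[idx - L]) / (2L * L + 1L))
  }
  if (nrow(spikes) > 0L) {
    excl <- ms_to_samples(exclude_ms, rate)
    centres <- round_half_away(spikes$t_spike * rate) + 1L
    for (c0 in centres) {
      lo <- max(1L, c0 - excl); hi <- min(n, c0 + excl)
      out[lo:hi] <- NA_real_
    }
  }
  out
}

#' Ordinary-least-squares drift slope
#'
#' Slope of the regression of `values` on `times`, reported per second.
#' Returns `fill` when fewer than 2 distinct time points are available.
#'
#' @param values numeric vector.
#' @param times numeric vector of the same length, seconds.
#' @param fill value returned for degenerate inputs.
#' @return slope (units of `values` per second).
#' @export
linear_drift <- function(values, times, fill = 0) {
  ok <- is.finite(values) & is.finite(times)
  values <- values[ok]; times <- times[ok]
  if (length(values) < 2L || length(unique(times)) < 2L) return(fill)
  tc <- times - mean(times)
  sum(tc * (values - mean(values))) / sum(tc^2)
}

#' Extract the 16 recording features
#'
#' Computes the canonical 16-feature vector for one recording from its
#' accepted spikes:
#' f1/f2 mean spike height (mV) / width (ms); f3/f4 their coefficients of
#' variation; f5/f6 mean/sd of the filtered potential trimmed to its own
#' 5th-95th percentile range (mV); f7/f8 mean/sd of the short-timescale
#' noise (mV); f9/f10/f11 OLS drifts of height, width and noise versus time
#' (per second); f12 minimal inter-spike interval (s); f13/f14 mean of the
#' per-spike extreme filtered-trace slopes (mV/ms); f15/f16 their standard
#' deviations.  All standard deviations are population (divide by N).
#'
#' Fill policy for degenerate traces (fewer than 2 spikes): spike-dependent
#' means, CVs, slopes and drifts are 0 and `f12` equals the trace duration;
#' `f5`-`f8` and `f11` are computed whenever the trace itself permits, else 0.
#'
#' @param trace an [ephys_trace()].
#' @param spikes `spike_events` from [detect_spikes()] on the same trace.
#' @param params [detection_params()].
#' @return named numeric vector of length 16 ([feature_names()]), all finite.
#' @export
extract_features <- function(trace, spikes, params = detection_params()) {
  filtered <- moving_average(trace$samples, trace$sampling_rate,
                             params$filter_window_ms)
  q <- pctl(filtered, c(0.05, 0.95))
  trimmed <- filtered[filtered >= q[1] & filtered <= q[2]]
  f5 <- if (length(trimmed)) mean(trimmed) else 0
  f6 <- if (length(trimmed)) pop_sd(trimmed) else 0
  nt <- short_timescale_noise(trace, filtered, spikes, params)
  nd <- nt[is.finite(nt)]
  f7 <- if (length(nd)) mean(nd) else 0
  f8 <- if (length(nd)) pop_sd(nd) else 0
  tt <- (seq_along(nt) - 1L) / trace$sampling_rate
  f11 <- if (length(nd) >= 2L) linear_drift(nt, tt) else 0
  ns <- nrow(spikes)
  if (ns >= 2L) {
    f1 <- mean(spikes$height)
    f2 <- mean(spikes$width)
    f3 <- if (f1 != 0) pop_sd(spikes$height) / f1 else 0
    f4 <- if (f2 != 0) pop_sd(spikes$width) / f2 else 0
    f9 <- linear_drift(spikes$height, spikes$t_spike)
    f10 <- linear_drift(spikes$width, spikes$t_spike)
    f12 <- min(diff(sort(spikes$t_spike)))
    f13 <- mean(spikes$max_slope)
    f14 <- mean(spikes$min_slope)
    f15 <- pop_sd(spikes$max_slope)
    f16 <- pop_sd(spikes$min_slope)
  } else {
    f1 <- f2 <- f3 <- f4 <- f9 <- f10 <- f13 <- f14 <- f15 <- f16 <- 0
    f12 <- trace_duration(trace)
  }
  out <- c(f1, f2, f3, f4, f5, f6, f7, f8, f9, f10, f11, f12, f13, f14, f15, f16)
  out[!is.finite(out)] <- 0
  stats::setNames(out, feature_names())
}

#' Extract the feature table for a set of recordings
#'
#' Runs [detect_spikes()] and [extract_features()] on every trace.  Per-trace
#' failures are caught: the row is filled with the degenerate-trace fill
#' values and flagged in the `failed` attribute.
#'
#' @param traces list of [ephys_trace()] objects.
#' @param params [detection_params()].
#' @return data.frame with columns `id` and the 16 features.
#' @export
extract_feature_table <- function(traces, params = detection_params()) {
  rows <- vector("list", length(traces))
  failed <- character()
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    fv <- tryCatch(
      extract_features(tr, detect_spikes(tr, params), params),
      error = function(e) {
        warning("feature extraction failed for '", tr$id, "': ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
    if (is.null(fv)) {
      failed <- c(failed, tr$id)
      fv <- stats::setNames(c(rep(0, 11), trace_duration(tr), rep(0, 4)),
                            feature_names())
    }
    rows[[i]] <- data.frame(id = tr$id, t(fv), check.names = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "failed") <- failed
  out
}
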