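#' Spike-detection parameters
#'
#' Parameters of the rule-based detector.  Defaults: a 3 ms moving-average
#' filter; derivative thresholds at three times the 80th (up) and 20th (down)
#' percentile of all observed derivatives; candidate events need a run of 3
#' consecutive super-threshold derivatives and, within 3 ms, a run of 3
#' consecutive sub-threshold ones; the local baseline is the mean voltage in
#' \[-6, -3\] and \[+3, +6\] ms around the spike maximum; eligible spikes must
#' dip below half height within 3 ms on both sides and be taller than half
#' the 95th height percentile of all candidates in the trace.
#'
#' @param filter_window_ms moving-average span, ms.
#' @param t_spike_max_ms maximal rise-to-fall gap, ms.
#' @param up_percentile,down_percentile derivative percentiles (0-100).
#' @param threshold_multiplier multiplier on the two percentiles.
#' @param run_length required number of consecutive threshold crossings.
#' @param baseline_inner_ms,baseline_outer_ms baseline window bounds, ms.
#' @param height_fraction fraction of the height-percentile cutoff.
#' @param height_percentile percentile of candidate heights for rule (ii).
#' @return a list of class `detection_params`.
#' @export
detection_params <- function(filter_window_ms = 3, t_spike_max_ms = 3,
                             up_percentile = 80, down_percentile = 20,
                             threshold_multiplier = 3, run_length = 3,
                             baseline_inner_ms = 3, baseline_outer_ms = 6,
                             height_fraction = 0.5, height_percentile = 95) {
  stopifnot(filter_window_ms > 0, t_spike_max_ms > 0,
            up_percentile > 0, up_percentile < 100,
            down_percentile > 0, down_percentile < 100,
            run_length >= 1, baseline_outer_ms > baseline_inner_ms)
  structure(as.list(environment()), class = "detection_params")
}

#' Centred moving average with edge shrink
#'
#' Half-width `L = round(window_ms/2 * rate/1000)` samples (half away from
#' zero), window `2L + 1`; at the trace edges the window shrinks to the
#' available samples, so output length equals input length.
#'
#' @param samples numeric vector.
#' @param sampling_rate Hz.
#' @param window_ms window span in ms.
#' @return filtered vector, same length as `samples`.
#' @export
moving_average <- function(samples, sampling_rate, window_ms = 3) {
  n <- length(samples)
  L <- ms_to_samples(window_ms / 2, sampling_rate)
  if (L == 0L) return(samples)
  if (n < 2L * L + 1L)
    stop("trace of ", n, " samples is shorter than the filter window (",
         2L * L + 1L, " samples)")
  cs <- c(0, cumsum(samples))
  i <- seq_len(n)
  lo <- pmax(i - L, 1L)
  hi <- pmin(i + L, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Filter half-width in samples (shared with the noise estimator)
filter_halfwidth <- function(sampling_rate, params) {
  ms_to_samples(params$filter_window_ms / 2, sampling_rate)
}

#' Forward-difference derivative in mV/ms
#'
#' `d[i] = (v[i+1] - v[i]) * rate / 1000`; length is `length(v) - 1`.
#'
#' @param filtered numeric vector (typically the filtered trace).
#' @param sampling_rate Hz.
#' @return derivative sequence in mV/ms.
#' @export
trace_derivative <- function(filtered, sampling_rate) {
  if (length(filtered) < 2L) stop("need at least 2 samples")
  diff(filtered) * sampling_rate / 1000
}

#' Percentile-derived derivative thresholds
#'
#' `theta_up = 3 * P80(derivs)`, `theta_down = 3 * P20(derivs)` (linear
#' interpolation percentiles).  A trace whose thresholds have the wrong sign
#' (`theta_up < 0` or `theta_down > 0`) or whose derivative is identically
#' zero has no usable spike content and is flagged degenerate; the detector
#' then returns zero spikes.
#'
#' @param derivs derivative sequence (mV/ms).
#' @param params [detection_params()].
#' @return list with `up`, `down` and logical `degenerate`.
#' @export
detection_thresholds <- function(derivs, params = detection_params()) {
  stopifnot(length(derivs) > 0)
  up <- params$threshold_multiplier * pctl(derivs, params$up_percentile / 100)
  down <- params$threshold_multiplier * pctl(derivs, params$down_percentile / 100)
  degenerate <- (up < 0) || (down > 0) || all(derivs == 0)
  list(up = up, down = down, degenerate = degenerate)
}

#' Find candidate spike events from the derivative sequence
#'
#' An event starts where `run_length` consecutive derivatives exceed
#' `theta_up`; within `t_spike_max_ms` after the end of that super-threshold
#' run (the maximal rise-to-fall gap) a run of `run_length` consecutive
#' derivatives below `theta_down` must begin.  The event's offset is the last
#' derivative below `theta_down` inside that window, and scanning resumes
#' after the offset, so events never overlap.  Note the gap is measured from
#' the end of the rising run: a centred moving-average filter of window `W`
#' smears the rising phase of the derivative over `W` plus the upstroke
#' duration, so a window measured from the first up-crossing could never
#' close within `t_spike_max_ms = W = 3` ms for any realistic spike.
#'
#' @param derivs derivative sequence.
#' @param thresholds list as returned by [detection_thresholds()].
#' @param sampling_rate Hz.
#' @param params [detection_params()].
#' @return data.frame with columns `onset`, `offset` (derivative indices,
#'   1-based); zero rows when nothing qualifies.
#' @export
find_candidate_events <- function(derivs, thresholds, sampling_rate,
                                  params = detection_params()) {
  empty <- data.frame(onset = integer(), offset = integer())
  if (isTRUE(thresholds$degenerate)) return(empty)
  nd <- length(derivs)
  rl <- params$run_length
  n_max <- ms_to_samples(params$t_spike_max_ms, sampling_rate)
  up <- derivs > thresholds$up
  down <- derivs < thresholds$down
  r <- rle(up)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  up_starts <- starts[r$values & r$lengths >= rl]
  up_run_ends <- ends[r$values & r$lengths >= rl]
  onsets <- integer(); offsets <- integer()
  pos <- 1L
  for (k in seq_along(up_starts)) {
    s <- up_starts[k]
    if (s < pos) next
    e <- up_run_ends[k]
    win_lo <- min(e + 1L, nd)
    win_end <- min(e + n_max, nd)
    # the down run must *begin* inside the window; it may extend past it
    ext_end <- min(win_end + rl - 1L, nd)
    found <- FALSE
    if (ext_end - win_lo + 1L >= rl) {
      w <- down[win_lo:ext_end]
      runs <- rle(w)
      ends <- cumsum(runs$lengths)
      starts_r <- ends - runs$lengths + 1L
      found <- any(runs$values & runs$lengths >= rl &
                     (win_lo - 1L + starts_r) <= win_end)
    }
    if (found) {
      offset <- win_lo - 1L + max(which(down[win_lo:win_end]))
      onsets <- c(onsets, s)
      offsets <- c(offsets, offset)
      pos <- offset + 1L
    } else {
      pos <- e + 1L
    }
  }
  data.frame(onset = onsets, offset = offsets)
}

#' Characterise a candidate spike event
#'
#' The spike maximum is taken on the raw trace between onset and offset; its
#' time defines `t_spike`.  The local baseline is the mean raw voltage over
#' \[-6, -3\] and \[+3, +6\] ms around `t_spike` (clipped to the trace);
#' height is max minus baseline; width is the time between the nearest
#' samples before and after `t_spike` that fall below baseline + height/2;
#' max/min slope are taken on the filtered-trace derivative between onset and
#' offset.
#'
#' @param trace an [ephys_trace()].
#' @param filtered filtered samples (same length).
#' @param derivs derivative of the filtered trace.
#' @param onset,offset derivative indices delimiting the event.
#' @param params [detection_params()].
#' @return one-row data.frame (a `spike_events` row); `width` is `NA` when no
#'   half-height crossing exists on one side.
#' @export
characterize_event <- function(trace, filtered, derivs, onset, offset,
                               params = detection_params()) {
  v <- trace$samples
  n <- length(v)
  rate <- trace$sampling_rate
  s_lo <- onset
  s_hi <- min(offset + 1L, n)      # derivative i spans samples i, i+1
  win <- s_lo:s_hi
  imax <- win[which.max(v[win])]
  v_max <- v[imax]
  b_in <- ms_to_samples(params$baseline_inner_ms, rate)
  b_out <- ms_to_samples(params$baseline_outer_ms, rate)
  bl_idx <- c(seq.int(imax - b_out, imax - b_in),
              seq.int(imax + b_in, imax + b_out))
  bl_idx <- bl_idx[bl_idx >= 1L & bl_idx <= n]
  baseline <- if (length(bl_idx)) mean(v[bl_idx]) else NA_real_
  height <- v_max - baseline
  half <- baseline + height / 2
  before <- which(v[seq_len(imax - 1L)] < half)
  j_before <- if (length(before)) max(before) else NA_integer_
  after_rel <- if (imax < n) which(v[(imax + 1L):n] < half) else integer()
  j_after <- if (length(after_rel)) imax + min(after_rel) else NA_integer_
  width <- if (!is.na(j_before) && !is.na(j_after))
    (j_after - j_before) / rate * 1000 else NA_real_
  dwin <- onset:min(offset, length(derivs))
  data.frame(t_spike = (imax - 1L) / rate, v_max = v_max, baseline = baseline,
             height = height, width = width,
             max_slope = max(derivs[dwin]), min_slope = min(derivs[dwin]),
             onset_index = s_lo, offset_index = s_hi,
             peak_index = imax,
             j_before = j_before, j_after = j_after)
}

#' Spike eligibility rules
#'
#' Keeps candidates that (i) dip below baseline + height/2 within
#' `t_spike_max_ms` both before and after the spike maximum, and (ii) are
#' taller than `height_fraction` times the `height_percentile`-th percentile
#' of all candidate heights in the trace (computed in a first pass over all
#' candidates).  Candidates without a baseline estimate are dropped.
#'
#' @param candidates data.frame of characterised events.
#' @param sampling_rate Hz.
#' @param params [detection_params()].
#' @return the accepted subset, same columns.
#' @export
eligibility_filter <- function(candidates, sampling_rate,
                               params = detection_params()) {
  if (nrow(candidates) == 0L) return(candidates)
  w_max <- ms_to_samples(params$t_spike_max_ms, sampling_rate)
  ok_baseline <- is.finite(candidates$baseline)
  rule_i <- !is.na(candidates$j_before) & !is.na(candidates$j_after) &
    (candidates$peak_index - candidates$j_before) <= w_max &
    (candidates$j_after - candidates$peak_index) <= w_max
  cutoff <- params$height_fraction *
    pctl(candidates$height[ok_baseline], params$height_percentile / 100)
  rule_ii <- candidates$height > cutoff
  keep <- ok_baseline & rule_i & rule_ii & candidates$height > 0
  candidates[keep, , drop = FALSE]
}

#' Detect spikes in a recording
#'
#' Composition of the full rule-based detector: moving-average filtering,
#' forward-difference derivative, percentile thresholds, candidate events,
#' characterisation and the two eligibility rules.  Deterministic.
#'
#' @param trace an [ephys_trace()].
#' @param params [detection_params()].
#' @return a `spike_events` data.frame (possibly 0 rows) with columns
#'   `t_spike` (s), `v_max`, `baseline`, `height` (mV), `width` (ms),
#'   `max_slope`, `min_slope` (mV/ms), `onset_index`, `offset_index`,
#'   `peak_index` (sample indices).  Attribute `degenerate` is `TRUE` when
#'   the derivative thresholds had the wrong sign.
#' @export
detect_spikes <- function(trace, params = detection_params()) {
  stopifnot(inherits(trace, "ephys_trace"))
  filtered <- moving_average(trace$samples, trace$sampling_rate,
                             params$filter_window_ms)
  derivs <- trace_derivative(filtered, trace$sampling_rate)
  th <- detection_thresholds(derivs, params)
  cols <- c("t_spike", "v_max", "baseline", "height", "width", "max_slope",
            "min_slope", "onset_index", "offset_index", "peak_index")
  empty <- stats::setNames(
    data.frame(matrix(numeric(), nrow = 0, ncol = length(cols))), cols)
  if (th$degenerate) {
    attr(empty, "degenerate") <- TRUE
    class(empty) <- c("spike_events", class(empty))
    return(empty)
  }
  ev <- find_candidate_events(derivs, th, trace$sampling_rate, params)
  if (nrow(ev) == 0L) {
    attr(empty, "degenerate") <- FALSE
    class(empty) <- c("spike_events", class(empty))
    return(empty)
  }
  chars <- do.call(rbind, lapply(seq_len(nrow(ev)), function(i) {
    characterize_event(trace, filtered, derivs, ev$onset[i], ev$offset[i], params)
  }))
  acc <- eligibility_filter(chars, trace$sampling_rate, params)
  acc <- acc[order(acc$t_spike), cols, drop = FALSE]
  rownames(acc) <- NULL
  attr(acc, "degenerate") <- FALSE
  attr(acc, "thresholds") <- th
  class(acc) <- c("spike_events", class(acc))
  acc
}
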