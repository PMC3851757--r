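#' Generator profile for synthetic sharp-electrode recordings
#'
#' Describes one quality class of the synthetic-trace generator: spike shape
#' statistics, firing statistics, baseline, Gaussian noise, linear drifts
#' and step/transient artefacts.  Traces are ~5 s at 10 kHz with a stimulus
#' window starting 1.5 s into the recording for 0.5 s during which the
#' firing rate is multiplied.
#'
#' @param label quality class ("good", "intermediate" or "bad").
#' @param spike_height_mean,spike_height_cv spike height distribution, mV.
#' @param spike_width_mean,spike_width_cv half-height spike width, ms.
#' @param firing_rate mean firing rate, Hz (0 for spikeless traces).
#' @param refractory_ms absolute refractory period, ms.
#' @param baseline_mV resting membrane potential, mV.
#' @param noise_sd Gaussian baseline noise sd, mV.
#' @param height_drift linear drift of spike height, mV/s.
#' @param noise_drift linear drift of the noise sd, mV/s.
#' @param baseline_drift linear drift of the baseline, mV/s.
#' @param step_prob,step_amp probability and amplitude (mV) of a persistent
#'   step artefact at a uniform random time.
#' @param transient_prob,transient_amp probability and amplitude (mV) of a
#'   broad (~15 ms) transient artefact.
#' @param duration_s,sampling_rate trace duration (s) and rate (Hz).
#' @param stim_onset,stim_duration,stim_rate_multiplier stimulus window (s)
#'   and the rate multiplier applied inside it.
#' @return list of class `generator_profile`.
#' @export
generator_profile <- function(label = "good",
                              spike_height_mean = 25, spike_height_cv = 0.1,
                              spike_width_mean = 1.8, spike_width_cv = 0.08,
                              firing_rate = 8, refractory_ms = 8,
                              baseline_mV = -62, noise_sd = 0.3,
                              height_drift = 0, noise_drift = 0,
                              baseline_drift = 0,
                              step_prob = 0, step_amp = 0,
                              transient_prob = 0, transient_amp = 0,
                              duration_s = 5, sampling_rate = 10000,
                              stim_onset = 1.5, stim_duration = 0.5,
                              stim_rate_multiplier = 1) {
  stopifnot(firing_rate >= 0, refractory_ms >= 0, noise_sd >= 0,
            spike_height_cv >= 0, spike_width_cv >= 0,
            duration_s > 0, sampling_rate > 0)
  structure(as.list(environment()), class = "generator_profile")
}

#' Default class profiles for the synthetic corpus
#'
#' Good: tall, narrow, regular spikes on a quiet, stable baseline with a
#' clear stimulus response.  Intermediate: smaller, broader, more variable
#' spikes, noisier baseline, mild drifts, occasional artefacts.  Bad: few
#' small spikes, heavy noise, unstable baseline and frequent step/transient
#' artefacts -- the failure modes a human rater rejects.
#'
#' @return named list of three [generator_profile()]s.
#' @export
default_profiles <- function() {
  list(
    good = generator_profile("good",
      spike_height_mean = 25, spike_height_cv = 0.10,
      spike_width_mean = 1.8, spike_width_cv = 0.08,
      firing_rate = 8, noise_sd = 0.3, baseline_mV = -62,
      stim_rate_multiplier = 3),
    intermediate = generator_profile("intermediate",
      spike_height_mean = 15, spike_height_cv = 0.25,
      spike_width_mean = 2.0, spike_width_cv = 0.20,
      firing_rate = 6, noise_sd = 0.9, baseline_mV = -57,
      height_drift = -0.6, noise_drift = 0.06, baseline_drift = 0.5,
      step_prob = 0.3, step_amp = 4,
      stim_rate_multiplier = 2),
    bad = generator_profile("bad",
      spike_height_mean = 8, spike_height_cv = 0.5,
      spike_width_mean = 2.4, spike_width_cv = 0.35,
      firing_rate = 2, noise_sd = 2.0, baseline_mV = -45,
      height_drift = -0.5, noise_drift = 0.25, baseline_drift = 3,
      step_prob = 0.8, step_amp = 12,
      transient_prob = 0.8, transient_amp = 40,
      stim_rate_multiplier = 1))
}

#' Named "bad recording" failure archetypes
#'
#' Three regression scenarios mirroring machine-vs-human disagreement modes:
#' a large artefact with no real spikes, an unstable baseline with otherwise
#' clean spikes, and a handful of large spikes interleaved with many small
#' secondary events.
#'
#' @param type one of `"artefact_no_spikes"`, `"unstable_baseline"`,
#'   `"few_large_with_secondary"`.
#' @return a [generator_profile()] (for the third type, a list of two
#'   profiles to be summed is emulated via the `secondary` attribute).
#' @export
bad_scenario_profile <- function(type = c("artefact_no_spikes",
                                          "unstable_baseline",
                                          "few_large_with_secondary")) {
  type <- match.arg(type)
  switch(type,
    artefact_no_spikes = generator_profile("bad",
      firing_rate = 0, noise_sd = 0.8, baseline_mV = -45,
      transient_prob = 1, transient_amp = 60, step_prob = 1, step_amp = 15),
    unstable_baseline = generator_profile("bad",
      spike_height_mean = 20, spike_height_cv = 0.08,
      firing_rate = 6, noise_sd = 0.5, baseline_mV = -55,
      baseline_drift = 6, step_prob = 1, step_amp = -10),
    few_large_with_secondary = {
      pr <- generator_profile("bad",
        spike_height_mean = 30, spike_height_cv = 0.05,
        firing_rate = 1, noise_sd = 0.4, baseline_mV = -60)
      attr(pr, "secondary") <- generator_profile("bad",
        spike_height_mean = 3, spike_height_cv = 0.2,
        spike_width_mean = 1.5, firing_rate = 12, noise_sd = 0,
        baseline_mV = 0)
      pr
    })
}

# Half-height width of the unit double-exponential bump
# s(t) = exp(-t/(2*tau)) - exp(-t/tau), in units of tau (rise tau, decay
# 2*tau); computed once and cached.
shape_constants <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    shape <- function(t) exp(-t / 2) - exp(-t)
    t_peak <- 2 * log(2)                 # argmax; peak value 1/4
    half <- shape(t_peak) / 2
    t1 <- stats::uniroot(function(t) shape(t) - half, c(1e-9, t_peak))$root
    t2 <- stats::uniroot(function(t) shape(t) - half, c(t_peak, 60))$root
    cache <<- list(t_peak = t_peak, peak_value = shape(t_peak),
                   half_width = t2 - t1)
    cache
  }
})

# render double-exponential spikes (peak time t_i, height h_i, half-height
# width w_i in ms) into `samples` (modified copy returned)
render_spikes <- function(samples, rate, t_spk, heights, widths_ms) {
  sc <- shape_constants()
  n <- length(samples)
  for (j in seq_along(t_spk)) {
    tau <- (widths_ms[j] / 1000) / sc$half_width   # rise time constant, s
    t0 <- t_spk[j] - sc$t_peak * tau
    i0 <- max(1L, floor(t0 * rate) + 1L)
    i1 <- min(n, ceiling((t0 + 14 * tau) * rate) + 1L)
    if (i1 <= i0) next
    tt <- ((i0:i1) - 1L) / rate - t0
    tt[tt < 0] <- 0
    s <- exp(-tt / (2 * tau)) - exp(-tt / tau)
    samples[i0:i1] <- samples[i0:i1] + heights[j] * s / sc$peak_value
  }
  samples
}

# renewal spike times: ISI = refractory + Exp(lambda) with lambda set so the
# mean ISI matches 1/rate; the rate is multiplied inside the stimulus window
draw_spike_times <- function(profile) {
  dur <- profile$duration_s
  ref <- profile$refractory_ms / 1000
  margin <- 0.02
  times <- numeric()
  t <- 0
  rate_at <- function(t) {
    r <- profile$firing_rate
    if (r > 0 && t >= profile$stim_onset &&
        t < profile$stim_onset + profile$stim_duration)
      r <- r * profile$stim_rate_multiplier
    r
  }
  repeat {
    r <- rate_at(t)
    if (r <= 0) {
      # jump to the stimulus window if it can still raise the rate
      if (profile$firing_rate <= 0) break
      break
    }
    mean_exp <- 1 / r - ref
    if (mean_exp <= 0) mean_exp <- 1e-3   # rate faster than refractory allows
    t <- t + ref + stats::rexp(1L, 1 / mean_exp)
    if (t >= dur - margin) break
    times <- c(times, t)
  }
  times
}

generate_trace_impl <- function(profile, id) {
  rate <- profile$sampling_rate
  n <- as.integer(round(profile$duration_s * rate))
  tt <- (seq_len(n) - 1L) / rate
  t_spk <- draw_spike_times(profile)
  nh <- length(t_spk)
  heights <- widths <- numeric(0)
  if (nh > 0L) {
    heights <- stats::rnorm(nh, profile$spike_height_mean,
                            profile$spike_height_cv * profile$spike_height_mean)
    heights <- heights + profile$height_drift * t_spk
    heights <- pmax(heights, 0.1)
    widths <- stats::rnorm(nh, profile$spike_width_mean,
                           profile$spike_width_cv * profile$spike_width_mean)
    widths <- pmax(widths, 0.3)
  }
  v <- rep(profile$baseline_mV, n) + profile$baseline_drift * tt
  v <- render_spikes(v, rate, t_spk, heights, widths)
  # secondary small-event population (named bad scenario)
  sec <- attr(profile, "secondary")
  sec_times <- numeric()
  if (!is.null(sec)) {
    sec_times <- draw_spike_times(sec)
    if (length(sec_times)) {
      sh <- pmax(stats::rnorm(length(sec_times), sec$spike_height_mean,
                              sec$spike_height_cv * sec$spike_height_mean), 0.1)
      sw <- pmax(stats::rnorm(length(sec_times), sec$spike_width_mean,
                              sec$spike_width_cv * sec$spike_width_mean), 0.3)
      v <- render_spikes(v, rate, sec_times, sh, sw)
    }
  }
  artefacts <- numeric()
  if (profile$step_prob > 0 && stats::runif(1L) < profile$step_prob) {
    t_step <- stats::runif(1L, 0.1, profile$duration_s - 0.1)
    v[tt >= t_step] <- v[tt >= t_step] + profile$step_amp
    artefacts <- c(artefacts, t_step)
  }
  if (profile$transient_prob > 0 && stats::runif(1L) < profile$transient_prob) {
    t_tr <- stats::runif(1L, 0.1, profile$duration_s - 0.1)
    v <- render_spikes(v, rate, t_tr, profile$transient_amp, 15)
    artefacts <- c(artefacts, t_tr)
  }
  if (profile$noise_sd > 0 || profile$noise_drift != 0) {
    sd_t <- pmax(profile$noise_sd + profile$noise_drift * tt, 0)
    v <- v + stats::rnorm(n, 0, 1) * sd_t
  }
  trace <- ephys_trace(v, rate, id = id, gain = 1,
                       stim_onset = profile$stim_onset,
                       stim_duration = profile$stim_duration)
  truth <- list(spike_times = t_spk, heights = heights, widths = widths,
                secondary_times = sec_times, artefact_times = artefacts,
                label = profile$label)
  list(trace = trace, ground_truth = truth)
}

#' Generate one synthetic recording with ground truth
#'
#' Spike times come from a renewal process (exponential inter-spike
#' intervals shifted by the refractory period, with the hazard matched so
#' the mean rate equals `firing_rate`; the rate is multiplied inside the
#' stimulus window).  Each spike is a double-exponential bump (decay time
#' constant twice the rise) whose half-height width equals the drawn width.
#' Gaussian noise, linear drifts and optional step/transient artefacts are
#' added on top.  Bit-identical under a fixed `seed`.
#'
#' @param profile a [generator_profile()].
#' @param seed RNG seed.
#' @param id recording id.
#' @return list with `trace` (an [ephys_trace()]) and `ground_truth`
#'   (spike times (s, peak times), per-spike heights/widths, artefact times,
#'   class label).
#' @export
generate_trace <- function(profile, seed = 1, id = "sim") {
  with_seed(seed, generate_trace_impl(profile, id))
}

#' Generate a labelled synthetic corpus
#'
#' Default counts follow the reference corpus composition of 100 good, 54
#' intermediate and 29 bad recordings.
#'
#' @param profiles named list of [generator_profile()]s (default
#'   [default_profiles()]).
#' @param counts named integer vector of per-class trace counts.
#' @param seed RNG seed; the whole corpus is reproducible.
#' @return list of class `synthetic_corpus` with `traces` (list of
#'   [ephys_trace()]), `labels` (named character vector) and `ground_truth`
#'   (list).
#' @export
generate_dataset <- function(profiles = default_profiles(),
                             counts = c(good = 100, intermediate = 54, bad = 29),
                             seed = 1) {
  stopifnot(all(names(counts) %in% names(profiles)), all(counts >= 1))
  traces <- list(); labels <- character(); truths <- list()
  with_seed(seed, {
    i <- 0L
    for (cl in names(counts)) {
      for (j in seq_len(counts[[cl]])) {
        i <- i + 1L
        id <- sprintf("r%03d", i)
        out <- generate_trace_impl(profiles[[cl]], id)
        traces[[id]] <- out$trace
        truths[[id]] <- out$ground_truth
        labels[id] <- profiles[[cl]]$label
      }
    }
  })
  structure(list(traces = traces, labels = labels, ground_truth = truths,
                 counts = counts, seed = seed),
            class = "synthetic_corpus")
}

#' Synthetic feature-space dataset with planted informative features
#'
#' Three classes on simplex-arranged centroids in the first
#' `n_informative` feature dimensions (pairwise separation `delta` in units
#' of the unit noise sd), plus `n_noise` pure-noise features.  Used to
#' validate that the wrapper search recovers the informative triple.
#'
#' @param n number of recordings (split near-equally over the 3 classes).
#' @param n_informative,n_noise numbers of informative / noise features.
#' @param delta class separation of the informative features.
#' @param seed RNG seed.
#' @return a [labeled_dataset()]; attribute `informative` holds the planted
#'   feature indices.
#' @export
planted_feature_dataset <- function(n = 200, n_informative = 3, n_noise = 13,
                                    delta = 2.5, seed = 1) {
  p <- n_informative + n_noise
  classes <- c("bad", "intermediate", "good")
  y <- rep(classes, length.out = n)
  with_seed(seed, {
    x <- matrix(stats::rnorm(n * p), n, p)
    for (ci in seq_along(classes)) {
      rows <- which(y == classes[ci])
      dim_i <- ((ci - 1L) %% n_informative) + 1L
      x[rows, dim_i] <- x[rows, dim_i] + delta
    }
  })
  colnames(x) <- sprintf("f%02d", seq_len(p))
  rownames(x) <- sprintf("s%03d", seq_len(n))
  ds <- labeled_dataset(x, stats::setNames(y, rownames(x)))
  attr(ds, "informative") <- seq_len(n_informative)
  ds
}
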