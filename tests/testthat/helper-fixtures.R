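# Shared fixtures, all built in code.

# a flat trace with one sharp triangular spike per requested peak sample
triangle_trace <- function(n = 200, peaks = 100, rise = 2, amp = 10,
                           baseline = 0, rate = 1000, id = "tri") {
  v <- rep(baseline, n)
  step <- amp / rise
  for (p in peaks) {
    for (k in seq_len(rise)) {
      v[p - rise + k] <- baseline + step * k
      v[p + rise - k] <- baseline + step * k
    }
    v[p] <- baseline + amp
  }
  ephys_trace(v, rate, id = id)
}

# constant qc_svm stub, used to exercise vote_predict tie-breaking
fake_model <- function(label) {
  structure(list(model = list(constant = label),
                 scaler = structure(list(center = 0, scale = 1),
                                    class = "qc_scaler"),
                 classes = encode_labels(label), class_labels = label,
                 features = NULL, config = svm_config()),
            class = "qc_svm")
}

# well-separated 3-class feature blobs
blob_dataset <- function(n_per = 20, d = 4, sep = 6, seed = 1) {
  with_seed <- get("with_seed", asNamespace("ephysqc"))
  with_seed(seed, {
    x <- rbind(matrix(stats::rnorm(n_per * d, 0), n_per),
               matrix(stats::rnorm(n_per * d, sep), n_per),
               matrix(stats::rnorm(n_per * d, 2 * sep), n_per))
    rownames(x) <- sprintf("b%03d", seq_len(3 * n_per))
    y <- stats::setNames(rep(c("bad", "intermediate", "good"), each = n_per),
                         rownames(x))
    labeled_dataset(x, y)
  })
}

# greedy one-to-one matching of detected vs ground-truth spike times
match_spikes <- function(detected, truth, tol = 1e-3) {
  used <- rep(FALSE, length(detected))
  hits <- 0L
  for (t in truth) {
    d <- abs(detected - t)
    d[used] <- Inf
    if (length(d) && min(d) <= tol) {
      used[which.min(d)] <- TRUE
      hits <- hits + 1L
    }
  }
  hits
}

clean_profile <- function(...) {
  generator_profile(noise_sd = 0, spike_height_cv = 0.08,
                    spike_width_cv = 0.05, stim_rate_multiplier = 1, ...)
}
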