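# Internal helpers shared across modules.

# Round half away from zero; used for every ms -> samples conversion so that
# window sizes are reproducible across platforms (base round() goes to even).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# ms -> number of samples at a given sampling rate (Hz)
ms_to_samples <- function(ms, sampling_rate) {
  as.integer(round_half_away(ms * sampling_rate / 1000))
}

# Population standard deviation (divide by N).  The package uses this
# convention consistently for features and scalers.
pop_sd <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

# Linear-interpolation percentile (R type 7), the single convention used for
# detection thresholds, eligibility and feature trimming.
pctl <- function(x, p) {
  stats::quantile(x, probs = p, type = 7, names = FALSE, na.rm = TRUE)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed < 2^31 from a base seed and a stream index.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(stream) * 16807) %% 2147483647)
}

qc_log <- function(..., level = "INFO", verbose = getOption("ephysqc.verbose", FALSE)) {
  if (isTRUE(verbose)) {
    message(sprintf("[%s] %s %s", level, format(Sys.time(), "%H:%M:%S"),
                    paste0(..., collapse = "")))
  }
  invisible(NULL)
}
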