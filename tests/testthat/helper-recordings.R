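# Shared fixtures, all generated in code.

# Short paired recording for pipeline-level tests (minutes, not hours).
tiny_config <- function(duration_s = 3600, strength = 1, period_s = 400,
                        seed = 42, ...) {
  synthetic_config(duration_s = duration_s,
                   coupling_periods_s = min(period_s, duration_s / 4),
                   coupling_strength = strength, seed = seed, ...)
}

# Small scale grid matched to short records.
tiny_grid <- function() scale_grid(100, 800, voices = 8)

# Independent percentile oracle: sort ascending and interpolate linearly
# between order statistics (the convention the pipeline pins).
oracle_percentile <- function(v, p) {
  s <- sort(v)
  h <- (length(s) - 1) * p / 100
  lo <- floor(h)
  s[lo + 1] + (h - lo) * (s[min(lo + 2, length(s))] - s[lo + 1])
}

# Dominant periodogram period (seconds) of a series.
peak_period_s <- function(x) {
  sp <- stats::spec.pgram(stats::ts(x$values, frequency = x$rate),
                          taper = 0, detrend = TRUE, plot = FALSE)
  1 / sp$freq[which.max(sp$spec)]
}

# Block means of |v| at the margin stride: a crude envelope at ~0.209 Hz
# used as an independent check of slow amplitude dynamics.
abs_block_means <- function(v, block = 1224L) {
  nb <- length(v) %/% block
  colMeans(matrix(abs(v[seq_len(nb * block)]), nrow = block))
}
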