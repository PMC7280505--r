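#' Evenly sampled signal
#'
#' The universal carrier for every signal in the pipeline: raw EEG (microvolts
#' at 256 Hz), rectified/envelope signals, aEEG margin traces (~0.209 Hz) and
#' SctO2 (percent). A `uniform_series` is a plain list with `values`, a
#' sampling `rate` in Hz, a start time `t0` in seconds and a `units` string.
#'
#' @param values numeric vector of samples; must be finite.
#' @param rate sampling rate in Hz; must be positive.
#' @param t0 time of the first sample in seconds.
#' @param units unit label carried as metadata, e.g. `"uV"` or `"%"`.
#' @return An object of class `uniform_series`.
#' @examples
#' x <- uniform_series(sin(seq(0, 10, by = 0.01)), rate = 100)
#' series_duration(x)
#' @export
uniform_series <- function(values, rate, t0 = 0, units = "") {
  values <- as.numeric(values)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("`rate` must be a single positive number", call. = FALSE)
  if (length(values) && !all(is.finite(values)))
    stop("`values` must be finite", call. = FALSE)
  structure(list(values = values, rate = rate, t0 = t0, units = units),
            class = "uniform_series")
}

#' @export
print.uniform_series <- function(x, ...) {
  cat(sprintf("<uniform_series> n = %d, rate = %.6g Hz, t0 = %.4g s%s\n",
              length(x$values), x$rate, x$t0,
              if (nzchar(x$units)) paste0(", units = ", x$units) else ""))
  invisible(x)
}

#' @export
length.uniform_series <- function(x) length(x$values)

#' Sample times of a uniform series
#' @param x a [uniform_series()].
#' @return numeric vector of sample times in seconds.
#' @export
series_times <- function(x) {
  stopifnot(inherits(x, "uniform_series"))
  x$t0 + (seq_along(x$values) - 1L) / x$rate
}

#' Duration spanned by a uniform series
#' @param x a [uniform_series()].
#' @return duration in seconds, `(n - 1) / rate`.
#' @export
series_duration <- function(x) {
  stopifnot(inherits(x, "uniform_series"))
  (length(x$values) - 1L) / x$rate
}

# Derive a reproducible sub-seed (< 2^31) from a master seed and a stream name.
# FNV-1a over the stream name, folded with the master seed.
derive_seed <- function(seed, stream) {
  h <- 2166136261
  for (b in utf8ToInt(stream)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  as.integer((h + as.numeric(seed) * 2654435761) %% 2147483647)
}

# Evaluate a function with a locally seeded RNG, restoring global RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Centered moving average with shortened windows at the ends (k odd).
moving_average <- function(x, k = 3L) {
  n <- length(x)
  if (k <= 1L || n < 2L) return(x)
  h <- k %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
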