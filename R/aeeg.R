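#' Specification of the asymmetric aEEG band-pass filter
#'
#' Describes the linear-phase FIR used as the first aEEG stage: a band-pass
#' over `stop_lo_hz`-`stop_hi_hz` whose in-band gain rises at
#' `slope_db_per_decade` (gain normalized to 1 at the lower corner),
#' compensating the scalp/skull attenuation of faster activity, with strong
#' attenuation outside the band.
#'
#' @param stop_lo_hz lower band corner in Hz.
#' @param stop_hi_hz upper band corner in Hz.
#' @param slope_db_per_decade in-band amplification slope, dB/decade.
#' @param n_taps FIR length; must be odd (symmetric, exactly linear phase).
#' @param transition_hz transition width to the stop bands, Hz.
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(stop_lo_hz = 2, stop_hi_hz = 15,
                        slope_db_per_decade = 12, n_taps = 401,
                        transition_hz = 0.5) {
  if (stop_lo_hz <= 0 || stop_hi_hz <= stop_lo_hz)
    stop("need 0 < stop_lo_hz < stop_hi_hz", call. = FALSE)
  if (n_taps %% 2 == 0)
    stop("`n_taps` must be odd for a symmetric linear-phase filter",
         call. = FALSE)
  structure(list(stop_lo_hz = stop_lo_hz, stop_hi_hz = stop_hi_hz,
                 slope_db_per_decade = slope_db_per_decade,
                 n_taps = as.integer(n_taps), transition_hz = transition_hz),
            class = "filter_spec")
}

#' Design the asymmetric linear-phase FIR
#'
#' Frequency-sampling design (windowed inverse DFT via [signal::fir2()]) of
#' the rising band-pass described by a [filter_spec()]. The desired
#' power-law ramp is extended slightly beyond the nominal corners before the
#' transition to zero so that window-induced droop falls outside the nominal
#' band; the realized 2 to 15 Hz gain ratio then sits at the nominal
#' `slope_db_per_decade * log10(15/2)` within a few percent.
#'
#' @param rate sampling rate in Hz.
#' @param spec a [filter_spec()].
#' @return Numeric coefficient vector (odd length, mirror-symmetric) with the
#'   spec attached as attribute `"spec"`.
#' @examples
#' b <- design_asymmetric_filter(256, filter_spec())
#' all.equal(b, rev(b))  # exactly linear phase
#' @export
design_asymmetric_filter <- function(rate, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  ny <- rate / 2
  if (spec$stop_hi_hz >= ny)
    stop("`stop_hi_hz` must be below the Nyquist frequency", call. = FALSE)
  # extend the ramp ~1/4 octave below and ~0.35 Hz above the corners
  lo <- spec$stop_lo_hz * 2^(-0.23)
  hi <- spec$stop_hi_hz + 0.35 * spec$stop_hi_hz / 15
  rf <- exp(seq(log(lo), log(hi), length.out = 40))
  amp <- (rf / spec$stop_lo_hz)^(spec$slope_db_per_decade / 20)
  fgrid <- c(0, max(lo - spec$transition_hz, lo / 2), rf,
             hi + spec$transition_hz, ny) / ny
  a <- c(0, 0, amp, 0, 0)
  b <- signal::fir2(spec$n_taps - 1L, fgrid, a)
  # verify the achieved response; refuse designs whose in-band error is large
  chk <- exp(seq(log(spec$stop_lo_hz), log(spec$stop_hi_hz), length.out = 25))
  got <- fir_response(b, chk, rate)
  des <- (chk / spec$stop_lo_hz)^(spec$slope_db_per_decade / 20)
  ripple <- max(abs(got / des - 1))
  if (ripple > 0.35)
    stop(sprintf(paste0("filter design failed: achieved in-band ripple %.2f ",
                        "(try more taps)"), ripple), call. = FALSE)
  attr(b, "spec") <- spec
  b
}

#' Magnitude response of an FIR filter at given frequencies
#' @param b FIR coefficients.
#' @param freqs_hz frequencies at which to evaluate, Hz.
#' @param rate sampling rate in Hz.
#' @return magnitude response (linear units) at `freqs_hz`.
#' @export
fir_response <- function(b, freqs_hz, rate) {
  k <- seq_along(b) - 1L
  vapply(freqs_hz,
         function(f) Mod(sum(b * exp(-1i * 2 * pi * f / rate * k))),
         numeric(1))
}

#' Apply a linear-phase FIR with group-delay compensation
#'
#' Overlap-add FFT filtering; the output is shifted by the filter's
#' `(n_taps - 1)/2`-sample group delay so features stay aligned with the
#' input. Same length as the input.
#'
#' @param x a [uniform_series()].
#' @param b symmetric FIR coefficients.
#' @return filtered [uniform_series()].
#' @export
apply_fir <- function(x, b) {
  stopifnot(inherits(x, "uniform_series"))
  d <- (length(b) - 1L) %/% 2L
  xp <- c(x$values, numeric(d))
  nb <- 2^ceiling(log2(32 * length(b)))   # overlap-add block
  y <- if (length(xp) > 2 * nb) signal::fftfilt(b, xp, n = nb)
       else signal::fftfilt(b, xp)
  uniform_series(y[(d + 1L):(d + length(x$values))], x$rate, x$t0, x$units)
}

#' Full-wave rectification
#'
#' Element-wise absolute value of the band-passed EEG (peak-sensitive
#' rectification), preserving rate and length.
#'
#' @param x a [uniform_series()].
#' @return rectified [uniform_series()].
#' @export
rectify <- function(x) {
  stopifnot(inherits(x, "uniform_series"))
  uniform_series(abs(x$values), x$rate, x$t0, x$units)
}

#' Zero-phase Butterworth envelope detection
#'
#' Low-pass Butterworth of the stated order applied forward and backward
#' ([signal::filtfilt()]) to the rectified signal; the result is clipped at
#' zero since an envelope is an amplitude. Unit DC gain.
#'
#' @param x rectified (nonnegative) [uniform_series()].
#' @param order filter order.
#' @param cutoff_hz low-pass cutoff in Hz; must be below Nyquist.
#' @return envelope [uniform_series()].
#' @export
envelope <- function(x, order = 5, cutoff_hz = 1) {
  stopifnot(inherits(x, "uniform_series"))
  ny <- x$rate / 2
  if (cutoff_hz <= 0 || cutoff_hz >= ny)
    stop("`cutoff_hz` must lie in (0, Nyquist)", call. = FALSE)
  bt <- signal::butter(order, cutoff_hz / ny, type = "low")
  v <- x$values
  n <- length(v)
  # odd-reflection padding suppresses the start-up transient of filtfilt
  L <- min(n - 1L, ceiling(10 * x$rate / cutoff_hz))
  xp <- c(2 * v[1] - rev(v[2:(L + 1)]), v, 2 * v[n] - rev(v[(n - L):(n - 1)]))
  y <- signal::filtfilt(bt, xp)[(L + 1):(L + n)]
  uniform_series(pmax(y, 0), x$rate, x$t0, x$units)
}

#' Apply a gain factor
#' @param x a [uniform_series()].
#' @param g positive gain.
#' @return scaled series.
#' @export
apply_gain <- function(x, g) {
  stopifnot(inherits(x, "uniform_series"))
  if (!is.numeric(g) || g <= 0) stop("`g` must be positive", call. = FALSE)
  uniform_series(x$values * g, x$rate, x$t0, x$units)
}

#' Per-epoch terminal points (percentile extraction)
#'
#' Slides a window of `epoch_len_s` across the envelope with stride
#' `step_s` and takes the `hi_pct`/`lo_pct` percentiles
#' (linear-interpolation convention, [stats::quantile()] type 7) of each
#' window as the upper/lower terminal points (UTP/LTP). Window and stride
#' are fixed in integer samples; the default stride of 1224 samples at
#' 256 Hz (4.78125 s) yields the 0.20915 Hz margin rate reported rounded as
#' 0.209 Hz.
#'
#' @param env envelope [uniform_series()].
#' @param epoch_len_s window length in seconds (>= `step_s`).
#' @param step_s stride in seconds.
#' @param hi_pct,lo_pct percentiles (0-100) for UTP and LTP.
#' @return A list of class `terminal_points` with `utp`, `ltp`, `rate`
#'   (1/stride), `t0` (center of the first window), `epoch_len_s`,
#'   `epoch_step_s`.
#' @export
extract_terminal_points <- function(env, epoch_len_s = 15,
                                    step_s = 1224 / 256,
                                    hi_pct = 90, lo_pct = 10) {
  stopifnot(inherits(env, "uniform_series"))
  if (epoch_len_s < step_s)
    stop("`epoch_len_s` must be >= `step_s`", call. = FALSE)
  win <- round(epoch_len_s * env$rate)
  stride <- round(step_s * env$rate)
  n <- length(env$values)
  if (n < win)
    stop("series shorter than one window", call. = FALSE)
  n_ep <- (n - win) %/% stride + 1L
  p <- c(lo_pct, hi_pct) / 100
  utp <- numeric(n_ep); ltp <- numeric(n_ep)
  block <- max(1L, 2e6 %/% win)  # epochs per chunk, caps memory
  i <- 1L
  while (i <= n_ep) {
    j <- min(i + block - 1L, n_ep)
    starts <- (i:j - 1L) * stride
    m <- matrix(env$values[outer(seq_len(win), starts, `+`)], nrow = win)
    q <- apply(m, 2L, stats::quantile, probs = p, names = FALSE, type = 7)
    ltp[i:j] <- q[1L, ]; utp[i:j] <- q[2L, ]
    i <- j + 1L
  }
  structure(list(utp = utp, ltp = ltp, rate = env$rate / stride,
                 t0 = env$t0 + (win - 1) / (2 * env$rate),
                 epoch_len_s = win / env$rate,
                 epoch_step_s = stride / env$rate),
            class = "terminal_points")
}

#' Construct an aEEG margin trace
#' @param uma,lma upper/lower margin [uniform_series()] (same rate/length).
#' @param method `"M1"`, `"M2"` or `"M3"`.
#' @param meta optional list of processing metadata.
#' @return An object of class `aeeg_trace`.
#' @export
aeeg_trace <- function(uma, lma, method, meta = list()) {
  stopifnot(inherits(uma, "uniform_series"), inherits(lma, "uniform_series"))
  if (length(uma$values) != length(lma$values) || uma$rate != lma$rate)
    stop("`uma` and `lma` must share rate and length", call. = FALSE)
  if (any(lma$values < 0) || any(uma$values < lma$values))
    stop("margins must satisfy uma >= lma >= 0", call. = FALSE)
  method <- match.arg(method, c("M1", "M2", "M3"))
  structure(list(uma = uma, lma = lma, method = method, meta = meta),
            class = "aeeg_trace")
}

#' @export
print.aeeg_trace <- function(x, ...) {
  cat(sprintf("<aeeg_trace %s> n = %d, rate = %.5f Hz, UMA %.2f uV, LMA %.2f uV (medians)\n",
              x$method, length(x$uma$values), x$uma$rate,
              stats::median(x$uma$values), stats::median(x$lma$values)))
  invisible(x)
}

margins_from_tp <- function(tp, method, smoother = c("ma3", "spline"),
                            meta = list()) {
  smoother <- match.arg(smoother)
  smooth_fun <- if (smoother == "ma3") {
    function(v) moving_average(v, 3L)
  } else {
    function(v) {
      if (length(v) < 4L) return(v)
      stats::smooth.spline(seq_along(v), v)$y
    }
  }
  uma_v <- smooth_fun(tp$utp)
  lma_v <- smooth_fun(tp$ltp)
  lma_v <- pmax(lma_v, 0)
  uma_v <- pmax(uma_v, lma_v)
  n_edge <- ceiling(tp$epoch_len_s / tp$epoch_step_s)
  meta <- c(meta, list(smoother = smoother, epoch_len_s = tp$epoch_len_s,
                       epoch_step_s = tp$epoch_step_s, n_edge = n_edge))
  aeeg_trace(uniform_series(uma_v, tp$rate, tp$t0, "uV"),
             uniform_series(lma_v, tp$rate, tp$t0, "uV"),
             method = method, meta = meta)
}

#' aEEG margins by the overlapping-window algorithm (M1)
#'
#' Terminal points from 15-s windows stepped by 4.78125 s (10.22-s overlap),
#' then a margin-smoothing pass (default 3-point centered moving average)
#' through the UTP and LTP sequences. Output rate ~0.209 Hz.
#'
#' @param env gained envelope [uniform_series()] at the EEG rate.
#' @param epoch_len_s,step_s window geometry in seconds.
#' @param hi_pct,lo_pct terminal-point percentiles.
#' @param smoother `"ma3"` (default) or `"spline"`.
#' @return An [aeeg_trace()] with `method = "M1"`.
#' @export
margins_m1 <- function(env, epoch_len_s = 15, step_s = 1224 / 256,
                       hi_pct = 90, lo_pct = 10, smoother = "ma3") {
  tp <- extract_terminal_points(env, epoch_len_s, step_s, hi_pct, lo_pct)
  margins_from_tp(tp, "M1", smoother)
}

#' aEEG margins by the non-overlapping-epoch algorithm (M2)
#'
#' Terminal points from contiguous non-overlapping 4.78125-s epochs (1224
#' samples at 256 Hz), then a centered 3-point moving average of the UTP and
#' LTP sequences (~15 s of effective support). Output rate ~0.209 Hz.
#'
#' @inheritParams margins_m1
#' @return An [aeeg_trace()] with `method = "M2"`.
#' @export
margins_m2 <- function(env, step_s = 1224 / 256, hi_pct = 90, lo_pct = 10,
                       smoother = "ma3") {
  tp <- extract_terminal_points(env, epoch_len_s = step_s, step_s = step_s,
                                hi_pct = hi_pct, lo_pct = lo_pct)
  margins_from_tp(tp, "M2", smoother)
}

#' aEEG margins from an externally computed 256 Hz aEEG (M3 path)
#'
#' Applies the same segmentation and margin pipeline as [margins_m1()] to an
#' amplitude series already converted to aEEG by an external device. The
#' device's own raw-EEG conversion is not reimplemented.
#'
#' @param aeeg_256 nonnegative device aEEG [uniform_series()] at the EEG rate.
#' @inheritParams margins_m1
#' @return An [aeeg_trace()] with `method = "M3"`.
#' @export
margins_m3 <- function(aeeg_256, epoch_len_s = 15, step_s = 1224 / 256,
                       hi_pct = 90, lo_pct = 10, smoother = "ma3") {
  stopifnot(inherits(aeeg_256, "uniform_series"))
  if (any(aeeg_256$values < 0))
    stop("device aEEG input must be nonnegative", call. = FALSE)
  tp <- extract_terminal_points(aeeg_256, epoch_len_s, step_s, hi_pct, lo_pct)
  margins_from_tp(tp, "M3", smoother)
}

#' aEEG bandwidth (UMA - LMA)
#'
#' The margin difference series that feeds the wavelet coherence stage.
#'
#' @param trace an [aeeg_trace()].
#' @return nonnegative [uniform_series()] in microvolts at the margin rate.
#' @export
bandwidth <- function(trace) {
  stopifnot(inherits(trace, "aeeg_trace"))
  uniform_series(trace$uma$values - trace$lma$values, trace$uma$rate,
                 trace$uma$t0, "uV")
}

#' Raw EEG to aEEG margins, full M1 chain
#'
#' Asymmetric FIR band-pass, full-wave rectification, zero-phase Butterworth
#' envelope, gain 2, then overlapping-window margin extraction.
#'
#' @param eeg raw EEG [uniform_series()] in microvolts.
#' @param spec a [filter_spec()].
#' @param cutoff_hz envelope cutoff in Hz.
#' @param gain envelope gain factor (2 for this chain).
#' @param ... passed to [margins_m1()].
#' @return An [aeeg_trace()].
#' @export
aeeg_m1 <- function(eeg, spec = filter_spec(), cutoff_hz = 1, gain = 2, ...) {
  b <- design_asymmetric_filter(eeg$rate, spec)
  env <- apply_gain(envelope(rectify(apply_fir(eeg, b)),
                             cutoff_hz = cutoff_hz), gain)
  margins_m1(env, ...)
}

#' Raw EEG to aEEG margins, full M2 chain
#'
#' Same filter family and envelope as [aeeg_m1()] but with gain 1.631 and
#' non-overlapping-epoch margin extraction.
#'
#' @inheritParams aeeg_m1
#' @param ... passed to [margins_m2()].
#' @export
aeeg_m2 <- function(eeg, spec = filter_spec(), cutoff_hz = 1, gain = 1.631,
                    ...) {
  b <- design_asymmetric_filter(eeg$rate, spec)
  env <- apply_gain(envelope(rectify(apply_fir(eeg, b)),
                             cutoff_hz = cutoff_hz), gain)
  margins_m2(env, ...)
}

#' Semi-logarithmic aEEG display coordinate
#'
#' The conventional aEEG axis: identity (linear) from 0 to 10 uV, and
#' `10 * (1 + log10(v / 10))` above 10 uV, continuous and monotone; 100 uV
#' maps to 20 display units.
#'
#' @param v nonnegative amplitude(s) in microvolts.
#' @return display coordinate(s).
#' @examples
#' semilog_display(c(5, 10, 100))
#' @export
semilog_display <- function(v) {
  if (any(v < 0)) stop("`v` must be nonnegative", call. = FALSE)
  ifelse(v <= 10, v, 10 * (1 + log10(v / 10)))
}

#' Plot an aEEG trace on the conventional semi-log panel
#' @param x an [aeeg_trace()].
#' @param max_uV upper axis limit in microvolts.
#' @param ... further arguments to [graphics::plot()].
#' @export
plot.aeeg_trace <- function(x, max_uV = 100, ...) {
  t_h <- series_times(x$uma) / 3600
  u <- semilog_display(pmin(x$uma$values, max_uV))
  l <- semilog_display(pmin(x$lma$values, max_uV))
  ticks <- c(0, 5, 10, 25, 50, 100)
  graphics::plot(t_h, u, type = "n", ylim = c(0, semilog_display(max_uV)),
                 xlab = "time (h)", ylab = "aEEG (uV)", yaxt = "n",
                 main = paste("aEEG", x$method), ...)
  graphics::axis(2, at = semilog_display(ticks), labels = ticks)
  graphics::abline(h = semilog_display(10), col = "grey80")
  graphics::polygon(c(t_h, rev(t_h)), c(u, rev(l)), col = "grey60",
                    border = NA)
  invisible(x)
}

#' Write an aEEG trace to CSV with a metadata sidecar
#'
#' Columns `time_s, uma_uV, lma_uV`; processing metadata (method, geometry,
#' smoother) goes to `<path>.json`.
#'
#' @param trace an [aeeg_trace()].
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_aeeg_csv <- function(trace, path) {
  stopifnot(inherits(trace, "aeeg_trace"))
  utils::write.csv(data.frame(time_s = series_times(trace$uma),
                              uma_uV = trace$uma$values,
                              lma_uV = trace$lma$values),
                   path, row.names = FALSE)
  jsonlite::write_json(c(list(method = trace$method), trace$meta),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a two-column time/value CSV as a uniform series
#'
#' Expects a header with a time column (seconds) first and the signal second;
#' the rate is inferred from the median time step and sampling must be
#' uniform to within 1%.
#'
#' @param path CSV path.
#' @param units unit label for the returned series.
#' @return A [uniform_series()].
#' @export
read_series_csv <- function(path, units = "") {
  d <- utils::read.csv(path)
  if (ncol(d) < 2) stop("expected a two-column CSV", call. = FALSE)
  dt <- diff(d[[1]])
  if (!length(dt) || any(dt <= 0) ||
      max(abs(dt / stats::median(dt) - 1)) > 0.01)
    stop("time column is not uniformly sampled", call. = FALSE)
  uniform_series(d[[2]], rate = 1 / stats::median(dt), t0 = d[[1]][1],
                 units = units)
}
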