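#' Logarithmic wavelet scale grid
#'
#' Dyadic scale grid for the Morlet continuous wavelet transform:
#' `s_min * 2^(j / voices)` up to the first scale at or above `s_max`. The
#' default covers the 640-10240 s slow-oscillation band (0.1-1.6 mHz under
#' reciprocal conversion) in which neurovascular coupling is quantified.
#'
#' @param s_min_s,s_max_s smallest/largest scale in seconds.
#' @param voices scales per octave.
#' @param omega0 Morlet center frequency (nondimensional); 6 is the standard
#'   choice, giving Fourier factor `4*pi/(omega0 + sqrt(2 + omega0^2))`
#'   ~ 1.033.
#' @return A list of class `scale_grid` with `scales_s`, `voices`, `omega0`,
#'   `fourier_factor`.
#' @examples
#' g <- scale_grid()
#' range(g$scales_s)
#' @export
scale_grid <- function(s_min_s = 640, s_max_s = 10240, voices = 12,
                       omega0 = 6) {
  if (s_min_s <= 0 || s_max_s <= s_min_s)
    stop("need 0 < s_min_s < s_max_s", call. = FALSE)
  J <- ceiling(voices * log2(s_max_s / s_min_s))
  scales <- s_min_s * 2^((0:J) / voices)
  structure(list(scales_s = scales, voices = voices, omega0 = omega0,
                 fourier_factor = 4 * pi / (omega0 + sqrt(2 + omega0^2))),
            class = "scale_grid")
}

#' Scale label to equivalent frequency
#'
#' Plain reciprocal conversion used for axis labels (640 s = 1.5625 mHz,
#' 10000 s = 0.1 mHz), not the Morlet Fourier-factor conversion.
#'
#' @param scale_s scale(s) in seconds.
#' @return frequency in mHz.
#' @export
scale_to_mhz <- function(scale_s) 1000 / scale_s

# angular frequencies of an np-point FFT at sampling step dt
fft_omega <- function(np, dt) {
  2 * pi * c(0:(np %/% 2), -((np - np %/% 2 - 1):1)) / (np * dt)
}

#' Morlet continuous wavelet transform
#'
#' FFT-based analytic Morlet CWT on a zero-padded series. Coefficients are
#' normalized so that a unit-amplitude sinusoid of period `P` has maximal
#' power at the scale nearest `P / fourier_factor`.
#'
#' @param x a [uniform_series()].
#' @param grid a [scale_grid()]; scales exceeding the series duration are
#'   excluded with a warning.
#' @return A list of class `cwt_result` with complex coefficient matrix `w`
#'   (time rows x scale columns), `scales_s`, `rate`, `t0`, `omega0`.
#' @export
cwt_morlet <- function(x, grid = scale_grid()) {
  stopifnot(inherits(x, "uniform_series"), inherits(grid, "scale_grid"))
  n <- length(x$values)
  dt <- 1 / x$rate
  scales <- grid$scales_s
  keep <- scales <= n * dt
  if (!all(keep)) {
    warning(sprintf("excluding %d scale(s) exceeding the series duration",
                    sum(!keep)))
    scales <- scales[keep]
  }
  if (!length(scales)) stop("no usable scales for this series", call. = FALSE)
  np <- 2^ceiling(log2(n))
  fx <- stats::fft(c(x$values, numeric(np - n)))
  omega <- fft_omega(np, dt)
  K <- morlet_kernels(np, omega, scales, dt, grid$omega0)
  W <- stats::mvfft(K * fx, inverse = TRUE) / np
  structure(list(w = W[seq_len(n), , drop = FALSE], scales_s = scales,
                 rate = x$rate, t0 = x$t0, omega0 = grid$omega0,
                 voices = grid$voices,
                 fourier_factor = grid$fourier_factor),
            class = "cwt_result")
}

morlet_kernels <- function(np, omega, scales, dt, omega0) {
  K <- matrix(0, np, length(scales))
  pos <- omega > 0
  for (j in seq_along(scales))
    K[pos, j] <- pi^(-1 / 4) * sqrt(2 * pi * scales[j] / dt) *
      exp(-((scales[j] * omega[pos] - omega0)^2) / 2)
  K
}

# Boxcar smoothing across scale columns covering ~0.6 octave,
# edge-renormalized; works on real or complex matrices.
smooth_scale <- function(M, voices, width_octave = 0.6) {
  L <- max(1L, round(width_octave * voices))
  h <- L %/% 2L
  if (h == 0L) return(M)
  ns <- ncol(M)
  out <- M
  for (j in seq_len(ns)) {
    cols <- max(1L, j - h):min(ns, j + h)
    out[, j] <- rowMeans(M[, cols, drop = FALSE])
  }
  out
}

# Precomputed machinery for repeated coherence computations on a fixed
# (length, rate, grid): wavelet kernels, smoothing kernels, COI. The
# smoothing operator is boxcar across scales (~0.6 octave) followed by a
# scale-matched Gaussian in time (SD = scale/sqrt(2)); FFT padding is
# chosen so the largest Gaussian cannot wrap around the record.
wtc_engine <- function(n, rate, grid) {
  dt <- 1 / rate
  scales <- grid$scales_s[grid$scales_s <= n * dt]
  if (!length(scales))
    stop("no usable scales for this series length", call. = FALSE)
  ns <- length(scales)
  np1 <- 2^ceiling(log2(n))
  om1 <- fft_omega(np1, dt)
  K <- morlet_kernels(np1, om1, scales, dt, grid$omega0)
  sig <- scales / sqrt(2) * rate              # Gaussian SD in samples
  np2 <- 2^ceiling(log2(n + ceiling(4 * max(sig))))
  om2 <- fft_omega(np2, 1)
  Gt <- matrix(0, np2, ns)
  for (j in seq_len(ns)) Gt[, j] <- exp(-0.5 * (sig[j] * om2)^2)
  coi <- coi_mask(n, rate, scales)

  std <- function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0)
      stop("cannot compute coherence of a constant series", call. = FALSE)
    (v - mean(v)) / s
  }

  # analytic CWTs of two real series via one packed FFT
  cwt_pair <- function(xv, yv) {
    z <- stats::fft(complex(real = c(xv, numeric(np1 - n)),
                            imaginary = c(yv, numeric(np1 - n))))
    idx <- c(1L, np1:2L)
    X <- (z + Conj(z[idx])) / 2
    Y <- (z - Conj(z[idx])) / (2i)
    list(wx = stats::mvfft(K * X, inverse = TRUE)[seq_len(n), , drop = FALSE] / np1,
         wy = stats::mvfft(K * Y, inverse = TRUE)[seq_len(n), , drop = FALSE] / np1)
  }

  # squared coherence at the requested scale columns
  r2 <- function(xv, yv, cols = seq_len(ns)) {
    w <- cwt_pair(std(xv), std(yv))
    inv_s <- matrix(1 / scales, n, ns, byrow = TRUE)
    A <- smooth_scale(w$wx * Conj(w$wy) * inv_s, grid$voices)[, cols,
                                                              drop = FALSE]
    # pack the two real power fields into one complex matrix
    pw <- matrix(complex(real = Mod(w$wx)^2, imaginary = Mod(w$wy)^2),
                 n, ns)
    P <- smooth_scale(pw * inv_s, grid$voices)[, cols, drop = FALSE]
    nc <- length(cols)
    pad <- matrix(0i, np2, 2L * nc)
    pad[seq_len(n), seq_len(nc)] <- A
    pad[seq_len(n), nc + seq_len(nc)] <- P
    Fp <- stats::mvfft(pad) * Gt[, c(cols, cols), drop = FALSE]
    sm <- stats::mvfft(Fp, inverse = TRUE)[seq_len(n), , drop = FALSE] / np2
    SA <- sm[, seq_len(nc), drop = FALSE]
    SP <- sm[, nc + seq_len(nc), drop = FALSE]
    denom <- Re(SP) * Im(SP)
    out <- Mod(SA)^2 / pmax(denom, .Machine$double.eps)
    out[denom <= 0] <- 0
    pmin(pmax(out, 0), 1)
  }

  list(n = n, rate = rate, scales_s = scales, voices = grid$voices,
       coi = coi, r2 = r2)
}

#' Wavelet transform coherence
#'
#' Squared coherence `R2 = |S(Wxy / s)|^2 / (S(|Wx|^2 / s) S(|Wy|^2 / s))`
#' between two series sampled at the same rate, where `S` smooths across
#' scales (boxcar of ~0.6 octave) and in time (scale-matched Gaussian,
#' SD = scale/sqrt(2)). Series are mean-removed and variance-normalized
#' first and trimmed to common length. Values are clamped to `[0, 1]`.
#'
#' @param x,y [uniform_series()] at the same rate (within 0.1% relative).
#' @param grid a [scale_grid()].
#' @return A list of class `coherence_map` with `r2` (time x scale),
#'   `scales_s`, `rate`, `t0`, `coi_mask` (TRUE = inside the cone of
#'   influence, i.e. edge-affected), and empty significance slots.
#' @export
wtc <- function(x, y, grid = scale_grid()) {
  stopifnot(inherits(x, "uniform_series"), inherits(y, "uniform_series"))
  if (abs(x$rate / y$rate - 1) > 1e-3)
    stop("`x` and `y` must share a sampling rate", call. = FALSE)
  n <- min(length(x$values), length(y$values))
  if (n < 8) stop("series too short after trimming", call. = FALSE)
  eng <- wtc_engine(n, x$rate, grid)
  r2 <- eng$r2(x$values[seq_len(n)], y$values[seq_len(n)])
  structure(list(r2 = r2, scales_s = eng$scales_s, rate = x$rate, t0 = x$t0,
                 coi_mask = eng$coi, sig_mask = NULL, thresholds = NULL,
                 alpha = NULL, voices = grid$voices),
            class = "coherence_map")
}

#' Cone-of-influence mask
#'
#' Marks (time, scale) cells within the Morlet e-folding distance
#' `sqrt(2) * scale` of either record edge as inside the cone of influence
#' (edge-affected); these cells are excluded from pixel counting.
#'
#' @param n series length in samples.
#' @param rate sampling rate in Hz.
#' @param scales_s scales in seconds.
#' @return logical matrix (time x scale), TRUE = inside the COI.
#' @export
coi_mask <- function(n, rate, scales_s) {
  tsec <- (seq_len(n) - 1) / rate
  dist_edge <- pmin(tsec, (n - 1) / rate - tsec)
  outer(dist_edge, sqrt(2) * scales_s, `<`)
}

#' Lag-1 autocorrelation (AR(1) coefficient estimate)
#'
#' The coefficient used to parameterize red-noise surrogates; clamped to
#' `[0, 0.99]`. Errors on constant input, for which an AR(1) fit is
#' undefined.
#'
#' @param v numeric vector.
#' @return lag-1 autocorrelation in `[0, 0.99]`.
#' @export
ar1_coef <- function(v) {
  if (!is.finite(stats::sd(v)) || stats::sd(v) == 0)
    stop("AR(1) fit undefined for a constant series", call. = FALSE)
  a <- stats::acf(v, lag.max = 1, plot = FALSE)$acf[2]
  min(max(a, 0), 0.99)
}

#' Per-scale significance thresholds from AR(1) surrogates
#'
#' Monte-Carlo null distribution of squared wavelet coherence for pairs of
#' independent AR(1) series with the given lag-1 coefficients: for each
#' scale, the `1 - alpha` quantile of the pooled outside-COI coherence
#' values over `n_surrogates` surrogate pairs. The pooled distribution is
#' accumulated in 2000 bins on `[0, 1]` (threshold resolution 5e-4). Because
#' the null quantile varies smoothly across scale, it is evaluated on every
#' `thin_scales`-th scale and interpolated linearly in log2(scale) for the
#' rest. The threshold depends only on `(n, grid, alpha_x, alpha_y)`, so it
#' can be computed once and shared across coherence maps on the same grid.
#'
#' @param n series length in samples.
#' @param rate sampling rate in Hz.
#' @param grid a [scale_grid()].
#' @param alpha_x,alpha_y AR(1) coefficients of the two series.
#' @param n_surrogates number of surrogate pairs (>= 100).
#' @param alpha significance level.
#' @param seed integer seed.
#' @param thin_scales evaluate the Monte Carlo on every `thin_scales`-th
#'   scale (1 = all scales).
#' @return A list of class `wtc_thresholds` with per-scale `thresholds`.
#' @export
wtc_thresholds <- function(n, rate, grid = scale_grid(), alpha_x, alpha_y,
                           n_surrogates = 300, alpha = 0.05, seed = 1L,
                           thin_scales = 2L) {
  if (n_surrogates < 100)
    stop("`n_surrogates` must be >= 100", call. = FALSE)
  if (alpha <= 0 || alpha > 1)
    stop("`alpha` must lie in (0, 1]", call. = FALSE)
  eng <- wtc_engine(n, rate, grid)
  scales <- eng$scales_s
  ns <- length(scales)
  cols <- unique(c(seq(1L, ns, by = max(1L, as.integer(thin_scales))), ns))
  nb <- 2000L
  counts <- matrix(0, nb, length(cols))
  outside <- !eng$coi[, cols, drop = FALSE]
  for (i in seq_len(n_surrogates)) {
    xs <- generate_ar1(n, alpha_x, 1, seed = derive_seed(seed, paste0("sx", i)))
    ys <- generate_ar1(n, alpha_y, 1, seed = derive_seed(seed, paste0("sy", i)))
    r2 <- eng$r2(xs$values, ys$values, cols = cols)
    for (j in seq_along(cols)) {
      v <- r2[outside[, j], j]
      if (length(v))
        counts[, j] <- counts[, j] + tabulate(pmin(floor(v * nb) + 1L, nb), nb)
    }
  }
  thr_c <- numeric(length(cols))
  for (j in seq_along(cols)) {
    tot <- sum(counts[, j])
    if (tot == 0) { thr_c[j] <- 1; next }
    cdf <- cumsum(counts[, j]) / tot
    thr_c[j] <- which(cdf >= 1 - alpha)[1] / nb  # upper edge of quantile bin
  }
  thr <- if (length(cols) == ns) thr_c else
    stats::approx(log2(scales[cols]), thr_c, xout = log2(scales),
                  rule = 2)$y
  structure(list(thresholds = thr, scales_s = scales, alpha = alpha,
                 n = n, rate = rate, alpha_x = alpha_x, alpha_y = alpha_y,
                 n_surrogates = n_surrogates, seed = seed,
                 thin_scales = thin_scales),
            class = "wtc_thresholds")
}

#' Mark significant coherence against the AR(1) surrogate null
#'
#' Attaches `sig_mask = r2 > threshold(scale)` to a coherence map. By
#' default the per-scale thresholds are computed by [wtc_thresholds()] with
#' AR(1) coefficients estimated (lag-1 autocorrelation) from `x` and `y`;
#' precomputed thresholds on the same grid can be supplied instead, which a
#' cohort run uses to share one Monte-Carlo null across methods.
#'
#' @param map a `coherence_map` from [wtc()].
#' @param x,y the series the map was computed from (used for AR(1)
#'   estimation; ignored when `thresholds` is given).
#' @param n_surrogates surrogate pairs (>= 100).
#' @param alpha significance level (`alpha = 1` marks everything).
#' @param seed integer seed for the surrogate draw.
#' @param thresholds optional precomputed [wtc_thresholds()].
#' @param thin_scales passed to [wtc_thresholds()].
#' @return The map with `sig_mask`, `thresholds` and `alpha` filled in.
#' @export
significance_mask <- function(map, x = NULL, y = NULL, n_surrogates = 300,
                              alpha = 0.05, seed = 1L, thresholds = NULL,
                              thin_scales = 2L) {
  stopifnot(inherits(map, "coherence_map"))
  if (is.null(thresholds)) {
    if (is.null(x) || is.null(y))
      stop("need `x` and `y` (or precomputed `thresholds`)", call. = FALSE)
    n <- nrow(map$r2)
    thresholds <- wtc_thresholds(n, map$rate, scale_grid_of(map),
                                 ar1_coef(x$values[seq_len(n)]),
                                 ar1_coef(y$values[seq_len(n)]),
                                 n_surrogates = n_surrogates, alpha = alpha,
                                 seed = seed, thin_scales = thin_scales)
  }
  stopifnot(inherits(thresholds, "wtc_thresholds"))
  if (length(thresholds$scales_s) != length(map$scales_s) ||
      max(abs(thresholds$scales_s / map$scales_s - 1)) > 1e-8)
    stop("threshold scales do not match the map grid", call. = FALSE)
  map$sig_mask <- sweep(map$r2, 2L, thresholds$thresholds, `>`)
  map$thresholds <- thresholds$thresholds
  map$alpha <- thresholds$alpha
  map
}

# Reconstruct the scale grid a map was computed on.
scale_grid_of <- function(map) {
  g <- scale_grid(min(map$scales_s), max(map$scales_s), voices = map$voices)
  g$scales_s <- map$scales_s
  g
}

#' Count significant coherence pixels outside the cone of influence
#'
#' One pixel is one (time sample x scale bin) cell of the coherence grid;
#' the total over all scales outside the COI is the neurovascular-coupling
#' statistic Pix_total. Maps being compared must share the same grid.
#'
#' @param map a `coherence_map` with `sig_mask` computed.
#' @return integer pixel count.
#' @export
pix_total <- function(map) {
  stopifnot(inherits(map, "coherence_map"))
  if (is.null(map$sig_mask) || is.null(map$coi_mask))
    stop("significance and COI masks must be computed first", call. = FALSE)
  sum(map$sig_mask & !map$coi_mask)
}

#' Coefficient of variation of pixel counts across methods
#'
#' Sample standard deviation of the three methods' Pix_total values divided
#' by their mean, in percent. Zero iff all counts are equal; `NA` (an
#' explicit no-coherence marker) when the mean is zero.
#'
#' @param pix numeric vector of three nonnegative pixel counts.
#' @return COV in percent, or `NA` if no method found any coherence.
#' @examples
#' cov_across_methods(c(100, 110, 120))
#' @export
cov_across_methods <- function(pix) {
  if (length(pix) != 3 || any(pix < 0))
    stop("`pix` must be three nonnegative counts", call. = FALSE)
  m <- mean(pix)
  if (m == 0) return(NA_real_)
  100 * stats::sd(pix) / m
}

#' Plot a coherence map with significance contours and COI shading
#' @param x a `coherence_map`.
#' @param ... further arguments to [graphics::image()].
#' @export
plot.coherence_map <- function(x, ...) {
  t_h <- (x$t0 + (seq_len(nrow(x$r2)) - 1) / x$rate) / 3600
  ls <- log2(x$scales_s)
  graphics::image(t_h, ls, x$r2, zlim = c(0, 1),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "time (h)", ylab = "scale (s)", yaxt = "n", ...)
  at <- pretty(ls)
  graphics::axis(2, at = at, labels = round(2^at))
  if (!is.null(x$sig_mask))
    graphics::contour(t_h, ls, x$sig_mask + 0, levels = 0.5, add = TRUE,
                      drawlabels = FALSE)
  coi_s <- apply(x$coi_mask, 1,
                 function(r) if (any(!r)) max(c(-Inf, ls[r])) else Inf)
  graphics::lines(t_h, pmin(coi_s, max(ls)), lty = 2)
  invisible(x)
}

#' Write a coherence map as a CSV bundle
#'
#' `<stem>_r2.csv` holds the R2 matrix (rows = time samples), and when
#' present `<stem>_sig.csv` / `<stem>_coi.csv` the masks; axis metadata goes
#' to `<stem>_axes.json`.
#'
#' @param map a `coherence_map`.
#' @param stem output path stem.
#' @return Invisibly, the written paths.
#' @export
write_coherence_csv <- function(map, stem) {
  stopifnot(inherits(map, "coherence_map"))
  paths <- paste0(stem, "_r2.csv")
  utils::write.table(map$r2, paths, sep = ",", row.names = FALSE,
                     col.names = paste0("s", signif(map$scales_s, 6)))
  for (m in c("sig_mask", "coi_mask")) if (!is.null(map[[m]])) {
    p <- paste0(stem, "_", sub("_mask", "", m), ".csv")
    utils::write.table(map[[m]] + 0L, p, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    paths <- c(paths, p)
  }
  p <- paste0(stem, "_axes.json")
  jsonlite::write_json(list(scales_s = map$scales_s, rate_hz = map$rate,
                            t0_s = map$t0, alpha = map$alpha),
                       p, digits = NA)
  invisible(c(paths, p))
}
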