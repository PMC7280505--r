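#' Configuration for a synthetic EEG + SctO2 recording
#'
#' Defines a paired recording: broadband EEG whose amplitude envelope carries
#' slow oscillations at the configured coupling periods, and an SctO2 series
#' that shares those oscillations in proportion to `coupling_strength`, plus
#' independent AR(1) noise. The defaults emulate a 20-hour neonatal
#' monitoring session: 256 Hz EEG and SctO2 at 256/1224 Hz (~0.209 Hz, the
#' rate at which the NIRS device reports), with coupling periods inside the
#' 640-10240 s analysis band.
#'
#' @param duration_s recording length in seconds.
#' @param eeg_rate EEG sampling rate in Hz.
#' @param scto2_rate SctO2 sampling rate in Hz; default `256/1224` (the exact
#'   value rounded elsewhere as 0.209 Hz).
#' @param pattern EEG background: `"continuous"` or `"burst_suppression"`.
#' @param coupling_periods_s periods (s) of the shared slow modulation; each
#'   must lie in `[2/scto2_rate, duration_s/4]` so the wavelet analysis can
#'   resolve it.
#' @param coupling_strength fraction in `[0, 1]` scaling how strongly the
#'   modulation enters SctO2 (0 = uncoupled).
#' @param mod_depth depth in `[0, 1)` of the multiplicative EEG amplitude
#'   modulation, `envelope = base * (1 + mod_depth * m(t))`.
#' @param envelope_base_uV baseline EEG envelope amplitude in microvolts.
#' @param noise_sd_uV SD of additive broadband sensor noise on the EEG, uV.
#' @param scto2_mean_pct mean SctO2 in percent.
#' @param scto2_coupling_amp_pct amplitude (percent) of the shared modulation
#'   in SctO2 at `coupling_strength = 1`.
#' @param scto2_noise_sd_pct SD of the AR(1) SctO2 noise, percent.
#' @param ar1_alpha lag-1 coefficient of the SctO2 noise, in `[0, 1)`.
#' @param scto2_lag_s lag (s) with which the modulation enters SctO2.
#' @param burst_rate_per_min,burst_len_s,suppression_ratio burst-suppression
#'   geometry, used when `pattern = "burst_suppression"`.
#' @param seed integer seed; identical configs give bit-identical recordings.
#' @return A validated list of class `synthetic_config`.
#' @seealso [generate_recording()]
#' @export
synthetic_config <- function(duration_s = 72000,
                             eeg_rate = 256,
                             scto2_rate = 256 / 1224,
                             pattern = c("continuous", "burst_suppression"),
                             coupling_periods_s = c(1280, 3200, 8000),
                             coupling_strength = 0.8,
                             mod_depth = 0.5,
                             envelope_base_uV = 25,
                             noise_sd_uV = 2,
                             scto2_mean_pct = 75,
                             scto2_coupling_amp_pct = 3,
                             scto2_noise_sd_pct = 1.5,
                             ar1_alpha = 0.8,
                             scto2_lag_s = 0,
                             burst_rate_per_min = 6,
                             burst_len_s = 2,
                             suppression_ratio = 0.1,
                             seed = 1L) {
  pattern <- match.arg(pattern)
  cfg <- list(duration_s = duration_s, eeg_rate = eeg_rate,
              scto2_rate = scto2_rate, pattern = pattern,
              coupling_periods_s = coupling_periods_s,
              coupling_strength = coupling_strength, mod_depth = mod_depth,
              envelope_base_uV = envelope_base_uV, noise_sd_uV = noise_sd_uV,
              scto2_mean_pct = scto2_mean_pct,
              scto2_coupling_amp_pct = scto2_coupling_amp_pct,
              scto2_noise_sd_pct = scto2_noise_sd_pct,
              ar1_alpha = ar1_alpha, scto2_lag_s = scto2_lag_s,
              burst_rate_per_min = burst_rate_per_min,
              burst_len_s = burst_len_s,
              suppression_ratio = suppression_ratio,
              seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  bad <- function(field, msg)
    stop(sprintf("invalid synthetic config: `%s` %s", field, msg), call. = FALSE)
  pos1 <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      bad(field, "must be a single positive number")
  }
  for (f in c("duration_s", "eeg_rate", "scto2_rate", "envelope_base_uV",
              "scto2_mean_pct")) pos1(f)
  if (cfg$coupling_strength < 0 || cfg$coupling_strength > 1)
    bad("coupling_strength", "must lie in [0, 1]")
  if (cfg$mod_depth < 0 || cfg$mod_depth >= 1)
    bad("mod_depth", "must lie in [0, 1)")
  if (cfg$ar1_alpha < 0 || cfg$ar1_alpha >= 1)
    bad("ar1_alpha", "must lie in [0, 1)")
  if (cfg$noise_sd_uV < 0) bad("noise_sd_uV", "must be >= 0")
  if (cfg$scto2_noise_sd_pct < 0) bad("scto2_noise_sd_pct", "must be >= 0")
  if (cfg$scto2_coupling_amp_pct < 0) bad("scto2_coupling_amp_pct", "must be >= 0")
  if (cfg$duration_s * cfg$eeg_rate < 1 || cfg$duration_s * cfg$scto2_rate < 1)
    bad("duration_s", "must contain at least one sample at both rates")
  p_lo <- 2 / cfg$scto2_rate
  p_hi <- cfg$duration_s / 4
  if (length(cfg$coupling_periods_s) &&
      (any(cfg$coupling_periods_s < p_lo) || any(cfg$coupling_periods_s > p_hi)))
    bad("coupling_periods_s",
        sprintf("must lie within [%.4g, %.4g] s to be resolvable", p_lo, p_hi))
  invisible(cfg)
}

#' First-order autoregressive (red) noise
#'
#' Generates `x[t] = alpha * x[t-1] + e[t]` with innovation variance chosen so
#' the stationary variance is `sd^2`. This is the noise family used both for
#' the SctO2 background and for the surrogate null of the coherence
#' significance test.
#'
#' @param n number of samples (>= 2).
#' @param alpha lag-1 coefficient, `0 <= alpha < 1`.
#' @param sd stationary standard deviation (output units).
#' @param seed integer seed.
#' @param rate sampling rate in Hz attached to the returned series.
#' @param units unit label for the returned series.
#' @return A [uniform_series()] of length `n`.
#' @examples
#' x <- generate_ar1(5000, alpha = 0.8, sd = 1, seed = 42)
#' acf(x$values, lag.max = 1, plot = FALSE)$acf[2]  # ~0.8
#' @export
generate_ar1 <- function(n, alpha, sd, seed, rate = 1, units = "") {
  if (n < 2) stop("`n` must be >= 2", call. = FALSE)
  if (alpha < 0 || alpha >= 1)
    stop("`alpha` must lie in [0, 1) (alpha >= 1 is non-stationary)",
         call. = FALSE)
  if (sd < 0) stop("`sd` must be >= 0", call. = FALSE)
  vals <- with_seed(seed, {
    if (sd == 0) numeric(n)
    else {
      e <- rnorm(n, sd = sd * sqrt(1 - alpha^2))
      x0 <- rnorm(1, sd = sd)
      if (alpha == 0) e
      else as.numeric(stats::filter(e, alpha, method = "recursive",
                                    init = x0))
    }
  })
  uniform_series(vals, rate = rate, units = units)
}

#' Burst-suppression broadband carrier
#'
#' Unit-burst-level broadband noise whose amplitude alternates between 1
#' (burst) and `suppression_ratio` (suppression), with burst onsets drawn
#' from a seeded Poisson point process. Emulates the discontinuous neonatal
#' EEG background; the burst/suppression labelling is attached as the
#' `"in_burst"` attribute for validation.
#'
#' @param duration_s length in seconds.
#' @param rate sampling rate in Hz.
#' @param burst_rate_per_min expected burst onsets per minute (0 allowed:
#'   constant suppressed signal).
#' @param burst_len_s burst duration in seconds.
#' @param suppression_ratio amplitude ratio suppression/burst, in (0, 1).
#' @param seed integer seed.
#' @return A [uniform_series()] with attribute `in_burst` (logical).
#' @export
burst_suppression_carrier <- function(duration_s, rate, burst_rate_per_min,
                                      burst_len_s, suppression_ratio, seed) {
  if (suppression_ratio <= 0 || suppression_ratio >= 1)
    stop("`suppression_ratio` must lie in (0, 1)", call. = FALSE)
  if (burst_rate_per_min < 0 || burst_len_s <= 0)
    stop("invalid burst geometry", call. = FALSE)
  if (burst_len_s * burst_rate_per_min / 60 >= 1)
    stop("infeasible burst geometry: expected burst occupancy >= 100%",
         call. = FALSE)
  n <- round(duration_s * rate)
  res <- with_seed(seed, {
    in_burst <- logical(n)
    k <- rpois(1, burst_rate_per_min * duration_s / 60)
    if (k > 0) {
      onsets <- sort(runif(k, 0, duration_s))
      len <- round(burst_len_s * rate)
      for (on in onsets) {
        i0 <- floor(on * rate) + 1L
        i1 <- min(i0 + len - 1L, n)
        in_burst[i0:i1] <- TRUE
      }
    }
    amp <- ifelse(in_burst, 1, suppression_ratio)
    list(vals = amp * rnorm(n), in_burst = in_burst)
  })
  out <- uniform_series(res$vals, rate = rate)
  attr(out, "in_burst") <- res$in_burst
  out
}

#' Generate a paired synthetic EEG + SctO2 recording
#'
#' Builds the EEG as a broadband carrier (continuous noise or
#' burst-suppression) multiplied by a slow envelope
#' `base * (1 + mod_depth * m(t))`, where `m(t)` is a sum of seeded-phase
#' sinusoids at `coupling_periods_s` normalized to `[-1, 1]`, plus additive
#' sensor noise. The SctO2 series receives
#' `coupling_strength * scto2_coupling_amp_pct * m(t - lag)` on top of its
#' mean plus independent AR(1) noise, then is clipped to `[0, 100]` (clip
#' events are counted in `truth$n_clipped`).
#'
#' @param cfg a [synthetic_config()].
#' @return A list of class `synthetic_recording` with elements `eeg` and
#'   `scto2` (both [uniform_series()]) and `truth` (the modulation signal at
#'   the SctO2 rate, coupling parameters and clip count).
#' @examples
#' cfg <- synthetic_config(duration_s = 3600, coupling_periods_s = 300,
#'                         seed = 7)
#' rec <- generate_recording(cfg)
#' rec$eeg; rec$scto2
#' @export
generate_recording <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  validate_synthetic_config(cfg)
  n_eeg <- round(cfg$duration_s * cfg$eeg_rate)
  n_s <- round(cfg$duration_s * cfg$scto2_rate)

  modulation <- function(t) {
    if (!length(cfg$coupling_periods_s)) return(numeric(length(t)))
    ph <- with_seed(derive_seed(cfg$seed, "phases"),
                    runif(length(cfg$coupling_periods_s), 0, 2 * pi))
    m <- numeric(length(t))
    for (i in seq_along(cfg$coupling_periods_s))
      m <- m + sin(2 * pi * t / cfg$coupling_periods_s[i] + ph[i])
    # normalize by the worst-case sum of amplitudes so |m| <= 1 regardless of t
    m / length(cfg$coupling_periods_s)
  }

  t_eeg <- (seq_len(n_eeg) - 1L) / cfg$eeg_rate
  m_eeg <- modulation(t_eeg)
  carrier <- if (cfg$pattern == "burst_suppression") {
    burst_suppression_carrier(cfg$duration_s, cfg$eeg_rate,
                              cfg$burst_rate_per_min, cfg$burst_len_s,
                              cfg$suppression_ratio,
                              seed = derive_seed(cfg$seed, "carrier"))$values
  } else {
    with_seed(derive_seed(cfg$seed, "carrier"), rnorm(n_eeg))
  }
  envelope_t <- cfg$envelope_base_uV * (1 + cfg$mod_depth * m_eeg)
  sensor <- if (cfg$noise_sd_uV > 0)
    with_seed(derive_seed(cfg$seed, "sensor"),
              rnorm(n_eeg, sd = cfg$noise_sd_uV)) else numeric(n_eeg)
  eeg <- uniform_series(envelope_t * carrier + sensor, rate = cfg$eeg_rate,
                        units = "uV")

  t_s <- (seq_len(n_s) - 1L) / cfg$scto2_rate
  m_s <- modulation(t_s - cfg$scto2_lag_s)
  noise <- generate_ar1(n_s, cfg$ar1_alpha, cfg$scto2_noise_sd_pct,
                        seed = derive_seed(cfg$seed, "scto2"),
                        rate = cfg$scto2_rate)$values
  raw <- cfg$scto2_mean_pct +
    cfg$coupling_strength * cfg$scto2_coupling_amp_pct * m_s + noise
  n_clipped <- sum(raw < 0 | raw > 100)
  scto2 <- uniform_series(pmin(pmax(raw, 0), 100), rate = cfg$scto2_rate,
                          units = "%")

  structure(list(
    eeg = eeg, scto2 = scto2,
    truth = list(modulation_scto2 = m_s,
                 coupling_periods_s = cfg$coupling_periods_s,
                 coupling_strength = cfg$coupling_strength,
                 mod_depth = cfg$mod_depth, n_clipped = n_clipped,
                 config = cfg)),
    class = "synthetic_recording")
}

#' Emulated device aEEG conversion (synthetic stand-in)
#'
#' A plausible cerebral-function-monitor style raw-EEG to 256 Hz aEEG
#' conversion used to exercise the device-ingestion (M3) path on synthetic
#' data: symmetric 5th-order Butterworth band-pass 2-15 Hz, full-wave
#' rectification, zero-phase Butterworth envelope and a gain of 2. It is a
#' synthetic stand-in for an undisclosed commercial algorithm, not a
#' reimplementation of any device.
#'
#' @param eeg raw EEG [uniform_series()] in microvolts.
#' @param cutoff_hz envelope low-pass cutoff in Hz.
#' @return A nonnegative 256 Hz amplitude [uniform_series()].
#' @export
synthetic_device_aeeg <- function(eeg, cutoff_hz = 1) {
  stopifnot(inherits(eeg, "uniform_series"))
  ny <- eeg$rate / 2
  bp <- signal::butter(5, c(2, 15) / ny, type = "pass")
  filt <- signal::filtfilt(bp, eeg$values)
  env <- envelope(uniform_series(abs(filt), eeg$rate, eeg$t0, eeg$units),
                  cutoff_hz = cutoff_hz)
  apply_gain(env, 2)
}

#' Write a synthetic recording to plain-text files
#'
#' EEG goes to `<stem>_eeg.csv` (`time_s,value_uV`), SctO2 to
#' `<stem>_scto2.csv` (`time_s,scto2_pct`) and the generating parameters to a
#' JSON sidecar `<stem>_config.json`. With `eeg_format = "edf"` the EEG is
#' written as a single-channel EDF instead.
#'
#' @param rec a `synthetic_recording` from [generate_recording()].
#' @param stem output path stem.
#' @param eeg_format `"csv"` or `"edf"`.
#' @return Invisibly, the written file paths.
#' @export
write_recording <- function(rec, stem, eeg_format = c("csv", "edf")) {
  stopifnot(inherits(rec, "synthetic_recording"))
  eeg_format <- match.arg(eeg_format)
  paths <- character()
  if (eeg_format == "edf") {
    p <- paste0(stem, "_eeg.edf")
    write_edf(p, list(EEG = rec$eeg))
  } else {
    p <- paste0(stem, "_eeg.csv")
    utils::write.csv(data.frame(time_s = series_times(rec$eeg),
                                value_uV = rec$eeg$values),
                     p, row.names = FALSE)
  }
  paths <- c(paths, p)
  p <- paste0(stem, "_scto2.csv")
  utils::write.csv(data.frame(time_s = series_times(rec$scto2),
                              scto2_pct = rec$scto2$values),
                   p, row.names = FALSE)
  paths <- c(paths, p)
  p <- paste0(stem, "_config.json")
  jsonlite::write_json(unclass(rec$truth$config), p, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(paths, p))
}
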