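#' Segmentation geometry of the aEEG margin pipeline
#'
#' Computes the arithmetic that links the 256 Hz EEG to the ~0.209 Hz margin
#' rate: samples per epoch, the exact margin rate, the overlap of the
#' 15-s sliding window, and the span of the reference toolbox smoothing
#' (five 3.12-s terminal points).
#'
#' @param eeg_rate EEG sampling rate in Hz.
#' @param step_s margin stride in seconds.
#' @param window_s sliding-window length in seconds (overlapping algorithm).
#' @return Named list: `epoch_samples`, `margin_rate_hz`, `window_samples`,
#'   `overlap_s`, `reference_epoch_s`, `reference_points`,
#'   `reference_smooth_s`.
#' @examples
#' aeeg_geometry()$epoch_samples  # 1224
#' @export
aeeg_geometry <- function(eeg_rate = 256, step_s = 1224 / 256,
                          window_s = 15) {
  epoch_samples <- round(step_s * eeg_rate)
  list(epoch_samples = epoch_samples,
       margin_rate_hz = eeg_rate / epoch_samples,
       window_samples = round(window_s * eeg_rate),
       overlap_s = window_s - epoch_samples / eeg_rate,
       reference_epoch_s = 3.12, reference_points = 5L,
       reference_smooth_s = 3.12 * 5)
}

#' Pipeline run configuration
#'
#' Aggregates every constant of the end-to-end run; the defaults are the
#' pipeline's canonical values (2-15 Hz asymmetric band-pass at
#' 12 dB/decade, gains 2 and 1.631, 90th/10th percentiles, 15-s windows
#' stepped by 4.78 s, 640-10240 s analysis band, 300 surrogates at
#' alpha = 0.05).
#'
#' @param mode `"synthetic"` or `"files"`.
#' @param synthetic a [synthetic_config()] (synthetic mode).
#' @param files list with paths `eeg` (CSV or EDF), `scto2` (CSV), optional
#'   `aeeg_device` (CSV, 256 Hz device aEEG) and `channel` (EDF channel
#'   label(s); two labels form a derivation such as C3-C4).
#' @param methods subset of `c("M1", "M2", "M3")` to run.
#' @param filter a [filter_spec()].
#' @param gains named envelope gains for the two raw-EEG chains.
#' @param envelope_cutoff_hz Butterworth envelope cutoff, Hz.
#' @param epoch_len_s,epoch_step_s margin window geometry, seconds.
#' @param hi_pct,lo_pct terminal-point percentiles.
#' @param smoother margin smoother, `"ma3"` or `"spline"`.
#' @param grid a [scale_grid()] shared by all methods.
#' @param n_surrogates Monte-Carlo surrogate pairs for significance.
#' @param alpha significance level.
#' @param share_thresholds compute the surrogate threshold once per subject
#'   and share it across methods (they are evaluated on the identical grid
#'   and their bandwidth series have near-identical AR(1) structure).
#' @param seed master seed; stage seeds are derived from it by name.
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @return A list of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "files"),
                       synthetic = synthetic_config(),
                       files = list(eeg = NULL, scto2 = NULL,
                                    aeeg_device = NULL,
                                    channel = c("C3", "C4")),
                       methods = c("M1", "M2", "M3"),
                       filter = filter_spec(),
                       gains = c(M1 = 2, M2 = 1.631),
                       envelope_cutoff_hz = 1,
                       epoch_len_s = 15, epoch_step_s = 1224 / 256,
                       hi_pct = 90, lo_pct = 10, smoother = "ma3",
                       grid = scale_grid(),
                       n_surrogates = 300, alpha = 0.05,
                       share_thresholds = TRUE,
                       seed = 1L, out_dir = NULL) {
  mode <- match.arg(mode)
  methods <- match.arg(methods, c("M1", "M2", "M3"), several.ok = TRUE)
  cfg <- list(mode = mode, synthetic = synthetic, files = files,
              methods = methods, filter = filter, gains = gains,
              envelope_cutoff_hz = envelope_cutoff_hz,
              epoch_len_s = epoch_len_s, epoch_step_s = epoch_step_s,
              hi_pct = hi_pct, lo_pct = lo_pct, smoother = smoother,
              grid = grid, n_surrogates = n_surrogates, alpha = alpha,
              share_thresholds = share_thresholds, seed = as.integer(seed),
              out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

# FNV-1a hash of the deparsed config, hex string; identifies a run.
config_hash <- function(cfg) {
  s <- paste(deparse(cfg[setdiff(names(cfg), "out_dir")]), collapse = "")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full pipeline for one subject
#'
#' Generates (or loads) the paired EEG/SctO2 recording, derives the aEEG
#' bandwidth with each requested method, computes wavelet coherence against
#' SctO2 on the shared grid, marks significance against the AR(1) surrogate
#' null, counts pixels and forms the cross-method COV.
#'
#' @param cfg a [run_config()].
#' @param verbose print per-stage lengths and rates.
#' @return A list of class `run_report`: `pix` (named per method), `cov_pct`,
#'   `maps`, `traces`, `bandwidths`, `scto2`, `hash`, `truth` (synthetic
#'   mode), `provenance`.
#' @export
run_subject <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  if (cfg$mode == "synthetic") {
    rec <- stage("synthetic", generate_recording(cfg$synthetic))
    eeg <- rec$eeg; scto2 <- rec$scto2
    device <- if ("M3" %in% cfg$methods)
      stage("device_aeeg",
            synthetic_device_aeeg(eeg, cutoff_hz = cfg$envelope_cutoff_hz))
    truth <- rec$truth
  } else {
    f <- cfg$files
    if (is.null(f$eeg) || is.null(f$scto2))
      stop("[input] file mode needs `files$eeg` and `files$scto2`",
           call. = FALSE)
    if ("M3" %in% cfg$methods && is.null(f$aeeg_device))
      stop("[input] method M3 needs `files$aeeg_device`", call. = FALSE)
    eeg <- stage("input", if (grepl("\\.edf$", f$eeg, ignore.case = TRUE))
      read_edf(f$eeg, f$channel) else read_series_csv(f$eeg, units = "uV"))
    scto2 <- stage("input", read_series_csv(f$scto2, units = "%"))
    device <- if ("M3" %in% cfg$methods) {
      if (is.null(f$aeeg_device))
        stop("[input] method M3 needs `files$aeeg_device`", call. = FALSE)
      stage("input", read_series_csv(f$aeeg_device, units = "uV"))
    }
    truth <- NULL
  }
  say("EEG: n = %d at %g Hz; SctO2: n = %d at %.5f Hz",
      length(eeg$values), eeg$rate, length(scto2$values), scto2$rate)

  traces <- list()
  env_base <- NULL
  if (any(c("M1", "M2") %in% cfg$methods)) {
    # shared preprocessing: asymmetric FIR, rectification, envelope
    env_base <- stage("preprocess", {
      b <- design_asymmetric_filter(eeg$rate, cfg$filter)
      envelope(rectify(apply_fir(eeg, b)), cutoff_hz = cfg$envelope_cutoff_hz)
    })
  }
  for (m in cfg$methods) {
    traces[[m]] <- stage(paste0("aeeg_", m), switch(m,
      M1 = margins_m1(apply_gain(env_base, cfg$gains[["M1"]]),
                      epoch_len_s = cfg$epoch_len_s,
                      step_s = cfg$epoch_step_s, hi_pct = cfg$hi_pct,
                      lo_pct = cfg$lo_pct, smoother = cfg$smoother),
      M2 = margins_m2(apply_gain(env_base, cfg$gains[["M2"]]),
                      step_s = cfg$epoch_step_s, hi_pct = cfg$hi_pct,
                      lo_pct = cfg$lo_pct, smoother = cfg$smoother),
      M3 = margins_m3(device, epoch_len_s = cfg$epoch_len_s,
                      step_s = cfg$epoch_step_s, hi_pct = cfg$hi_pct,
                      lo_pct = cfg$lo_pct, smoother = cfg$smoother)))
    say("%s margins: n = %d at %.5f Hz", m, length(traces[[m]]$uma$values),
        traces[[m]]$uma$rate)
  }
  bws <- lapply(traces, bandwidth)

  maps <- list()
  thr <- NULL
  # identical time-scale grid across methods: trim every pair to the common
  # margin length so Pix_total counts the same usable cells for each method
  n_common <- min(vapply(bws, length, numeric(1)), length(scto2$values))
  bws <- lapply(bws, function(b)
    uniform_series(b$values[seq_len(n_common)], b$rate, b$t0, b$units))
  scto2_c <- uniform_series(scto2$values[seq_len(n_common)], scto2$rate,
                            scto2$t0, scto2$units)
  if (cfg$share_thresholds) {
    ax <- mean(vapply(bws, function(b)
      ar1_coef(b$values[seq_len(n_common)]), numeric(1)))
    ay <- ar1_coef(scto2$values[seq_len(n_common)])
    thr <- stage("significance",
                 wtc_thresholds(n_common, scto2$rate, cfg$grid, ax, ay,
                                n_surrogates = cfg$n_surrogates,
                                alpha = cfg$alpha,
                                seed = derive_seed(cfg$seed, "surrogates")))
  }
  for (m in cfg$methods) {
    map <- stage(paste0("wtc_", m), wtc(bws[[m]], scto2_c, cfg$grid))
    maps[[m]] <- stage("significance", significance_mask(
      map, bws[[m]], scto2_c, n_surrogates = cfg$n_surrogates,
      alpha = cfg$alpha, seed = derive_seed(cfg$seed, paste0("surr_", m)),
      thresholds = thr))
  }
  pix <- vapply(maps, pix_total, numeric(1))
  cov_pct <- if (all(c("M1", "M2", "M3") %in% cfg$methods))
    cov_across_methods(pix[c("M1", "M2", "M3")]) else NA_real_
  if (is.na(cov_pct) && length(cfg$methods) < 3)
    message("COV unavailable: needs all three methods")

  report <- structure(list(
    pix = pix, cov_pct = cov_pct, maps = maps, traces = traces,
    bandwidths = bws, scto2 = scto2, truth = truth,
    hash = config_hash(cfg),
    provenance = list(seed = cfg$seed, alpha = cfg$alpha,
                      n_surrogates = cfg$n_surrogates,
                      share_thresholds = cfg$share_thresholds,
                      version = as.character(utils::packageVersion("nvcwave")))),
    class = "run_report")
  if (!is.null(cfg$out_dir)) write_run_report(report, cfg)
  report
}

write_run_report <- function(report, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stem <- file.path(cfg$out_dir, report$hash)
  for (m in names(report$traces))
    write_aeeg_csv(report$traces[[m]], paste0(stem, "_aeeg_", m, ".csv"))
  for (m in names(report$maps))
    write_coherence_csv(report$maps[[m]], paste0(stem, "_wtc_", m))
  jsonlite::write_json(list(hash = report$hash,
                            pix_total = as.list(report$pix),
                            cov_pct = report$cov_pct,
                            provenance = report$provenance),
                       paste0(stem, "_nvc.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>", x$hash, "\n  Pix_total:",
      paste(sprintf("%s=%d", names(x$pix), x$pix), collapse = ", "),
      sprintf("\n  COV = %.2f%%\n", x$cov_pct))
  invisible(x)
}

#' Configurations for a synthetic cohort
#'
#' One [run_config()] per subject, identical in every respect except the
#' coupling strength and the seed stream, so the cohort spans weak to strong
#' neurovascular coupling on a shared wavelet grid.
#'
#' @param n_subjects number of subjects.
#' @param coupling_strengths coupling strength per subject.
#' @param duration_s recording length per subject, seconds.
#' @param coupling_periods_s shared modulation periods, seconds.
#' @param pattern EEG background pattern, recycled over subjects.
#' @param seed master seed.
#' @param ... further arguments to [run_config()].
#' @return List of `run_config`.
#' @export
synthetic_cohort <- function(n_subjects = 8,
                             coupling_strengths = seq(0.1, 1,
                                                      length.out = n_subjects),
                             duration_s = 32400,
                             coupling_periods_s = c(1600, 4800),
                             pattern = c("continuous", "burst_suppression"),
                             seed = 1L, ...) {
  pattern <- rep_len(match.arg(pattern, several.ok = TRUE), n_subjects)
  lapply(seq_len(n_subjects), function(i) {
    run_config(mode = "synthetic",
               synthetic = synthetic_config(
                 duration_s = duration_s,
                 coupling_periods_s = coupling_periods_s,
                 coupling_strength = coupling_strengths[i],
                 pattern = pattern[i],
                 seed = derive_seed(seed, paste0("subject", i))),
               seed = derive_seed(seed, paste0("run", i)), ...)
  })
}

#' Run a cohort and assemble agreement analytics
#'
#' Runs [run_subject()] for each configuration (all must share the wavelet
#' grid), then produces the cohort table (subject, method, Pix_total, COV),
#' pairwise Bland-Altman comparisons and identity regressions of Pix_total,
#' and the per-method regression of COV on Pix_total.
#'
#' @param cfgs list of [run_config()], length >= 2 for agreement outputs.
#' @param verbose passed to [run_subject()].
#' @return A list of class `cohort_report`: `table` (data frame), `pix`
#'   (subjects x methods), `cov_pct`, `bland_altman` and
#'   `identity` (per method pair), `cov_regression` (per method),
#'   `reports`.
#' @export
run_cohort <- function(cfgs, verbose = FALSE) {
  stopifnot(is.list(cfgs), length(cfgs) >= 1)
  grids <- vapply(cfgs, function(cfg)
    paste(signif(cfg$grid$scales_s, 10), collapse = ","), character(1))
  if (length(unique(grids)) != 1)
    stop("all subjects must share the same wavelet grid", call. = FALSE)
  reports <- lapply(cfgs, run_subject, verbose = verbose)
  methods <- names(reports[[1]]$pix)
  pix <- do.call(rbind, lapply(reports, function(r) r$pix))
  rownames(pix) <- paste0("N", seq_len(nrow(pix)))
  covv <- vapply(reports, function(r) r$cov_pct, numeric(1))
  tab <- data.frame(subject = rep(rownames(pix), each = length(methods)),
                    method = rep(methods, times = nrow(pix)),
                    pix_total = as.vector(t(pix)),
                    cov_pct = rep(covv, each = length(methods)))
  ba <- ident <- list()
  covreg <- NULL
  if (length(reports) >= 2 && length(methods) >= 2) {
    prs <- utils::combn(methods, 2, simplify = FALSE)
    for (p in prs) {
      key <- paste(p, collapse = "_vs_")
      ba[[key]] <- bland_altman(pix[, p[1]], pix[, p[2]])
      if (nrow(pix) >= 3)
        ident[[key]] <- identity_regression(pix[, p[1]], pix[, p[2]])
    }
  } else if (length(reports) < 2) {
    warning("single subject: agreement section omitted")
  }
  if (nrow(pix) >= 3 && !anyNA(covv))
    covreg <- cov_vs_pix(pix, covv)
  structure(list(table = tab, pix = pix, cov_pct = covv, bland_altman = ba,
                 identity = ident, cov_regression = covreg,
                 reports = reports),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report>", nrow(x$pix), "subjects\n")
  print(cbind(as.data.frame(x$pix), cov_pct = round(x$cov_pct, 2)))
  invisible(x)
}
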