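test_that("identical config and seed give bit-identical recordings", {
  cfg <- tiny_config(duration_s = 600, seed = 7)
  a <- generate_recording(cfg)
  b <- generate_recording(cfg)
  expect_identical(a$eeg$values, b$eeg$values)
  expect_identical(a$scto2$values, b$scto2$values)
  # and a different seed changes the draw
  c <- generate_recording(tiny_config(duration_s = 600, seed = 8))
  expect_false(identical(a$eeg$values, c$eeg$values))
})

test_that("invalid configuration errors name the offending field", {
  expect_error(tiny_config(strength = 2), "coupling_strength")
  expect_error(synthetic_config(ar1_alpha = 1), "ar1_alpha")
  expect_error(synthetic_config(duration_s = 3600,
                                coupling_periods_s = 2000),
               "coupling_periods_s")
  expect_error(synthetic_config(duration_s = -1), "duration_s")
})

test_that("AR(1) generator matches its nominal autocorrelation and variance", {
  # alpha = 0: white noise, lag-1 autocorrelation near zero
  w <- generate_ar1(10000, alpha = 0, sd = 1, seed = 1)
  expect_lt(abs(acf(w$values, lag.max = 1, plot = FALSE)$acf[2]), 0.03)
  # alpha = 0.8: lag-1 near 0.8, stationary sd near 1
  r <- generate_ar1(10000, alpha = 0.8, sd = 1, seed = 2)
  expect_equal(acf(r$values, lag.max = 1, plot = FALSE)$acf[2], 0.8,
               tolerance = 0.025)
  expect_equal(sd(r$values), 1, tolerance = 0.06)
  # degenerate cases
  expect_identical(generate_ar1(5, 0.5, 0, seed = 3)$values, numeric(5))
  expect_error(generate_ar1(100, 1, 1, seed = 4), "non-stationary")
  expect_error(generate_ar1(1, 0.5, 1, seed = 5))
})

test_that("burst-suppression carrier respects its amplitude geometry", {
  bs <- burst_suppression_carrier(600, 256, burst_rate_per_min = 6,
                                  burst_len_s = 2, suppression_ratio = 0.1,
                                  seed = 9)
  lab <- attr(bs, "in_burst")
  expect_true(any(lab) && any(!lab))
  rms <- function(v) sqrt(mean(v^2))
  expect_equal(rms(bs$values[!lab]) / rms(bs$values[lab]), 0.1,
               tolerance = 0.02)
  # zero bursts requested: constant-amplitude suppressed noise
  none <- burst_suppression_carrier(60, 256, 0, 2, 0.1, seed = 1)
  expect_false(any(attr(none, "in_burst")))
  expect_equal(sd(none$values), 0.1, tolerance = 0.01)
  # suppression ratio near 1 is statistically like a continuous carrier
  near <- burst_suppression_carrier(600, 256, 6, 2, 0.999, seed = 9)
  expect_equal(var(near$values), 1, tolerance = 0.02)
  expect_error(burst_suppression_carrier(60, 256, 40, 2, 0.1, seed = 1),
               "infeasible")
})

test_that("single-period coupling leaves a spectral peak in both signals", {
  cfg <- synthetic_config(duration_s = 18000, coupling_periods_s = 3000,
                          coupling_strength = 1, scto2_noise_sd_pct = 0.5,
                          seed = 11)
  rec <- generate_recording(cfg)
  expect_equal(peak_period_s(rec$scto2), 3000, tolerance = 0.15)
  env <- uniform_series(abs_block_means(rec$eeg$values),
                        rate = rec$eeg$rate / 1224)
  expect_equal(peak_period_s(env), 3000, tolerance = 0.15)
})

test_that("SctO2 is clipped to [0, 100] and clip events are counted", {
  cfg <- synthetic_config(duration_s = 4000, coupling_periods_s = 500,
                          scto2_mean_pct = 99.5, scto2_noise_sd_pct = 2,
                          seed = 5)
  rec <- generate_recording(cfg)
  expect_true(all(rec$scto2$values <= 100 & rec$scto2$values >= 0))
  expect_gt(rec$truth$n_clipped, 0)
})

test_that("uncoupled SctO2 is uncorrelated with the EEG envelope", {
  cfg <- tiny_config(duration_s = 7200, strength = 0, seed = 13)
  rec <- generate_recording(cfg)
  env <- abs_block_means(rec$eeg$values)
  n <- min(length(env), length(rec$scto2$values))
  r <- cor(env[1:n], rec$scto2$values[1:n])
  expect_lt(abs(r), 2.5 / sqrt(n))  # |r| within sampling noise of zero
})

test_that("uncoupled recordings produce chance-level significant pixels", {
  # full-pipeline null at reduced scale: 20 replicate uncoupled subjects,
  # significant-pixel fraction outside the COI within 3 MC SE of alpha
  g <- tiny_grid()
  rate <- 256 / 1224
  fr <- numeric(20)
  thr <- NULL
  for (i in 1:20) {
    rec <- generate_recording(tiny_config(duration_s = 7200, strength = 0,
                                          period_s = 300, seed = 200 + i))
    bw <- bandwidth(aeeg_m1(rec$eeg))
    n <- min(length(bw$values), length(rec$scto2$values))
    if (is.null(thr))
      thr <- wtc_thresholds(n, rate, g, ar1_coef(bw$values[1:n]),
                            ar1_coef(rec$scto2$values[1:n]),
                            n_surrogates = 300, seed = 77)
    m <- significance_mask(wtc(bw, rec$scto2, g), thresholds = thr)
    fr[i] <- mean(m$sig_mask[!m$coi_mask])
  }
  expect_lte(abs(mean(fr) - 0.05), 3 * sd(fr) / sqrt(length(fr)))
})

test_that("recordings round-trip through CSV sidecar files", {
  rec <- generate_recording(tiny_config(duration_s = 300, seed = 3))
  stem <- file.path(tempdir(), "rec_test")
  paths <- write_recording(rec, stem)
  eeg <- read_series_csv(paste0(stem, "_eeg.csv"), units = "uV")
  expect_equal(eeg$values, rec$eeg$values, tolerance = 1e-8)
  expect_equal(eeg$rate, rec$eeg$rate, tolerance = 1e-6)
  cfg <- jsonlite::read_json(paste0(stem, "_config.json"))
  expect_equal(cfg$coupling_strength, 1)
  unlink(c(paths))
})
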