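test_that("asymmetric filter realizes the 12 dB/decade rising band", {
  b <- design_asymmetric_filter(256, filter_spec())
  expect_identical(length(b), 401L)
  expect_equal(as.numeric(b), rev(as.numeric(b)))  # exactly linear phase
  H <- fir_response(b, c(0.5, 2, 15), 256)
  db_rise <- 20 * log10(H[3] / H[2])
  expect_equal(db_rise, 12 * log10(15 / 2), tolerance = 0.15)  # ~10.5 dB
  # low-frequency artifact attenuation: 0.5 Hz well over 20 dB below 2 Hz
  expect_lt(20 * log10(H[1] / H[2]), -20)
  # mid-band tracks the power law closely
  fr <- exp(seq(log(2.5), log(14), length.out = 20))
  expect_lt(max(abs(fir_response(b, fr, 256) / (fr / 2)^0.6 - 1)), 0.08)
})

test_that("underpowered filter designs are refused with the achieved ripple", {
  expect_error(design_asymmetric_filter(256, filter_spec(n_taps = 31)),
               "ripple")
  expect_error(filter_spec(n_taps = 400), "odd")
})

test_that("rectification is full-wave and preserves structure", {
  t <- seq(0, 1, by = 1 / 256)
  x <- uniform_series(sin(2 * pi * 10 * t), 256)
  r <- rectify(x)
  expect_true(all(r$values >= 0))
  expect_equal(r$values, abs(x$values))
  expect_identical(rectify(uniform_series(numeric(10), 256))$values,
                   numeric(10))
  # mean of a rectified unit sine is 2/pi
  expect_equal(mean(r$values), 2 / pi, tolerance = 0.01)
})

test_that("envelope detection has unit DC gain and zero phase", {
  const <- uniform_series(rep(3.5, 2560), 256)
  expect_equal(envelope(const)$values, rep(3.5, 2560), tolerance = 1e-6)
  # rectified 10 Hz sine with 1 Hz cutoff settles at its mean 2/pi
  t <- seq(0, 20, by = 1 / 256)
  env <- envelope(rectify(uniform_series(sin(2 * pi * 10 * t), 256)))
  mid <- env$values[1000:(length(t) - 1000)]
  expect_equal(mean(mid), 2 / pi, tolerance = 0.01)
  expect_lt(diff(range(mid)), 0.02)
  # zero-phase: a symmetric pulse keeps its center of mass
  n <- 2048
  pulse <- exp(-((seq_len(n) - 1024)^2) / (2 * 40^2))
  e <- envelope(uniform_series(pulse, 256), cutoff_hz = 4)$values
  expect_equal(sum(seq_len(n) * e) / sum(e), 1024, tolerance = 0.5)
  expect_error(envelope(const, cutoff_hz = 200), "Nyquist")
})

test_that("terminal-point extraction matches an independent percentile oracle", {
  set.seed(31)
  for (i in 1:200) {
    v <- rnorm(1224, sd = runif(1, 0.5, 20))
    env <- uniform_series(abs(v), 256)
    tp <- extract_terminal_points(env, epoch_len_s = 1224 / 256,
                                  step_s = 1224 / 256)
    expect_equal(tp$utp, oracle_percentile(abs(v), 90), tolerance = 1e-12)
    expect_equal(tp$ltp, oracle_percentile(abs(v), 10), tolerance = 1e-12)
  }
})

test_that("segmentation geometry gives the 0.209 Hz margin rate", {
  env <- uniform_series(abs(rnorm(256 * 120)) + 1, 256)
  tp <- extract_terminal_points(env)
  expect_equal(round(tp$epoch_step_s * 256), 1224)
  expect_lt(abs(tp$rate - 0.209) / 0.209, 1e-3)
  # epoch count: floor((N - window)/stride) + 1
  expect_length(tp$utp, (256 * 120 - 3840) %/% 1224 + 1)
  # constant window: UTP = LTP = c
  cp <- extract_terminal_points(uniform_series(rep(2, 3840 * 2), 256))
  expect_true(all(cp$utp == 2 & cp$ltp == 2))
  expect_error(extract_terminal_points(uniform_series(1:100, 256)),
               "shorter")
})

test_that("margin extraction keeps UMA >= LMA >= 0 and the stated rates", {
  rec <- generate_recording(tiny_config(duration_s = 240, seed = 2))
  env <- apply_gain(envelope(rectify(rec$eeg)), 2)
  for (tr in list(margins_m1(env), margins_m2(env))) {
    expect_true(all(tr$uma$values >= tr$lma$values))
    expect_true(all(tr$lma$values >= 0))
    expect_lt(abs(tr$uma$rate - 0.209) / 0.209, 1e-3)
  }
  # constant envelope collapses both margins onto the constant
  ce <- uniform_series(rep(4, 256 * 90), 256)
  m <- margins_m1(ce)
  expect_true(all(abs(m$uma$values - 4) < 1e-12))
  expect_true(all(abs(m$lma$values - 4) < 1e-12))
  expect_true(all(bandwidth(m)$values == 0))
})

test_that("M2 margins equal the 3-point moving average of oracle terminal points", {
  set.seed(17)
  v <- abs(rnorm(256 * 60)) + 0.5
  env <- uniform_series(v, 256)
  m2 <- margins_m2(env)
  n_ep <- length(v) %/% 1224
  utp <- vapply(seq_len(n_ep), function(i)
    oracle_percentile(v[((i - 1) * 1224 + 1):(i * 1224)], 90), numeric(1))
  ltp <- vapply(seq_len(n_ep), function(i)
    oracle_percentile(v[((i - 1) * 1224 + 1):(i * 1224)], 10), numeric(1))
  ma3 <- function(z) vapply(seq_along(z), function(i)
    mean(z[max(1, i - 1):min(length(z), i + 1)]), numeric(1))
  expect_equal(m2$uma$values, ma3(utp), tolerance = 1e-12)
  expect_equal(m2$lma$values, ma3(ltp), tolerance = 1e-12)
})

test_that("the device path reuses the shared segmentation exactly", {
  rec <- generate_recording(tiny_config(duration_s = 240, seed = 5))
  env <- apply_gain(envelope(rectify(rec$eeg)), 2)
  m1 <- margins_m1(env)
  m3 <- margins_m3(env)
  expect_identical(m3$uma$values, m1$uma$values)
  expect_identical(m3$lma$values, m1$lma$values)
  expect_identical(m3$method, "M3")
  expect_error(margins_m3(uniform_series(c(-1, rep(1, 5000)), 256)),
               "nonnegative")
})

test_that("the whole margin chain is homogeneous in the input amplitude", {
  rec <- generate_recording(tiny_config(duration_s = 120, seed = 23))
  k <- 3.7
  scaled <- uniform_series(rec$eeg$values * k, 256, units = "uV")
  a <- aeeg_m1(rec$eeg)
  b <- aeeg_m1(scaled)
  expect_equal(b$uma$values, k * a$uma$values, tolerance = 1e-6)
  expect_equal(b$lma$values, k * a$lma$values, tolerance = 1e-6)
  expect_equal(bandwidth(b)$values, k * bandwidth(a)$values,
               tolerance = 1e-6)
})

test_that("M1 and M2 bandwidths share the injected slow modulation period", {
  rec <- generate_recording(tiny_config(duration_s = 4800, period_s = 480,
                                        seed = 29))
  b1 <- bandwidth(aeeg_m1(rec$eeg))
  b2 <- bandwidth(aeeg_m2(rec$eeg))
  expect_equal(peak_period_s(b1), 480, tolerance = 0.15)
  expect_equal(peak_period_s(b2), 480, tolerance = 0.15)
  # the two methods' amplitudes differ (gain 2 vs 1.631) but dynamics agree
  n <- min(length(b1$values), length(b2$values))
  expect_gt(cor(b1$values[1:n], b2$values[1:n]), 0.9)
})

test_that("semi-log display map is the conventional piecewise axis", {
  expect_identical(semilog_display(5), 5)
  expect_identical(semilog_display(10), 10)
  expect_equal(semilog_display(100), 20)
  expect_error(semilog_display(-1), "nonnegative")
  v <- seq(0, 100, by = 0.25)
  d <- semilog_display(v)
  expect_true(all(diff(d) > 0))                       # monotone
  expect_lt(abs(semilog_display(10 + 1e-9) - 10), 1e-6)  # continuous
})

test_that("aEEG traces round-trip through CSV with metadata", {
  rec <- generate_recording(tiny_config(duration_s = 240, seed = 2))
  tr <- aeeg_m2(rec$eeg)
  p <- file.path(tempdir(), "trace.csv")
  write_aeeg_csv(tr, p)
  d <- utils::read.csv(p)
  expect_equal(d$uma_uV, tr$uma$values, tolerance = 1e-8)
  meta <- jsonlite::read_json(paste0(p, ".json"))
  expect_identical(meta$method, "M2")
  unlink(c(p, paste0(p, ".json")))
})
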