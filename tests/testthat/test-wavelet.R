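test_that("Morlet CWT localizes a sinusoid at the expected scale", {
  g <- scale_grid(20, 400, voices = 12)
  n <- 4096
  x <- uniform_series(sin(2 * pi * (0:(n - 1)) / 100), rate = 1)  # P = 100 s
  cw <- cwt_morlet(x, g)
  pow <- colMeans(Mod(cw$w[1000:3000, ])^2)
  best <- cw$scales_s[which.max(pow)]
  expect_equal(best, 100 / g$fourier_factor, tolerance = 2^(1.5 / 12) - 1)
  # zero input, zero coefficients; linearity in the input
  z <- cwt_morlet(uniform_series(numeric(512), 1), scale_grid(20, 80))
  expect_true(all(Mod(z$w) == 0))
  ax <- cwt_morlet(uniform_series(3 * x$values[1:512], 1), scale_grid(20, 80))
  x5 <- cwt_morlet(uniform_series(x$values[1:512], 1), scale_grid(20, 80))
  expect_equal(ax$w, 3 * x5$w, tolerance = 1e-10)
})

test_that("scales beyond the record are dropped with a warning", {
  x <- uniform_series(rnorm(256), 1)
  expect_warning(cw <- cwt_morlet(x, scale_grid(20, 2000)), "excluding")
  expect_lte(max(cw$scales_s), 256)
})

test_that("coherence is bounded and high for self-coherence", {
  set.seed(4)
  x <- uniform_series(sin(2 * pi * (0:1499) / 150) + 0.3 * rnorm(1500), 1)
  g <- scale_grid(50, 300, voices = 8)
  m <- wtc(x, x, g)
  expect_true(all(m$r2 >= 0 & m$r2 <= 1))
  expect_false(anyNA(m$r2))
  expect_gt(mean(m$r2[!m$coi_mask]), 0.99)
})

test_that("a shared oscillation produces an in-band coherence ridge", {
  set.seed(9)
  n <- 2000
  s <- sin(2 * pi * (0:(n - 1)) / 200)
  x <- uniform_series(s + rnorm(n), 1)
  y <- uniform_series(s + rnorm(n), 1)
  g <- scale_grid(50, 800, voices = 8)
  m <- wtc(x, y, g)
  in_band <- abs(log2(m$scales_s / (200 / 1.033))) < 0.5
  out_band <- abs(log2(m$scales_s / (200 / 1.033))) > 1.2
  mu <- colMeans(m$r2)
  expect_gt(mean(mu[in_band]), mean(mu[out_band]) + 0.25)
})

test_that("coherence rejects mismatched or degenerate inputs", {
  x <- uniform_series(rnorm(500), 1)
  g <- scale_grid(20, 100, voices = 8)
  expect_error(wtc(x, uniform_series(rnorm(500), 2), g), "rate")
  expect_error(wtc(x, uniform_series(rep(1, 500), 1), g), "constant")
})

test_that("cone of influence follows the sqrt(2)*scale e-folding rule", {
  n <- 2000; rate <- 1
  scales <- c(10, 50, 400)
  coi <- coi_mask(n, rate, scales)
  for (j in seq_along(scales)) {
    expected_edge <- sqrt(2) * scales[j]
    first_out <- which(!coi[, j])[1]
    expect_equal((first_out - 1) / rate, expected_edge,
                 tolerance = 1.5 / (expected_edge * rate))
  }
  # small scales exclude only a sliver; overlong scales the entire row
  expect_lt(mean(coi[, 1]), 0.05)
  expect_true(all(coi_mask(100, 1, 200)[, 1]))
})

test_that("significance masking is monotone in alpha and handles limits", {
  set.seed(11)
  x <- generate_ar1(800, 0.5, 1, seed = 21, rate = 1)
  y <- generate_ar1(800, 0.5, 1, seed = 22, rate = 1)
  g <- scale_grid(20, 100, voices = 8)
  m <- wtc(x, y, g)
  m05 <- significance_mask(m, x, y, n_surrogates = 100, alpha = 0.05,
                           seed = 3)
  m01 <- significance_mask(m, x, y, n_surrogates = 100, alpha = 0.01,
                           seed = 3)
  expect_true(all(m01$sig_mask <= m05$sig_mask))  # stricter alpha is a subset
  mall <- significance_mask(m, x, y, n_surrogates = 100, alpha = 1, seed = 3)
  expect_true(all(mall$sig_mask))
  expect_error(significance_mask(m, x, uniform_series(rep(1, 800), 1),
                                 n_surrogates = 100), "constant")
  expect_error(significance_mask(m, x, y, n_surrogates = 10), ">= 100")
  # thresholds computed on another grid are refused
  thr_other <- wtc_thresholds(800, 1, scale_grid(20, 50, voices = 8),
                              0.5, 0.5, n_surrogates = 100, seed = 3)
  expect_error(significance_mask(m, thresholds = thr_other), "grid")
})

test_that("pixel counting respects the masks", {
  m <- structure(list(r2 = matrix(0.5, 10, 3), scales_s = c(10, 20, 40),
                      rate = 1, t0 = 0,
                      coi_mask = coi_mask(10, 1, c(10, 20, 40)),
                      sig_mask = NULL, voices = 8),
                 class = "coherence_map")
  expect_error(pix_total(m), "mask")
  m$sig_mask <- matrix(FALSE, 10, 3)
  expect_identical(pix_total(m), 0L)
  m$sig_mask <- matrix(TRUE, 10, 3)
  expect_identical(pix_total(m), sum(!m$coi_mask))
})

test_that("coupling increases the significant pixel count", {
  g <- scale_grid(100, 800, voices = 8)
  n <- 1500; rate <- 0.209
  thr <- wtc_thresholds(n, rate, g, 0.6, 0.6, n_surrogates = 100, seed = 55)
  pix <- function(strength, seed) {
    s <- sin(2 * pi * (0:(n - 1)) / rate / 400)   # period 400 s, in band
    x <- uniform_series(s + generate_ar1(n, 0.6, 1, seed)$values, rate)
    y <- uniform_series(strength * s +
                          generate_ar1(n, 0.6, 1, seed + 999)$values, rate)
    pix_total(significance_mask(wtc(x, y, g), thresholds = thr))
  }
  coupled <- vapply(1:10, function(i) pix(1.5, 100 + i), numeric(1))
  uncoupled <- vapply(1:10, function(i) pix(0, 100 + i), numeric(1))
  expect_gt(median(coupled), median(uncoupled))
  expect_gt(mean(coupled > uncoupled), 0.8)
})

test_that("COV across methods matches direct arithmetic", {
  expect_identical(cov_across_methods(c(100, 100, 100)), 0)
  expect_equal(cov_across_methods(c(100, 110, 120)),
               100 * sd(c(100, 110, 120)) / 110)
  expect_equal(cov_across_methods(c(100, 110, 120)), 9.090909,
               tolerance = 1e-6)
  # permutation invariance and the no-coherence marker
  expect_identical(cov_across_methods(c(100, 110, 120)),
                   cov_across_methods(c(120, 100, 110)))
  expect_true(is.na(cov_across_methods(c(0, 0, 0))))
  expect_error(cov_across_methods(c(1, 2)), "three")
})
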