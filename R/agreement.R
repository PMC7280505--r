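#' Bland-Altman agreement analysis
#'
#' Pairwise differences `a - b` against means `(a + b)/2`, with limits of
#' agreement at the mean difference plus/minus `k` sample standard
#' deviations (k = 1.96 by convention).
#'
#' @param a,b paired measurements (equal length >= 2), e.g. Pix_total per
#'   subject from two aEEG methods.
#' @param k limit multiplier.
#' @return A list of class `bland_altman`: `diffs`, `means`, `mean_diff`,
#'   `sd_diff`, `upper_limit`, `lower_limit`, `n_outside` (diffs strictly
#'   outside the limits).
#' @examples
#' ba <- bland_altman(c(3, 5, 8), c(2, 3, 5))
#' ba$mean_diff; ba$upper_limit
#' @export
bland_altman <- function(a, b, k = 1.96) {
  if (length(a) != length(b) || length(a) < 2)
    stop("`a` and `b` must be paired with length >= 2", call. = FALSE)
  diffs <- a - b
  means <- (a + b) / 2
  md <- mean(diffs)
  sdd <- stats::sd(diffs)
  up <- md + k * sdd
  lo <- md - k * sdd
  structure(list(diffs = diffs, means = means, mean_diff = md, sd_diff = sdd,
                 upper_limit = up, lower_limit = lo,
                 n_outside = sum(diffs > up | diffs < lo), k = k),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(paste0("<bland_altman> n = %d, mean diff = %.4g, SD = %.4g,\n",
                     "  limits [%.4g, %.4g] (+/- %.3g SD), %d outside\n"),
              length(x$diffs), x$mean_diff, x$sd_diff, x$lower_limit,
              x$upper_limit, x$k, x$n_outside))
  invisible(x)
}

#' Plot a Bland-Altman comparison
#' @param x a [bland_altman()] result.
#' @param ... further arguments to [graphics::plot()].
#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$diffs, xlab = "mean of methods",
                 ylab = "difference", ...)
  graphics::abline(h = c(x$mean_diff, x$upper_limit, x$lower_limit),
                   lty = c(1, 2, 2), col = "blue")
  invisible(x)
}

#' Scatter of paired method results with identity and regression lines
#'
#' One panel per method pair: points, the line of identity (perfect match)
#' and the fitted regression of `b` on `a`.
#'
#' @param a,b paired measurements (e.g. Pix_total per subject).
#' @param xlab,ylab axis labels.
#' @param ... further arguments to [graphics::plot()].
#' @return Invisibly, the [identity_regression()] fit.
#' @export
plot_method_agreement <- function(a, b, xlab = "method A",
                                  ylab = "method B", ...) {
  fit <- identity_regression(a, b)
  graphics::plot(a, b, xlab = xlab, ylab = ylab, ...)
  graphics::abline(0, 1, col = "blue")
  graphics::abline(fit$intercept, fit$slope, col = "red")
  invisible(fit)
}

#' Regression against the line of identity
#'
#' Ordinary least squares of `b` on `a`, with Pearson r and the Euclidean
#' distance of `(slope, intercept)` from the perfect-match line `(1, 0)`.
#'
#' @param a,b paired measurements, equal length >= 3.
#' @return A list of class `regression_result`: `slope`, `intercept`, `r`,
#'   `identity_distance`, and the slope's standard error `slope_se`.
#' @export
identity_regression <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3)
    stop("need paired data of length >= 3", call. = FALSE)
  if (stats::sd(a) == 0)
    stop("zero variance in `a`", call. = FALSE)
  fit <- stats::lm(b ~ a)
  cf <- stats::coef(fit)
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit)))[2])  # 0 for exact fits
  r_ab <- if (stats::sd(b) == 0) NA_real_ else stats::cor(a, b)
  structure(list(slope = unname(cf[2]), intercept = unname(cf[1]),
                 r = r_ab,
                 identity_distance = unname(sqrt((cf[2] - 1)^2 + cf[1]^2)),
                 slope_se = unname(se)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression> slope = %.4g (SE %.3g), intercept = %.4g, r = %.3f\n",
              x$slope, x$slope_se, x$intercept, x$r))
  invisible(x)
}

#' COV versus Pix_total relationship across subjects
#'
#' Per-method ordinary least squares of the cross-method COV on Pix_total
#' across subjects. A negative slope reproduces the association between
#' stronger coupling (more significant pixels) and lower cross-algorithm
#' variability.
#'
#' @param pix_per_subject numeric matrix or data frame, subjects x methods,
#'   of Pix_total values.
#' @param cov_per_subject COV (percent) per subject.
#' @return Named list of `regression_result`, one per method column.
#' @export
cov_vs_pix <- function(pix_per_subject, cov_per_subject) {
  pix <- as.matrix(pix_per_subject)
  if (nrow(pix) < 3)
    stop("need >= 3 subjects", call. = FALSE)
  if (nrow(pix) != length(cov_per_subject))
    stop("subject counts disagree", call. = FALSE)
  methods <- colnames(pix)
  if (is.null(methods)) methods <- paste0("M", seq_len(ncol(pix)))
  out <- lapply(seq_len(ncol(pix)), function(j)
    identity_regression(pix[, j], cov_per_subject))
  names(out) <- methods
  out
}
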