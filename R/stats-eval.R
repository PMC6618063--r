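#' Least-squares linear regression with F-test
#'
#' Ordinary least squares of `y = beta * x + alpha` with the coefficient of
#' determination, the F statistic for a linear relationship
#' `F = R^2 / ((1 - R^2) / (n - 2))` on (1, n - 2) degrees of freedom, and
#' its p value. Significance is conventionally declared at p < 0.05.
#'
#' @param y Response values.
#' @param x Predictor values (same length, non-degenerate).
#' @return An object of class `regression_result`: `slope`, `intercept`,
#'   `r_squared`, `f_statistic`, `p_value`, `n`, `significant`.
#' @export
linear_regression <- function(y, x) {
  assert_that(length(y) == length(x), "y and x must have equal length")
  n <- length(y)
  assert_that(n >= 3, "regression needs n >= 3")
  sxx <- sum((x - mean(x))^2)
  if (sxx <= 0)
    stop_ctx("x is degenerate (zero variance)",
             class = "spiral4d_degenerate_x")
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  syy <- sum((y - mean(y))^2)
  r2 <- if (syy > 0) sxy^2 / (sxx * syy) else 1
  fstat <- if (r2 < 1) (r2 / 1) / ((1 - r2) / (n - 2)) else Inf
  p <- stats::pf(fstat, 1, n - 2, lower.tail = FALSE)
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 f_statistic = fstat, p_value = p, n = n,
                 significant = is.finite(p) && p < 0.05 || is.infinite(fstat)),
            class = "regression_result")
}

#' @exportS3Method print regression_result
print.regression_result <- function(x, ...) {
  cat("y = ", signif(x$slope, 4), " x + ", signif(x$intercept, 4),
      "  (R^2 = ", signif(x$r_squared, 3), ", F = ",
      signif(x$f_statistic, 4), ", p = ", format(x$p_value, digits = 4),
      ", n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' Tidy a regression result
#'
#' @param x A `regression_result`.
#' @param ... Unused.
#' @return Data frame with one row per model term.
#' @export
tidy.regression_result <- function(x, ...) {
  data.frame(term = c("intercept", "slope"),
             estimate = c(x$intercept, x$slope))
}

#' One-row model summary of a regression result
#'
#' @param x A `regression_result`.
#' @param ... Unused.
#' @return One-row data frame: r.squared, statistic, p.value, nobs.
#' @export
glance.regression_result <- function(x, ...) {
  data.frame(r.squared = x$r_squared, statistic = x$f_statistic,
             p.value = x$p_value, nobs = x$n)
}

#' Generic tidiers
#'
#' `tidy()` and `glance()` generics for the package's fitted objects
#' (broom-compatible).
#' @param x Object to tidy.
#' @param ... Passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Bland-Altman agreement analysis
#'
#' Bias as the mean of the pairwise differences `a - b`, with limits of
#' agreement at bias +/- 1.96 times the sample SD of the differences.
#'
#' @param a,b Paired measurements.
#' @return An object of class `bland_altman_result`: `bias`, `sd_diff`,
#'   `lower`, `upper` limits, `n`, and the means/differences for plotting.
#' @export
bland_altman <- function(a, b) {
  assert_that(length(a) == length(b), "a and b must be paired")
  n <- length(a)
  assert_that(n >= 2, "Bland-Altman needs n >= 2")
  d <- a - b
  bias <- mean(d)
  sdd <- stats::sd(d)
  structure(list(bias = bias, sd_diff = sdd,
                 lower = bias - 1.96 * sdd, upper = bias + 1.96 * sdd,
                 n = n, means = (a + b) / 2, differences = d),
            class = "bland_altman_result")
}

#' @exportS3Method print bland_altman_result
print.bland_altman_result <- function(x, ...) {
  cat("Bland-Altman: bias ", signif(x$bias, 4), ", limits of agreement [",
      signif(x$lower, 4), ", ", signif(x$upper, 4), "] (n = ", x$n, ")\n",
      sep = "")
  invisible(x)
}

#' @export
plot.bland_altman_result <- function(x, ...) {
  graphics::plot(x$means, x$differences, pch = 16,
                 xlab = "mean of methods", ylab = "difference", ...)
  graphics::abline(h = c(x$bias, x$lower, x$upper), lty = c(1, 2, 2))
  invisible(x)
}
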