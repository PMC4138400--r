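#' Percent change in tracking error between two visits
#'
#' Computed as `(post - pre) / pre`: negative values mean the error
#' decreased (the subject improved).  Summary tables conventionally report
#' improvement as a positive number, so the companion
#' [improvement_magnitude()] returns the negation.
#'
#' @param mae_pre,mae_post visit MAE scores in %MVC; `mae_pre` must be > 0.
#' @return signed fraction; `-0.2` means the error dropped by 20%.
#' @examples
#' percent_improvement(10, 8)      # -0.20 (error decreased)
#' improvement_magnitude(10, 8)    # +0.20
#' @export
percent_improvement <- function(mae_pre, mae_post) {
  if (any(mae_pre <= 0)) {
    gs_abort("percent improvement undefined for mae_pre <= 0",
             "gs_undefined_ratio")
  }
  (mae_post - mae_pre) / mae_pre
}

#' @rdname percent_improvement
#' @export
improvement_magnitude <- function(mae_pre, mae_post) {
  -percent_improvement(mae_pre, mae_post)
}

#' Pearson product-moment correlation with two-sided p-value
#'
#' Standard Pearson r; the p-value is two-sided, from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length, n >= 3, each with nonzero
#'   variance.
#' @return A `correlation_result`: `r`, `p_value`, `n`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) gs_abort("x and y lengths differ", "gs_shape_error")
  n <- length(x)
  if (n < 3L) gs_abort("need at least 3 pairs", "gs_invalid_input")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    gs_abort("zero variance: correlation undefined", "gs_degenerate_input")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(
    list(r = unname(ct$estimate), p_value = ct$p.value, n = n),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> r = %.3f, p = %.3g, n = %d\n",
              x$r, x$p_value, x$n))
  invisible(x)
}

# plain-arithmetic simple OLS; shared by the leave-one-out refits
ols_line <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  slope <- sum((x - mx) * (y - my)) / sxx
  c(intercept = my - slope * mx, slope = slope)
}

#' Simple linear regression with influence diagnostics
#'
#' Ordinary least squares of `y` on `x` with an intercept (k = 1 fitted
#' slope parameter).  Returns the pieces needed by the Cook's-distance
#' outlier screen: fitted values, residuals, the residual root mean square
#' `s = sqrt(sum(e^2) / (n - k - 1))`, and the hat-matrix leverages.
#'
#' @param x,y numeric vectors, n >= 4, `x` with nonzero variance.
#' @return A `regression_diagnostics` object.
#' @export
fit_simple_regression <- function(x, y) {
  if (length(x) != length(y)) gs_abort("x and y lengths differ", "gs_shape_error")
  n <- length(x)
  k <- 1L
  if (n < 4L) gs_abort("need at least 4 points", "gs_invalid_input")
  if (stats::sd(x) == 0) {
    gs_abort("constant x: regression undefined", "gs_degenerate_input")
  }
  fit <- stats::lm(y ~ x)
  e <- stats::residuals(fit)
  structure(
    list(
      slope = unname(stats::coef(fit)[2L]),
      intercept = unname(stats::coef(fit)[1L]),
      fitted_values = unname(stats::fitted(fit)),
      residuals = unname(e),
      rmse_s = sqrt(sum(e^2) / (n - k - 1L)),
      leverage = unname(stats::hatvalues(fit)),
      n = n,
      k = k
    ),
    class = "regression_diagnostics"
  )
}

#' Cook's distance by leave-one-out refitting
#'
#' For each point i the regression is refitted without that point and the
#' influence of i is the scaled shift it induces in the fitted values at all
#' n original design points:
#' \deqn{d_i = \frac{\sum_{j=1}^n (\hat y_j - \hat y_{j(-i)})^2}{(k+1)\,s^2}}
#' where s is the residual root mean square of the full fit and k = 1 the
#' number of fitted slope parameters.  The equivalent closed form
#' `e_i^2 h_ii / ((k+1) s^2 (1-h_ii)^2)` is computed alongside and the two
#' routes are required to agree, as a guard on the diagnostics.
#'
#' @param diagnostics a `regression_diagnostics` from
#'   [fit_simple_regression()].
#' @param x,y the data the diagnostics were fitted on.
#' @return numeric vector of Cook's distances (non-negative).
#' @export
cooks_distance <- function(diagnostics, x, y) {
  stopifnot(inherits(diagnostics, "regression_diagnostics"))
  n <- diagnostics$n
  k <- diagnostics$k
  if (length(x) != n || length(y) != n) {
    gs_abort("x/y do not match the fitted diagnostics", "gs_shape_error")
  }
  if (n - 1L <= k + 1L) {
    gs_abort("too few points to refit with one removed", "gs_degenerate_refit")
  }
  s2 <- diagnostics$rmse_s^2
  yhat <- diagnostics$fitted_values
  d_loo <- vapply(seq_len(n), function(i) {
    co <- ols_line(x[-i], y[-i])
    yhat_loo <- co[["intercept"]] + co[["slope"]] * x
    sum((yhat - yhat_loo)^2) / ((k + 1L) * s2)
  }, numeric(1))
  h <- diagnostics$leverage
  e <- diagnostics$residuals
  d_closed <- e^2 * h / ((k + 1L) * s2 * (1 - h)^2)
  if (any(abs(d_loo - d_closed) > 1e-8 * pmax(1, d_closed))) {
    gs_abort("leave-one-out and closed-form Cook's distances disagree",
             "gs_internal_error")
  }
  d_loo
}

#' Flag influential points by the 4/(n-(k+1)) rule
#'
#' A point is flagged as a potential outlier when its Cook's distance
#' reaches `4 / (n - (k + 1))`; for a simple regression (k = 1) the
#' threshold is `4 / (n - 2)`.  The rule is inclusive (`>=`).
#'
#' @param cooks_d vector of Cook's distances.
#' @param n number of data points in the fitted regression (defaults to
#'   `length(cooks_d)`).
#' @param k number of fitted slope parameters (default 1).
#' @return logical vector of flags.
#' @export
flag_outliers <- function(cooks_d, n = length(cooks_d), k = 1L) {
  if (n <= k + 1L) gs_abort("n must exceed k + 1", "gs_invalid_parameter")
  cooks_d >= 4 / (n - (k + 1L))
}

#' Bland-Altman agreement between two measurement methods
#'
#' Per-pair differences `a - b` summarize how two methods measuring the
#' same quantity disagree: the bias is the mean difference, and the 95%
#' limits of agreement `bias +/- 1.96 * sd(diff)` are expected to contain
#' about 95% of differences.  The confidence interval of the bias uses the
#' normal multiplier by default (`bias +/- 1.96 * sd / sqrt(n)`); a
#' t-quantile version is available via `ci_method = "t"`.
#'
#' @param a,b numeric vectors of paired measurements (direction `a - b`),
#'   equal length n >= 3.
#' @param ci_method `"normal"` (1.96) or `"t"` (t quantile on n - 1 df) for
#'   the bias confidence interval.
#' @return An `agreement_result`: `bias`, `bias_ci` (length 2), `loa_lower`,
#'   `loa_upper`, `sd_diff`, `n`, `direction`, plus per-pair `means` and
#'   `diffs` for plotting.
#' @export
bland_altman <- function(a, b, ci_method = c("normal", "t")) {
  ci_method <- match.arg(ci_method)
  if (length(a) != length(b)) gs_abort("a and b lengths differ", "gs_shape_error")
  n <- length(a)
  if (n < 3L) gs_abort("need at least 3 pairs", "gs_invalid_input")
  diffs <- a - b
  bias <- mean(diffs)
  sd_diff <- stats::sd(diffs)
  mult <- if (ci_method == "normal") 1.96 else stats::qt(0.975, n - 1L)
  structure(
    list(
      bias = bias,
      bias_ci = bias + c(-1, 1) * mult * sd_diff / sqrt(n),
      loa_lower = bias - 1.96 * sd_diff,
      loa_upper = bias + 1.96 * sd_diff,
      sd_diff = sd_diff,
      n = n,
      direction = "first - second",
      means = (a + b) / 2,
      diffs = diffs
    ),
    class = "agreement_result"
  )
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(
    "<agreement_result> bias %.3f (95%% CI %.3f to %.3f), LoA %.3f to %.3f, n = %d\n",
    x$bias, x$bias_ci[1], x$bias_ci[2], x$loa_lower, x$loa_upper, x$n))
  invisible(x)
}

#' Two-sample t-test between groups
#'
#' Welch's unequal-variance t-test by default (the group spreads in
#' tracking studies differ grossly); set `var_equal = TRUE` for the pooled
#' Student version.  Two-sided p-value.
#'
#' @param sample_a,sample_b numeric vectors, each of length >= 2 with
#'   finite variance.
#' @param var_equal pool the variances (Student) instead of Welch.
#' @return A `group_comparison`: group means/SDs/sizes, `t_statistic`,
#'   `dof`, `p_value`.
#' @export
welch_t_test <- function(sample_a, sample_b, var_equal = FALSE) {
  if (length(sample_a) < 2L || length(sample_b) < 2L) {
    gs_abort("each sample needs at least 2 observations", "gs_invalid_input")
  }
  tt <- stats::t.test(sample_a, sample_b, var.equal = var_equal,
                      alternative = "two.sided")
  structure(
    list(
      mean_a = mean(sample_a), sd_a = stats::sd(sample_a), n_a = length(sample_a),
      mean_b = mean(sample_b), sd_b = stats::sd(sample_b), n_b = length(sample_b),
      t_statistic = unname(tt$statistic),
      dof = unname(tt$parameter),
      p_value = tt$p.value,
      var_equal = var_equal
    ),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> %.2f±%.2f (n=%d) vs %.2f±%.2f (n=%d): t = %.3f, df = %.1f, p = %.3g\n",
    x$mean_a, x$sd_a, x$n_a, x$mean_b, x$sd_b, x$n_b,
    x$t_statistic, x$dof, x$p_value))
  invisible(x)
}
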