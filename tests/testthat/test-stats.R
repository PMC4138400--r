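test_that("percent improvement follows the signed pre/post formula", {
  expect_equal(percent_improvement(10, 10), 0)
  expect_equal(percent_improvement(10, 8), -0.20)
  expect_equal(improvement_magnitude(10, 8), 0.20)
  # worsening group means: error grew by ~10.4%
  expect_equal(percent_improvement(11.24, 12.41), 0.1041, tolerance = 1e-4)
  expect_error(percent_improvement(0, 5), class = "gs_undefined_ratio")
  # scale invariance: units of the MAE cancel
  set.seed(1)
  for (i in 1:20) {
    pre <- runif(1, 1, 20); post <- runif(1, 1, 20); c_fac <- runif(1, 0.1, 9)
    expect_equal(percent_improvement(c_fac * pre, c_fac * post),
                 percent_improvement(pre, post), tolerance = 1e-12)
  }
})

test_that("pearson matches the direct-formula oracle and edge cases", {
  x <- 1:8
  expect_equal(pearson(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson(x, -x)$r, -1, tolerance = 1e-12)
  set.seed(13)
  x <- rnorm(10); y <- 0.5 * x + rnorm(10)
  got <- pearson(x, y)
  orc <- oracle_pearson(x, y)
  expect_equal(got$r, orc$r, tolerance = 1e-12)
  expect_equal(got$p_value, orc$p, tolerance = 1e-12)
  expect_equal(got$n, 10)
  expect_error(pearson(x, rep(1, 10)), class = "gs_degenerate_input")
  expect_error(pearson(1:3, 1:4), class = "gs_shape_error")
  expect_error(pearson(1:2, 2:1), class = "gs_invalid_input")
})

test_that("pearson r is affine-invariant and flips sign under negation", {
  set.seed(17)
  x <- rnorm(15); y <- rnorm(15)
  r0 <- pearson(x, y)$r
  expect_equal(pearson(3 * x + 2, y)$r, r0, tolerance = 1e-12)
  expect_equal(pearson(x, 0.1 * y - 7)$r, r0, tolerance = 1e-12)
  expect_equal(pearson(-x, y)$r, -r0, tolerance = 1e-12)
})

test_that("simple regression matches the normal equations", {
  x <- c(0, 1, 2, 3); y <- c(0, 1, 2, 10)
  fit <- fit_simple_regression(x, y)
  # closed-form normal equations
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(fit$slope, slope, tolerance = 1e-12)
  expect_equal(fit$intercept, mean(y) - slope * mean(x), tolerance = 1e-12)
  expect_equal(sum(fit$residuals), 0, tolerance = 1e-10)
  expect_equal(fit$rmse_s, sqrt(sum(fit$residuals^2) / 2), tolerance = 1e-12)
  # exact fit: zero residuals, zero rmse
  exact <- fit_simple_regression(x, 3 * x - 1)
  expect_equal(exact$residuals, rep(0, 4), tolerance = 1e-10)
  expect_equal(exact$rmse_s, 0, tolerance = 1e-10)
  # duplicating every point leaves the line unchanged
  dup <- fit_simple_regression(rep(x, 2), rep(y, 2))
  expect_equal(dup$slope, fit$slope, tolerance = 1e-12)
  expect_equal(dup$intercept, fit$intercept, tolerance = 1e-12)
  expect_error(fit_simple_regression(rep(1, 5), 1:5),
               class = "gs_degenerate_input")
  expect_error(fit_simple_regression(1:3, 1:3), class = "gs_invalid_input")
})

test_that("leave-one-out Cook's distance agrees with stats::cooks.distance", {
  set.seed(29)
  for (rep_i in 1:25) {
    n <- sample(8:40, 1)
    x <- runif(n); y <- 1 + 2 * x + rnorm(n)
    fit <- fit_simple_regression(x, y)
    d <- cooks_distance(fit, x, y)
    ref <- unname(stats::cooks.distance(lm(y ~ x)))
    expect_equal(d, ref, tolerance = 1e-10)
    expect_true(all(d >= 0))
  }
})

test_that("a point on the line through the others has zero influence", {
  x4 <- c(1, 2, 3, 4); y4 <- c(1, 3, 2, 5)
  base <- fit_simple_regression(x4, y4)
  x <- c(x4, 10)
  y <- c(y4, base$intercept + base$slope * 10)
  fit <- fit_simple_regression(x, y)
  d <- cooks_distance(fit, x, y)
  expect_equal(d[5], 0, tolerance = 1e-12)
  # and removing it leaves the line untouched
  expect_equal(fit$slope, base$slope, tolerance = 1e-12)
  expect_equal(fit$intercept, base$intercept, tolerance = 1e-12)
})

test_that("symmetric configurations get equal Cook's distances", {
  x <- c(0, 0, 1, 1); y <- c(0, 1, 0, 1)
  fit <- fit_simple_regression(x, y)
  d <- cooks_distance(fit, x, y)
  expect_equal(max(d) - min(d), 0, tolerance = 1e-12)
  expect_error(cooks_distance(fit, x[1:3], y[1:3]), class = "gs_shape_error")
})

test_that("outlier flags implement the inclusive 4/(n-(k+1)) rule", {
  expect_equal(4 / (22 - 2), 0.2)  # threshold at n = 22, k = 1
  expect_false(any(flag_outliers(rep(0, 10))))
  expect_equal(flag_outliers(c(0.01, 0.5), n = 10, k = 1),
               c(FALSE, TRUE))  # 0.5 == threshold: inclusive
  expect_error(flag_outliers(c(0, 0), n = 3, k = 2),
               class = "gs_invalid_parameter")
})

test_that("Bland-Altman reproduces direct mean/SD computation", {
  a <- c(0.1, 0.2, 0.3); expect_s3_class(bland_altman(a, a), "agreement_result")
  same <- bland_altman(a, a)
  expect_equal(same$bias, 0)
  expect_equal(same$loa_lower, 0)
  expect_equal(same$loa_upper, 0)
  # constant shift: bias is minus the shift, a - b direction
  set.seed(31)
  x <- runif(12)
  shifted <- bland_altman(x, x + 0.26)
  expect_equal(shifted$bias, -0.26, tolerance = 1e-12)
  y <- runif(12)
  got <- bland_altman(x, y)
  orc <- oracle_bland_altman(x, y)
  expect_equal(got$bias, orc$bias, tolerance = 1e-12)
  expect_equal(got$loa_upper, orc$upper, tolerance = 1e-12)
  expect_equal(got$loa_lower, orc$lower, tolerance = 1e-12)
  # limit identity holds exactly
  expect_equal(got$loa_upper - got$loa_lower, 3.92 * got$sd_diff)
  # t-based CI is wider than the normal CI at n = 12
  t_ci <- bland_altman(x, y, ci_method = "t")$bias_ci
  expect_gt(diff(t_ci), diff(got$bias_ci))
  expect_error(bland_altman(1:3, 1:4), class = "gs_shape_error")
})

test_that("Welch t-test matches the textbook formulas", {
  a <- c(5.1, 4.9, 5.3, 5.2, 4.8)
  b <- c(6.4, 5.9, 6.8, 6.1, 7.0)
  got <- welch_t_test(a, b)
  orc <- oracle_welch(a, b)
  expect_equal(got$t_statistic, orc$t, tolerance = 1e-10)
  expect_equal(got$dof, orc$dof, tolerance = 1e-10)
  expect_equal(got$p_value, orc$p, tolerance = 1e-10)
  # identical samples: t = 0, p = 1
  same <- welch_t_test(a, a)
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  # antisymmetry under swapping
  rev <- welch_t_test(b, a)
  expect_equal(rev$t_statistic, -got$t_statistic, tolerance = 1e-12)
  expect_equal(rev$p_value, got$p_value, tolerance = 1e-12)
  expect_error(welch_t_test(1, a), class = "gs_invalid_input")
})
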