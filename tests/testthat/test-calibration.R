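test_that("foci summaries follow the Poisson convention", {
  m <- summarize_counts(17, 100)
  expect_equal(m$mean, 0.17)
  expect_equal(m$se, sqrt(0.17 / 100))
  expect_equal(summarize_counts(0, 100)$se, 0)
  m2 <- summarize_counts(94, 100)
  expect_equal(m2$mean, 0.94)
  expect_equal(m2$se, 0.0970, tolerance = 1e-3)
  # per-cell counts are accepted directly
  m3 <- summarize_counts(c(0, 1, 0, 2, 1))
  expect_equal(m3$cells, 5)
  expect_equal(m3$mean, 0.8)
  expect_error(summarize_counts(5, 0), "at least 1")
  expect_error(summarize_counts(1.5, 10), "integer")
})

test_that("background subtraction combines Poisson errors in quadrature", {
  s <- summarize_counts(94, 100)
  b <- summarize_counts(17, 100)
  nr <- net_rif(s, b)
  expect_equal(nr$net, 0.77)
  expect_equal(nr$se, sqrt(s$se^2 + b$se^2))
  expect_equal(net_rif(b, b)$net, 0)
  # negative nets are legitimate and must not be clipped
  expect_lt(net_rif(summarize_counts(10, 100), b)$net, 0)
})

test_that("an exact line is recovered exactly", {
  x <- c(10, 20, 40, 80)
  f <- fit_dataset(x, 0.1 + 0.02 * x)
  expect_equal(f$slope, 0.02, tolerance = 1e-12)
  expect_equal(f$intercept, 0.1, tolerance = 1e-12)
  expect_equal(f$r_squared, 1)
})

test_that("OLS agrees with the brute-force normal-equation oracle", {
  set.seed(61)
  for (n in c(3, 6, 25)) {
    x <- runif(n, 5, 95)
    y <- 0.04 + 0.015 * x + rnorm(n, 0, 0.08)
    f <- fit_dataset(x, y)
    o <- ols_oracle(x, y)
    expect_equal(f$slope, o$slope, tolerance = 1e-8)
    expect_equal(f$intercept, o$intercept, tolerance = 1e-8)
    expect_equal(unclass(f$cov), unclass(o$cov), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(f$r_squared, o$r_squared, tolerance = 1e-8)
    expect_equal(sum(o$residuals), 0, tolerance = 1e-9)
  }
})

test_that("degenerate designs are rejected", {
  expect_error(fit_dataset(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_dataset(c(5, 5, 5), c(1, 2, 3)), "distinct|variance")
  expect_error(pooled_fit(c(1, 2, 3), c(1, 2, 3), anova_p = 0.01),
               "force = TRUE")
  f <- pooled_fit(c(1, 2, 3), c(1, 2.1, 2.9), anova_p = 0.01, force = TRUE)
  expect_s3_class(f, "calibration_fit")
})

test_that("fits are invariant to sample ordering", {
  set.seed(71)
  x <- runif(12, 6, 95); y <- 0.03 + 0.015 * x + rnorm(12, 0, 0.05)
  p <- sample(12)
  f1 <- fit_dataset(x, y); f2 <- fit_dataset(x[p], y[p])
  expect_equal(f1$slope, f2$slope, tolerance = 1e-12)
  expect_equal(f1$se_slope, f2$se_slope, tolerance = 1e-12)
})

test_that("Shapiro-Wilk behaves like the standard test", {
  sw <- shapiro_wilk(c(-1, 0, 1))
  expect_equal(sw$W, 1, tolerance = 1e-6)
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n <= 50")
  expect_error(shapiro_wilk(rnorm(51)), "3 <= n <= 50")
  # p-values are uniform under the null
  set.seed(81)
  ps <- replicate(1000, shapiro_wilk(rnorm(10))$p)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("one-way ANOVA matches hand-computed mean squares", {
  # groups (1,2,3), (2,3,4), (6,7,8): SSB = 42, MSB = 21, MSW = 1
  vals <- c(1, 2, 3, 2, 3, 4, 6, 7, 8)
  grp <- rep(c("a", "b", "c"), each = 3)
  a <- anova_oneway(vals, grp)
  expect_equal(a$F, 21, tolerance = 1e-6)
  expect_equal(a$p, stats::pf(21, 2, 6, lower.tail = FALSE),
               tolerance = 1e-9)
  # identical group means with nonzero within-variance: F = 0
  a0 <- anova_oneway(c(1, 3, 1, 3, 1, 3), rep(c("a", "b", "c"), each = 2))
  expect_equal(a0$F, 0, tolerance = 1e-12)
  expect_error(anova_oneway(1:3, c("a", "a", "a")), "2 groups")
  expect_error(anova_oneway(1:3, c("a", "b", "c")), "degenerate")
})

test_that("ANOVA holds its nominal type-I error rate", {
  set.seed(91)
  rej <- replicate(1000, {
    anova_oneway(rnorm(15), rep(1:3, each = 5))$p < 0.05
  })
  expect_equal(mean(rej), 0.05, tolerance = 0.02 / 0.05)
})

test_that("the confidence band follows the OLS identities", {
  set.seed(101)
  x <- runif(20, 6, 95); y <- 0.04 + 0.015 * x + rnorm(20, 0, 0.06)
  f <- fit_dataset(x, y)
  band <- confidence_band(f, mean(x))
  half <- (band$upper - band$lower) / 2
  expect_equal(half, stats::qt(0.975, f$df) * sqrt(f$sigma2 / f$n),
               tolerance = 1e-9)
  grid <- seq(0, 100, by = 10)
  b <- confidence_band(f, grid)
  expect_equal(b$fit - b$lower, b$upper - b$fit, tolerance = 1e-12)
  expect_equal(b$fit, predict_rif(f, grid), tolerance = 1e-12)
  # narrowest at the mean design dose
  expect_equal(grid[which.min(b$upper - b$lower)],
               grid[which.min(abs(grid - mean(x)))])
  expect_error(confidence_band(f, 50, level = 1.2), "level")
})

test_that("prediction from the reference calibration reproduces known points", {
  ref <- reference_calibration()
  expect_equal(round(predict_rif(ref, 500), 1), 7.4)
  expect_equal(predict_rif(ref, 0), ref$intercept)
  expect_equal(predict_rif(ref, 50), 0.7713, tolerance = 1e-9)
  expect_error(predict_rif(ref, -5), "non-negative")
})

test_that("prediction and dose estimation are mutual inverses", {
  ref <- reference_calibration()
  est <- estimate_dose(ref, list(net = 0.7713, se = 0))
  expect_equal(est$dose, 50, tolerance = 1e-9)
  expect_equal(estimate_dose(ref, list(net = ref$intercept, se = 0))$dose, 0)
  for (d in c(5, 50, 500)) {
    y <- predict_rif(ref, d)
    expect_equal(estimate_dose(ref, list(net = y, se = 0))$dose, d,
                 tolerance = 1e-9)
  }
})

test_that("dose estimates clip below zero and order their intervals", {
  ref <- reference_calibration()
  est <- estimate_dose(ref, summarize_counts(10, 100),
                       summarize_counts(17, 100))
  expect_true(est$clipped)
  expect_equal(est$dose, 0)
  expect_lte(est$ci_low, est$dose)
  expect_gte(est$ci_high, est$dose)
  ok <- estimate_dose(ref, summarize_counts(94, 100),
                      summarize_counts(17, 100))
  expect_false(ok$clipped)
  expect_lt(ok$ci_low, ok$dose)
  expect_gt(ok$ci_high, ok$dose)
  fe <- estimate_dose(ref, summarize_counts(94, 100),
                      summarize_counts(17, 100), method = "fieller")
  expect_lt(fe$ci_low, ok$dose)
  expect_gt(fe$ci_high, ok$dose)
  bad <- reference_calibration(); bad$slope <- -0.01
  expect_error(estimate_dose(bad, list(net = 0.5, se = 0)), "positive")
})
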