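test_that("Atwater baseline applies 4/4/9 and the COD conversion", {
  p <- atwater_params(kcal_per_gcod = 3.2)
  expect_equal(as.numeric(atwater_cod_m(0, 0, 0, p)), 0)
  a <- atwater_cod_m(0, 0, 100, p)
  expect_equal(attr(a, "kcal"), 900)
  expect_equal(as.numeric(a), 900 / 3.2)
  b <- atwater_cod_m(50, 50, 0, p)
  expect_equal(attr(b, "kcal"), 400)
  expect_error(atwater_cod_m(-1, 0, 0, p), "non-negative")
  expect_error(atwater_params(kcal_per_gcod = 0), "positive")
})

test_that("identity-line R2 matches hand computation and degenerate cases", {
  meas <- c(1, 2, 3)
  expect_equal(r2_identity(meas, meas), 1)
  expect_equal(r2_identity(rep(mean(meas), 3), meas), 0)
  expect_equal(r2_identity(c(1.1, 2.0, 2.9), meas), 1 - 0.02 / 2)
  # heavily biased predictions push R2 far below zero
  expect_lt(r2_identity(meas + 10, meas), -1)
  expect_error(r2_identity(c(1, 1), c(2, 2)), "zero variance")
  expect_error(r2_identity(1, c(1, 2)), "equal length")
})

test_that("sigma_est is the RMSE about the identity line", {
  meas <- c(1, 2, 3)
  expect_equal(sigma_est_identity(meas, meas), 0)
  expect_equal(sigma_est_identity(meas + 5, meas), 5)
  expect_equal(sigma_est_identity(c(1.1, 2.0, 2.9), meas), sqrt(0.02 / 3))
  # translation covariance and scaling
  expect_equal(sigma_est_identity(2 * (meas + 0.3), 2 * meas),
               2 * sigma_est_identity(meas + 0.3, meas))
  expect_equal(sigma_est_identity(c(2, 3), c(1, 2), df_correction = 1),
               sqrt(2))
  expect_error(sigma_est_identity(numeric(0), numeric(0)), "length >= 1")
})

test_that("Bland-Altman limits are symmetric about the mean difference", {
  meas <- c(1, 2, 3, 4)
  ba0 <- bland_altman(meas, meas)
  expect_equal(c(ba0$mean_diff, ba0$lower, ba0$upper), c(0, 0, 0))
  ba5 <- bland_altman(meas + 5, meas)
  expect_equal(c(ba5$mean_diff, ba5$lower, ba5$upper), c(5, 5, 5))
  # differences -1, +1: mean 0, sd sqrt(2), limits +/- 1.96 sqrt(2)
  ba <- bland_altman(c(0, 3), c(1, 2))
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$upper, 1.96 * sqrt(2))
  expect_equal(ba$lower, -1.96 * sqrt(2))
  expect_equal(ba$upper - ba$mean_diff, ba$mean_diff - ba$lower)
})

test_that("limits of agreement cover ~95% of Gaussian differences", {
  set.seed(99)
  meas <- stats::rnorm(2000, 100, 10)
  pred <- meas + stats::rnorm(2000, 0, 4)
  ba <- bland_altman(pred, meas)
  inside <- mean(ba$diffs >= ba$lower & ba$diffs <= ba$upper)
  expect_gte(inside, 0.93)
})

test_that("one-sample t against zero difference matches hand computation", {
  d <- c(1, 2, 3, 4)
  tt <- one_sample_t_zero(d)
  expect_equal(tt$t, 2.5 / (stats::sd(d) / 2))
  expect_equal(tt$t, 3.873, tolerance = 1e-3)
  expect_equal(tt$df, 3)
  sym <- one_sample_t_zero(c(-2, -1, 1, 2))
  expect_equal(sym$t, 0)
  expect_equal(sym$p, 1)
  expect_error(one_sample_t_zero(c(2, 2, 2)), "zero variance")
})

test_that("Kendall tau handles monotone, reversed and tied input", {
  expect_equal(kendall_tau(1:5, (1:5)^2)$tau, 1)
  expect_equal(kendall_tau(1:5, -(1:5))$tau, -1)
  kt <- kendall_tau(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(kt$tau, 2 / 3)
  expect_error(kendall_tau(c(1, 1, 1), c(1, 2, 3)), "all-tied")
})

test_that("the full agreement report returns exact degenerate values", {
  x <- c(10, 20, 30, 40)
  rep0 <- agreement_report(x, x)
  expect_equal(rep0$r2, 1)
  expect_equal(rep0$sigma_est, 0)
  expect_equal(rep0$mean_diff, 0)
  # zero-variance differences: t and tau undefined, reported as NA
  expect_true(is.na(rep0$t))
  expect_true(is.na(rep0$tau))
  df <- as.data.frame(rep0)
  expect_equal(df$n, 4)
  expect_equal(df$r2, 1)
})
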