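test_that("cylindrical cell mass reproduces the seeding constants", {
  wt <- cell_wet_mass(1.5, 1, 1)
  expect_equal(signif(wt, 2), 1.2e-12)
  # organic dry mass per cell: 20% dry, 90% of dry organic
  expect_equal(signif(wt * 0.2 * 0.9, 1), 2e-13)
  # geometry: doubling the diameter quadruples the mass
  expect_equal(cell_wet_mass(1.5, 2, 1), 4 * wt)
  expect_error(cell_wet_mass(0, 1, 1), "positive")
})

test_that("mcrA seeding is linear in copies and in the retention factor", {
  p <- methanogen_params()
  expect_equal(xm0_from_mcra(0, p), 0)
  expect_equal(xm0_from_mcra(1e10, p), 1e10 * 1.2e-12 * 0.2 * 0.9 * 1.42)
  expect_equal(xm0_from_mcra(1e10, p), 3.07e-3, tolerance = 1e-3)
  p258 <- methanogen_params(xm_factor = 2.58)
  expect_equal(xm0_from_mcra(1e10, p258), 2.58 * xm0_from_mcra(1e10, p))
  expect_equal(xm0_from_mcra(2e10, p), 2 * xm0_from_mcra(1e10, p))
  expect_error(xm0_from_mcra(-1, p), "non-negative")
  expect_error(methanogen_params(f_dry = 1.2), "fractions")
})

make_calibration <- function(factor, n = 10, noise_sd = 0, seed = 5) {
  set.seed(seed)
  d <- data.frame(
    mcra_copies = stats::rlnorm(n, log(5e11), 0.8),
    ctt_days = stats::rlnorm(n, log(1.5), 0.3),
    h2_prod_gcod_per_day = stats::runif(n, 0.3, 2))
  p <- methanogen_params(xm_factor = factor)
  kin <- kinetic_params()
  fs_m <- default_product_ratios()$fs_m
  d$ch4_gcod_per_day <- vapply(seq_len(n), function(i) {
    h <- steady_state_h2(d$h2_prod_gcod_per_day[i], kin$k_m,
                         xm0_from_mcra(d$mcra_copies[i], p), d$ctt_days[i])
    (1 - fs_m) * h$r_meth
  }, numeric(1))
  if (noise_sd > 0)
    d$ch4_gcod_per_day <- d$ch4_gcod_per_day *
      (1 + stats::rnorm(n, 0, noise_sd))
  d
}

test_that("grid search recovers the generating factor on clean data", {
  fit <- fit_xm_factor(make_calibration(2.58), ch4_floor = 0)
  expect_equal(unname(coef(fit)), 2.58, tolerance = 0.011)
  fit1 <- fit_xm_factor(make_calibration(1), ch4_floor = 0)
  expect_equal(fit1$factor, 1, tolerance = 0.011)
  # profile is unimodal around the optimum on clean data
  prof <- fit$profile$sigma_est
  k <- which.min(prof)
  expect_true(all(diff(prof[seq_len(k)]) <= 1e-12))
  expect_true(all(diff(prof[k:length(prof)]) >= -1e-12))
})

test_that("fit object supports the standard modelling methods", {
  d <- make_calibration(2, n = 8)
  fit <- fit_xm_factor(d, ch4_floor = 0)
  expect_s3_class(fit, "damm_fit")
  expect_named(coef(fit), "xm_factor")
  expect_length(fitted(fit), fit$n)
  expect_equal(residuals(fit), fitted(fit) - fit$data$ch4_gcod_per_day)
  expect_equal(predict(fit), fitted(fit))
  expect_equal(predict(fit, d[1:3, ]), fitted(fit)[1:3], tolerance = 1e-10)
  expect_output(print(fit), "X_M Factor")
})

test_that("methane-negative observations are excluded and guarded", {
  d <- make_calibration(2.58, n = 6)
  d$ch4_gcod_per_day[1:2] <- 0          # negatives fall below any floor
  fit <- fit_xm_factor(d, ch4_floor = 1e-6)
  expect_equal(fit$n, 4)
  expect_equal(fit$n_excluded, 2)
  d$ch4_gcod_per_day <- 0
  expect_error(fit_xm_factor(d), "methane-positive")
})
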