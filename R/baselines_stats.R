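# Atwater baseline and agreement statistics relative to the identity line.
# R2 and sigma_est are evaluated against prediction = measurement (not a
# fitted regression), so R2 can be negative and sigma_est is an RMSE about
# the identity line.

#' Atwater parameters
#'
#' The classic empirical metabolizable-energy factors: 4 kcal/g protein,
#' 4 kcal/g carbohydrate, 9 kcal/g fat, with a configurable kcal-to-gCOD
#' conversion.
#'
#' @param protein,carb,fat kcal per gram factors.
#' @param kcal_per_gcod Conversion factor to COD units.
#' @return A list of class `atwater_params`.
#' @export
atwater_params <- function(protein = 4, carb = 4, fat = 9,
                           kcal_per_gcod = 3.2) {
  p <- list(protein = protein, carb = carb, fat = fat,
            kcal_per_gcod = kcal_per_gcod)
  if (any(unlist(p) <= 0))
    stop("Atwater factors and conversion must be positive", call. = FALSE)
  structure(p, class = "atwater_params")
}

#' Atwater prediction of metabolizable COD
#'
#' `E_m = 4 P + 4 C + 9 F` kcal/d from macronutrient grams, converted to
#' gCOD/d by the configured kcal-per-gCOD factor.
#'
#' @param protein_g,carb_g,fat_g Daily macronutrient intakes, g/d.
#' @param params An [atwater_params()].
#' @return Metabolizable COD, gCOD/d (attribute `kcal` holds E_m in kcal/d).
#' @export
atwater_cod_m <- function(protein_g, carb_g, fat_g,
                          params = atwater_params()) {
  if (any(c(protein_g, carb_g, fat_g) < 0))
    stop("macronutrient masses must be non-negative", call. = FALSE)
  kcal <- params$protein * protein_g + params$carb * carb_g +
    params$fat * fat_g
  structure(kcal_to_cod(kcal, params$kcal_per_gcod), kcal = kcal)
}

#' Coefficient of determination relative to the identity line
#'
#' `1 - sum((pred - meas)^2) / sum((meas - mean(meas))^2)`. Because the
#' reference is prediction = measurement rather than a fitted line, the value
#' is unbounded below (strongly biased predictions give large negative R2).
#'
#' @param pred,meas Equal-length numeric vectors, length >= 2.
#' @return R2 as a fraction (<= 1).
#' @export
r2_identity <- function(pred, meas) {
  if (length(pred) != length(meas) || length(meas) < 2)
    stop("pred and meas must have equal length >= 2", call. = FALSE)
  ss_tot <- sum((meas - mean(meas))^2)
  if (ss_tot == 0)
    stop("measurements have zero variance; R2 undefined", call. = FALSE)
  1 - sum((pred - meas)^2) / ss_tot
}

#' Standard error of the estimate relative to the identity line
#'
#' RMSE about prediction = measurement: `sqrt(sum((pred - meas)^2) / n)`.
#' Denominator `n` because the identity line estimates no parameters; set
#' `df_correction = 2` for the regression-style `n - 2` convention.
#'
#' @param pred,meas Equal-length numeric vectors, length >= 1.
#' @param df_correction Degrees of freedom subtracted from n (default 0).
#' @return Same units as the inputs.
#' @export
sigma_est_identity <- function(pred, meas, df_correction = 0) {
  n <- length(meas)
  if (length(pred) != n || n < 1)
    stop("pred and meas must have equal length >= 1", call. = FALSE)
  if (n - df_correction <= 0)
    stop("not enough observations for the requested df correction",
         call. = FALSE)
  sqrt(sum((pred - meas)^2) / (n - df_correction))
}

#' Bland-Altman agreement
#'
#' Mean difference (pred - meas) with 95% limits of agreement
#' `mean +/- 1.96 sd` (sample sd, n - 1).
#'
#' @param pred,meas Equal-length numeric vectors, length >= 2.
#' @return List: `mean_diff`, `lower`, `upper`, `sd_diff`, and the per-pair
#'   `means`/`diffs` used for plotting.
#' @export
bland_altman <- function(pred, meas) {
  if (length(pred) != length(meas) || length(meas) < 2)
    stop("pred and meas must have equal length >= 2", call. = FALSE)
  diffs <- pred - meas
  m <- mean(diffs)
  s <- stats::sd(diffs)
  list(mean_diff = m, lower = m - 1.96 * s, upper = m + 1.96 * s,
       sd_diff = s, means = (pred + meas) / 2, diffs = diffs)
}

#' One-sample t test of the differences against zero
#'
#' Systematic-bias test: `t = mean(d) / (sd(d)/sqrt(n))`, two-sided p from
#' the t distribution with n - 1 df (via [stats::t.test()]).
#'
#' @param differences Numeric vector, length >= 2, nonzero variance.
#' @return List: `t`, `p`, `df`, `mean_diff`.
#' @export
one_sample_t_zero <- function(differences) {
  if (length(differences) < 2)
    stop("need at least 2 differences", call. = FALSE)
  if (stats::sd(differences) == 0)
    stop("differences have zero variance; t statistic undefined",
         call. = FALSE)
  tt <- stats::t.test(differences, mu = 0)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_diff = mean(differences))
}

#' Kendall rank correlation
#'
#' Tie-corrected tau (tau-b) with p value via
#' [stats::cor.test()]. For proportional-bias assessment apply it to the
#' per-pair means and differences of two methods (as [agreement_report()]
#' does).
#'
#' @param x,y Equal-length numeric vectors, length >= 2.
#' @return List: `tau`, `p`.
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stop("x and y must have equal length >= 2", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("all-tied input; Kendall tau undefined", call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall"))
  list(tau = unname(ct$estimate), p = ct$p.value)
}

#' Full agreement report between predictions and measurements
#'
#' Bundles the evaluation suite: R2 and sigma_est relative to the identity
#' line, Bland-Altman mean difference with 95% limits of agreement, a
#' one-sample t test of the differences against zero (systematic bias), and
#' Kendall tau between per-pair means and differences (proportional bias).
#' Degenerate branches: with pred identical to meas the t test and tau are
#' undefined (zero variance) and reported as NA.
#'
#' @param pred,meas Equal-length numeric vectors, length >= 2.
#' @return A list of class `agreement_report`.
#' @export
agreement_report <- function(pred, meas) {
  ba <- bland_altman(pred, meas)
  tt <- tryCatch(one_sample_t_zero(ba$diffs),
                 error = function(e) list(t = NA_real_, p = NA_real_,
                                          df = NA_real_,
                                          mean_diff = ba$mean_diff))
  kt <- tryCatch(kendall_tau(ba$means, ba$diffs),
                 error = function(e) list(tau = NA_real_, p = NA_real_))
  structure(list(
    n = length(meas),
    r2 = r2_identity(pred, meas),
    sigma_est = sigma_est_identity(pred, meas),
    mean_diff = ba$mean_diff, loa_lower = ba$lower, loa_upper = ba$upper,
    t = tt$t, t_p = tt$p,
    tau = kt$tau, tau_p = kt$p,
    pred = pred, meas = meas
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement vs identity line (n = %d)\n", x$n))
  cat(sprintf("  R2        %8.2f%%\n", 100 * x$r2))
  cat(sprintf("  sigma_est %8.4g\n", x$sigma_est))
  cat(sprintf("  Bland-Altman mean %.4g [%.4g, %.4g]\n",
              x$mean_diff, x$loa_lower, x$loa_upper))
  if (is.na(x$t)) cat("  t test: undefined (zero-variance differences)\n")
  else cat(sprintf("  t = %.3f (p = %.3g)\n", x$t, x$t_p))
  if (is.na(x$tau)) cat("  Kendall tau: undefined (ties)\n")
  else cat(sprintf("  tau = %.3f (p = %.3g)\n", x$tau, x$tau_p))
  invisible(x)
}

#' Bland-Altman plot of an agreement report
#'
#' @param x An `agreement_report`.
#' @param ... Passed to [plot()].
#' @export
plot.agreement_report <- function(x, ...) {
  means <- (x$pred + x$meas) / 2
  diffs <- x$pred - x$meas
  plot(means, diffs, xlab = "Mean of prediction and measurement",
       ylab = "Prediction - measurement", main = "Bland-Altman", ...)
  graphics::abline(h = c(x$mean_diff, x$loa_lower, x$loa_upper),
                   lty = c(1, 2, 2), col = "grey40")
  invisible(x)
}

#' Turn an agreement report into a one-row data frame
#'
#' @param x An `agreement_report`.
#' @param ... Unused.
#' @export
as.data.frame.agreement_report <- function(x, ...) {
  data.frame(n = x$n, r2 = x$r2, sigma_est = x$sigma_est,
             mean_diff = x$mean_diff, loa_lower = x$loa_lower,
             loa_upper = x$loa_upper, t = x$t, t_p = x$t_p,
             tau = x$tau, tau_p = x$tau_p)
}
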