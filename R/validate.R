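#' Validate a risk model on a cohort
#'
#' External-validation report for a fixed logistic risk model:
#' discrimination (C-statistic with stratified bootstrap CI), overall
#' performance (Brier score, residual deviance, AIC), and calibration
#' (intercept with the linear predictor as offset, slope from the
#' intercept+slope logistic fit, loess calibration curve with
#' Emax/Eavg). The model is taken as given: its residual deviance is
#' minus twice its log-likelihood at the fixed coefficients, and
#' `AIC = deviance + 2 * n_free`, where `n_free` is the number of
#' parameters that were estimated on this cohort (0 for a fully external
#' model, 1/2/5 for the in-the-large / recalibrated / revised updates).
#'
#' @param model A [risk_model()].
#' @param cohort Cohort data frame with outcome column `hcc`.
#' @param n_free Number of parameters of `model` estimated on `cohort`.
#' @param boot_reps Bootstrap replicates for the C-statistic CI (0 skips).
#' @param span Loess span for the calibration curve.
#' @param seed Integer seed for the bootstrap.
#' @param conf Confidence level.
#' @return An object of class `risk_validation`.
#' @export
#' @examples
#' co <- simulate_cohort(seed = 1)
#' validate_risk_model(asap_model(), co, boot_reps = 50)
validate_risk_model <- function(model, cohort, n_free = 0, boot_reps = 2000,
                                span = 0.75, seed = 1, conf = 0.95) {
  stopifnot(inherits(model, "risk_model"), "hcc" %in% names(cohort))
  y <- as.integer(cohort$hcc)
  lp <- linear_predictor(model, cohort)
  p <- stats::plogis(lp)
  cs <- c_statistic(lp, y)
  ci <- c(NA_real_, NA_real_)
  if (boot_reps > 0) {
    b <- bootstrap_ci(function(d) c_statistic(d$lp, d$y),
                      data.frame(lp = lp, y = y), reps = boot_reps,
                      seed = seed, strata = y, conf = conf)
    ci <- unname(b[c("lower", "upper")])
  }
  dev <- binomial_deviance(p, y)
  cal_a <- calibration_intercept_slope(lp, y, mode = "intercept_only")
  cal_ab <- calibration_intercept_slope(lp, y, mode = "intercept_slope")
  cc <- calibration_curve(p, y, span = span)
  structure(list(
    model = model, n = length(y), n_free = n_free,
    c_statistic = cs, c_lower = ci[1L], c_upper = ci[2L],
    brier = brier_score(p, y),
    residual_deviance = dev, df = length(y) - n_free,
    aic = dev + 2 * n_free,
    calibration_intercept = unname(cal_a["intercept"]),
    calibration_slope = unname(cal_ab["slope"]),
    calibration_curve = cc$curve, emax = cc$emax, eavg = cc$eavg,
    conf = conf), class = "risk_validation")
}

#' @export
print.risk_validation <- function(x, digits = 3, ...) {
  cat("Risk-model validation (n = ", x$n, ", model: ",
      x$model$provenance, ")\n", sep = "")
  ci <- if (is.na(x$c_lower)) "" else
    sprintf(" (%.0f%% CI %.3f-%.3f)", 100 * x$conf, x$c_lower, x$c_upper)
  cat(sprintf("  C-statistic          %.3f%s\n", x$c_statistic, ci))
  cat(sprintf("  Brier score          %.4f\n", x$brier))
  cat(sprintf("  Residual deviance    %.2f on %d df (AIC %.2f)\n",
              x$residual_deviance, x$df, x$aic))
  cat(sprintf("  Calibration intercept %.3f, slope %.3f\n",
              x$calibration_intercept, x$calibration_slope))
  cat(sprintf("  Emax %.3f, Eavg %.3f\n", x$emax, x$eavg))
  invisible(x)
}

#' Export a validation report as a flat record
#'
#' @param x A `risk_validation` object.
#' @return One-row data frame of the scalar metrics.
#' @export
as.data.frame.risk_validation <- function(x, ...) {
  data.frame(model = x$model$provenance, n = x$n, n_free = x$n_free,
             c_statistic = x$c_statistic, c_lower = x$c_lower,
             c_upper = x$c_upper, brier = x$brier,
             residual_deviance = x$residual_deviance, df = x$df,
             aic = x$aic,
             calibration_intercept = x$calibration_intercept,
             calibration_slope = x$calibration_slope,
             emax = x$emax, eavg = x$eavg,
             stringsAsFactors = FALSE)
}
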