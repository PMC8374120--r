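new_risk_fit <- function(model, deviance, n, n_free) {
  structure(list(model = model, deviance = deviance,
                 loglik = -deviance / 2, n = n, n_free = n_free,
                 df = n - n_free, aic = deviance + 2 * n_free),
            class = "risk_fit")
}

#' @export
print.risk_fit <- function(x, ...) {
  cat("Risk-model fit (", x$model$provenance, "): deviance ",
      format(x$deviance, digits = 6), " on ", x$df, " df (",
      x$n_free, " free parameter(s), AIC ",
      format(x$aic, digits = 6), ")\n", sep = "")
  invisible(x)
}

check_cohort_outcome <- function(cohort) {
  stopifnot("hcc" %in% names(cohort))
  y <- as.integer(cohort$hcc)
  if (length(unique(y)) < 2L)
    stop("both outcome classes must be present in the cohort")
  y
}

#' Evaluate a model on a cohort without refitting
#'
#' The "no update" fit: the model's coefficients are fixed, so it has
#' zero free parameters and its deviance is minus twice its
#' log-likelihood at the given coefficients.
#'
#' @param model A [risk_model()].
#' @param cohort Cohort with outcome column `hcc`.
#' @return A `risk_fit` with 0 free parameters.
#' @export
evaluate_model <- function(model, cohort) {
  y <- check_cohort_outcome(cohort)
  p <- predict(model, cohort)
  new_risk_fit(model, binomial_deviance(p, y), length(y), 0L)
}

#' Recalibration-in-the-large
#'
#' Updates only the model intercept: the original linear predictor enters
#' a logistic regression as an offset (coefficient fixed at 1) and the
#' intercept correction `a` is estimated by maximum likelihood. The
#' returned model keeps every slope coefficient and has intercept
#' `original intercept + a`.
#'
#' @param model A [risk_model()].
#' @param cohort Cohort with outcome column `hcc`.
#' @return A `risk_fit` with 1 free parameter.
#' @export
recalibrate_in_the_large <- function(model, cohort) {
  y <- check_cohort_outcome(cohort)
  lp <- linear_predictor(model, cohort)
  cal <- calibration_intercept_slope(lp, y, mode = "intercept_only")
  new_risk_fit(shift_intercept(model, unname(cal["intercept"])),
               attr(cal, "deviance"), length(y), 1L)
}

#' Logistic recalibration
#'
#' Estimates both the intercept `a` and the slope `b` of
#' `logit(p) = a + b * LP` by maximum likelihood. The returned model's
#' coefficients are exactly `b` times the original ones, and its
#' intercept is `b * original intercept + a`, so its linear predictor
#' equals the recalibrated one.
#'
#' @inheritParams recalibrate_in_the_large
#' @return A `risk_fit` with 2 free parameters.
#' @export
recalibrate <- function(model, cohort) {
  y <- check_cohort_outcome(cohort)
  lp <- linear_predictor(model, cohort)
  cal <- calibration_intercept_slope(lp, y, mode = "intercept_slope")
  new_risk_fit(rescale_model(model, unname(cal["intercept"]),
                             unname(cal["slope"])),
               attr(cal, "deviance"), length(y), 2L)
}

#' Model revision
#'
#' Refits all five parameters (intercept, age, sex, log AFP, log
#' PIVKA-II) on the cohort by maximum-likelihood logistic regression,
#' keeping the original variable set.
#'
#' @inheritParams recalibrate_in_the_large
#' @return A `risk_fit` with 5 free parameters.
#' @export
revise <- function(model, cohort) {
  y <- check_cohort_outcome(cohort)
  check_markers(cohort)
  dat <- data.frame(y = y, age = cohort$age, sex = cohort$sex,
                    lafp = log(cohort$afp), lpivka = log(cohort$pivka2))
  fit <- withCallingHandlers(
    stats::glm(y ~ age + sex + lafp + lpivka, family = stats::binomial(),
               data = dat, control = glm_ctrl()),
    warning = function(w) invokeRestart("muffleWarning"))
  cf <- stats::coef(fit)
  if (!fit$converged || any(!is.finite(cf)))
    stop("model revision did not converge")
  if (any(abs(cf[-1L]) > 30)) {
    dir <- names(cf)[-1L][which.max(abs(cf[-1L]))]
    stop("separation detected in model revision along covariate '", dir,
         "': no finite maximum-likelihood estimate")
  }
  m <- risk_model(cf[["(Intercept)"]], cf[["age"]], cf[["sex"]],
                  cf[["lafp"]], cf[["lpivka"]], provenance = "revised")
  new_risk_fit(m, stats::deviance(fit), length(y), 5L)
}

#' Likelihood ratio test between nested fits
#'
#' Chi-square statistic `deviance(restricted) - deviance(full)` with
#' degrees of freedom equal to the difference in free parameters.
#'
#' @param restricted,full `risk_fit` objects on the same cohort;
#'   `restricted` must be nested in `full`.
#' @return List with `chi_square`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(restricted, full) {
  stopifnot(inherits(restricted, "risk_fit"), inherits(full, "risk_fit"))
  if (restricted$n != full$n)
    stop("fits compare different cohorts (n differs)")
  df <- full$n_free - restricted$n_free
  if (df <= 0L) stop("'full' must have more free parameters than 'restricted'")
  chi <- restricted$deviance - full$deviance
  if (chi < -1e-8)
    stop("negative LRT statistic (", format(chi),
         "): fits are non-nested or not converged")
  chi <- max(chi, 0)
  list(chi_square = chi, df = df,
       p_value = stats::pchisq(chi, df, lower.tail = FALSE))
}

#' Update a risk model by closed testing
#'
#' Fits all three updating strategies and selects the final model with
#' the closed testing procedure: the revision is tested against the
#' original model (5 df), then against recalibration-in-the-large (4 df),
#' then against recalibration (3 df), each at level `alpha`; the first
#' comparison that is \emph{not} significant stops the chain and the
#' corresponding simpler model is adopted (original, in-the-large,
#' recalibration); if all three are significant the revision is adopted.
#' A p-value exactly at `alpha` counts as non-significant.
#'
#' `closed_test()` is an alias taking the same arguments.
#'
#' @param model The existing [risk_model()] to update (default the
#'   published ASAP model).
#' @param data Cohort data frame with outcome column `hcc`.
#' @param alpha Significance level of each sequential test (0.05).
#' @return An object of class `closed_test`: the four `risk_fit`s
#'   (`original`, `in_the_large`, `recalibration`, `revision`), the LRT
#'   `chain` data frame, the `adopted` strategy name and `adopted_fit`,
#'   with print/summary/coef/predict/plot methods.
#' @export
#' @examples
#' co <- simulate_cohort(seed = 1)
#' up <- update_risk_model(asap_model(), co)
#' up$adopted
#' coef(up)
update_risk_model <- function(model = asap_model(), data, alpha = 0.05) {
  stopifnot(inherits(model, "risk_model"), alpha > 0, alpha < 1)
  fits <- list()
  run <- function(label, expr) {
    tryCatch(expr, error = function(e)
      stop("closed test aborted at stage '", label, "': ",
           conditionMessage(e), call. = FALSE))
  }
  fits$original <- run("original", evaluate_model(model, data))
  fits$in_the_large <- run("in_the_large",
                           recalibrate_in_the_large(model, data))
  fits$recalibration <- run("recalibration", recalibrate(model, data))
  fits$revision <- run("revision", revise(model, data))

  cmp <- c("revision vs original", "revision vs in_the_large",
           "revision vs recalibration")
  against <- c("original", "in_the_large", "recalibration")
  chain <- data.frame(comparison = cmp, chi_square = NA_real_,
                      df = NA_integer_, p_value = NA_real_,
                      significant = NA, stringsAsFactors = FALSE)
  adopted <- "revision"
  for (i in seq_along(against)) {
    lrt <- likelihood_ratio_test(fits[[against[i]]], fits$revision)
    chain$chi_square[i] <- lrt$chi_square
    chain$df[i] <- lrt$df
    chain$p_value[i] <- lrt$p_value
    chain$significant[i] <- lrt$p_value < alpha  # p == alpha: keep simpler
    if (!chain$significant[i]) { adopted <- against[i]; break }
  }
  structure(list(fits = fits, chain = chain, adopted = adopted,
                 adopted_fit = fits[[adopted]], alpha = alpha,
                 data = data, n = nrow(data)),
            class = "closed_test")
}

#' @rdname update_risk_model
#' @param ... Passed to `update_risk_model()`.
#' @export
closed_test <- function(...) update_risk_model(...)

#' @export
print.closed_test <- function(x, ...) {
  cat("Closed testing procedure for model updating (n = ", x$n,
      ", alpha = ", x$alpha, ")\n", sep = "")
  ch <- x$chain[!is.na(x$chain$p_value), , drop = FALSE]
  for (i in seq_len(nrow(ch)))
    cat(sprintf("  %-28s chi2 = %8.3f, df = %d, p = %s\n",
                ch$comparison[i], ch$chi_square[i], ch$df[i],
                format.pval(ch$p_value[i], digits = 3)))
  cat("  Adopted strategy:", x$adopted, "\n")
  invisible(x)
}

#' @export
coef.closed_test <- function(object, ...) coef(object$adopted_fit$model)

#' @export
predict.closed_test <- function(object, newdata = object$data,
                                type = c("response", "link"), ...) {
  predict(object$adopted_fit$model, newdata, type = match.arg(type))
}

#' @export
residuals.closed_test <- function(object, ...) {
  as.integer(object$data$hcc) - predict(object)
}

#' Summary of a closed-test model update
#'
#' Side-by-side report of the original and the three updated models on
#' the updating cohort: coefficients, calibration intercept and slope,
#' residual deviance and df, LRT p-value against the revision, AIC,
#' Brier score and C-statistic.
#'
#' @param object A `closed_test` object.
#' @param boot_reps Bootstrap replicates for C-statistic CIs (0 skips).
#' @param seed Seed for the bootstrap.
#' @param ... Unused.
#' @return A `summary.closed_test` object wrapping the comparison table.
#' @export
summary.closed_test <- function(object, boot_reps = 0, seed = 1, ...) {
  y <- as.integer(object$data$hcc)
  rows <- lapply(names(object$fits), function(nm) {
    f <- object$fits[[nm]]
    v <- validate_risk_model(f$model, object$data, n_free = f$n_free,
                             boot_reps = boot_reps, seed = seed)
    p_lrt <- if (nm == "revision") NA_real_ else
      object$chain$p_value[match(paste("revision vs", nm),
                                 object$chain$comparison)]
    cbind(data.frame(strategy = nm, t(coef(f$model))),
          data.frame(calibration_intercept = v$calibration_intercept,
                     calibration_slope = v$calibration_slope,
                     residual_deviance = f$deviance, df = f$df,
                     lrt_p = p_lrt, aic = f$aic, brier = v$brier,
                     c_statistic = v$c_statistic,
                     c_lower = v$c_lower, c_upper = v$c_upper))
  })
  structure(list(table = do.call(rbind, rows), adopted = object$adopted,
                 alpha = object$alpha, n = object$n),
            class = "summary.closed_test")
}

#' @export
print.summary.closed_test <- function(x, digits = 4, ...) {
  cat("Model updating summary (n = ", x$n, ")\n\n", sep = "")
  tab <- x$table
  tab$lrt_p <- ifelse(is.na(tab$lrt_p), "-",
                      format.pval(tab$lrt_p, digits = 3))
  print(format(tab, digits = digits), row.names = FALSE)
  cat("\nAdopted strategy:", x$adopted, "\n")
  invisible(x)
}

#' Plot method for a closed-test update
#'
#' Two panels: the loess calibration curves of the original and adopted
#' models, and their decision curves with treat-all/treat-none
#' references.
#'
#' @param x A `closed_test` object.
#' @param span Loess span for the calibration curves.
#' @param grid Threshold grid for the decision curves.
#' @param ... Unused.
#' @export
plot.closed_test <- function(x, span = 0.75,
                             grid = seq(0.01, 0.99, by = 0.01), ...) {
  y <- as.integer(x$data$hcc)
  p0 <- predict(x$fits$original$model, x$data)
  p1 <- predict(x$adopted_fit$model, x$data)
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  c0 <- calibration_curve(p0, y, span)$curve
  c1 <- calibration_curve(p1, y, span)$curve
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 3, col = "grey40",
                 xlab = "Predicted probability",
                 ylab = "Observed (loess)", main = "Calibration")
  graphics::lines(c0$predicted, c0$observed, col = 2)
  graphics::lines(c1$predicted, c1$observed, col = 4)
  graphics::legend("topleft", c("original", x$adopted), col = c(2, 4),
                   lty = 1, bty = "n")
  d0 <- decision_curve(p0, y, grid)
  d1 <- decision_curve(p1, y, grid)
  graphics::plot(d0$threshold, d0$net_benefit, type = "l", col = 2,
                 ylim = range(0, d0$net_benefit, d1$net_benefit,
                              d1$treat_all),
                 xlab = "Threshold probability", ylab = "Net benefit",
                 main = "Decision curves")
  graphics::lines(d1$threshold, d1$net_benefit, col = 4)
  graphics::lines(d1$threshold, d1$treat_all, col = "grey40", lty = 2)
  graphics::abline(h = 0, lty = 3)
  graphics::legend("topright", c("original", x$adopted, "treat all"),
                   col = c(2, 4, "grey40"), lty = c(1, 1, 2), bty = "n")
  invisible(x)
}

#' Bootstrap optimism correction and shrinkage for the revised model
#'
#' Harrell's bootstrap: the revision is refit on each resample of the
#' cohort, its apparent C-statistic on the resample is compared with its
#' C-statistic on the original cohort, and the mean difference (the
#' optimism) is subtracted from the apparent C of the revision fit on the
#' full cohort. The shrinkage factor is the mean calibration slope of the
#' bootstrap-refitted linear predictors evaluated on the original cohort.
#' Replicates with separation or a single outcome class are redrawn.
#'
#' @param cohort Cohort with outcome column `hcc`.
#' @param reps Bootstrap replicates (>= 50; 200 by default).
#' @param seed Integer seed.
#' @param model Starting model defining the covariate set.
#' @return List with `c_apparent`, `optimism`, `c_corrected`,
#'   `shrinkage`, `reps`.
#' @export
bootstrap_optimism <- function(cohort, reps = 200, seed = 1,
                               model = asap_model()) {
  if (reps < 50) stop("bootstrap_optimism needs reps >= 50")
  y <- check_cohort_outcome(cohort)
  n <- nrow(cohort)
  fit0 <- revise(model, cohort)
  lp0 <- linear_predictor(fit0$model, cohort)
  c_app <- c_statistic(lp0, y)
  set.seed(as.integer(seed))
  opt <- slope <- numeric(reps)
  redrawn <- 0L
  for (r in seq_len(reps)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      res <- tryCatch({
        fb <- revise(model, cohort[idx, , drop = FALSE])
        lp_b <- linear_predictor(fb$model, cohort[idx, , drop = FALSE])
        lp_o <- linear_predictor(fb$model, cohort)
        list(opt = c_statistic(lp_b, y[idx]) - c_statistic(lp_o, y),
             slope = unname(calibration_intercept_slope(
               lp_o, y, mode = "intercept_slope")["slope"]))
      }, error = function(e) NULL)
      if (!is.null(res)) break
      redrawn <- redrawn + 1L
      if (redrawn > 100L * reps) stop("too many degenerate bootstrap replicates")
    }
    opt[r] <- res$opt
    slope[r] <- res$slope
  }
  if (redrawn > 0L)
    message("bootstrap_optimism: ", redrawn, " replicate(s) redrawn")
  list(c_apparent = c_app, optimism = mean(opt),
       c_corrected = c_app - mean(opt), shrinkage = mean(slope),
       reps = reps)
}
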