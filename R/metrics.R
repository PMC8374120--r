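# Probabilities are clipped away from 0/1 before any log-likelihood so
# deviance stays finite for extreme predictions.
clip_prob <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

# Binomial deviance (-2 log likelihood) of fixed probabilities.
binomial_deviance <- function(probs, labels) {
  p <- clip_prob(probs)
  -2 * sum(labels * log(p) + (1 - labels) * log(1 - p))
}

#' Concordance statistic (C-statistic)
#'
#' Probability that a randomly chosen case scores higher than a randomly
#' chosen control, ties credited 0.5 — equivalent to the area under the
#' ROC curve. Computed by the rank (Wilcoxon) identity in O(n log n).
#'
#' @param scores Numeric risk scores (any monotone scale: logits or
#'   probabilities give identical values).
#' @param labels 0/1 outcome labels; both classes must be present.
#' @return Concordance in `[0, 1]`.
#' @export
#' @examples
#' c_statistic(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
c_statistic <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("C-statistic undefined: both outcome classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Brier score
#'
#' Mean squared difference between predicted probabilities and binary
#' outcomes; lower is better, 0.25 for a constant 0.5 prediction.
#'
#' @param probs Predicted probabilities in `[0, 1]`.
#' @param labels 0/1 outcome labels.
#' @return Value in `[0, 1]`.
#' @export
brier_score <- function(probs, labels) {
  labels <- as.integer(labels)
  stopifnot(length(probs) == length(labels), all(labels %in% 0:1))
  if (any(!is.finite(probs)) || any(probs < 0 | probs > 1))
    stop("probs must lie in [0, 1]")
  mean((probs - labels)^2)
}

# Shared IRLS settings: deviance tolerance tight enough that the score
# equations are satisfied to ~1e-10, needed for valid LRT chains.
glm_ctrl <- function() stats::glm.control(epsilon = 1e-12, maxit = 100)

#' Calibration intercept and slope
#'
#' Logistic regression of the observed outcome on a model's linear
#' predictor. With `mode = "intercept_only"` the linear predictor enters
#' as an offset (coefficient fixed at 1) and only the intercept `a` is
#' estimated — the recalibration-in-the-large fit. With
#' `mode = "intercept_slope"` both `a` and the slope `b` of
#' `logit(p) = a + b * LP` are estimated by maximum likelihood. A
#' perfectly calibrated model has `(a, b) = (0, 1)`.
#'
#' @param lp Per-patient linear predictors (logit scale).
#' @param labels 0/1 outcomes; both classes must be present.
#' @param mode `"intercept_only"` or `"intercept_slope"`.
#' @return Named vector `c(intercept, slope)` (slope fixed at 1 in
#'   intercept-only mode), with attributes `deviance` and `df_free`
#'   (number of estimated parameters).
#' @export
calibration_intercept_slope <- function(lp, labels,
                                        mode = c("intercept_slope",
                                                 "intercept_only")) {
  mode <- match.arg(mode)
  labels <- as.integer(labels)
  stopifnot(length(lp) == length(labels), all(labels %in% 0:1))
  if (length(unique(labels)) < 2L)
    stop("both outcome classes must be present")
  if (mode == "intercept_only") {
    fit <- stats::glm(labels ~ 1 + offset(lp), family = stats::binomial(),
                      control = glm_ctrl())
    out <- c(intercept = unname(stats::coef(fit)[1L]), slope = 1)
    kfree <- 1L
  } else {
    fit <- stats::glm(labels ~ lp, family = stats::binomial(),
                      control = glm_ctrl())
    out <- c(intercept = unname(stats::coef(fit)[1L]),
             slope = unname(stats::coef(fit)[2L]))
    kfree <- 2L
  }
  if (!fit$converged)
    stop("calibration fit did not converge after ", fit$iter, " iterations")
  attr(out, "deviance") <- stats::deviance(fit)
  attr(out, "df_free") <- kfree
  out
}

#' Loess calibration curve with Emax and Eavg
#'
#' Locally weighted (loess, degree 1) regression of the binary outcome on
#' the predicted probability, evaluated at each observed prediction. The
#' maximum and mean absolute differences between predicted and smoothed
#' observed probabilities are the Emax and Eavg calibration errors.
#'
#' @param probs Predicted probabilities (>= 20 observations).
#' @param labels 0/1 outcomes.
#' @param span Loess span in `(0, 1]`; 0.75 by default.
#' @return List with `curve` (data frame `predicted`, `observed`, sorted
#'   by prediction), `emax` and `eavg`.
#' @export
calibration_curve <- function(probs, labels, span = 0.75) {
  labels <- as.integer(labels)
  stopifnot(length(probs) == length(labels))
  if (length(probs) < 20L)
    stop("calibration_curve needs at least 20 observations")
  if (span <= 0 || span > 1) stop("span must lie in (0, 1]")
  fit <- stats::loess(labels ~ probs, span = span, degree = 1,
                      family = "gaussian")
  sm <- clip_prob(stats::predict(fit, newdata = data.frame(probs = probs)),
                  eps = 0)
  abs_err <- abs(probs - sm)
  ord <- order(probs)
  list(curve = data.frame(predicted = probs[ord], observed = sm[ord]),
       emax = max(abs_err), eavg = mean(abs_err))
}

#' Percentile bootstrap confidence interval
#'
#' Resamples a data frame with replacement (optionally stratified, e.g.
#' by outcome class so every replicate keeps the original case mix) and
#' returns the 2.5/97.5 percentile bounds of a statistic. The point
#' estimate always comes from the original sample. Replicates on which
#' the statistic fails (e.g. a single-class resample) are redrawn and a
#' message reports how many.
#'
#' @param statistic Function taking a data frame and returning a scalar.
#' @param data Data frame of observations.
#' @param reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed.
#' @param strata Optional vector (length `nrow(data)`) defining resampling
#'   strata; `NULL` for simple resampling.
#' @param conf Confidence level (0.95).
#' @return Named vector `c(point, lower, upper)`.
#' @export
bootstrap_ci <- function(statistic, data, reps = 2000, seed = 1,
                         strata = NULL, conf = 0.95) {
  stopifnot(is.function(statistic), reps >= 1)
  n <- nrow(data)
  if (!is.null(strata)) {
    stopifnot(length(strata) == n)
    idx_by <- split(seq_len(n), strata)
  }
  set.seed(as.integer(seed))
  point <- statistic(data)
  vals <- numeric(reps)
  redrawn <- 0L
  for (r in seq_len(reps)) {
    for (try in 1:100) {
      idx <- if (is.null(strata)) {
        sample.int(n, n, replace = TRUE)
      } else {
        unlist(lapply(idx_by, function(i)
          i[sample.int(length(i), length(i), replace = TRUE)]),
          use.names = FALSE)
      }
      v <- tryCatch(statistic(data[idx, , drop = FALSE]),
                    error = function(e) NA_real_)
      if (is.finite(v)) break
      redrawn <- redrawn + 1L
    }
    if (!is.finite(v)) stop("bootstrap replicate failed 100 consecutive redraws")
    vals[r] <- v
  }
  if (redrawn > 0L)
    message("bootstrap_ci: ", redrawn, " degenerate replicate(s) redrawn")
  alpha <- (1 - conf) / 2
  q <- stats::quantile(vals, c(alpha, 1 - alpha), names = FALSE, type = 7)
  c(point = point, lower = q[1L], upper = q[2L])
}
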