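#' Four-covariate logistic risk model
#'
#' Constructs a logistic risk model on age (years), sex (0 = male,
#' 1 = female), log alpha-fetoprotein (natural-log ng/mL) and log PIVKA-II
#' (natural-log mAU/mL). The linear predictor is
#' \deqn{LP = intercept + b_{age} \cdot age + b_{sex} \cdot sex +
#'   b_{AFP} \cdot \ln(AFP) + b_{PIVKA} \cdot \ln(PIVKA\mbox{-}II)}
#' and the predicted probability of hepatocellular carcinoma is
#' \eqn{1/(1+e^{-LP})}. Both markers enter on the natural-log scale.
#'
#' @param intercept Intercept on the logit scale.
#' @param b_age Coefficient per year of age.
#' @param b_sex Coefficient for female vs male.
#' @param b_afp Coefficient per natural-log ng/mL of AFP.
#' @param b_pivka Coefficient per natural-log mAU/mL of PIVKA-II.
#' @param provenance One of `"original"`, `"in_the_large"`,
#'   `"recalibrated"`, `"revised"`; records how the model was obtained.
#' @return An object of class `risk_model`.
#' @seealso [asap_model()], [linear_predictor()], [predict.risk_model()]
#' @export
#' @examples
#' m <- risk_model(-2, 0.03, -0.5, 0.4, 1.1)
#' coef(m)
risk_model <- function(intercept, b_age, b_sex, b_afp, b_pivka,
                       provenance = c("original", "in_the_large",
                                      "recalibrated", "revised")) {
  provenance <- match.arg(provenance)
  coefs <- c(intercept = intercept, b_age = b_age, b_sex = b_sex,
             b_afp = b_afp, b_pivka = b_pivka)
  if (!is.numeric(coefs) || length(coefs) != 5L || any(!is.finite(coefs)))
    stop("all five model coefficients must be finite numbers")
  structure(list(intercept = intercept, b_age = b_age, b_sex = b_sex,
                 b_afp = b_afp, b_pivka = b_pivka, provenance = provenance),
            class = "risk_model")
}

#' The published ASAP risk model
#'
#' Returns the ASAP hepatocellular-carcinoma risk model with its published
#' development-cohort coefficients (age, sex, log AFP, log PIVKA-II).
#'
#' @return A `risk_model` with provenance `"original"`.
#' @export
#' @examples
#' exp(coef(asap_model())["b_age"])  # odds ratio per year of age, 1.048
asap_model <- function() {
  risk_model(intercept = -7.57711770,
             b_age     =  0.04666357,
             b_sex     = -0.57611693,
             b_afp     =  0.42243533,
             b_pivka   =  1.10518910,
             provenance = "original")
}

check_markers <- function(cohort) {
  need <- c("age", "sex", "afp", "pivka2")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort is missing required column(s): ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(cohort$afp) | cohort$afp <= 0 |
               !is.finite(cohort$pivka2) | cohort$pivka2 <= 0)
  if (length(bad))
    stop("nonpositive or missing marker values in row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  invisible(TRUE)
}

#' Linear predictor of a risk model
#'
#' Evaluates the model's linear predictor (logit scale) for each patient.
#' Marker values must be strictly positive; they are log-transformed
#' internally (natural log).
#'
#' @param model A [risk_model()].
#' @param cohort A data frame with columns `age`, `sex`, `afp`, `pivka2`.
#' @return Numeric vector of per-patient logits.
#' @export
#' @examples
#' pt <- data.frame(age = 50, sex = 0, afp = 10, pivka2 = 100)
#' linear_predictor(asap_model(), pt)  # 0.8183
linear_predictor <- function(model, cohort) {
  stopifnot(inherits(model, "risk_model"))
  check_markers(cohort)
  model$intercept + model$b_age * cohort$age + model$b_sex * cohort$sex +
    model$b_afp * log(cohort$afp) + model$b_pivka * log(cohort$pivka2)
}

#' Predict method for risk models
#'
#' @param object A [risk_model()].
#' @param newdata Cohort data frame (columns `age`, `sex`, `afp`, `pivka2`).
#' @param type `"response"` for probabilities, `"link"` for logits.
#' @param ... Unused.
#' @return Numeric vector of probabilities (strictly inside (0,1)) or logits.
#' @export
predict.risk_model <- function(object, newdata,
                               type = c("response", "link"), ...) {
  type <- match.arg(type)
  lp <- linear_predictor(object, newdata)
  if (type == "link") lp else stats::plogis(lp)
}

#' @export
coef.risk_model <- function(object, ...) {
  c(intercept = object$intercept, b_age = object$b_age, b_sex = object$b_sex,
    b_afp = object$b_afp, b_pivka = object$b_pivka)
}

#' @export
print.risk_model <- function(x, digits = 8, ...) {
  cat("Logistic HCC risk model (", x$provenance, ")\n", sep = "")
  cat("  logit(P) =", format(x$intercept, digits = digits), "\n")
  cat("    +", format(x$b_age, digits = digits), "* age\n")
  cat("    +", format(x$b_sex, digits = digits), "* sex (female = 1)\n")
  cat("    +", format(x$b_afp, digits = digits), "* log(AFP)\n")
  cat("    +", format(x$b_pivka, digits = digits), "* log(PIVKA-II)\n")
  invisible(x)
}

#' Simulate binary outcomes from a risk model
#'
#' Draws Bernoulli hepatocellular-carcinoma labels for each patient in
#' `newdata` with probabilities given by the model.
#'
#' @param object A [risk_model()].
#' @param nsim Number of simulated label vectors.
#' @param seed Integer seed (required for reproducibility).
#' @param newdata Cohort data frame of covariates.
#' @param ... Unused.
#' @return A data frame with `nsim` columns of 0/1 labels.
#' @export
simulate.risk_model <- function(object, nsim = 1, seed = NULL, newdata, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- predict(object, newdata)
  out <- as.data.frame(replicate(nsim, stats::rbinom(length(p), 1L, p)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Shift a model intercept (recalibration-in-the-large form)
#'
#' Returns a copy of the model with `a` added to the intercept; all slope
#' coefficients are kept. This is the model produced by
#' recalibration-in-the-large, where `a` is the fitted calibration
#' intercept of the original linear predictor taken as an offset.
#'
#' @param model A [risk_model()].
#' @param a Intercept shift on the logit scale.
#' @return A `risk_model` with provenance `"in_the_large"`.
#' @export
shift_intercept <- function(model, a) {
  stopifnot(inherits(model, "risk_model"), is.finite(a))
  risk_model(model$intercept + a, model$b_age, model$b_sex,
             model$b_afp, model$b_pivka, provenance = "in_the_large")
}

#' Rescale a model by calibration intercept and slope (recalibration form)
#'
#' Applies logistic recalibration parameters to a model: every coefficient
#' (including the intercept) is multiplied by the calibration slope `b`,
#' and `a` is added to the intercept, so the new linear predictor equals
#' `a + b * LP_old` exactly.
#'
#' @param model A [risk_model()].
#' @param a Calibration intercept.
#' @param b Calibration slope.
#' @return A `risk_model` with provenance `"recalibrated"`.
#' @export
rescale_model <- function(model, a, b) {
  stopifnot(inherits(model, "risk_model"), is.finite(a), is.finite(b))
  risk_model(b * model$intercept + a, b * model$b_age, b * model$b_sex,
             b * model$b_afp, b * model$b_pivka, provenance = "recalibrated")
}

#' Read / write a risk model as JSON
#'
#' Serializes the five coefficients and the provenance tag to a small JSON
#' document, and reads one back.
#'
#' @param model A [risk_model()].
#' @param path File path.
#' @return `read_model_json()` returns a `risk_model`; `write_model_json()`
#'   returns `path` invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "risk_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  risk_model(x$intercept, x$b_age, x$b_sex, x$b_afp, x$b_pivka,
             provenance = x$provenance)
}
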