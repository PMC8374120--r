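#' Subgroup parameters for the synthetic surveillance cohort
#'
#' One diagnostic subgroup of the simulated case mix: its size, age
#' distribution (normal, truncated below at the surveillance entry age),
#' male fraction, and the per-subgroup normal distributions of the
#' natural-log serum markers. Marker levels are log-normal: AFP and
#' PIVKA-II are drawn as `exp(Normal(mean, sd))` on the natural-log scale.
#'
#' @param label Subgroup label: `"hepatitis"`, `"cirrhosis"`,
#'   `"benign_SOL"` or `"HCC"`.
#' @param n Number of patients (>= 0).
#' @param age_mean,age_sd Age distribution in years (sd >= 0).
#' @param male_frac Fraction of males, in `[0, 1]` (sex coded 0 = male).
#' @param logafp_mean,logafp_sd Natural-log AFP (ng/mL) moments.
#' @param logpivka_mean,logpivka_sd Natural-log PIVKA-II (mAU/mL) moments.
#' @return A `subgroup_params` list.
#' @export
subgroup_params <- function(label, n, age_mean, age_sd, male_frac,
                            logafp_mean, logafp_sd,
                            logpivka_mean, logpivka_sd) {
  label <- match.arg(label, c("hepatitis", "cirrhosis", "benign_SOL", "HCC"))
  if (n < 0 || n != round(n)) stop("subgroup n must be a nonnegative integer")
  if (age_sd < 0 || logafp_sd < 0 || logpivka_sd < 0)
    stop("standard deviations must be nonnegative")
  if (male_frac < 0 || male_frac > 1)
    stop("male_frac must lie in [0, 1]")
  structure(list(label = label, n = as.integer(n),
                 age_mean = age_mean, age_sd = age_sd, male_frac = male_frac,
                 logafp_mean = logafp_mean, logafp_sd = logafp_sd,
                 logpivka_mean = logpivka_mean, logpivka_sd = logpivka_sd),
            class = "subgroup_params")
}

#' Default case mix of the synthetic validation cohort
#'
#' Subgroup sizes 451/308/96/157 (hepatitis, cirrhosis, benign
#' space-occupying lesion, HCC), giving 1012 patients with an overall HCC
#' prevalence of 15.5% (157/1012). Ages, male fractions, and log-marker
#' moments are the per-subgroup summary statistics of the surveillance
#' cohort the generator emulates.
#'
#' @return A list of four [subgroup_params()] objects.
#' @export
default_subgroup_params <- function() {
  list(
    subgroup_params("hepatitis",  451, 50.7,  9.4, 345/451, 1.46, 1.09, 3.14, 0.58),
    subgroup_params("cirrhosis",  308, 58.1, 10.7, 206/308, 1.70, 1.32, 3.33, 1.00),
    subgroup_params("benign_SOL",  96, 58.5, 12.4,  58/96,  1.87, 1.55, 3.54, 1.08),
    subgroup_params("HCC",        157, 59.6, 12.0, 133/157, 5.94, 3.85, 8.47, 2.56)
  )
}

# Normal truncated below at `lower`, drawn by inverse-CDF so the
# random-number stream consumes exactly n uniforms.
rnorm_trunc_lower <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(max(mean, lower), n))
  p0 <- stats::pnorm(lower, mean, sd)
  u <- stats::runif(n, p0, 1)
  stats::qnorm(u, mean, sd)
}

#' Generate a synthetic surveillance cohort
#'
#' Draws a patient-level cohort from per-subgroup distributions: truncated
#' normal ages (at or above `age_min`, the surveillance entry age),
#' Bernoulli sex (0 = male, 1 = female), and jointly log-normal AFP and
#' PIVKA-II with within-subgroup correlation `marker_cor` on the log
#' scale. HCC status is 1 exactly for the HCC subgroup. A fixed seed gives
#' a byte-identical table.
#'
#' @param params List of [subgroup_params()]; default [default_subgroup_params()].
#' @param seed Integer seed for the single pseudo-random stream.
#' @param marker_cor Correlation of log AFP and log PIVKA-II within a
#'   subgroup (the source data report marginals only; 0.3 by default).
#' @param age_min Lower truncation of age in years (inclusion criterion).
#' @return A data frame with columns `age`, `sex`, `afp`, `pivka2`, `hcc`,
#'   `subgroup`.
#' @export
#' @examples
#' co <- simulate_cohort(seed = 1)
#' nrow(co); sum(co$hcc)  # 1012 patients, 157 HCC
simulate_cohort <- function(params = default_subgroup_params(), seed = 1,
                            marker_cor = 0.3, age_min = 35) {
  if (!length(params)) stop("at least one subgroup is required")
  if (abs(marker_cor) > 1) stop("marker_cor must lie in [-1, 1]")
  set.seed(as.integer(seed))
  rows <- lapply(params, function(g) {
    stopifnot(inherits(g, "subgroup_params"))
    n <- g$n
    if (n == 0L) return(NULL)
    age <- rnorm_trunc_lower(n, g$age_mean, g$age_sd, age_min)
    sex <- stats::rbinom(n, 1L, 1 - g$male_frac)  # 1 = female
    z1 <- stats::rnorm(n)
    z2 <- stats::rnorm(n)
    la <- g$logafp_mean + g$logafp_sd * z1
    lp <- g$logpivka_mean +
      g$logpivka_sd * (marker_cor * z1 + sqrt(1 - marker_cor^2) * z2)
    data.frame(age = age, sex = sex, afp = exp(la), pivka2 = exp(lp),
               hcc = as.integer(g$label == "HCC"), subgroup = g$label,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(age = numeric(), sex = integer(), afp = numeric(),
                      pivka2 = numeric(), hcc = integer(),
                      subgroup = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Follow-up process parameters
#'
#' Exponential event hazards per risk group (events/month), a
#' loss-to-follow-up fraction, and an administrative censoring horizon.
#' Defaults: hazards calibrated so 18-month cumulative incidences
#' approximate 0.9%, 5.8% and 22.2% in the low/medium/high groups,
#' 18.8% loss to follow-up, 24-month horizon.
#'
#' @param hazards Named numeric vector of per-group event hazards
#'   (events/month, >= 0); names are the risk-group labels.
#' @param loss_frac Probability of loss to follow-up, in `[0, 1]`; lost
#'   patients are censored at a uniform time before the horizon.
#' @param horizon Administrative censoring time in months (>= 0).
#' @return A `followup_params` list.
#' @export
followup_params <- function(hazards = c(low    = -log(1 - 0.009) / 18,
                                        medium = -log(1 - 0.058) / 18,
                                        high   = -log(1 - 0.222) / 18),
                            loss_frac = 0.188, horizon = 24) {
  if (any(hazards < 0)) stop("hazards must be nonnegative")
  if (loss_frac < 0 || loss_frac > 1) stop("loss_frac must lie in [0, 1]")
  if (horizon < 0) stop("horizon must be nonnegative")
  if (is.null(names(hazards))) stop("hazards must be named by risk group")
  structure(list(hazards = hazards, loss_frac = loss_frac, horizon = horizon),
            class = "followup_params")
}

#' Simulate follow-up times and events for a cohort
#'
#' Adds censored time-to-event columns to a cohort: exponential event
#' times with the risk-group-specific hazard, censored at the minimum of
#' an (optional) loss-to-follow-up time, uniform on `(0, horizon)`, and
#' the administrative horizon. `event = 1` iff the event time precedes
#' the censoring time.
#'
#' @param cohort Cohort data frame (no missing covariates).
#' @param group Character or factor of per-patient risk groups; must match
#'   the names of `fp$hazards` and contain no missing values.
#' @param fp A [followup_params()].
#' @param seed Integer seed.
#' @return The cohort with `time` (months) and `event` (0/1) columns.
#' @export
simulate_followup <- function(cohort, group, fp = followup_params(), seed = 1) {
  stopifnot(inherits(fp, "followup_params"))
  n <- nrow(cohort)
  group <- as.character(group)
  if (length(group) != n || anyNA(group))
    stop("every patient needs a risk-group assignment")
  unknown <- setdiff(unique(group), names(fp$hazards))
  if (length(unknown))
    stop("no hazard configured for group(s): ", paste(unknown, collapse = ", "))
  set.seed(as.integer(seed))
  h <- fp$hazards[group]
  e <- stats::rexp(n)                       # unit-rate draws; time = e / h
  t_event <- ifelse(h > 0, e / h, Inf)
  lost <- stats::rbinom(n, 1L, fp$loss_frac) == 1L
  t_loss <- ifelse(lost, stats::runif(n, 0, fp$horizon), Inf)
  censor <- pmin(t_loss, fp$horizon)
  cohort$time <- pmin(t_event, censor)
  cohort$event <- as.integer(t_event <= censor)
  cohort
}
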