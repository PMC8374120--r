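#' Confusion counts at a probability threshold
#'
#' A positive call is `prob >= pt` (boundary inclusive).
#'
#' @param probs Predicted probabilities.
#' @param labels 0/1 outcomes.
#' @param pt Threshold probability in (0, 1).
#' @return Named integer vector `c(TP, FP, TN, FN)` summing to `n`.
#' @export
confusion_at_threshold <- function(probs, labels, pt) {
  labels <- as.integer(labels)
  stopifnot(length(probs) == length(labels), all(labels %in% 0:1))
  if (pt <= 0 || pt >= 1) stop("pt must lie strictly in (0, 1)")
  pos <- probs >= pt
  c(TP = sum(pos & labels == 1L), FP = sum(pos & labels == 0L),
    TN = sum(!pos & labels == 0L), FN = sum(!pos & labels == 1L))
}

#' Net benefit at a threshold probability
#'
#' `NB = TP/n - (FP/n) * pt/(1 - pt)`: true positives per patient minus
#' false positives weighted by the odds of the threshold, the standard
#' decision-curve-analysis weighting.
#'
#' @param counts Named vector with at least `TP` and `FP` elements, e.g.
#'   from [confusion_at_threshold()].
#' @param n Total number of patients (defaults to `sum(counts)` when all
#'   four confusion cells are supplied).
#' @param pt Threshold probability in (0, 1).
#' @return Net benefit (dimensionless, at most the prevalence).
#' @export
#' @examples
#' net_benefit(c(TP = 157, FP = 428), n = 1012, pt = 0.013)  # 0.150
net_benefit <- function(counts, n = sum(counts), pt) {
  if (pt <= 0 || pt >= 1) stop("pt must lie strictly in (0, 1)")
  stopifnot(all(c("TP", "FP") %in% names(counts)), n > 0)
  unname(counts["TP"] / n - (counts["FP"] / n) * pt / (1 - pt))
}

#' Classification statistics at a threshold
#'
#' Sensitivity, specificity, PPV, NPV and net benefit at a probability
#' threshold, either from explicit confusion counts or computed from
#' predictions; with `boot_reps > 0` (and predictions supplied) each
#' statistic gets a stratified percentile bootstrap CI (resampling within
#' outcome classes, as in a case-mix-preserving bootstrap).
#'
#' @param pt Threshold probability in (0, 1).
#' @param counts Named vector `c(TP, FP, TN, FN)`; alternatively supply
#'   `probs` and `labels`.
#' @param probs,labels Predictions and 0/1 outcomes.
#' @param boot_reps Bootstrap replicates (2000 reproduces the reference
#'   analysis; 0 skips CIs).
#' @param seed Integer seed for the bootstrap.
#' @param conf Confidence level.
#' @return A one-row data frame of class `threshold_stats` with counts,
#'   the four proportions, net benefit, and (if bootstrapped)
#'   `*_lower`/`*_upper` bounds. An empty predicted-positive set gives
#'   `NA` PPV with a warning.
#' @export
#' @examples
#' classification_stats(0.013, counts = c(TP = 157, FP = 428, TN = 427, FN = 0))
classification_stats <- function(pt, counts = NULL, probs = NULL,
                                 labels = NULL, boot_reps = 0, seed = 1,
                                 conf = 0.95) {
  if (is.null(counts)) {
    if (is.null(probs) || is.null(labels))
      stop("supply either counts or probs + labels")
    counts <- confusion_at_threshold(probs, labels, pt)
  }
  stopifnot(all(c("TP", "FP", "TN", "FN") %in% names(counts)))
  n <- sum(counts)
  one <- function(ct) {
    npos <- ct["TP"] + ct["FP"]
    c(sensitivity = unname(ct["TP"] / (ct["TP"] + ct["FN"])),
      specificity = unname(ct["TN"] / (ct["TN"] + ct["FP"])),
      ppv = unname(if (npos == 0) NA_real_ else ct["TP"] / npos),
      npv = unname(ct["TN"] / (ct["TN"] + ct["FN"])),
      nb = net_benefit(ct, sum(ct), pt))
  }
  est <- one(counts)
  if (is.na(est["ppv"]))
    warning("no predicted positives at pt = ", pt, "; PPV undefined")
  out <- data.frame(threshold = pt, t(counts), n = n, t(est))
  if (boot_reps > 0) {
    if (is.null(probs))
      stop("bootstrap CIs need probs + labels, not bare counts")
    dat <- data.frame(p = probs, y = as.integer(labels))
    for (stat in names(est)) {
      b <- bootstrap_ci(function(d)
        one(confusion_at_threshold(d$p, d$y, pt))[[stat]],
        dat, reps = boot_reps, seed = seed, strata = dat$y, conf = conf)
      out[[paste0(stat, "_lower")]] <- b[["lower"]]
      out[[paste0(stat, "_upper")]] <- b[["upper"]]
    }
  }
  class(out) <- c("threshold_stats", "data.frame")
  out
}

#' Named clinical threshold presets
#'
#' The seven thresholds of the reference analysis: 1.3% (median
#' predicted probability of non-HCC patients), 13.1% (optimal cutoff),
#' 15.5% (cohort HCC incidence), 1/3 and 2/3 (the original model's
#' published decision thresholds), 50% (sigmoid midpoint) and 98.3%
#' (median predicted probability of HCC patients).
#'
#' @return Named numeric vector of thresholds.
#' @export
threshold_presets <- function() {
  c(median_non_hcc = 0.013, optimal = 0.131, incidence = 0.155,
    one_third = 1/3, midpoint = 0.5, two_thirds = 2/3,
    median_hcc = 0.983)
}

#' Youden-index optimal cutoff
#'
#' The observed predicted probability maximizing sensitivity +
#' specificity - 1.
#'
#' @param probs Predicted probabilities.
#' @param labels 0/1 outcomes.
#' @return The cutoff probability.
#' @export
youden_cutoff <- function(probs, labels) {
  labels <- as.integer(labels)
  cand <- sort(unique(probs))
  cand <- cand[cand > 0 & cand < 1]
  j <- vapply(cand, function(pt) {
    ct <- confusion_at_threshold(probs, labels, pt)
    ct[["TP"]] / (ct[["TP"]] + ct[["FN"]]) +
      ct[["TN"]] / (ct[["TN"]] + ct[["FP"]]) - 1
  }, 0)
  cand[which.max(j)]
}

#' Table of classification statistics across thresholds
#'
#' One row per threshold, optionally restricted to a cohort subset (e.g.
#' an etiology subgroup).
#'
#' @param probs,labels Predictions and 0/1 outcomes.
#' @param thresholds Vector of thresholds; default [threshold_presets()].
#' @param boot_reps,seed,conf Passed to [classification_stats()].
#' @param subset Optional logical/integer index restricting the cohort.
#' @return Data frame with one `threshold_stats` row per threshold.
#' @export
threshold_report <- function(probs, labels, thresholds = threshold_presets(),
                             boot_reps = 0, seed = 1, conf = 0.95,
                             subset = NULL) {
  if (!is.null(subset)) {
    probs <- probs[subset]
    labels <- labels[subset]
  }
  rows <- lapply(thresholds, function(pt)
    classification_stats(pt, probs = probs, labels = labels,
                         boot_reps = boot_reps, seed = seed, conf = conf))
  out <- do.call(rbind, rows)
  if (!is.null(names(thresholds))) out$name <- names(thresholds)
  out
}

#' Decision curve
#'
#' Net benefit of the model, the treat-all policy
#' (`prevalence - (1 - prevalence) * pt/(1 - pt)`) and the treat-none
#' policy (0) across a threshold grid.
#'
#' @param probs,labels Predictions and 0/1 outcomes.
#' @param grid Thresholds inside (0, 1); default 0.01 to 0.99 by 0.01.
#' @return Data frame `threshold`, `net_benefit`, `treat_all`, `treat_none`.
#' @export
decision_curve <- function(probs, labels, grid = seq(0.01, 0.99, by = 0.01)) {
  labels <- as.integer(labels)
  if (any(grid <= 0 | grid >= 1)) stop("grid must lie strictly in (0, 1)")
  prev <- mean(labels)
  nb <- vapply(grid, function(pt)
    net_benefit(confusion_at_threshold(probs, labels, pt), length(labels),
                pt), 0)
  data.frame(threshold = grid, net_benefit = nb,
             treat_all = prev - (1 - prev) * grid / (1 - grid),
             treat_none = 0)
}

#' Two-threshold risk stratification
#'
#' Assigns each patient to the low (`p < t_low`), medium
#' (`t_low <= p <= t_high`) or high (`p > t_high`) risk group and, when
#' outcomes are supplied, tabulates per-group incidence and relative
#' risks against the medium (reference) group.
#'
#' @param probs Predicted probabilities.
#' @param t_low,t_high Stratification thresholds, `0 < t_low < t_high < 1`;
#'   defaults 1.3% and 15.5%.
#' @param labels Optional 0/1 outcomes.
#' @param conf Confidence level for the relative-risk CIs.
#' @return Object of class `risk_strata`: `group` factor, `thresholds`,
#'   and (with labels) a `table` of n/events/incidence and `rr` against
#'   the medium group.
#' @export
stratify <- function(probs, t_low = 0.013, t_high = 0.155, labels = NULL,
                     conf = 0.95) {
  if (!(0 < t_low && t_low < t_high && t_high < 1))
    stop("need 0 < t_low < t_high < 1")
  group <- factor(ifelse(probs < t_low, "low",
                         ifelse(probs > t_high, "high", "medium")),
                  levels = c("low", "medium", "high"))
  out <- list(group = group, thresholds = c(t_low = t_low, t_high = t_high))
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    nn <- tapply(labels, group, length, default = 0L)
    ev <- tapply(labels, group, sum, default = 0L)
    tab <- data.frame(group = levels(group), n = as.integer(nn),
                      events = as.integer(ev),
                      incidence = ifelse(nn > 0, ev / nn, NA_real_))
    ref <- tab[tab$group == "medium", ]
    rr <- lapply(c("low", "high"), function(g) {
      r <- tab[tab$group == g, ]
      if (r$n == 0 || ref$n == 0) return(NULL)
      cbind(group = g, as.data.frame(t(relative_risk(
        r$events, r$n, ref$events, ref$n, conf = conf))))
    })
    out$table <- tab
    out$rr <- do.call(rbind, rr)
  }
  class(out) <- "risk_strata"
  out
}

#' @export
print.risk_strata <- function(x, ...) {
  cat(sprintf("Risk stratification at thresholds %.3f / %.3f\n",
              x$thresholds["t_low"], x$thresholds["t_high"]))
  print(table(x$group))
  if (!is.null(x$table)) {
    print(x$table, row.names = FALSE)
    cat("Relative risk vs medium group:\n")
    print(x$rr, row.names = FALSE)
  }
  invisible(x)
}

#' Relative risk of two proportions
#'
#' `RR = (events_a/n_a) / (events_b/n_b)` with the Katz log-normal
#' confidence interval. A zero numerator incidence gives RR 0; a zero
#' reference incidence gives RR Inf.
#'
#' @param events_a,n_a Events and size of the comparison group.
#' @param events_b,n_b Events and size of the reference group.
#' @param conf Confidence level.
#' @return Named vector `c(rr, lower, upper)`.
#' @export
#' @examples
#' relative_risk(142, 183, 15, 402)  # 20.8
relative_risk <- function(events_a, n_a, events_b, n_b, conf = 0.95) {
  stopifnot(n_a > 0, n_b > 0, events_a >= 0, events_b >= 0)
  rr <- (events_a / n_a) / (events_b / n_b)
  if (events_a == 0 || events_b == 0)
    return(c(rr = rr, lower = NA_real_, upper = NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  se <- sqrt(1 / events_a - 1 / n_a + 1 / events_b - 1 / n_b)
  c(rr = rr, lower = rr * exp(-z * se), upper = rr * exp(z * se))
}

#' Chi-square comparison of two proportions
#'
#' Pearson chi-square on the 2x2 table with Yates continuity correction.
#'
#' @inheritParams relative_risk
#' @return List with `chi_square`, `df`, `p_value`.
#' @export
compare_proportions <- function(events_a, n_a, events_b, n_b) {
  if (n_a <= 0 || n_b <= 0) stop("group sizes must be positive")
  tot_e <- events_a + events_b
  if (tot_e == 0 || tot_e == n_a + n_b)
    stop("a margin of the 2x2 table is zero; chi-square test undefined")
  ht <- stats::prop.test(c(events_a, events_b), c(n_a, n_b), correct = TRUE)
  list(chi_square = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}
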