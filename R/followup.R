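#' Kaplan-Meier curve
#'
#' Product-limit estimate of event-free survival; the complement is the
#' cumulative incidence. All events sharing a distinct time are processed
#' together; censored subjects leave the risk set after their time.
#'
#' @param times Follow-up times in months (>= 0).
#' @param events 0/1 event indicators (1 = incident HCC).
#' @return Object of class `km_curve`: data frame `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`, `cum_incidence` over the distinct
#'   observed times.
#' @export
km_estimate <- function(times, events) {
  events <- as.integer(events)
  stopifnot(length(times) == length(events), all(events %in% 0:1))
  if (any(times < 0)) stop("negative follow-up times are not allowed")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    survival = fit$surv,
                    cum_incidence = 1 - fit$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Cumulative incidence at given times
#'
#' Steps the Kaplan-Meier cumulative incidence at arbitrary time points
#' (right-continuous: the value just after the last event at or before
#' each time).
#'
#' @param curve A [km_estimate()] result.
#' @param at Numeric times (months).
#' @return Numeric vector of cumulative incidences.
#' @export
cum_incidence_at <- function(curve, at) {
  stopifnot(inherits(curve, "km_curve"))
  vapply(at, function(t0) {
    i <- which(curve$time <= t0)
    if (!length(i)) 0 else curve$cum_incidence[max(i)]
  }, 0)
}

#' Log-rank test across risk groups
#'
#' Standard log-rank chi-square with `k - 1` degrees of freedom, with
#' per-group observed and expected event counts. With
#' `pairwise = TRUE`, each two-group test is also reported (unadjusted
#' p-values).
#'
#' @param times Follow-up times (months).
#' @param events 0/1 event indicators.
#' @param groups Group labels (>= 2 groups, >= 1 event overall).
#' @param pairwise Also compute all two-group tests.
#' @return Object of class `logrank_result`: `chi_square`, `df`,
#'   `p_value`, `table` (group, n, observed, expected) and optionally
#'   `pairwise` (data frame of two-group comparisons).
#' @export
logrank <- function(times, events, groups, pairwise = FALSE) {
  events <- as.integer(events)
  groups <- factor(groups)
  stopifnot(length(times) == length(events), length(groups) == length(times))
  if (nlevels(droplevels(groups)) < 2L)
    stop("log-rank test needs at least two groups")
  if (sum(events) == 0L)
    stop("log-rank test undefined with no events (all observations censored)")
  groups <- droplevels(groups)
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- nlevels(groups) - 1L
  out <- list(chi_square = unname(sd$chisq), df = df,
              p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
              table = data.frame(group = levels(groups), n = as.vector(sd$n),
                                 observed = sd$obs, expected = sd$exp))
  if (pairwise) {
    cmb <- utils::combn(levels(groups), 2, simplify = FALSE)
    out$pairwise <- do.call(rbind, lapply(cmb, function(pr) {
      keep <- groups %in% pr
      sub <- logrank(times[keep], events[keep], droplevels(groups[keep]))
      data.frame(group_a = pr[1], group_b = pr[2],
                 chi_square = sub$chi_square, p_value = sub$p_value)
    }))
  }
  class(out) <- "logrank_result"
  out
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank test: chi2 = %.3f, df = %d, p = %s\n",
              x$chi_square, x$df, format.pval(x$p_value, digits = 3)))
  print(x$table, row.names = FALSE)
  if (!is.null(x$pairwise)) {
    cat("Pairwise (unadjusted):\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' Per-group cumulative incidence summary
#'
#' Kaplan-Meier cumulative incidences of each risk group at selected
#' horizons (3, 6 and 18 months by default).
#'
#' @param times,events,groups As in [logrank()].
#' @param at Horizons in months.
#' @return Data frame: one row per group, one column per horizon.
#' @export
followup_summary <- function(times, events, groups, at = c(3, 6, 18)) {
  groups <- factor(groups)
  rows <- lapply(levels(groups), function(g) {
    keep <- groups == g
    ci <- cum_incidence_at(km_estimate(times[keep], events[keep]), at)
    stats::setNames(data.frame(g, nrow = sum(keep), t(ci)),
                    c("group", "n", paste0("cuminc_", at, "m")))
  })
  do.call(rbind, rows)
}
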