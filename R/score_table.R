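#' Nomogram score table for a risk model
#'
#' Builds the standard 0-100-point nomogram construction: each
#' covariate's contribution to the linear predictor over its configured
#' range is mapped linearly to points, anchored so that the range
#' endpoint minimizing the contribution scores 0 and the covariate with
#' the widest contribution spans exactly 100 points; the total-points
#' scale maps back to probability through the logistic. Markers are
#' handled on their natural-log scale, so points are linear in log(AFP)
#' and log(PIVKA-II) but tabulated in native units.
#'
#' @param model A [risk_model()].
#' @param ranges Named list of `c(min, max)` native-unit ranges for
#'   `age`, `sex`, `afp`, `pivka2` (markers must be positive). Defaults
#'   cover a surveillance population: age 35-90, sex 0-1, AFP
#'   0.6-60,000 ng/mL, PIVKA-II 10-75,000 mAU/mL.
#' @param n_breaks Number of tabulated breakpoints per covariate.
#' @return Object of class `score_table`.
#' @export
#' @examples
#' st <- build_score_table(asap_model())
#' pt <- data.frame(age = 55, sex = 0, afp = 400, pivka2 = 2000)
#' score_to_probability(st, score_points(st, pt))
#' predict(asap_model(), pt)  # identical
build_score_table <- function(model,
                              ranges = list(age = c(35, 90), sex = c(0, 1),
                                            afp = c(0.6, 6e4),
                                            pivka2 = c(10, 7.5e4)),
                              n_breaks = 11) {
  stopifnot(inherits(model, "risk_model"))
  covs <- c("age", "sex", "afp", "pivka2")
  if (!all(covs %in% names(ranges)))
    stop("ranges must name age, sex, afp and pivka2")
  b <- c(age = model$b_age, sex = model$b_sex, afp = model$b_afp,
         pivka2 = model$b_pivka)
  trans <- function(cov, x) if (cov %in% c("afp", "pivka2")) log(x) else x
  z_lo <- z_hi <- z_ref <- numeric(length(covs))
  names(z_lo) <- names(z_hi) <- names(z_ref) <- covs
  for (cov in covs) {
    rg <- sort(as.numeric(ranges[[cov]]))
    if (length(rg) != 2L || !all(is.finite(rg)))
      stop("range for ", cov, " must be two finite numbers")
    if (cov %in% c("afp", "pivka2") && rg[1] <= 0)
      stop("marker ranges must be positive")
    z_lo[cov] <- trans(cov, rg[1]); z_hi[cov] <- trans(cov, rg[2])
    # reference endpoint: the one minimizing b * z
    z_ref[cov] <- if (b[cov] >= 0) z_lo[cov] else z_hi[cov]
  }
  span <- abs(b * (z_hi - z_lo))     # contribution width per covariate
  M <- max(span)
  if (M <= 0)
    stop("the widest covariate contribution has zero width; ",
         "ranges are degenerate or all coefficients are zero")
  lp0 <- model$intercept + sum(b * z_ref)
  breaks <- lapply(covs, function(cov) {
    x <- seq(sort(as.numeric(ranges[[cov]]))[1],
             sort(as.numeric(ranges[[cov]]))[2], length.out = n_breaks)
    data.frame(covariate = cov, value = x,
               points = 100 * b[cov] * (trans(cov, x) - z_ref[cov]) / M)
  })
  structure(list(model = model, ranges = ranges, b = b,
                 z_ref = z_ref, scale = M, lp0 = lp0,
                 max_points = sum(100 * span / M),
                 breaks = do.call(rbind, breaks)),
            class = "score_table")
}

#' Per-patient nomogram points
#'
#' @param table A [build_score_table()] result.
#' @param cohort Cohort data frame (columns `age`, `sex`, `afp`, `pivka2`).
#' @return Numeric vector of total points.
#' @export
score_points <- function(table, cohort) {
  stopifnot(inherits(table, "score_table"))
  check_markers(cohort)
  z <- cbind(age = cohort$age, sex = cohort$sex, afp = log(cohort$afp),
             pivka2 = log(cohort$pivka2))
  pts <- sweep(z, 2, table$z_ref[colnames(z)])
  rowSums(sweep(pts, 2, 100 * table$b[colnames(z)] / table$scale, `*`))
}

#' Probability from total nomogram points
#'
#' Inverts the points scale through the logistic: strictly increasing in
#' points. Points must lie within the table's total range.
#'
#' @param table A [build_score_table()] result.
#' @param total_points Numeric total points.
#' @return Probability in (0, 1).
#' @export
score_to_probability <- function(table, total_points) {
  stopifnot(inherits(table, "score_table"))
  if (any(total_points < -1e-9 | total_points > table$max_points + 1e-9))
    stop("total points outside the table range [0, ",
         format(table$max_points), "]")
  stats::plogis(table$lp0 + total_points * table$scale / 100)
}

#' @export
print.score_table <- function(x, ...) {
  cat("Nomogram score table (0-100 points per covariate; max total ",
      format(x$max_points, digits = 4), ")\n", sep = "")
  print(x$breaks, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
as.data.frame.score_table <- function(x, ...) x$breaks
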