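test_that("default synthetic cohort reproduces the configured case mix", {
  co <- simulate_cohort(seed = 1)
  expect_equal(nrow(co), 1012L)
  expect_equal(sum(co$hcc), 157L)
  expect_equal(as.vector(table(co$subgroup)[c("hepatitis", "cirrhosis",
                                              "benign_SOL", "HCC")]),
               c(451L, 308L, 96L, 157L))
  # HCC status is 1 exactly for the HCC subgroup
  expect_true(all(co$hcc[co$subgroup == "HCC"] == 1L))
  expect_true(all(co$hcc[co$subgroup != "HCC"] == 0L))
  expect_true(all(co$age >= 35))
  expect_true(all(co$afp > 0 & co$pivka2 > 0))
})

test_that("cohort generation is byte-for-byte reproducible under a seed", {
  a <- simulate_cohort(seed = 99)
  b <- simulate_cohort(seed = 99)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  expect_false(identical(a$afp, simulate_cohort(seed = 100)$afp))
})

test_that("all-zero subgroup sizes give an empty cohort", {
  params <- lapply(default_subgroup_params(), function(g) { g$n <- 0L; g })
  co <- simulate_cohort(params, seed = 1)
  expect_equal(nrow(co), 0L)
  expect_setequal(names(co),
                  c("age", "sex", "afp", "pivka2", "hcc", "subgroup"))
})

test_that("invalid subgroup parameters are rejected", {
  expect_error(subgroup_params("HCC", -1, 60, 10, 0.8, 5.9, 3.8, 8.5, 2.6),
               "nonnegative")
  expect_error(subgroup_params("HCC", 10, 60, -1, 0.8, 5.9, 3.8, 8.5, 2.6),
               "deviations")
  expect_error(subgroup_params("HCC", 10, 60, 10, 1.2, 5.9, 3.8, 8.5, 2.6),
               "male_frac")
})

test_that("generated log markers recover the configured moments", {
  params <- list(subgroup_params("HCC", 10000, 59.6, 12.0, 0.85,
                                 5.94, 3.85, 8.47, 2.56))
  co <- simulate_cohort(params, seed = 5)
  la <- log(co$afp)
  expect_lt(abs(mean(la) - 5.94), 3 * 3.85 / sqrt(10000))
  expect_lt(abs(sd(la) - 3.85), 3 * 3.85 / sqrt(2 * 10000))
  lp <- log(co$pivka2)
  expect_lt(abs(mean(lp) - 8.47), 3 * 2.56 / sqrt(10000))
  # configured within-subgroup log-marker correlation
  expect_lt(abs(cor(la, lp) - 0.3), 0.04)
})

test_that("follow-up respects degenerate hazards and horizons", {
  co <- simulate_cohort(seed = 2)[1:50, ]
  grp <- rep("g", 50)
  fp0 <- followup_params(hazards = c(g = 0), loss_frac = 0.2, horizon = 24)
  fu <- simulate_followup(co, grp, fp0, seed = 3)
  expect_true(all(fu$event == 0L))
  fph <- followup_params(hazards = c(g = 0.1), loss_frac = 0.2, horizon = 0)
  fu <- simulate_followup(co, grp, fph, seed = 3)
  expect_true(all(fu$time == 0))
  expect_true(all(fu$event == 0L))
  expect_error(simulate_followup(co, rep(NA, 50), fp0), "assignment")
  expect_error(simulate_followup(co, rep("other", 50), fp0), "other")
})

test_that("events always occur at or before the censoring horizon", {
  co <- simulate_cohort(seed = 4)
  fp <- followup_params()
  grp <- sample(names(fp$hazards), nrow(co), replace = TRUE)
  fu <- simulate_followup(co, grp, fp, seed = 6)
  expect_true(all(fu$time <= fp$horizon))
  expect_true(all(fu$time[fu$event == 1L] <= fp$horizon))
  # loss-to-follow-up produces censoring strictly inside the horizon
  expect_gt(sum(fu$event == 0L & fu$time < fp$horizon), 0)
})

test_that("simulated follow-up matches closed-form exponential incidence", {
  params <- list(subgroup_params("hepatitis", 5000, 50, 10, 0.7,
                                 1.5, 1.1, 3.1, 0.6))
  co <- simulate_cohort(params, seed = 11)
  fp <- followup_params(hazards = c(g = 0.01), loss_frac = 0, horizon = 24)
  fu <- simulate_followup(co, rep("g", 5000), fp, seed = 12)
  km <- km_estimate(fu$time, fu$event)
  truth <- 1 - exp(-0.12)
  se <- sqrt(truth * (1 - truth) / 5000)
  expect_lt(abs(cum_incidence_at(km, 12) - truth), 3 * se)
})
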