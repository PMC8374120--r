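test_that("recalibration-in-the-large shifts only the intercept", {
  m <- asap_model()
  true_shift <- -3.243
  shifted <- shift_intercept(m, true_shift)
  co <- model_cohort(shifted, n_scale = 20, seed = 41)
  fit <- recalibrate_in_the_large(m, co)
  expect_identical(fit$n_free, 1L)
  expect_identical(fit$df, nrow(co) - 1L)
  # slopes untouched, intercept = original + fitted a (machine precision)
  expect_identical(coef(fit$model)[-1], coef(m)[-1])
  a_hat <- fit$model$intercept - m$intercept
  # the injected shift is recovered within 3 SE of the offset fit
  se <- sqrt(1 / sum(predict(fit$model, co) *
                       (1 - predict(fit$model, co))))
  expect_lt(abs(a_hat - true_shift), 3 * se)
})

test_that("halving the odds by construction is recovered as a = -log 2", {
  m <- asap_model()
  co <- model_cohort(shift_intercept(m, -log(2)), n_scale = 20, seed = 43)
  fit <- recalibrate_in_the_large(m, co)
  a_hat <- fit$model$intercept - m$intercept
  se <- sqrt(1 / sum(predict(fit$model, co) *
                       (1 - predict(fit$model, co))))
  expect_lt(abs(a_hat + log(2)), 3 * se)
})

test_that("logistic recalibration is self-consistent on model-generated data", {
  m <- asap_model()
  co <- model_cohort(m, n_scale = 20, seed = 45)
  fit <- recalibrate(m, co)
  expect_identical(fit$n_free, 2L)
  b_hat <- fit$model$b_age / m$b_age
  a_hat <- fit$model$intercept - b_hat * m$intercept
  expect_lt(abs(a_hat), 0.2)
  expect_lt(abs(b_hat - 1), 0.1)
  # returned coefficients are exactly slope x original
  expect_equal(coef(fit$model)[-1] / coef(m)[-1],
               rep(b_hat, 4), ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("model revision recovers known coefficients within 3 SE", {
  m <- asap_model()
  co <- model_cohort(m, n_scale = 10, seed = 47)
  fit <- revise(m, co)
  expect_identical(fit$n_free, 5L)
  # standard errors from the information matrix of the revision fit
  X <- cbind(1, co$age, co$sex, log(co$afp), log(co$pivka2))
  p <- predict(fit$model, co)
  se <- sqrt(diag(solve(crossprod(X * sqrt(p * (1 - p))))))
  expect_true(all(abs(coef(fit$model) - coef(m)) < 3 * se))
})

test_that("nested updating strategies have nonincreasing deviance", {
  for (seed in c(1, 13)) {
    co <- simulate_cohort(seed = seed)
    m <- asap_model()
    d <- c(evaluate_model(m, co)$deviance,
           recalibrate_in_the_large(m, co)$deviance,
           recalibrate(m, co)$deviance,
           revise(m, co)$deviance)
    expect_true(all(diff(d) <= 1e-8))
  }
})

test_that("likelihood ratio test handles edge cases and the chi-square tail", {
  f0 <- asapval:::new_risk_fit(asap_model(), 100, 500, 1L)
  f1 <- asapval:::new_risk_fit(asap_model(), 100, 500, 2L)
  eq <- likelihood_ratio_test(f0, f1)
  expect_equal(eq$chi_square, 0)
  expect_equal(eq$p_value, 1)
  f2 <- asapval:::new_risk_fit(asap_model(), 100 - 3.84, 500, 2L)
  lrt <- likelihood_ratio_test(f0, f2)
  expect_equal(lrt$df, 1L)
  expect_equal(lrt$p_value, 0.05, tolerance = 0.002)
  bad <- asapval:::new_risk_fit(asap_model(), 150, 500, 2L)
  expect_error(likelihood_ratio_test(bad, f0), "more free parameters")
  expect_error(likelihood_ratio_test(
    asapval:::new_risk_fit(asap_model(), 90, 500, 1L), f2), "negative")
})

test_that("closed test adopts in-the-large on a pure intercept shift", {
  m <- asap_model()
  co <- model_cohort(shift_intercept(m, -3.243), seed = 51)
  ct <- update_risk_model(m, co)
  expect_identical(ct$adopted, "in_the_large")
  # the first comparison (against the original) must be significant
  expect_true(ct$chain$significant[1])
  expect_false(ct$chain$significant[2])
  expect_identical(coef(ct), coef(ct$fits$in_the_large$model))
})

test_that("closed test adopts revision when covariate effects truly differ", {
  m <- asap_model()
  truth <- risk_model(-9, 0.09, -0.6, 0.1, 1.4)
  co <- model_cohort(truth, n_scale = 5, seed = 53)
  ct <- update_risk_model(m, co)
  expect_identical(ct$adopted, "revision")
})

test_that("closed test aborts with the failing stage named", {
  co <- simulate_cohort(seed = 55)
  co$hcc <- 0L
  expect_error(update_risk_model(asap_model(), co), "stage 'original'")
})

test_that("updated models re-validate as perfectly calibrated on their own data", {
  co <- simulate_cohort(seed = 57)
  m <- asap_model()
  y <- co$hcc
  for (fit in list(recalibrate_in_the_large(m, co), recalibrate(m, co),
                   revise(m, co))) {
    lp <- linear_predictor(fit$model, co)
    a <- calibration_intercept_slope(lp, y, "intercept_only")[["intercept"]]
    expect_lt(abs(a), 1e-6)
    if (fit$n_free >= 2L) {
      ab <- calibration_intercept_slope(lp, y, "intercept_slope")
      expect_lt(abs(ab[["intercept"]]), 1e-6)
      expect_lt(abs(ab[["slope"]] - 1), 1e-6)
    }
  }
})

test_that("AIC penalizes the revision when the LRT is non-significant", {
  m <- asap_model()
  co <- model_cohort(rescale_model(m, -3.5, 1.2), seed = 59)
  ct <- update_risk_model(m, co)
  s <- summary(ct)
  tab <- s$table
  i_rec <- match("recalibration", tab$strategy)
  i_rev <- match("revision", tab$strategy)
  if (!ct$chain$significant[3] && ct$adopted == "recalibration")
    expect_lt(tab$aic[i_rec], tab$aic[i_rev])
  # deviance/df bookkeeping follows df = n - free parameters
  expect_equal(tab$df, nrow(co) - c(0L, 1L, 2L, 5L))
})

test_that("bootstrap optimism shows overfitting direction and asymptotic limit", {
  m <- asap_model()
  big <- model_cohort(m, n_scale = 10, seed = 61)
  o_big <- bootstrap_optimism(big, reps = 50, seed = 62, model = m)
  expect_lt(abs(o_big$optimism), 0.01)
  expect_lt(abs(o_big$shrinkage - 1), 0.05)
  small <- model_cohort(m, n_scale = 0.1, seed = 63)
  o_small <- bootstrap_optimism(small, reps = 100, seed = 64, model = m)
  expect_lt(o_small$shrinkage, 1)
  expect_gt(o_small$optimism, 0)
  # determinism under a fixed seed
  o2 <- bootstrap_optimism(small, reps = 100, seed = 64, model = m)
  expect_identical(o_small, o2)
  expect_error(bootstrap_optimism(small, reps = 10), "reps >= 50")
})
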