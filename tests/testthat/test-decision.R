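test_that("confusion counts partition the cohort at any threshold", {
  p <- c(0.05, 0.2, 0.4, 0.9)
  y <- c(0, 0, 1, 1)
  expect_equal(confusion_at_threshold(p, y, 0.01),
               c(TP = 2L, FP = 2L, TN = 0L, FN = 0L))
  expect_equal(confusion_at_threshold(p, y, 0.95),
               c(TP = 0L, FP = 0L, TN = 2L, FN = 2L))
  # boundary is inclusive: the control sitting exactly at pt is positive
  expect_equal(confusion_at_threshold(p, y, 0.2)[["FP"]], 1L)
  expect_equal(confusion_at_threshold(p, y, 0.2)[["TN"]], 1L)
  expect_error(confusion_at_threshold(p, y, 0), "strictly")
})

test_that("classification statistics reproduce the published confusion rows", {
  # 1.3% threshold: 427 controls below, all 157 cases above
  s1 <- classification_stats(0.013,
                             counts = c(TP = 157, FP = 428, TN = 427, FN = 0))
  expect_equal(s1$sensitivity, 1)
  expect_equal(round(s1$specificity, 3), 0.499)
  expect_equal(round(s1$ppv, 3), 0.268)
  expect_equal(s1$npv, 1)
  expect_equal(round(s1$nb, 3), 0.150)
  # 50% threshold
  s2 <- classification_stats(0.5,
                             counts = c(TP = 131, FP = 7, TN = 848, FN = 26))
  expect_equal(s2$ppv, 131 / 138, tolerance = 1e-12)
  expect_equal(round(s2$nb, 3), 0.123)
  # 98.3% threshold: specificity and PPV of 1
  s3 <- classification_stats(0.983,
                             counts = c(TP = 79, FP = 0, TN = 855, FN = 78))
  expect_equal(s3$specificity, 1)
  expect_equal(s3$ppv, 1)
  expect_equal(round(s3$npv, 3), 0.916)
  expect_equal(round(s3$nb, 3), 0.078)
  # perfect classifier
  s4 <- classification_stats(0.5,
                             counts = c(TP = 10, FP = 0, TN = 90, FN = 0))
  expect_equal(unlist(s4[c("sensitivity", "specificity", "ppv", "npv")]),
               c(sensitivity = 1, specificity = 1, ppv = 1, npv = 1))
})

test_that("an empty predicted-positive set reports missing PPV with a warning", {
  expect_warning(
    s <- classification_stats(0.9,
                              counts = c(TP = 0, FP = 0, TN = 50, FN = 5)),
    "PPV")
  expect_true(is.na(s$ppv))
})

test_that("net benefit follows the threshold-odds weighting", {
  expect_equal(round(net_benefit(c(TP = 157, FP = 428), 1012, 0.013), 3),
               0.150)
  expect_equal(round(net_benefit(c(TP = 79, FP = 0), 1012, 0.983), 3),
               0.078)
  # with no false positives and a vanishing threshold, NB tends to TP/n
  expect_equal(net_benefit(c(TP = 79, FP = 0), 1012, 1e-6), 79 / 1012,
               tolerance = 1e-6)
})

test_that("bootstrap CIs of threshold statistics bracket the point estimate", {
  co <- simulate_cohort(seed = 71)
  p <- predict(asap_model(), co)
  s <- classification_stats(0.5, probs = p, labels = co$hcc,
                            boot_reps = 100, seed = 1)
  for (stat in c("sensitivity", "specificity", "ppv", "npv", "nb")) {
    expect_lte(s[[paste0(stat, "_lower")]], s[[stat]])
    expect_gte(s[[paste0(stat, "_upper")]], s[[stat]])
  }
})

test_that("sensitivity falls and specificity rises along the threshold grid", {
  co <- simulate_cohort(seed = 73)
  p <- predict(asap_model(), co)
  tr <- threshold_report(p, co$hcc, thresholds = seq(0.01, 0.99, 0.01))
  expect_true(all(diff(tr$sensitivity) <= 1e-12))
  expect_true(all(diff(tr$specificity) >= -1e-12))
})

test_that("decision curve has the exact treat-all and perfect-model geometry", {
  y <- rep(c(0, 1), c(80, 20))       # prevalence 0.2
  p_perfect <- ifelse(y == 1, 0.9, 0.05)
  dc <- decision_curve(p_perfect, y, grid = c(0.1, 0.2, 0.5, 0.8))
  expect_equal(dc$treat_none, rep(0, 4))
  # treat-all net benefit is algebraically zero at pt = prevalence
  expect_equal(dc$treat_all[dc$threshold == 0.2], 0, tolerance = 1e-12)
  # a perfect predictor attains NB = prevalence below the case probability
  expect_equal(dc$net_benefit[dc$threshold <= 0.8], rep(0.2, 4))
  # model NB at the prevalence threshold never exceeds the prevalence
  co <- simulate_cohort(seed = 75)
  p <- predict(asap_model(), co)
  prev <- mean(co$hcc)
  nb_at_prev <- net_benefit(confusion_at_threshold(p, co$hcc, prev),
                            nrow(co), prev)
  expect_lte(nb_at_prev, prev)
})

test_that("a well-calibrated informative model dominates treat-all", {
  m <- asap_model()
  co <- model_cohort(m, n_scale = 49, seed = 77)
  p <- predict(m, co)
  dc <- decision_curve(p, co$hcc)
  expect_true(all(dc$net_benefit >= dc$treat_all - 2e-3))
  expect_true(all(dc$net_benefit >= -2e-3))
})

test_that("two-threshold stratification reproduces the published split", {
  # probabilities placed to mirror the published 427/402/183 partition
  p <- c(runif(427, 0.001, 0.012),
         runif(402, 0.014, 0.15),
         runif(183, 0.16, 0.99))
  y <- c(rep(0, 427), rep(c(1, 0), c(15, 387)), rep(c(1, 0), c(142, 41)))
  st <- stratify(p, 0.013, 0.155, labels = y)
  expect_equal(st$table$n, c(427L, 402L, 183L))
  expect_equal(st$table$events, c(0L, 15L, 142L))
  expect_equal(round(100 * st$table$incidence, 1), c(0, 3.7, 77.6))
  rr_high <- st$rr[st$rr$group == "high", ]
  expect_equal(round(rr_high$rr, 1), 20.8)
  # a zero-event group has relative risk 0 against the reference
  expect_equal(relative_risk(0, 427, 15, 402)[["rr"]], 0)
  expect_error(stratify(p, 0.5, 0.5), "t_low < t_high")
  one <- stratify(rep(0.001, 10), 0.013, 0.155)
  expect_equal(sum(one$group == "low"), 10L)
})

test_that("relative risk matches its defining ratio with a log-normal CI", {
  rr <- relative_risk(142, 183, 15, 402)
  expect_equal(rr[["rr"]], (142 / 183) / (15 / 402), tolerance = 1e-12)
  expect_lt(rr[["lower"]], rr[["rr"]])
  expect_gt(rr[["upper"]], rr[["rr"]])
  expect_equal(relative_risk(5, 100, 5, 100)[["rr"]], 1)
  expect_equal(relative_risk(5, 100, 0, 100)[["rr"]], Inf)
})

test_that("proportion comparison agrees with the hand chi-square formula", {
  # identical proportions: continuity-corrected statistic is 0
  same <- compare_proportions(10, 100, 10, 100)
  expect_equal(same$p_value, 1)
  # hand Yates chi-square on the 2x2 table 122/782 vs 35/230
  x11 <- 122; x12 <- 782 - 122; x21 <- 35; x22 <- 230 - 35; n <- 1012
  hand <- n * (abs(x11 * x22 - x12 * x21) - n / 2)^2 /
    ((x11 + x12) * (x21 + x22) * (x11 + x21) * (x12 + x22))
  ht <- compare_proportions(122, 782, 35, 230)
  expect_equal(ht$chi_square, hand, tolerance = 1e-9)
  expect_equal(ht$p_value, pchisq(hand, 1, lower.tail = FALSE),
               tolerance = 1e-9)
  expect_equal(round(ht$p_value, 2), 0.97)
  # large effects are detected
  expect_lt(compare_proportions(50, 100, 5, 100)$p_value, 0.001)
  expect_error(compare_proportions(0, 50, 0, 60), "margin")
})

test_that("the Youden cutoff maximizes sensitivity plus specificity", {
  p <- c(0.1, 0.2, 0.3, 0.6, 0.7, 0.8)
  y <- c(0, 0, 0, 1, 1, 1)
  expect_equal(youden_cutoff(p, y), 0.6)
})
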