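---
title: "Methods: external validation and updating of the ASAP HCC risk model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: external validation and updating of the ASAP HCC risk model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asapval)
```

## The problem

Hepatocellular carcinoma (HCC) surveillance programmes need a way to
turn routinely measured serum markers into an individual risk of
prevalent HCC. The ASAP model does this with a logistic regression on
age (years), sex (0 = male, 1 = female), alpha-fetoprotein (AFP, ng/mL)
and PIVKA-II (mAU/mL):

$$\mathrm{logit}\,P(\mathrm{HCC}) = \beta_0 + \beta_{age}\,age +
\beta_{sex}\,sex + \beta_{AFP}\ln(AFP) + \beta_{PIVKA}\ln(\mathrm{PIVKA\text{-}II}).$$

A model transported to a new population and clinical setting usually
keeps its discrimination but loses calibration — in particular when the
outcome prevalence differs strongly between development and deployment.
This package implements the full repair workflow: quantify the
miscalibration, update the model as little as the data demand, and
re-examine its clinical usefulness.

Both markers enter on the **natural** logarithm. This deserves emphasis
because "log" is ambiguous in clinical reporting: we use natural logs
throughout, which is the only reading under which the published
coefficient magnitudes and the subgroup summary levels (e.g.
$e^{8.47} \approx 4{,}770$ mAU/mL of PIVKA-II in HCC patients) are
clinically sensible.

## Validation metrics

* **C-statistic.** The probability that a random case outranks a random
  control, ties credited 0.5; computed by the Wilcoxon rank identity and
  tested against an exhaustive $O(n^2)$ pair enumeration. It is
  invariant under strictly increasing transforms of the score, so the
  original, intercept-shifted and rescaled linear predictors share one
  C-statistic exactly.
* **Calibration intercept and slope.** Logistic regressions of the
  outcome on the linear predictor (LP): intercept-only with LP as an
  offset (coefficient fixed at 1), or intercept + slope. A perfectly
  calibrated model gives $(0, 1)$. These are maximum-likelihood fits via
  iteratively reweighted least squares with a deviance tolerance of
  $10^{-12}$ and at most 100 iterations — tight enough that re-validating
  an updated model on its own fitting data returns an intercept of 0
  within $10^{-6}$, which the tests assert.
* **Calibration curve, Emax, Eavg.** A loess (degree 1, span 0.75)
  smooth of the outcome against the predicted probability, evaluated at
  each observed prediction; Emax/Eavg are the maximum/mean absolute
  differences between predicted and smoothed-observed probabilities. The
  span is a free parameter: the reference analysis names only the
  algorithm, and 0.75 is the conventional default. Smoothed values are
  clipped to $[0,1]$.
* **Brier score, deviance, AIC.** The Brier score is the mean squared
  probability error. A fixed (external) model has zero free parameters,
  so its AIC equals its residual deviance; updated models pay $2k$ for
  $k \in \{1, 2, 5\}$ estimated parameters, and degrees of freedom are
  $n - k$. Probabilities are clipped to $[10^{-12}, 1-10^{-12}]$ before
  any log-likelihood so extreme predictions cannot produce infinities.
* **Bootstrap intervals.** Percentile intervals (2.5/97.5) from
  resampling stratified by outcome class, which preserves the case mix
  of every replicate; 2000 replicates reproduce the reference analysis.
  Percentile rather than BCa because nothing in the source analysis
  indicates acceleration corrections; degenerate replicates (a failing
  statistic) are redrawn and counted.

## Model updating and the closed test

Three nested updates of a model with linear predictor $LP$:

1. **Recalibration-in-the-large** — fit $\mathrm{logit}(p) = a + LP$
   (offset): one free parameter; the returned model is the original with
   $a$ added to its intercept.
2. **Logistic recalibration** — fit $\mathrm{logit}(p) = a + b\,LP$: two
   free parameters; the returned coefficients are exactly $b$ times the
   originals with intercept $b\beta_0 + a$, an identity the tests check
   to machine precision.
3. **Model revision** — refit all five parameters.

The **closed testing procedure** compares the revision against the
original (5 df), the in-the-large update (4 df) and the recalibration
(3 df) by likelihood-ratio tests, in that order, and adopts the first
model not rejected at $\alpha = 0.05$. A p-value exactly at $\alpha$
counts as non-significant (the tie favours the simpler model). Because
the fits share one IRLS engine and tolerance, the LRT statistics are
differences of converged deviances; a negative difference beyond
$10^{-8}$ aborts with an error rather than being silently clamped.
Separation in the revision (a coefficient escaping to $\pm\infty$) is
detected and reported with the offending covariate.

**Optimism correction** uses Harrell's bootstrap: refit the revision on
each resample, compare its apparent C on the resample with its C on the
original cohort, and subtract the mean difference from the full-data
apparent C; the shrinkage factor is the mean calibration slope of the
bootstrap models' predictors on the original data. The default of 200
replicates balances Monte-Carlo error against cost and is configurable;
the source analysis does not state a count.

## Clinical utility

A positive call is $p \ge p_t$ (boundary inclusive — the convention
under which the published 1.3%-threshold row, with all 157 cases and 428
of 855 controls called positive, is representable). Net benefit weighs
false positives by the threshold odds:

$$NB(p_t) = \frac{TP}{n} - \frac{FP}{n}\cdot\frac{p_t}{1-p_t},$$

and decision curves trace it over $p_t \in \{0.01, \dots, 0.99\}$
against treat-all, $\pi - (1-\pi)\,p_t/(1-p_t)$, and treat-none (0).
The seven preset thresholds are 1.3% (median predicted probability of
the non-HCC patients), 13.1% (Youden-index optimal cutoff — the source
labels but never defines "optimal", and the Youden maximizer is the
standard reading), 15.5% (cohort incidence), 1/3 and 2/3 (the
development-time decision thresholds), 50%, and 98.3% (median predicted
probability of HCC patients).

Risk stratification uses two thresholds: low ($p < t_{low}$), medium
($t_{low} \le p \le t_{high}$), high ($p > t_{high}$), defaults 1.3% and
15.5%. Relative risks against the medium (reference) group carry Katz
log-normal intervals; group incidence comparisons use the
Yates-corrected Pearson chi-square. Follow-up of the at-risk (non-HCC)
patients uses the Kaplan–Meier product-limit estimator (all events at a
distinct time processed together) and the log-rank test with
$k - 1$ df; pairwise group comparisons are reported without multiplicity
adjustment, matching how such pairwise values are conventionally
displayed alongside the omnibus test.

## Nomogram score tables

The standard 0–100-point construction: each covariate's contribution
$\beta_j z_j$ over its configured range is mapped linearly to points,
anchored at the range endpoint minimizing the contribution (0 points),
and scaled so the covariate with the widest contribution spans exactly
100. Total points map back to probability through the logistic, making
`score_to_probability(score_points(x))` algebraically identical to the
model probability — asserted to $10^{-9}$ over 1000 random patients. A
zero-width contribution on the widest covariate is an error. Markers are
tabulated in native units but scored on their log scale. No graphical
nomogram is drawn; the tables are the deliverable.

## The synthetic cohort generator

The validation cohort itself is not publicly deposited, so the package
generates cohorts with its statistical skeleton:

| subgroup | n | age mean (SD) | male | log AFP mean (SD) | log PIVKA-II mean (SD) |
|---|---|---|---|---|---|
| hepatitis | 451 | 50.7 (9.4) | 76.5% | 1.46 (1.09) | 3.14 (0.58) |
| cirrhosis | 308 | 58.1 (10.7) | 66.9% | 1.70 (1.32) | 3.33 (1.00) |
| benign SOL | 96 | 58.5 (12.4) | 60.4% | 1.87 (1.55) | 3.54 (1.08) |
| HCC | 157 | 59.6 (12.0) | 84.7% | 5.94 (3.85) | 8.47 (2.56) |

Ages are normal truncated below at 35 years (the surveillance entry
criterion), drawn by inverse-CDF so the random stream length is
deterministic. Markers are jointly log-normal within subgroup with a
configurable log-scale correlation, default 0.3 — the source reports
marginals only, so any dependence is an assumption; covariances between
age, sex and markers are likewise not modelled. HCC status is 1 exactly
for the HCC subgroup (diagnosis defines the subgroup). One integer seed
drives a single documented pseudo-random stream per operation.

Follow-up is exponential per risk group. The default hazards are
back-calculated once from target 18-month cumulative incidences of
0.9%, 5.8% and 22.2% in the low/medium/high groups via
$h = -\ln(1-F)/18$, with 18.8% loss to follow-up (censored uniformly
before the horizon) and a 24-month administrative horizon. These hazards
are free parameters chosen to make the group ordering realistic, not
estimates.

**What passing tests do and do not show.** The generator reproduces
subgroup sizes, marginal moments and prevalence, so tests against it
validate the *estimators* (recovery of known truths, invariances, error
control), and the qualitative transportability phenomenon — strong
discrimination with prevalence-driven overestimation — emerges from the
case mix alone. It does not reproduce the empirical joint distribution
of a real cohort: tails beyond the log-normal, covariate-marker
dependence, etiology structure and staggered study entry are absent. In
particular the observed median follow-up of a real staggered-entry study
is not reproduced by the loss/horizon censoring mechanism, and
behaviour at extreme probability thresholds (above ~0.95) is dominated
by a handful of simulated tail patients. Conclusions about a real
population require the real data through `read_cohort()`.

## Numerical choices and test scale

* IRLS: deviance tolerance $10^{-12}$, max 100 iterations, shared by all
  fits so LRT chains are valid.
* Probability clipping $10^{-12}$; LRT negativity tolerance $10^{-8}$;
  nomogram round-trip tolerance $10^{-9}$.
* Confidence level 95% everywhere.
* Simulation sizes in the test suite are package choices balancing
  Monte-Carlo error against runtime: coefficient recovery on cohorts of
  ~50,000; loess calibration-curve consistency at 20,000 (loess is the
  one superlinear step); closed-test null behaviour over 200 cohorts of
  1012; LRT type-I error over 500 replicates; bootstrap coverage over
  500 simulations of $n = 200$.
* Monte-Carlo assertions use 3-standard-error bands around the known
  truth, or binomial-sampling bands around nominal rates.

## Known limitations

* Binary-outcome validation only: no time-dependent C-index, Cox
  modelling, competing risks or interval censoring.
* No penalized or Firth fitting: perfectly separable cohorts error out
  rather than being shrunk.
* Brier scores are reported descriptively and not formally compared;
  only likelihood-ratio comparisons are implemented.
* The relative-risk interval is the Katz construction; other variance
  choices exist and give slightly different bounds.
* Etiology subsets are supported through the `subset` argument of
  `threshold_report()` and passthrough cohort columns, but the generator
  does not simulate etiology-specific marker distributions.
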