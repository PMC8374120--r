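Package: asapval
Title: External Validation and Updating of the ASAP Hepatocellular
    Carcinoma Risk Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for externally validating and updating the ASAP
    logistic risk model for hepatocellular carcinoma (age, sex,
    alpha-fetoprotein, PIVKA-II). Implements linear-predictor evaluation,
    discrimination (C-statistic), overall performance (Brier score),
    loess-based calibration curves with Emax/Eavg, three logistic
    updating strategies (recalibration-in-the-large, logistic
    recalibration, model revision) selected by a closed testing
    procedure, bootstrap optimism correction, decision curve analysis
    and net benefit at clinical thresholds, two-threshold risk
    stratification with relative risks, Kaplan-Meier follow-up analysis
    with log-rank tests, nomogram score tables, and a synthetic cohort
    generator emulating a surveillance case mix for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
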