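Package: rpntcp
Title: Validation and Updating of NTCP Models for Radiation Pneumonitis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for external validation and updating of logistic normal
    tissue complication probability (NTCP) models for grade >=2 radiation
    pneumonitis after thoracic radiotherapy. Ships a registry of published
    risk models (QUANTEC, Appelt, and locally updated variants) with fixed
    coefficients, a closed-testing model-updating ladder (intercept
    recalibration, full logistic recalibration, model revision, and
    BIC-guided simplification with ridge or lasso shrinkage), a full
    discrimination and calibration suite (AUC with bootstrap intervals,
    Brier score, calibration-in-the-large, calibration slope,
    Hosmer-Lemeshow statistics, Nagelkerke R-squared), decision curve
    analysis, bootstrap optimism correction, and a synthetic cohort
    generator that reproduces the marginal structure of a contemporary
    IMRT lung-cancer cohort so that every pipeline stage is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    jsonlite,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
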