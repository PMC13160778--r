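# rpntcp

Validation and updating of logistic NTCP (normal tissue complication
probability) models for grade ≥2 radiation pneumonitis (RP) after thoracic
radiotherapy.

Published RP risk models — the MLD-only QUANTEC model, the multifactorial
Appelt model — were derived in the 3D-conformal era. Applied to contemporary
IMRT cohorts they usually still *rank* patients sensibly but misestimate
*absolute* risk. `rpntcp` is for the analyst who has a local cohort (a CSV of
demographics, smoking, comorbidity, stage, hematology, DVH metrics and RP
grades) and needs to answer, reproducibly: how miscalibrated is the published
model here, what is the least extensive update that fixes it, and does a
locally refit model transport to another center?

## What it implements

All models are fixed-coefficient logistic models
`NTCP = [1 + exp(−LP)]⁻¹`, `LP = β₀ + Σ βⱼxⱼ`, shipped as data in
`model_registry()` (QUANTEC original/recalibrated/final, Appelt
original/A/B, an MLD-only simplified model, and a final simplified local
model using age, stage, smoking, tumor location, pulmonary comorbidity,
NLR, SII, V30 and MLD). Around them:

* **Validation panel** (`validate_model()`): Mann–Whitney AUC with
  percentile-bootstrap CI, Brier score, LL/AIC/BIC/Nagelkerke R²,
  calibration-in-the-large (CITL) and calibration slope (two separate
  maximum-likelihood logistic fits on the logit scale), Hosmer–Lemeshow on
  quantile bins with duplicate cut-points dropped and an explicit df
  policy, binned calibration curves.
* **Closed-testing update ladder** (`closed_test()`,
  `recalibrate_intercept()`, `recalibrate()`, `revise()`): likelihood-ratio
  tests select the least extensive update — none → intercept →
  intercept+slope → full revision — with the complete test trace returned.
  Ridge/lasso re-estimation via glmnet; `bic_simplify()` does deterministic
  backward elimination under BIC; `rcs_nonlinearity_check()` tests
  linearity with restricted cubic splines.
* **Decision curve analysis** (`net_benefit()`, `decision_curve()`):
  `TP/n − (FP/n)·t/(1−t)` against treat-all and treat-none over a threshold
  grid.
* **Validation protocols** (`bootstrap_optimism()`, `external_validate()`):
  Harrell optimism correction with a fixed predictor set; locked-coefficient
  external validation with small-cohort calibration presets.
* **Synthetic cohorts** (`synthetic_config()`, `generate_cohort()`,
  `make_center_pair()`): seeded cohorts reproducing the baseline-table
  structure of a contemporary IMRT lung-cancer cohort (including the
  MLD–V30 rank correlation 0.768 via a Gaussian copula and a ~30.7% event
  rate), with a configurable true model and injectable calibration drift —
  so every stage above is testable with known ground truth.

See `vignettes/ntcp-model-updating.Rmd` for the methods account.

## Worked example

```r
library(rpntcp)
reg <- model_registry()

# The classic benchmark: QUANTEC risk at a mean lung dose of 20 Gy
predict_risk(reg$quantec_original, data.frame(MLD = 20))
#> [1] 0.2058704        # i.e. ~20% grade >=2 RP risk

# A seeded synthetic development cohort
cohort <- generate_cohort(synthetic_config(n = 580, seed = 11), label = "demo")
cohort
#> <rp_cohort> demo - 580 patients, 191 events (32.9%)

# How does the original QUANTEC model do here?
validate_model(reg$quantec_original, cohort)
#> <validation_report> quantec_original on demo
#>   n = 580, events = 191 (32.9%)
#>   AUC = 0.744
#>   Brier = 0.272, Nagelkerke R2 = -0.729
#>   LL = -489.63, AIC = 983.26, BIC = 991.98 (k = 2)
#>   CITL = 1.867, slope = 1.868
#>   Hosmer-Lemeshow chi2 = 567.424 (df = 8, p = 2.35e-117, 10 groups)
```

Ranking is fine (AUC 0.74) but the model badly underestimates absolute risk
(CITL 1.87 — observed logits sit almost two units above predictions, hence
the enormous Hosmer–Lemeshow statistic and a negative Nagelkerke R² of the
fixed-coefficient predictions against the null). The closed test says how
much updating that requires:

```r
closed_test(reg$quantec_original, cohort)
#> <update_result> selected level: intercept_slope (alpha = 0.05)
#>                    comparison        lr df            p
#>             intercept vs none 323.73563  1 2.224406e-72
#>  intercept_slope vs intercept  19.00404  1 1.304420e-05
#>   revision vs intercept_slope   0.00000  0 1.000000e+00
```

Both the intercept and the slope need re-estimation (for a one-term model,
"revision" coincides with full recalibration, hence the df-0 last row).
The recalibrated model is returned with the update folded into its
coefficients:

```r
closed_test(reg$quantec_original, cohort)$models$intercept_slope
#> <risk_model> quantec_original_recal
#>   intercept: -3.178768
#>   terms:
#>      MLD = 0.2353756
```

A tiny example cohort CSV (synthetic, generated by this package) is at
`inst/extdata/example_cohort_synthetic.csv` for trying `read_cohort()` and
the command-line interface (`exec/rpntcp`, subcommands `simulate`,
`predict`, `summarize`, `validate`, `update`, `dca`, `report`).

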