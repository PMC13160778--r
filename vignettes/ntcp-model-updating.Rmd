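---
title: "Validating and updating NTCP models for radiation pneumonitis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating and updating NTCP models for radiation pneumonitis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpntcp)
```

## The modelling problem

Grade ≥2 radiation pneumonitis (RP) is the dose-limiting toxicity of
thoracic radiotherapy. Normal tissue complication probability (NTCP) models
predict a patient's RP risk from the lung dose–volume histogram and clinical
covariates, typically as a logistic model

$$\mathrm{NTCP} = \left[1 + \exp(-\mathrm{LP})\right]^{-1}, \qquad
\mathrm{LP} = \beta_0 + \textstyle\sum_j \beta_j x_j .$$

Models of this family were mostly derived in the 3D-conformal era. Applied
to contemporary IMRT cohorts treated with multimodal therapy they often
*rank* patients adequately but systematically misestimate *absolute* risk:
discrimination transfers, calibration does not. The practical questions this
package addresses are therefore:

1. How miscalibrated is a published, fixed-coefficient model on a local
   cohort (validation)?
2. What is the *least extensive* update that fixes it — a new intercept, a
   full logistic recalibration, or re-estimation of every coefficient
   (closed-testing model updating)?
3. Is a simplified locally refit model worth it, and does it transport to an
   independent center (BIC-guided simplification, bootstrap internal
   validation, fixed-coefficient external validation, decision curves)?

The package ships eight fixed-coefficient models in `model_registry()`: the
MLD-only QUANTEC model and its two local updates, the multifactorial Appelt
model and its intercept-/fully-recalibrated variants, the MLD-only
BIC-simplified model, and a final simplified local model combining age,
stage, smoking, tumor location, pulmonary comorbidity, the inflammatory
markers NLR and SII, and the dosimetric pair MLD + V30. Coefficients are
data, not fit objects; applying a model never modifies it.

## Covariate coding

The cohort encoder emits canonical term names so every registry model sees
exactly the covariates it was published with: `MLD` (Gy, physical dose,
total bilateral lung), `V30` (% lung volume ≥30 Gy), `NLR` =
neutrophils/lymphocytes, `SII` = platelets × neutrophils / lymphocytes,
`age` (years, continuous), `stage` (numeric 1–4), `comorbidity` (binary
pulmonary comorbidity), the smoking indicator pair
`smoke_former`/`smoke_current` (never smoker as reference), `old_age`,
`seq_chemo`, and `loc_midinf`.

Three encodings are deliberately configurable because the source models do
not pin them down:

* **`old_age` cutoff** (default 63 years). The multifactorial model uses a
  binary "old age" indicator whose cutoff is not printed; 63 is close to
  the cohort median age and is exposed as `age_cutoff=`. This is a package
  decision, not a published fact.
* **`loc_midinf` mapping** (default levels {1, 2} of the three-level
  `location3` coding). The three-level site coding is institution-specific;
  the binary mid/inferior indicator is derived through `midinf_levels=`.
* **`seq_chemo`**. The published term means *sequential* (non-concurrent)
  chemotherapy. Cohort files that carry a `chemo_concurrent` phase flag get
  `chemo == 1 & chemo_concurrent == 0`; files with only a bare `chemo` flag
  fall back to it, which over-counts concurrent patients and is documented
  here as the price of a minimal schema.

The final simplified local model is shipped on **raw covariate scales**
exactly as printed. Its source pipeline standardized "where appropriate"
without printing the scalings, so identity transforms are the only reading
fully determined by the published equation; the model-spec JSON format lets
a user attach `center`/`scale` transforms without touching coefficients.
One consequence is visible in the registry itself: at raw scale the printed
intercept is hard to reconcile with a ~30% event rate at cohort-mean
covariates, which is why the synthetic generator re-tunes the intercept (see
below) rather than trusting it.

## Validation metrics

`validate_model()` computes the full panel from predictions and outcomes:

* **AUC** in Mann–Whitney midrank form, exactly invariant under any
  strictly increasing transform of the predictions — hence provably
  unchanged by recalibration. Percentile bootstrap CIs resample patients;
  single-class resamples are redrawn and counted.
* **Brier score**, mean squared error of the predicted probability.
* **Log-likelihood, AIC, BIC, Nagelkerke R²** with an explicit parameter
  count `k`. At external validation no parameter is estimated, so `k` is a
  bookkeeping convention (term count + 1) kept for table continuity.
* **Calibration-in-the-large (CITL)** — intercept of a logistic fit of the
  outcome on the model's logit as a *fixed offset* — and **calibration
  slope** — coefficient of a free-intercept logistic refit. These are two
  separate maximum-likelihood fits, the dominant convention; the free fit's
  intercept is also reported because the two intercept definitions differ
  whenever the slope is not 1. Probabilities are clipped at `1e-12` before
  the logit, with a message when clipping actually occurs.
* **Hosmer–Lemeshow** on quantile bins (default deciles) with duplicate
  cut-points dropped. Because the appropriate degrees of freedom depend on
  whether the model was fit to the evaluated data, the df policy is an
  explicit argument: `groups - 2` for development data, `groups` for
  external data. Right-closed bins on unique quantile edges define the
  grouping; the same binning drives `calibration_curve()` (default 10
  groups, 4 for small external cohorts).

## The closed-testing update ladder

`closed_test()` fits four nested levels — original model, intercept
recalibration (`recalibrate_intercept()`), full logistic recalibration
(`recalibrate()`), and full revision (`revise()`) — and walks up the ladder
by likelihood-ratio tests at `alpha = 0.05`: intercept vs none (df 1),
slope vs intercept (df 1), revision vs slope (df = number of terms − 1).
The selected level is the last rung whose entry test rejected; the full
trace is returned so alternative orderings can be audited. Two structural
notes:

* For a single-term model, revision and full recalibration coincide; the
  third test has df 0 and the ladder can never select "revision".
* Full recalibration folds the fitted `(a, b)` back into the coefficient
  vector (`intercept = a + b\beta_0`, `terms = b\beta`), so the updated model's
  predictions equal `plogis(a + b·LP)` bit-exactly, and every updated
  coefficient is the original times the calibration slope — the identity
  the shipped recalibrated-model coefficients satisfy to the printed
  precision.

Inside `closed_test()` the revision rung is fit tolerantly (aliased columns
get coefficient 0, quasi-separated fits are kept at the iteration cap) so
the likelihood comparison always exists; the standalone `revise()` is
strict and errors on separation with advice to use ridge.

`revise()` supports ridge and lasso shrinkage through glmnet: covariates
are standardized internally, coefficients reported on the input scale, the
intercept unpenalized, and the penalty chosen by 10-fold cross-validated
deviance on a logarithmic grid (25 points, 1e-4–1e2), seed-controlled
because no published value of the penalty exists. Likelihood criteria on
penalized fits are ill-defined, so the lasso offers a relaxed refit of the
selected support, and `bic_simplify()` — deterministic backward elimination
dropping at each step the term whose removal lowers BIC most, ties broken
in canonical term order, forced terms never dropped — always works on
unpenalized refits. Collinearity between MLD and V30 (rank correlation
0.77) is left to the BIC criterion itself: both survive only if their joint
inclusion improves fit; no variance-inflation cutoff is imposed.

`rcs_nonlinearity_check()` tests departures from linearity (age being the
motivating covariate) with a restricted cubic spline at quantile knots
(3 knots at 0.1/0.5/0.9 by default; 4 and 5 follow the standard
placements), comparing spline vs linear fits by likelihood ratio; a 3-knot
basis adds exactly one term.

## Decision curves

`net_benefit()` uses the counting definition
$\mathrm{TP}/n - (\mathrm{FP}/n)\, t/(1-t)$ with the classification rule
`pred >= t` (closed on the left — stated explicitly because boundary
patients move small-cohort curves). `decision_curve()` scans a default grid
0.01–0.50 in steps of 0.01, covering the low-to-intermediate thresholds at
which intensified RP management is plausible, and reports the threshold
range where the model beats both treat-all and treat-none. Curves are raw
step values; smoothing is presentation, not statistics.

## Internal and external validation protocols

`bootstrap_optimism()` implements the optimism bootstrap with the predictor
set held fixed: refit in each resample of the original size, evaluate in
the resample and in the original cohort, subtract the mean difference from
apparent performance. Optimism is computed for the AUC and, as labelled
extensions, the Brier score and calibration slope. Failed resamples are
skipped (not redrawn) to keep the resample plan seed-reproducible; more
than 5% failures aborts. One honest caveat established by simulation with
this package's own generator: under extreme overfitting (ten pure-noise
predictors at n = 100) the corrected AUC comes back near 0.55 rather than
0.50 — the bootstrap "population" is the original sample, which the
resample model partially memorizes — so corrected performance under severe
p/n should be read as an upper bound.

`external_validate()` applies a locked model to an independent cohort with
the external df policy, 4 calibration groups by default, and patient-level
bootstrap for the AUC CI. The transportability logic is testable end to
end: `make_center_pair()` draws a development and an external cohort from
one shared true model with an injected drift `(delta0, delta1)` on the
linear predictor, and the external CITL/slope estimates recover the
injected drift within Monte-Carlo error.

## The synthetic cohort generator

`synthetic_config()` encodes the study conditions the package is tested
under; `generate_cohort()` draws from them. Defaults reproduce the
development-cohort baseline table of a contemporary IMRT lung-cancer
population: age 63.23 ± 9.61 years on [24, 86]; MLD 9.90 ± 4.14 Gy (> 0);
V30 with mean 15.97 and SD 18.72% — an SD above the mean, so the marginal
is log-normal, truncated at 100; NLR 4.28 ± 4.61 and SII 956 ± 1604 as
moment-matched log-normals; smoking 1.4/63.1/35.5% current/former/never;
comorbidity 47.9%; stage 4.0/3.4/39.1/53.4%; chemotherapy 74.0% (49.2% of
treated concurrently); immunotherapy 52.4%; event rate 30.7%.

Numerical choices worth knowing:

* **Truncation is moment-matched.** Parent parameters of every truncated
  marginal are solved (closed-form truncated moments, Nelder–Mead) so the
  *truncated* distribution hits the configured mean and SD; naive
  truncation would bias MLD by +0.1 Gy and V30 by −0.9%.
* **Dependence.** Only the MLD–V30 pair is linked, through a Gaussian
  copula with latent correlation `2·sin(π·ρ_S/6)` calibrated to Spearman
  ρ = 0.768 — the only dependence quantified in the source material. All
  other covariates are drawn independently; real cohorts are not like
  this (age, stage, smoking and dose metrics co-vary), so passing tests
  demonstrate correctness of the *methods*, not realism of the joint
  distribution.
* **Hematology identities.** Lymphocytes are log-normal; neutrophils and
  platelets are derived as `NLR × L` and `SII / NLR`, so the NLR and SII
  definitions hold exactly on every record. The platelet marginal is
  implied rather than matched — a stated simplification.
* **Outcome process.** Events are Bernoulli with probability
  `plogis(delta0 + delta1 · LP)` where LP comes from a configurable true
  model (default: the final simplified local model). Because that model's
  raw-scale intercept does not reproduce a 30.7% event rate, the intercept
  is re-tuned by root finding on the generated cohort's linear predictors
  *before* drift is applied; the tuned true model is attached to the cohort
  so recovery experiments have exact ground truth. V5 and V20 are monotone
  functions of MLD plus noise, bounded to [0, 100]; no shipped model uses
  them. Event grades default to 2; an optional mixture (69.1% II, 24.2%
  III, 6.2% IV, 0.6% V) serves summary-table tests.
* **Determinism.** The seed fully determines the cohort; covariates are
  drawn in a fixed order and intercept tuning consumes no randomness.

## Problem sizes and test design

The package's own simulation studies use sizes chosen to bound Monte-Carlo
error while staying desk-scale: marginal-moment checks at n = 10⁵;
recalibration and drift recovery at n = 20,000 and n = 5,000 with
assertions at 3 estimated standard errors; unpenalized-revision recovery
at n = 50,000; closed-testing operating characteristics at n = 2,000 over
1,000 replicates (type-I band 0.03–0.07 at α = 0.05) plus 100 replicates
under a one-logit intercept shift; optimism experiments at B = 150–200
resamples, averaged over replicated n = 100 noise cohorts because single
draws of the corrected AUC have a spread of ±0.1.

## Limitations

* Independence of clinical covariates and the single copula link make the
  generator a statistical emulation, not a digital twin; effect sizes
  estimated on it transfer only as far as a logistic truth with those
  marginals is plausible.
* The shipped final local model's raw-scale reading (no hidden
  standardization) is a documented interpretation; users with the original
  scalings can attach transforms in the model-spec JSON.
* Degrees of freedom for Hosmer–Lemeshow and the CITL/slope estimation
  convention are parameterized rather than guessed, because neither is
  universal across published implementations; comparisons against external
  software should pin both.
* The optimism bootstrap's residual bias under extreme overfitting (above)
  is a property of the estimator, not of this implementation.
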