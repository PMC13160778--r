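# Closed-testing update ladder, re-estimation, BIC simplification, splines.

test_that("intercept recalibration changes only the intercept and recovers shifts", {
  reg <- model_registry()
  cfg <- synthetic_config(n = 20000, seed = 101, true_model = reg$appelt_original,
                          target_prevalence = 0.307, delta0 = 1.0, delta1 = 1)
  co <- generate_cohort(cfg)
  truth <- attr(co, "true_model") # prevalence-tuned Appelt

  up <- recalibrate_intercept(truth, co)
  expect_identical(up$terms, truth$terms) # bit-exact contract
  shift_hat <- up$intercept - truth$intercept
  lp <- linear_predictor(truth, encode_for_model(co, truth))
  se <- summary(glm(co$event ~ 1 + offset(lp), family = binomial()))$coefficients[1, 2]
  expect_lt(abs(shift_hat - 1.0), 3 * se)

  # already-calibrated model is a fixed point
  cfg0 <- synthetic_config(n = 20000, seed = 102, true_model = reg$appelt_original,
                           target_prevalence = 0.307)
  co0 <- generate_cohort(cfg0)
  truth0 <- attr(co0, "true_model")
  up0 <- recalibrate_intercept(truth0, co0)
  expect_lt(abs(up0$intercept - truth0$intercept), 0.1)
})

test_that("full recalibration scales every coefficient by the fitted slope", {
  reg <- model_registry()
  co <- small_synth(n = 2000, seed = 103)
  rec <- recalibrate(reg$appelt_original, co)
  b <- attr(rec, "calibration_slope")
  a <- attr(rec, "calibration_intercept")
  expect_equal(rec$terms, b * reg$appelt_original$terms, tolerance = 1e-12)
  expect_equal(rec$intercept, a + b * reg$appelt_original$intercept,
               tolerance = 1e-12)
  # recalibration is monotone: AUC is untouched
  enc <- encode_for_model(co, reg$appelt_original)
  expect_identical(auc_mw(predict_risk(reg$appelt_original, enc), co$event),
                   auc_mw(predict_risk(rec, enc), co$event))
})

test_that("recalibration recovers injected intercept and slope drift", {
  reg <- model_registry()
  cfg <- synthetic_config(n = 20000, seed = 104, true_model = reg$appelt_original,
                          target_prevalence = 0.307, delta0 = 1.0, delta1 = 0.6)
  co <- generate_cohort(cfg)
  truth <- attr(co, "true_model")
  rec <- recalibrate(truth, co)
  lp <- linear_predictor(truth, encode_for_model(co, truth))
  ses <- summary(glm(co$event ~ lp, family = binomial()))$coefficients[, 2]
  expect_lt(abs(attr(rec, "calibration_intercept") - 1.0), 3 * ses[1])
  expect_lt(abs(attr(rec, "calibration_slope") - 0.6), 3 * ses[2])

  # identity process returns approximately the original model
  cfg1 <- synthetic_config(n = 20000, seed = 105, true_model = reg$appelt_original,
                           target_prevalence = 0.307)
  co1 <- generate_cohort(cfg1)
  truth1 <- attr(co1, "true_model")
  rec1 <- recalibrate(truth1, co1)
  expect_lt(abs(attr(rec1, "calibration_slope") - 1), 0.1)
  expect_equal(rec1$terms, truth1$terms, tolerance = 0.12)
})

test_that("unpenalized revision recovers generating coefficients", {
  reg <- model_registry()
  cfg <- synthetic_config(n = 50000, seed = 106, true_model = reg$appelt_original,
                          target_prevalence = 0.307)
  co <- generate_cohort(cfg)
  truth <- attr(co, "true_model")
  fit <- revise(names(truth$terms), co, penalty = "none")
  # compare against glm standard errors on the same design
  enc <- encode_covariates(as.data.frame(co))
  g <- glm(co$event ~ ., family = binomial(),
           data = enc[names(truth$terms)])
  ses <- summary(g)$coefficients[, 2]
  for (tm in names(truth$terms)) {
    expect_lt(abs(fit$terms[[tm]] - truth$terms[[tm]]), 3 * ses[[tm]])
  }
})

test_that("ridge shrinkage has the correct limits", {
  co <- small_synth(n = 1500, seed = 107)
  terms <- c("MLD", "age", "NLR")
  mle <- revise(terms, co, penalty = "none")
  tiny <- revise(terms, co, penalty = "ridge", lambda_grid = c(1e-6, 1e-5), seed = 1)
  expect_equal(tiny$terms[terms], mle$terms[terms], tolerance = 0.05)
  huge <- revise(terms, co, penalty = "ridge", lambda_grid = c(1e4, 1e5), seed = 1)
  expect_lt(max(abs(huge$terms)), 0.01)
  expect_equal(huge$intercept, qlogis(mean(co$event)), tolerance = 0.05)
  expect_error(revise(terms, co, penalty = "ridge"), "seed")
})

test_that("lasso with relaxation refits the selected support unpenalized", {
  co <- small_synth(n = 2000, seed = 108)
  fit <- revise(c("MLD", "age", "NLR", "SII", "V30"), co, penalty = "lasso",
                seed = 2, relax = TRUE)
  refit <- revise(names(fit$terms), co, penalty = "none")
  expect_equal(fit$terms, refit$terms, tolerance = 1e-8)
})

test_that("closed test keeps the original model when it is correct and climbs under drift", {
  reg <- model_registry()
  # correct specification: moderate replicate count here; full operating
  # characteristics are exercised in the acceptance suite
  picks <- vapply(1:40, function(i) {
    co <- generate_cohort(synthetic_config(n = 2000, seed = 9000 + i,
                                           true_model = reg$appelt_original,
                                           target_prevalence = 0.307))
    closed_test(attr(co, "true_model"), co)$selected_level
  }, character(1))
  expect_gte(mean(picks == "none"), 0.80)

  # development-like miscalibration: strong positive offset and slope < 1
  co <- generate_cohort(synthetic_config(n = 5000, seed = 110,
                                         true_model = reg$appelt_original,
                                         target_prevalence = 0.307,
                                         delta0 = 1.8, delta1 = 0.62))
  res <- closed_test(attr(co, "true_model"), co)
  expect_true(res$selected_level %in% c("intercept_slope", "revision"))

  # nested likelihood monotonicity on the fitting data
  expect_true(all(diff(res$log_likelihoods) >= -1e-8))
})

test_that("closed test handles single-term models (revision collapses to recalibration)", {
  reg <- model_registry()
  co <- small_synth(n = 2000, seed = 111)
  res <- closed_test(reg$quantec_original, co)
  expect_equal(res$tests$df[3], 0)
  expect_equal(res$tests$p[3], 1)
  expect_true(res$selected_level != "revision")
})

test_that("BIC simplification eliminates noise terms and honors forced terms", {
  reg <- model_registry()
  # truth uses MLD only; the other candidates are noise for the outcome
  cfg <- synthetic_config(n = 5000, seed = 112, true_model = reg$quantec_original,
                          target_prevalence = 0.307)
  keep_mld <- 0
  for (i in 1:5) {
    co <- generate_cohort(synthetic_config(n = 5000, seed = 112 + i,
                                           true_model = reg$quantec_original,
                                           target_prevalence = 0.307))
    out <- bic_simplify(co, c("MLD", "age", "NLR", "SII", "comorbidity", "stage"))
    keep_mld <- keep_mld + identical(names(out$model$terms), "MLD")
  }
  expect_gte(keep_mld, 4) # noise eliminated in nearly all replicates

  co <- generate_cohort(cfg)
  forced <- bic_simplify(co, c("MLD", "age", "NLR"), forced_terms = c("age", "NLR"))
  expect_true(all(c("age", "NLR") %in% names(forced$model$terms)))
  # final BIC never exceeds any earlier step
  expect_equal(min(forced$trace$bic), forced$trace$bic[nrow(forced$trace)])

  minimal <- bic_simplify(co, "MLD", forced_terms = "MLD")
  expect_equal(nrow(minimal$trace), 1)
  expect_identical(names(minimal$model$terms), "MLD")
  expect_error(bic_simplify(co, character(0)), "nonempty")
})

test_that("spline nonlinearity check has the right basis dimension and power", {
  co <- small_synth(n = 3000, seed = 113)
  res <- rcs_nonlinearity_check(co, "age", knots = 3)
  expect_equal(res$df, 1L) # 3-knot restricted cubic spline adds one term
  # truth is linear in age on the logit scale -> usually verdict "linear"
  expect_gt(res$p, 0.001)

  # inject a strong quadratic age effect
  df <- as.data.frame(co)
  set.seed(114)
  lpq <- -1 + 0.004 * (df$age - 63)^2
  df$event <- rbinom(nrow(df), 1, plogis(lpq))
  df$rp_grade <- ifelse(df$event == 1, 2L, 0L)
  coq <- as_cohort(df)
  resq <- rcs_nonlinearity_check(coq, "age", knots = 3)
  expect_equal(resq$verdict, "nonlinear")
  expect_error(rcs_nonlinearity_check(co, "age", knots = 7), "3, 4 or 5")
  expect_error(rcs_nonlinearity_check(as_cohort(toy_cohort_df()), "age"), "distinct")
})
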