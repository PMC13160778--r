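# Discrimination, calibration and fit statistics.

test_that("AUC matches exhaustive pair counting and handles ties", {
  expect_equal(auc_mw(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(auc_mw(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(auc_mw(runif(5), rep(1, 5)), "both outcome classes")

  set.seed(101)
  for (rep in 1:5) {
    n <- 20
    pred <- round(runif(n), 1) # rounding forces ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    # brute-force concordance oracle over all event/non-event pairs
    ev <- pred[y == 1]; nv <- pred[y == 0]
    conc <- 0
    for (a in ev) for (b in nv) conc <- conc + (a > b) + 0.5 * (a == b)
    expect_equal(auc_mw(pred, y), conc / (length(ev) * length(nv)))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(202)
  pred <- runif(200)
  y <- rbinom(200, 1, pred)
  expect_equal(auc_mw(pred, y),
               as.numeric(pROC::auc(pROC::roc(y, pred, quiet = TRUE))))
})

test_that("bootstrap AUC interval is reproducible and degenerate when separation is perfect", {
  y <- rep(c(0, 1), 30)
  ci1 <- bootstrap_auc_ci(y, y, B = 200, seed = 5)
  expect_equal(as.numeric(ci1), c(1, 1))
  set.seed(303)
  pred <- runif(60); yy <- rbinom(60, 1, 0.4)
  ci_a <- bootstrap_auc_ci(pred, yy, B = 200, seed = 9)
  ci_b <- bootstrap_auc_ci(pred, yy, B = 200, seed = 9)
  expect_identical(as.numeric(ci_a), as.numeric(ci_b))
  expect_lte(ci_a[1], attr(ci_a, "auc"))
  expect_gte(ci_a[2], attr(ci_a, "auc"))
  expect_error(bootstrap_auc_ci(pred, yy, B = 50, seed = 1), "at least 100")
})

test_that("bootstrap AUC interval width shrinks roughly as 1/sqrt(n)", {
  width_at <- function(n, seed) {
    set.seed(seed)
    pred <- runif(n)
    y <- rbinom(n, 1, pred)
    ci <- bootstrap_auc_ci(pred, y, B = 300, seed = seed)
    diff(as.numeric(ci))
  }
  w_small <- width_at(100, 41)
  w_big <- width_at(2500, 42)
  # 25x the sample should shrink the width ~5x; allow wide slack
  expect_lt(w_big, w_small / 2.5)
})

test_that("Brier score identities hold", {
  y <- rbinom(100, 1, 0.3)
  expect_equal(brier_score(y, y), 0)
  expect_equal(brier_score(rep(0.5, 100), y), 0.25)
  pi_hat <- mean(y)
  expect_equal(brier_score(rep(pi_hat, 100), y), pi_hat * (1 - pi_hat),
               tolerance = 1e-12)
})

test_that("fit statistics match an independent likelihood computation", {
  # n = 6 toy, expected values from the Bernoulli density directly
  y <- c(1, 0, 1, 1, 0, 0)
  p <- c(0.8, 0.3, 0.6, 0.9, 0.2, 0.4)
  fs <- fit_stats(p, y, k = 2)
  ll_oracle <- sum(dbinom(y, 1, p, log = TRUE))
  expect_equal(fs$log_likelihood, ll_oracle, tolerance = 1e-10)
  expect_equal(fs$aic, -2 * ll_oracle + 4, tolerance = 1e-10)
  expect_equal(fs$bic, -2 * ll_oracle + 2 * log(6), tolerance = 1e-10)
  expect_equal(fs$aic - fs$bic, 2 * 2 - 2 * log(6))
  # null-model predictions give Nagelkerke exactly 0
  fs0 <- fit_stats(rep(mean(y), 6), y, k = 1)
  expect_equal(fs0$nagelkerke_r2, 0, tolerance = 1e-12)
})

test_that("fit statistics agree with glm on fitted models", {
  co <- small_synth(n = 800, seed = 21)
  fit <- glm(event ~ mld + age, family = binomial(), data = as.data.frame(co))
  fs <- fit_stats(fitted(fit), co$event, k = 3)
  expect_equal(fs$log_likelihood, as.numeric(logLik(fit)), tolerance = 1e-8)
  expect_equal(fs$aic, AIC(fit), tolerance = 1e-8)
  expect_equal(fs$bic, BIC(fit), tolerance = 1e-8)
})

test_that("CITL and slope are (0,1) on self-fitted predictions and recover shifts", {
  co <- small_synth(n = 1200, seed = 31)
  fit <- glm(event ~ mld + nlr, family = binomial(), data = as.data.frame(co))
  cs <- citl_and_slope(fitted(fit), co$event)
  expect_equal(cs$citl, 0, tolerance = 1e-6)
  expect_equal(cs$slope, 1, tolerance = 1e-6)
  expect_equal(cs$joint_intercept, 0, tolerance = 1e-6)

  # shifting predictions by delta on the logit scale shows up as CITL ~ -delta
  delta <- 0.7
  shifted <- plogis(qlogis(fitted(fit)) + delta)
  cs2 <- citl_and_slope(shifted, co$event)
  expect_equal(cs2$citl, -delta, tolerance = 0.15)
  expect_equal(cs2$slope, 1, tolerance = 0.15)
})

test_that("calibration slope estimates the generating slope at large n", {
  set.seed(404)
  n <- 50000
  lp <- rnorm(n, 0, 1.2)
  b <- 0.6
  y <- rbinom(n, 1, plogis(-0.3 + b * lp))
  cs <- citl_and_slope(plogis(lp), y)
  se <- summary(glm(y ~ lp, family = binomial()))$coefficients["lp", "Std. Error"]
  expect_lt(abs(cs$slope - b), 3 * se)
})

test_that("Hosmer-Lemeshow equals the two-class summation oracle on a 3-bin toy", {
  # three clearly separated prediction clusters of 4 patients each
  pred <- c(rep(0.1, 4), rep(0.4, 4), rep(0.8, 4))
  y <- c(0, 0, 0, 1, 0, 1, 1, 0, 1, 1, 1, 0)
  hl <- hosmer_lemeshow(pred, y, groups = 3, df_policy = "external")
  oracle <- 0
  for (p0 in c(0.1, 0.4, 0.8)) {
    idx <- pred == p0
    o1 <- sum(y[idx]); e1 <- sum(pred[idx])
    o0 <- sum(idx) - o1; e0 <- sum(idx) - e1
    oracle <- oracle + (o1 - e1)^2 / e1 + (o0 - e0)^2 / e0
  }
  expect_equal(hl$chi2, oracle, tolerance = 1e-12)
  expect_equal(hl$groups_used, 3L)
  expect_equal(hl$df, 3L)
  expect_equal(hosmer_lemeshow(pred, y, groups = 3)$df, 1L) # development policy
  expect_gte(hl$chi2, 0)
  expect_error(hosmer_lemeshow(rep(0.3, 20), rbinom(20, 1, 0.3)), "constant")
})

test_that("duplicate quantile cut-points are dropped, not duplicated", {
  pred <- c(rep(0.2, 50), runif(10, 0.5, 0.9))
  y <- rbinom(60, 1, pred)
  hl <- hosmer_lemeshow(pred, y, groups = 10, df_policy = "external")
  expect_lt(hl$groups_used, 10)
  expect_gte(hl$groups_used, 2)
})

test_that("Hosmer-Lemeshow flags gross miscalibration and passes calibrated data", {
  co <- small_synth(n = 4000, seed = 55)
  p_true <- attr(co, "true_p")
  hl_good <- hosmer_lemeshow(p_true, co$event)
  expect_lt(hl_good$chi2, 30)
  # systematic underestimation on the logit scale: chi2 explodes
  p_bad <- plogis(qlogis(p_true) - 2)
  hl_bad <- hosmer_lemeshow(p_bad, co$event)
  expect_gt(hl_bad$chi2, 50 * hl_bad$df)
})

test_that("calibration curve tracks the diagonal for calibrated predictions", {
  co <- small_synth(n = 8000, seed = 77)
  p_true <- attr(co, "true_p")
  cc <- calibration_curve(p_true, co$event, groups = 10)
  expect_equal(nrow(cc), 10)
  expect_equal(sum(cc$n), 8000)
  expect_lt(max(abs(cc$mean_pred - cc$obs_rate)), 0.08)
  # an all-event bin reports observed rate 1
  cc2 <- calibration_curve(c(0.1, 0.15, 0.9, 0.95), c(0, 0, 1, 1), groups = 2)
  expect_equal(cc2$obs_rate, c(0, 1))
})

test_that("validate_model assembles a coherent report", {
  co <- small_synth(n = 1000, seed = 88)
  rep <- validate_model(model_registry()$model_d, co, B = 200, seed = 3)
  expect_s3_class(rep, "validation_report")
  expect_equal(rep$n, 1000)
  expect_lte(rep$events, rep$n)
  expect_lte(rep$auc_ci[1], rep$auc)
  expect_gte(rep$auc_ci[2], rep$auc)
  expect_lte(rep$hl_groups_used, 10)
  expect_equal(sum(rep$calibration_curve$n), rep$n)
})
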