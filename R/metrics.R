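# Discrimination, calibration and overall-fit metrics for probabilistic
# predictions of a binary endpoint.

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Concordance probability computed from midranks, so ties are handled the
#' standard way and the statistic is invariant under any strictly increasing
#' transform of the predictions (hence unchanged by logistic recalibration).
#'
#' @param pred numeric predictions (any monotone score; probabilities usual).
#' @param y binary 0/1 outcomes.
#' @return AUC in `[0, 1]`.
#' @export
auc_mw <- function(pred, y) {
  y <- check_binary_outcome(y)
  if (length(pred) != length(y)) stop("pred and y must have equal length")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) stop("AUC requires both outcome classes present")
  r <- rank(pred, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Percentile bootstrap confidence interval for the AUC
#'
#' Patient-level resampling with replacement; resamples containing a single
#' outcome class are redrawn (their count is attached as attribute
#' `"redraws"`). Reproducible given `seed`.
#'
#' @inheritParams auc_mw
#' @param B number of bootstrap resamples (`>= 100`).
#' @param seed integer RNG seed (mandatory).
#' @param level confidence level (default 0.95).
#' @return length-2 vector `c(lower, upper)` with attributes `auc`, `B`,
#'   `redraws`.
#' @export
bootstrap_auc_ci <- function(pred, y, B = 1000, seed, level = 0.95) {
  y <- check_pred_y(pred, y)
  if (B < 100) stop("B must be at least 100")
  if (missing(seed)) stop("seed is required for bootstrap resampling")
  set.seed(seed)
  n <- length(y)
  stats_b <- numeric(B)
  redraws <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[idx])) == 2L) break
      redraws <- redraws + 1L
    }
    stats_b[b] <- auc_mw(pred[idx], y[idx])
  }
  a <- (1 - level) / 2
  ci <- stats::quantile(stats_b, probs = c(a, 1 - a), names = FALSE)
  structure(ci, auc = auc_mw(pred, y), B = B, redraws = redraws)
}

#' Brier score
#'
#' Mean squared difference between predicted probability and the 0/1
#' outcome; lower is better, 0.25 corresponds to an uninformative constant
#' 0.5 predictor.
#'
#' @inheritParams auc_mw
#' @export
brier_score <- function(pred, y) {
  y <- check_pred_y(pred, y)
  mean((pred - y)^2)
}

#' Likelihood-based fit statistics
#'
#' Bernoulli log-likelihood of the predictions plus AIC (`-2LL + 2k`), BIC
#' (`-2LL + k log n`) and Nagelkerke R-squared (Cox-Snell rescaled by its
#' maximum), with the null log-likelihood taken from the intercept-only
#' model (constant prevalence prediction).
#'
#' @inheritParams auc_mw
#' @param k number of free parameters charged to the model (intercept
#'   included); for a fixed-coefficient external model this is a bookkeeping
#'   convention, not an estimate of effective dimension.
#' @param clip probabilities are clipped to `[clip, 1-clip]` before logs.
#' @return list with `log_likelihood`, `aic`, `bic`, `nagelkerke_r2`.
#' @export
fit_stats <- function(pred, y, k, clip = 1e-12) {
  y <- check_pred_y(pred, y)
  p <- clip_prob(pred, clip)
  n <- length(y)
  ll <- sum(y * log(p) + (1 - y) * log(1 - p))
  p0 <- mean(y)
  ll0 <- sum(y * log(p0) + (1 - y) * log(1 - p0))
  cox_snell <- 1 - exp(-2 * (ll - ll0) / n)
  max_cs <- 1 - exp(2 * ll0 / n)
  list(
    log_likelihood = ll,
    aic = -2 * ll + 2 * k,
    bic = -2 * ll + k * log(n),
    nagelkerke_r2 = cox_snell / max_cs
  )
}

#' Calibration-in-the-large and calibration slope
#'
#' Both are estimated on the logit scale (`lp = qlogis(pred)` after
#' clipping). CITL is the intercept of the maximum-likelihood logistic fit
#' of `y` on `lp` entered as a fixed offset; the slope is the coefficient on
#' `lp` in a free-intercept logistic refit. The free fit's intercept is also
#' returned (`joint_intercept`) because the two conventions differ whenever
#' the slope is not 1.
#'
#' @inheritParams auc_mw
#' @param clip clipping bound applied before the logit.
#' @return list with `citl`, `slope`, `joint_intercept`.
#' @export
citl_and_slope <- function(pred, y, clip = 1e-12) {
  y <- check_pred_y(pred, y)
  lp <- stats::qlogis(clip_prob(pred, clip))
  f_off <- stats::glm(y ~ 1 + offset(lp), family = stats::binomial())
  f_free <- stats::glm(y ~ lp, family = stats::binomial())
  if (!f_off$converged || !f_free$converged) {
    stop("calibration fit did not converge (n=", length(y),
         ", events=", sum(y), ", lp range=",
         paste(signif(range(lp), 4), collapse = ".."), ")")
  }
  list(
    citl = unname(stats::coef(f_off)[1]),
    slope = unname(stats::coef(f_free)[2]),
    joint_intercept = unname(stats::coef(f_free)[1])
  )
}

# Quantile bin assignment shared by hosmer_lemeshow and calibration_curve:
# right-closed bins on unique quantile edges; duplicate cut-points dropped.
quantile_bins <- function(pred, groups) {
  if (groups < 2) stop("groups must be at least 2")
  edges <- unique(stats::quantile(pred, probs = seq(0, 1, length.out = groups + 1),
                                  names = FALSE, type = 7))
  if (length(edges) < 3) {
    stop("fewer than 2 distinct prediction bins; predictions are (nearly) constant")
  }
  cut(pred, breaks = edges, include.lowest = TRUE, right = TRUE)
}

#' Hosmer-Lemeshow goodness-of-fit statistic
#'
#' Quantile (default decile) risk groups with duplicate cut-points dropped;
#' the chi-squared statistic sums `(O-E)^2/E` over both outcome classes in
#' every group. Because the appropriate degrees of freedom depend on whether
#' the model was fitted to the evaluated data, the df policy is an explicit
#' argument: `"development"` uses `groups_used - 2`, `"external"` uses
#' `groups_used`.
#'
#' @inheritParams auc_mw
#' @param groups requested number of quantile groups (default 10).
#' @param df_policy `"development"` or `"external"` (see above).
#' @return list with `chi2`, `df`, `p`, `groups_used`.
#' @export
hosmer_lemeshow <- function(pred, y, groups = 10,
                            df_policy = c("development", "external")) {
  y <- check_pred_y(pred, y)
  df_policy <- match.arg(df_policy)
  bins <- quantile_bins(pred, groups)
  o1 <- tapply(y, bins, sum)
  e1 <- tapply(pred, bins, sum)
  nb <- tapply(y, bins, length)
  keep <- !is.na(nb)
  o1 <- o1[keep]; e1 <- e1[keep]; nb <- nb[keep]
  o0 <- nb - o1
  e0 <- nb - e1
  chi2 <- sum((o1 - e1)^2 / e1 + (o0 - e0)^2 / e0)
  g <- length(nb)
  df <- if (df_policy == "development") g - 2L else g
  p <- if (df >= 1) stats::pchisq(chi2, df, lower.tail = FALSE) else NA_real_
  list(chi2 = chi2, df = as.integer(df), p = p, groups_used = as.integer(g))
}

#' Binned calibration curve
#'
#' Mean predicted risk versus observed event rate in quantile groups, the
#' data behind a calibration plot. Small external cohorts conventionally use
#' 4 groups; development-size cohorts use 10.
#'
#' @inheritParams hosmer_lemeshow
#' @return data frame with `bin`, `n`, `mean_pred`, `obs_rate`.
#' @export
calibration_curve <- function(pred, y, groups = 10) {
  y <- check_pred_y(pred, y)
  bins <- quantile_bins(pred, groups)
  nb <- tapply(y, bins, length)
  keep <- which(!is.na(nb))
  data.frame(
    bin = seq_along(keep),
    n = as.integer(nb[keep]),
    mean_pred = as.numeric(tapply(pred, bins, mean)[keep]),
    obs_rate = as.numeric(tapply(y, bins, mean)[keep])
  )
}

#' Full validation report for a model on a cohort
#'
#' Applies a fixed-coefficient [risk_model] to a cohort and computes the
#' complete metric panel: AUC (optionally with a percentile-bootstrap CI),
#' Brier score, log-likelihood/AIC/BIC/Nagelkerke R-squared, CITL and
#' calibration slope, Hosmer-Lemeshow statistic, and the binned calibration
#' curve.
#'
#' @param model a [risk_model].
#' @param cohort an `rp_cohort`.
#' @param groups quantile groups for Hosmer-Lemeshow and the calibration
#'   curve.
#' @param df_policy Hosmer-Lemeshow df policy (see [hosmer_lemeshow()]).
#' @param B bootstrap resamples for the AUC CI; `NULL` skips the CI.
#' @param seed RNG seed, required when `B` is given.
#' @param k parameters charged in AIC/BIC; defaults to the model's term
#'   count plus one.
#' @param age_cutoff,midinf_levels passed to [encode_for_model()].
#' @return object of class `validation_report`.
#' @export
validate_model <- function(model, cohort, groups = 10,
                           df_policy = c("development", "external"),
                           B = NULL, seed = NULL, k = NULL,
                           age_cutoff = 63, midinf_levels = c(1, 2)) {
  df_policy <- match.arg(df_policy)
  y <- as.data.frame(cohort)$event
  pred <- predict_risk(model, encode_for_model(cohort, model,
                                               age_cutoff = age_cutoff,
                                               midinf_levels = midinf_levels))
  if (is.null(k)) k <- length(model$terms) + 1L
  fs <- fit_stats(pred, y, k = k)
  cs <- citl_and_slope(pred, y)
  hl <- hosmer_lemeshow(pred, y, groups = groups, df_policy = df_policy)
  ci <- NULL
  if (!is.null(B)) {
    if (is.null(seed)) stop("seed is required when a bootstrap CI is requested")
    ci <- bootstrap_auc_ci(pred, y, B = B, seed = seed)
  }
  structure(list(
    model = model$name,
    cohort = attr(cohort, "label") %||% "cohort",
    n = length(y), events = sum(y),
    auc = auc_mw(pred, y),
    auc_ci = if (!is.null(ci)) as.numeric(ci),
    brier = brier_score(pred, y),
    log_likelihood = fs$log_likelihood, aic = fs$aic, bic = fs$bic,
    nagelkerke_r2 = fs$nagelkerke_r2,
    citl = cs$citl, calibration_slope = cs$slope,
    joint_intercept = cs$joint_intercept,
    hl_chi2 = hl$chi2, hl_df = hl$df, hl_p = hl$p,
    hl_groups_used = hl$groups_used,
    calibration_curve = calibration_curve(pred, y, groups = groups),
    df_policy = df_policy, k = k
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>", x$model, "on", x$cohort, "\n")
  cat(sprintf("  n = %d, events = %d (%.1f%%)\n", x$n, x$events, 100 * x$events / x$n))
  if (!is.null(x$auc_ci)) {
    cat(sprintf("  AUC = %.3f (95%% CI %.3f-%.3f)\n", x$auc, x$auc_ci[1], x$auc_ci[2]))
  } else {
    cat(sprintf("  AUC = %.3f\n", x$auc))
  }
  cat(sprintf("  Brier = %.3f, Nagelkerke R2 = %.3f\n", x$brier, x$nagelkerke_r2))
  cat(sprintf("  LL = %.2f, AIC = %.2f, BIC = %.2f (k = %d)\n",
              x$log_likelihood, x$aic, x$bic, x$k))
  cat(sprintf("  CITL = %.3f, slope = %.3f\n", x$citl, x$calibration_slope))
  cat(sprintf("  Hosmer-Lemeshow chi2 = %.3f (df = %d, p = %.3g, %d groups)\n",
              x$hl_chi2, x$hl_df, x$hl_p, x$hl_groups_used))
  invisible(x)
}
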