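# Orchestrated validation protocols: bootstrap optimism correction for
# internal validation and the fixed-coefficient external validation panel.

#' Bootstrap optimism-corrected internal validation
#'
#' Harrell's optimism bootstrap with the predictor set held fixed (no
#' per-resample selection): the model is refitted in each bootstrap sample
#' of the original size, its performance evaluated both in the bootstrap
#' sample and in the original cohort, and the mean difference (optimism)
#' subtracted from the apparent performance. Optimism is computed for the
#' AUC, and additionally for the Brier score and calibration slope as
#' standard extensions. Resamples where the refit fails (or a single
#' outcome class is drawn) are skipped, keeping the resample plan
#' seed-reproducible; more than 5% failures is an error.
#'
#' @param cohort development `rp_cohort`.
#' @param terms character vector of model terms (the final, fixed predictor
#'   set).
#' @param B number of bootstrap resamples (default 1000, `>= 100`).
#' @param seed integer RNG seed (required).
#' @param age_cutoff,midinf_levels passed to [encode_for_model()].
#' @return object of class `optimism_report` with `apparent`, `optimism`,
#'   `corrected` (each a named vector over `auc`, `brier`, `slope`), `B`,
#'   `completed`, `seed`.
#' @export
bootstrap_optimism <- function(cohort, terms, B = 1000, seed,
                               age_cutoff = 63, midinf_levels = c(1, 2)) {
  if (B < 100) stop("B must be at least 100")
  if (missing(seed)) stop("seed is required for bootstrap resampling")
  df <- as.data.frame(cohort)
  y <- df$event
  cov <- encode_covariates(df, age_cutoff = age_cutoff, midinf_levels = midinf_levels)
  missing_t <- setdiff(terms, names(cov))
  if (length(missing_t)) stop("cannot encode term(s): ", paste(missing_t, collapse = ", "))
  x <- cbind(`(Intercept)` = 1, as.matrix(cov[, terms, drop = FALSE]))
  n <- length(y)

  fit_coef <- function(xmat, yvec) {
    fit <- suppressWarnings(
      stats::glm.fit(xmat, yvec, family = stats::binomial(),
                     control = stats::glm.control(maxit = 100)))
    if (!fit$converged) return(NULL)
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0 # aliased (constant/collinear) columns drop out
    cf
  }
  fit_pred <- function(xmat, yvec, newx) {
    cf <- fit_coef(xmat, yvec)
    if (is.null(cf)) return(NULL)
    inv_logit(drop(newx %*% cf))
  }

  panel <- function(pred, yvec) {
    slope <- tryCatch(
      suppressMessages(citl_and_slope(pred, yvec))$slope,
      error = function(e) NA_real_) # near-degenerate refits: slope undefined
    c(auc = auc_mw(pred, yvec),
      brier = brier_score(pred, yvec),
      slope = slope)
  }

  pred_app <- fit_pred(x, y, x)
  if (is.null(pred_app)) stop("apparent model fit failed")
  apparent <- panel(pred_app, y)

  set.seed(seed)
  opt <- matrix(NA_real_, nrow = B, ncol = 3,
                dimnames = list(NULL, c("auc", "brier", "slope")))
  failed <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    yb <- y[idx]
    if (length(unique(yb)) < 2L) { failed <- failed + 1L; next }
    xb <- x[idx, , drop = FALSE]
    cfb <- tryCatch(fit_coef(xb, yb), error = function(e) NULL)
    if (is.null(cfb)) { failed <- failed + 1L; next }
    pred_boot <- inv_logit(drop(xb %*% cfb))
    pred_orig <- inv_logit(drop(x %*% cfb))
    perf_boot <- tryCatch(panel(pred_boot, yb), error = function(e) NULL)
    perf_orig <- tryCatch(panel(pred_orig, y), error = function(e) NULL)
    if (is.null(perf_boot) || is.null(perf_orig)) { failed <- failed + 1L; next }
    opt[b, ] <- perf_boot - perf_orig
  }
  if (failed > 0.05 * B) {
    stop(failed, " of ", B, " bootstrap refits failed (> 5%); ",
         "the model is too unstable for optimism correction")
  }
  if (failed > 0) message(failed, " of ", B, " bootstrap resamples skipped")
  optimism <- colMeans(opt, na.rm = TRUE)
  structure(list(
    apparent = apparent,
    optimism = optimism,
    corrected = apparent - optimism,
    B = B, completed = B - failed, seed = seed, terms = terms
  ), class = "optimism_report")
}

#' @export
print.optimism_report <- function(x, ...) {
  cat("<optimism_report>", x$completed, "of", x$B, "resamples completed\n")
  m <- rbind(apparent = x$apparent, optimism = x$optimism, corrected = x$corrected)
  print(round(m, 4))
  invisible(x)
}

#' Fixed-coefficient external validation
#'
#' Applies a locked model (no re-estimation of any coefficient) to an
#' independent cohort and computes the full validation panel with the
#' external Hosmer-Lemeshow df policy and a bootstrap CI for the AUC. The
#' bootstrap resamples patients of the external cohort. Calibration curves
#' default to 4 groups, the usual choice for small external cohorts. AIC
#' and BIC are reported with `k` equal to the model's term count plus one
#' for continuity with development-side tables, although no parameter is
#' actually estimated externally.
#'
#' @param model a [risk_model]; returned predictions come from exactly
#'   these coefficients.
#' @param cohort external `rp_cohort`.
#' @param groups calibration/HL groups (default 4).
#' @param B bootstrap resamples for the AUC CI (default 1000).
#' @param seed RNG seed (required).
#' @param age_cutoff,midinf_levels passed to [encode_for_model()].
#' @return a `validation_report` (see [validate_model()]).
#' @export
external_validate <- function(model, cohort, groups = 4, B = 1000, seed,
                              age_cutoff = 63, midinf_levels = c(1, 2)) {
  if (missing(seed)) stop("seed is required for the bootstrap AUC CI")
  validate_model(model, cohort, groups = groups, df_policy = "external",
                 B = B, seed = seed,
                 age_cutoff = age_cutoff, midinf_levels = midinf_levels)
}
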