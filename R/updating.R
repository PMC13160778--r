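# Model updating: the closed-testing ladder (intercept recalibration, full
# recalibration, revision), penalized re-estimation, BIC-guided backward
# simplification, and the restricted-cubic-spline nonlinearity check.

model_lp <- function(model, cohort, age_cutoff = 63, midinf_levels = c(1, 2)) {
  linear_predictor(model, encode_for_model(cohort, model,
                                           age_cutoff = age_cutoff,
                                           midinf_levels = midinf_levels))
}

cohort_ll <- function(pred, y) {
  p <- pmin(pmax(pred, 1e-15), 1 - 1e-15)
  sum(y * log(p) + (1 - y) * log(1 - p))
}

#' Recalibration-in-the-large (intercept update only)
#'
#' Re-estimates the intercept by maximum likelihood with the model's linear
#' predictor as a fixed offset; every term coefficient is carried over
#' unchanged. This corrects a baseline-risk offset between the model's
#' development population and the target cohort without touching predictor
#' effects.
#'
#' @param model a [risk_model].
#' @param cohort target `rp_cohort` (both outcome classes present).
#' @param age_cutoff,midinf_levels passed to [encode_for_model()].
#' @return updated [risk_model].
#' @export
recalibrate_intercept <- function(model, cohort, age_cutoff = 63, midinf_levels = c(1, 2)) {
  y <- as.data.frame(cohort)$event
  lp <- model_lp(model, cohort, age_cutoff, midinf_levels)
  fit <- stats::glm(y ~ 1 + offset(lp), family = stats::binomial())
  if (!fit$converged) stop("intercept recalibration did not converge")
  alpha <- unname(stats::coef(fit)[1])
  risk_model(
    name = paste0(model$name, "_citl"),
    intercept = model$intercept + alpha,
    terms = model$terms,
    transforms = model$transforms,
    provenance = paste0(model$provenance, " | intercept recalibrated (offset ",
                        signif(alpha, 6), ")")
  )
}

#' Full logistic recalibration (intercept and slope)
#'
#' Fits `y ~ a + b*LP` by maximum likelihood and folds the fitted intercept
#' and slope back into the coefficient vector: the returned model has
#' intercept `a + b*b0` and every term coefficient multiplied by `b`, so its
#' predictions equal `plogis(a + b*LP)` exactly. Being a strictly monotone
#' transform of the original predictions, recalibration leaves
#' discrimination (AUC) unchanged.
#'
#' @inheritParams recalibrate_intercept
#' @return updated [risk_model] with attributes `calibration_intercept` and
#'   `calibration_slope` (the fitted `a`, `b`).
#' @export
recalibrate <- function(model, cohort, age_cutoff = 63, midinf_levels = c(1, 2)) {
  y <- as.data.frame(cohort)$event
  lp <- model_lp(model, cohort, age_cutoff, midinf_levels)
  fit <- stats::glm(y ~ lp, family = stats::binomial())
  if (!fit$converged) stop("logistic recalibration did not converge")
  a <- unname(stats::coef(fit)[1]); b <- unname(stats::coef(fit)[2])
  out <- risk_model(
    name = paste0(model$name, "_recal"),
    intercept = a + b * model$intercept,
    terms = b * model$terms,
    transforms = model$transforms,
    provenance = paste0(model$provenance, " | fully recalibrated (a=",
                        signif(a, 6), ", b=", signif(b, 6), ")")
  )
  attr(out, "calibration_intercept") <- a
  attr(out, "calibration_slope") <- b
  out
}

#' Re-estimate all predictor-outcome associations (model revision)
#'
#' Refits a logistic model with the given term set on the cohort, by plain
#' maximum likelihood or with ridge/lasso shrinkage. Penalized fits
#' standardize covariates internally (the glmnet convention) and report
#' coefficients back on the input scale; the intercept is never penalized.
#' The ridge/lasso penalty is chosen by 10-fold cross-validated deviance
#' over a logarithmic grid.
#'
#' @param terms character vector of term names to estimate, or a
#'   [risk_model] whose term set is reused.
#' @param cohort target `rp_cohort`.
#' @param penalty `"none"` (maximum likelihood), `"ridge"` or `"lasso"`.
#' @param lambda_grid penalty grid for glmnet (default 25 points,
#'   `1e-4 .. 1e2`).
#' @param seed RNG seed controlling the cross-validation folds (required for
#'   penalized fits).
#' @param relax for `"lasso"`, refit the selected support unpenalized
#'   (relaxed lasso) so likelihood-based criteria are well defined.
#' @param name name for the returned model.
#' @param age_cutoff,midinf_levels passed to [encode_for_model()].
#' @return fitted [risk_model]; penalized fits carry a `lambda` attribute.
#' @export
revise <- function(terms, cohort, penalty = c("none", "ridge", "lasso"),
                   lambda_grid = 10^seq(log10(1e-4), log10(1e2), length.out = 25),
                   seed = NULL, relax = FALSE, name = "revised",
                   age_cutoff = 63, midinf_levels = c(1, 2)) {
  penalty <- match.arg(penalty)
  if (inherits(terms, "risk_model")) terms <- names(terms$terms)
  if (!length(terms)) stop("term set must be nonempty")
  df <- as.data.frame(cohort)
  y <- df$event
  cov <- encode_covariates(df, age_cutoff = age_cutoff, midinf_levels = midinf_levels)
  missing <- setdiff(terms, names(cov))
  if (length(missing)) stop("cannot encode term(s): ", paste(missing, collapse = ", "))
  x <- as.matrix(cov[, terms, drop = FALSE])

  if (penalty == "none") {
    fit <- suppressWarnings(
      stats::glm.fit(cbind(`(Intercept)` = 1, x), y, family = stats::binomial(),
                     control = stats::glm.control(maxit = 100)))
    cf <- fit$coefficients
    if (!fit$converged || any(is.na(cf)) || any(abs(cf[-1]) > 15)) {
      stop("unpenalized revision failed (separation or rank deficiency); ",
           "consider penalty = 'ridge'")
    }
    out <- risk_model(name, unname(cf[1]), cf[-1],
                      provenance = "revised by maximum likelihood on the target cohort")
    return(out)
  }

  if (is.null(seed)) stop("seed is required for penalized revision (CV folds)")
  set.seed(seed)
  alpha <- if (penalty == "ridge") 0 else 1
  foldid <- sample(rep_len(1:10, length(y)))
  cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = alpha,
                          lambda = sort(lambda_grid, decreasing = TRUE),
                          foldid = foldid, type.measure = "deviance",
                          standardize = TRUE)
  cf <- as.numeric(stats::coef(cv, s = "lambda.min"))
  names(cf) <- c("(Intercept)", colnames(x))
  if (penalty == "lasso" && relax) {
    support <- colnames(x)[cf[-1] != 0]
    if (!length(support)) {
      out <- risk_model(name, stats::qlogis(mean(y)), numeric(0),
                        provenance = "relaxed lasso selected the empty support")
    } else {
      out <- revise(support, cohort, penalty = "none", name = name,
                    age_cutoff = age_cutoff, midinf_levels = midinf_levels)
      out$provenance <- "relaxed lasso: unpenalized refit on the selected support"
    }
  } else {
    out <- risk_model(name, unname(cf[1]), cf[-1],
                      provenance = paste0("revised with ", penalty,
                                          " shrinkage (lambda.min = ",
                                          signif(cv$lambda.min, 4), ")"))
  }
  attr(out, "lambda") <- cv$lambda.min
  out
}

#' Closed-testing procedure for model updating
#'
#' Determines the least extensive update a published model needs on a new
#' cohort by likelihood-ratio testing of nested update levels, in order:
#' intercept recalibration versus the original model (df 1), full
#' recalibration versus intercept recalibration (df 1), and full revision
#' versus full recalibration (df = number of terms - 1). Starting from
#' "none", the ladder moves up while the current step's test rejects at
#' `alpha` and stops at the first non-rejection; the complete trace is
#' returned so alternative orderings can be audited. For single-term models
#' revision coincides with full recalibration (df 0), so the last rung can
#' never be selected.
#'
#' @inheritParams recalibrate_intercept
#' @param alpha significance level (default 0.05).
#' @return object of class `update_result`: `selected_level` (one of
#'   `"none"`, `"intercept"`, `"intercept_slope"`, `"revision"`), `models`
#'   (fitted model at every level), `tests` (LR trace), `alpha`.
#' @export
closed_test <- function(model, cohort, alpha = 0.05,
                        age_cutoff = 63, midinf_levels = c(1, 2)) {
  y <- as.data.frame(cohort)$event
  m_none <- model
  m_int <- recalibrate_intercept(model, cohort, age_cutoff, midinf_levels)
  m_slope <- recalibrate(model, cohort, age_cutoff, midinf_levels)
  p <- length(model$terms)
  m_rev <- if (p > 1) {
    # tolerant refit: aliased columns get coefficient 0 and quasi-separated
    # fits are kept (capped by the IRLS iteration limit) so the likelihood
    # comparison is always available
    cov <- encode_covariates(as.data.frame(cohort), age_cutoff = age_cutoff,
                             midinf_levels = midinf_levels)
    xr <- cbind(`(Intercept)` = 1, as.matrix(cov[, names(model$terms), drop = FALSE]))
    fit <- suppressWarnings(
      stats::glm.fit(xr, y, family = stats::binomial(),
                     control = stats::glm.control(maxit = 100)))
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    risk_model(paste0(model$name, "_revised"), unname(cf[1]), cf[-1],
               provenance = "revised by maximum likelihood on the target cohort")
  } else {
    m_slope # one free slope: revision and full recalibration coincide
  }

  ll <- vapply(list(m_none, m_int, m_slope, m_rev), function(m) {
    cohort_ll(predict_risk(m, encode_for_model(cohort, m,
                                               age_cutoff = age_cutoff,
                                               midinf_levels = midinf_levels)), y)
  }, numeric(1))
  names(ll) <- c("none", "intercept", "intercept_slope", "revision")

  lr <- pmax(0, 2 * diff(ll))
  dfs <- c(1L, 1L, max(p - 1L, 0L))
  pv <- ifelse(dfs >= 1, stats::pchisq(lr, dfs, lower.tail = FALSE), 1)
  tests <- data.frame(
    comparison = c("intercept vs none", "intercept_slope vs intercept",
                   "revision vs intercept_slope"),
    lr = as.numeric(lr), df = dfs, p = as.numeric(pv)
  )

  levels <- c("none", "intercept", "intercept_slope", "revision")
  selected <- 1L
  for (i in 1:3) {
    if (tests$p[i] < alpha) selected <- i + 1L else break
  }

  structure(list(
    selected_level = levels[selected],
    models = list(none = m_none, intercept = m_int,
                  intercept_slope = m_slope, revision = m_rev),
    log_likelihoods = ll,
    tests = tests,
    alpha = alpha
  ), class = "update_result")
}

#' @export
print.update_result <- function(x, ...) {
  cat("<update_result> selected level:", x$selected_level,
      sprintf("(alpha = %g)\n", x$alpha))
  print(x$tests, row.names = FALSE)
  invisible(x)
}

#' BIC-guided backward simplification
#'
#' Deterministic backward elimination of logistic-model terms: at each step
#' the removable term whose deletion lowers BIC the most is dropped;
#' elimination stops when no single deletion lowers BIC. Ties are broken by
#' the canonical term order. Terms in `forced_terms` are never removed.
#'
#' @param cohort target `rp_cohort`.
#' @param candidate_terms character vector of candidate term names.
#' @param forced_terms terms that must stay in the model.
#' @param name name for the returned model.
#' @param age_cutoff,midinf_levels passed to [encode_for_model()].
#' @return list with `model` (the refitted [risk_model] on the final term
#'   set) and `trace` (data frame of candidate term sets and their BIC, in
#'   visit order; the final BIC is the minimum of the trace).
#' @export
bic_simplify <- function(cohort, candidate_terms, forced_terms = character(),
                         name = "bic_simplified",
                         age_cutoff = 63, midinf_levels = c(1, 2)) {
  if (!length(candidate_terms)) stop("candidate term set must be nonempty")
  df <- as.data.frame(cohort)
  y <- df$event
  cov <- encode_covariates(df, age_cutoff = age_cutoff, midinf_levels = midinf_levels)
  all_terms <- order_terms(unique(c(candidate_terms, forced_terms)))
  missing <- setdiff(all_terms, names(cov))
  if (length(missing)) stop("cannot encode term(s): ", paste(missing, collapse = ", "))

  bic_of <- function(terms) {
    x <- cbind(`(Intercept)` = 1, as.matrix(cov[, terms, drop = FALSE]))
    fit <- stats::glm.fit(x, y, family = stats::binomial())
    -2 * cohort_ll(fit$fitted.values, y) + ncol(x) * log(length(y))
  }

  current <- all_terms
  trace <- list(data.frame(step = 0L, terms = paste(current, collapse = "+"),
                           bic = bic_of(current)))
  step <- 0L
  repeat {
    bic_now <- trace[[length(trace)]]$bic
    droppable <- setdiff(current, forced_terms)
    if (!length(droppable)) break
    cand <- vapply(droppable, function(tm) bic_of(setdiff(current, tm)), numeric(1))
    best <- droppable[which.min(cand)] # ties: first in canonical order
    if (min(cand) < bic_now) {
      step <- step + 1L
      current <- setdiff(current, best)
      trace[[length(trace) + 1L]] <- data.frame(
        step = step, terms = paste(current, collapse = "+"), bic = min(cand))
    } else break
  }

  final_fit <- if (length(current)) {
    revise(current, cohort, penalty = "none", name = name,
           age_cutoff = age_cutoff, midinf_levels = midinf_levels)
  } else {
    risk_model(name, stats::qlogis(mean(y)), numeric(0),
               provenance = "BIC elimination removed every candidate term")
  }
  list(model = final_fit, trace = do.call(rbind, trace))
}

# Harrell's default knot placements for restricted cubic splines.
RCS_KNOT_QUANTILES <- list(
  `3` = c(0.10, 0.50, 0.90),
  `4` = c(0.05, 0.35, 0.65, 0.95),
  `5` = c(0.05, 0.275, 0.50, 0.725, 0.95)
)

#' Restricted-cubic-spline nonlinearity check
#'
#' Tests whether a continuous covariate's association with the outcome
#' departs from linearity, by a likelihood-ratio test of a restricted cubic
#' spline (natural cubic spline) expansion against the linear term. Knots
#' are placed at standard quantiles (3 knots: 0.1/0.5/0.9); a k-knot basis
#' adds k-2 terms beyond linear.
#'
#' @param cohort an `rp_cohort`.
#' @param covariate cohort column name (continuous, e.g. `"age"`).
#' @param knots number of knots, 3 (default), 4 or 5.
#' @param alpha significance level for the verdict.
#' @return list with `statistic` (LR chi-squared), `df`, `p`, `verdict`
#'   (`"linear"` when `p >= alpha`, else `"nonlinear"`), `knots` (dose
#'   locations used).
#' @export
rcs_nonlinearity_check <- function(cohort, covariate, knots = 3, alpha = 0.05) {
  if (!knots %in% 3:5) stop("knots must be 3, 4 or 5")
  df <- as.data.frame(cohort)
  if (!covariate %in% names(df)) stop("unknown covariate: ", covariate)
  x <- df[[covariate]]
  y <- df$event
  if (length(unique(x)) < knots + 2) {
    stop("too few distinct values of ", covariate, " for a ", knots, "-knot spline")
  }
  kq <- stats::quantile(x, RCS_KNOT_QUANTILES[[as.character(knots)]], names = FALSE)
  if (anyDuplicated(kq)) stop("duplicate knot locations for ", covariate)
  basis <- splines::ns(x, knots = kq[-c(1, length(kq))],
                       Boundary.knots = kq[c(1, length(kq))])
  f_lin <- stats::glm(y ~ x, family = stats::binomial())
  f_spl <- stats::glm(y ~ basis, family = stats::binomial())
  lr <- max(0, 2 * (stats::logLik(f_spl) - stats::logLik(f_lin)))
  dof <- ncol(basis) - 1L
  p <- stats::pchisq(lr, dof, lower.tail = FALSE)
  list(statistic = as.numeric(lr), df = dof, p = p,
       verdict = if (p >= alpha) "linear" else "nonlinear",
       knots = kq)
}
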