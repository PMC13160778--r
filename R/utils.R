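# Internal numeric helpers shared across modules.

# Linear predictors are clamped to +/-700 before exponentiation so exp()
# cannot overflow; the resulting probability is then pinned strictly inside
# (0,1) so downstream logits stay finite.
LP_CLAMP <- 700
PROB_EPS <- 1e-16

inv_logit <- function(lp) {
  lp <- pmin(pmax(lp, -LP_CLAMP), LP_CLAMP)
  p <- stats::plogis(lp)
  pmin(pmax(p, PROB_EPS), 1 - PROB_EPS)
}

clip_prob <- function(p, eps = 1e-12) {
  stopifnot(is.numeric(p))
  if (any(!is.finite(p))) stop("non-finite probabilities supplied")
  clipped <- p < eps | p > 1 - eps
  if (any(clipped)) {
    message(sum(clipped), " prediction(s) clipped to [", eps, ", 1-", eps, "] before logit")
  }
  pmin(pmax(p, eps), 1 - eps)
}

check_binary_outcome <- function(y) {
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  as.integer(y)
}

check_pred_y <- function(pred, y) {
  if (length(pred) != length(y)) stop("pred and y must have equal length")
  if (any(!is.finite(pred)) || any(pred < 0) || any(pred > 1)) {
    stop("predictions must be probabilities in [0,1]")
  }
  check_binary_outcome(y)
}

# Canonical covariate/term ordering used for deterministic tie-breaking and
# table layout.
CANONICAL_TERMS <- c(
  "MLD", "V30", "V20", "V5", "smoke_former", "smoke_current", "comorbidity",
  "age", "old_age", "stage", "NLR", "SII", "seq_chemo", "loc_midinf"
)

order_terms <- function(terms) {
  known <- terms[terms %in% CANONICAL_TERMS]
  known <- known[order(match(known, CANONICAL_TERMS))]
  c(known, sort(setdiff(terms, CANONICAL_TERMS)))
}
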