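# Decision curve analysis: net benefit of risk-guided management versus
# treat-all and treat-none strategies over a grid of threshold probabilities.

#' Net benefit at a threshold probability
#'
#' `TP/n - (FP/n) * t/(1-t)`, where patients with predicted risk `>= t`
#' (closed on the left; ties count as positive) are classified positive.
#' The threshold odds `t/(1-t)` weight false positives by the harm-benefit
#' trade-off implied by choosing `t`.
#'
#' @param pred predicted probabilities.
#' @param y binary 0/1 outcomes.
#' @param t threshold probability, strictly inside (0, 1).
#' @return net benefit (events per patient scale).
#' @export
net_benefit <- function(pred, y, t) {
  y <- check_pred_y(pred, y)
  if (length(t) != 1 || t <= 0 || t >= 1) stop("threshold t must lie strictly in (0, 1)")
  n <- length(y)
  pos <- pred >= t
  tp <- sum(pos & y == 1)
  fp <- sum(pos & y == 0)
  tp / n - (fp / n) * t / (1 - t)
}

#' Decision curve for a set of predictions
#'
#' Pointwise net benefit of the model, of treating everyone (`pred == 1`:
#' `pi - (1-pi) t/(1-t)` with `pi` the prevalence) and of treating no one
#' (identically 0) over a threshold grid. The default grid 0.01-0.50 in
#' steps of 0.01 covers the low-to-intermediate thresholds relevant for
#' escalating RP risk management. The range of thresholds where the model
#' beats both default strategies is reported as `positive_range` (`NULL`
#' when empty).
#'
#' @inheritParams net_benefit
#' @param thresholds strictly increasing grid in (0, 1).
#' @return object of class `decision_curve`: list with `curve` (data frame
#'   `threshold`, `nb_model`, `nb_all`, `nb_none`) and `positive_range`.
#' @export
decision_curve <- function(pred, y, thresholds = seq(0.01, 0.50, by = 0.01)) {
  y <- check_pred_y(pred, y)
  if (!length(thresholds) || any(thresholds <= 0) || any(thresholds >= 1)) {
    stop("thresholds must lie strictly in (0, 1)")
  }
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly increasing")
  }
  ones <- rep(1 - 1e-15, length(y)) # treat-all: everyone above any t < 1
  nb_model <- vapply(thresholds, function(t) net_benefit(pred, y, t), numeric(1))
  nb_all <- vapply(thresholds, function(t) net_benefit(ones, y, t), numeric(1))
  curve <- data.frame(threshold = thresholds, nb_model = nb_model,
                      nb_all = nb_all, nb_none = 0)
  pos <- nb_model > pmax(nb_all, 0)
  positive_range <- if (any(pos)) range(thresholds[pos]) else NULL
  structure(list(curve = curve, positive_range = positive_range),
            class = "decision_curve")
}

#' @export
print.decision_curve <- function(x, ...) {
  cat("<decision_curve>", nrow(x$curve), "thresholds\n")
  if (is.null(x$positive_range)) {
    cat("  model never beats both treat-all and treat-none on this grid\n")
  } else {
    cat(sprintf("  model beats treat-all and treat-none for t in [%.2f, %.2f]\n",
                x$positive_range[1], x$positive_range[2]))
  }
  invisible(x)
}
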