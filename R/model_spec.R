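#' Construct a logistic NTCP risk model
#'
#' A `risk_model` is a fixed-coefficient logistic model: the predicted
#' probability of the toxicity endpoint (grade >=2 radiation pneumonitis)
#' is `plogis(b0 + sum(b_j * x_j))` where the `x_j` are coded covariates on
#' the transformed scale. Coefficients are data, not a fit object, so
#' published models can be shipped, serialized, and applied with coefficients
#' locked.
#'
#' @param name model identifier.
#' @param intercept numeric intercept (`b0`).
#' @param terms named numeric vector of term coefficients; names are the
#'   canonical covariate/term names (e.g. `MLD`, `smoke_former`).
#' @param transforms optional named list of covariate transforms. Each
#'   element is a list with fields `center` (default 0), `scale` (default 1,
#'   must be positive) and optionally `encoding`, a named list mapping
#'   categorical levels to indicator-term names.
#' @param provenance free-text note on where the coefficients come from.
#' @return an object of class `risk_model`.
#' @examples
#' m <- risk_model("quantec", -3.87, c(MLD = 0.126))
#' predict_risk(m, data.frame(MLD = 20))
#' @export
risk_model <- function(name, intercept, terms, transforms = list(), provenance = "") {
  stopifnot(is.character(name), length(name) == 1L)
  stopifnot(is.numeric(intercept), length(intercept) == 1L, is.finite(intercept))
  if (length(terms)) {
    if (is.null(names(terms)) || any(names(terms) == "")) {
      stop("all term coefficients must be named")
    }
    if (anyDuplicated(names(terms))) stop("duplicate term names")
    if (any(!is.finite(terms))) stop("all term coefficients must be finite")
  }
  terms <- stats::setNames(as.numeric(terms), names(terms))
  for (nm in names(transforms)) {
    tr <- transforms[[nm]]
    if (is.null(tr$center)) transforms[[nm]]$center <- 0
    if (is.null(tr$scale)) transforms[[nm]]$scale <- 1
    if (transforms[[nm]]$scale <= 0) stop("transform scale must be positive for ", nm)
  }
  structure(
    list(name = name, intercept = intercept, terms = terms,
         transforms = transforms, provenance = provenance),
    class = "risk_model"
  )
}

#' @export
print.risk_model <- function(x, ...) {
  cat("<risk_model>", x$name, "\n")
  cat("  intercept:", format(x$intercept), "\n")
  if (length(x$terms)) {
    cat("  terms:\n")
    for (nm in names(x$terms)) cat("    ", nm, "=", format(x$terms[[nm]]), "\n")
  } else {
    cat("  terms: (intercept only)\n")
  }
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

# Resolve the model's term columns from a coded-covariate data frame.
# A term resolves either to a column of `data` of the same name, or to an
# indicator derived from a declared categorical encoding. Center/scale
# transforms named after the term are then applied.
resolve_terms <- function(model, data) {
  data <- as.data.frame(data)
  out <- matrix(NA_real_, nrow = nrow(data), ncol = length(model$terms),
                dimnames = list(NULL, names(model$terms)))
  for (term in names(model$terms)) {
    if (term %in% names(data)) {
      v <- data[[term]]
    } else {
      v <- NULL
      for (cov in names(model$transforms)) {
        enc <- model$transforms[[cov]]$encoding
        if (!is.null(enc) && term %in% unlist(enc) && cov %in% names(data)) {
          lev <- names(enc)[vapply(enc, function(e) term %in% e, logical(1))][1]
          v <- as.numeric(data[[cov]] == lev)
          break
        }
      }
      if (is.null(v)) {
        stop("covariate for term '", term, "' not found; available: ",
             paste(names(data), collapse = ", "))
      }
    }
    if (!is.numeric(v)) stop("non-numeric value supplied for term '", term, "'")
    if (any(is.na(v))) stop("missing value supplied for term '", term, "'")
    tr <- model$transforms[[term]]
    if (!is.null(tr)) v <- (v - tr$center) / tr$scale
    out[, term] <- v
  }
  out
}

#' Linear predictor of a risk model
#'
#' Evaluates `b0 + sum(b_j * x_j)` on the transformed covariate scale for
#' each row of `data`.
#'
#' @param model a [risk_model].
#' @param data data frame (or coercible) supplying one column per model term
#'   (canonical names), or categorical covariates declared via transforms.
#' @return numeric vector of linear predictors.
#' @export
linear_predictor <- function(model, data) {
  stopifnot(inherits(model, "risk_model"))
  if (!length(model$terms)) {
    return(rep(model$intercept, nrow(as.data.frame(data))))
  }
  x <- resolve_terms(model, data)
  drop(model$intercept + x %*% model$terms)
}

#' Predicted toxicity risk
#'
#' Inverse-logit of [linear_predictor()]. The linear predictor is clamped to
#' +/-700 before exponentiation and the returned probability is strictly
#' inside (0,1).
#'
#' @inheritParams linear_predictor
#' @return numeric vector of probabilities in (0,1).
#' @export
predict_risk <- function(model, data) {
  inv_logit(linear_predictor(model, data))
}

#' Dose-response curve over a grid of mean lung dose values
#'
#' Evaluates the model risk over an MLD grid with all other covariates held
#' fixed, the standard way NTCP dose-response curves are drawn (optionally
#' stratified by age or smoking by varying `fixed`).
#'
#' @param model a [risk_model] containing an `MLD` term.
#' @param mld numeric grid of mean lung dose values (Gy), all `>= 0`.
#' @param fixed single-row data frame (or named list) of the remaining
#'   covariates.
#' @return data frame with columns `MLD` and `risk`.
#' @export
dose_response_curve <- function(model, mld, fixed = NULL) {
  stopifnot(inherits(model, "risk_model"))
  if (!length(mld)) stop("MLD grid must be nonempty")
  if (any(mld < 0)) stop("MLD values must be nonnegative")
  grid <- data.frame(MLD = as.numeric(mld))
  if (!is.null(fixed)) {
    fixed <- as.data.frame(fixed)
    if (nrow(fixed) != 1L) stop("`fixed` must describe a single covariate profile")
    grid <- cbind(grid, fixed[rep(1L, nrow(grid)), , drop = FALSE])
    rownames(grid) <- NULL
  }
  data.frame(MLD = grid$MLD, risk = predict_risk(model, grid))
}

#' Save a risk model as JSON
#'
#' Serializes name, intercept, terms, transforms and provenance at full
#' precision; [load_model()] reproduces the coefficients bit-exactly.
#'
#' @param model a [risk_model].
#' @param path output file path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "risk_model"))
  obj <- list(
    name = model$name,
    intercept = model$intercept,
    terms = as.list(model$terms),
    transforms = model$transforms,
    provenance = model$provenance
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a risk model from JSON
#'
#' @param path path to a model-spec JSON file written by [save_model()] (or
#'   by hand: fields `name`, `intercept`, `terms`; optional `transforms`,
#'   `provenance`).
#' @return a [risk_model].
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path)
  missing <- setdiff(c("name", "intercept", "terms"), names(obj))
  if (length(missing)) {
    stop("model spec file is missing required field(s): ",
         paste(missing, collapse = ", "))
  }
  bad <- c(
    if (!is.character(obj$name)) "name",
    if (!is.numeric(obj$intercept)) "intercept",
    if (!is.list(obj$terms) || !all(vapply(obj$terms, is.numeric, logical(1)))) "terms"
  )
  if (length(bad)) stop("model spec field(s) malformed: ", paste(bad, collapse = ", "))
  transforms <- if (is.null(obj$transforms)) list() else
    lapply(obj$transforms, function(tr) {
      list(center = tr$center %||% 0, scale = tr$scale %||% 1,
           encoding = tr$encoding)
    })
  risk_model(
    name = obj$name,
    intercept = obj$intercept,
    terms = unlist(obj$terms),
    transforms = transforms,
    provenance = obj$provenance %||% ""
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Registry of published and locally updated RP risk models
#'
#' Returns the eight fixed-coefficient logistic models the package ships:
#' the pooled-analysis QUANTEC model (MLD only) plus its intercept/slope
#' recalibration and ridge-shrunk final update for a contemporary IMRT
#' cohort; the multifactorial Appelt model plus its intercept-recalibrated
#' (A) and fully recalibrated (B) variants; the BIC-simplified MLD-only
#' model (C); and the final simplified local model (D) combining clinical,
#' inflammatory (NLR, SII) and dosimetric (MLD, V30) predictors. All
#' coefficients are on the raw covariate scale (transforms are identity);
#' Model D in particular is shipped exactly as printed, on raw scales.
#'
#' @return named list of [risk_model] objects, class `model_registry`.
#' @export
model_registry <- function() {
  reg <- list(
    quantec_original = risk_model(
      "quantec_original", -3.87, c(MLD = 0.126),
      provenance = "QUANTEC pooled analysis; LP = -3.87 + 0.126*MLD (Gy, physical dose)"
    ),
    quantec_recalibrated = risk_model(
      "quantec_recalibrated", -1.742, c(MLD = 0.164),
      provenance = "QUANTEC with intercept and MLD coefficient re-estimated in a contemporary IMRT development cohort (n=580)"
    ),
    quantec_final = risk_model(
      "quantec_final", -1.652, c(MLD = 0.155),
      provenance = "QUANTEC update after coefficient re-estimation with ridge shrinkage"
    ),
    appelt_original = risk_model(
      "appelt_original", -4.76,
      c(MLD = 0.138, smoke_current = -0.48, smoke_former = -0.37,
        comorbidity = 0.82, old_age = 0.51, seq_chemo = 0.47,
        loc_midinf = 0.63),
      provenance = "Appelt multifactorial NTCP model; binary old-age, sequential-chemo and mid/inferior-location indicators"
    ),
    appelt_a = risk_model(
      "appelt_a", -1.7575,
      c(MLD = 0.138, smoke_current = -0.48, smoke_former = -0.37,
        comorbidity = 0.82, old_age = 0.51, seq_chemo = 0.47,
        loc_midinf = 0.63),
      provenance = "Appelt after recalibration-in-the-large (intercept update only)"
    ),
    appelt_b = risk_model(
      "appelt_b", -1.127,
      c(MLD = 0.085, smoke_current = -0.2956, smoke_former = -0.2279,
        comorbidity = 0.5051, old_age = 0.3141, seq_chemo = 0.2895,
        loc_midinf = 0.388),
      provenance = "Appelt after full recalibration (intercept and slope 0.6159)"
    ),
    model_c = risk_model(
      "model_c", -1.7422, c(MLD = 0.1637),
      provenance = "BIC-guided simplification of the Appelt framework; MLD retained as sole predictor"
    ),
    model_d = risk_model(
      "model_d", -0.8714,
      c(MLD = 0.1199, smoke_former = -0.0572, smoke_current = -2.15,
        comorbidity = -0.0626, age = 0.0405, stage = -0.2493,
        NLR = -0.1669, SII = 0.0006, V30 = 0.0498),
      provenance = paste(
        "Final simplified local model; age continuous (years), stage numeric 1-4,",
        "NLR/SII/V30/MLD raw scale. Shipped on raw covariate scales as printed;",
        "any standardization used at fit time is undocumented, so transforms are identity."
      )
    )
  )
  structure(reg, class = c("model_registry", "list"))
}
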