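# Cohort ingestion, validation, model encoding and Table-1 style summaries.

REQUIRED_COLS <- c("age", "stage", "smoking", "comorbidity", "location3",
                   "neut", "lymph", "plt", "mld", "v30", "rp_grade")
SMOKING_LEVELS <- c("never", "former", "current")

validate_cohort_df <- function(df, strict = TRUE) {
  missing_cols <- setdiff(REQUIRED_COLS, names(df))
  if (length(missing_cols)) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  model_cols <- intersect(c(REQUIRED_COLS, "nlr", "sii", "event"), names(df))
  incomplete <- !stats::complete.cases(df[model_cols])
  if (any(incomplete)) {
    if (strict) {
      stop(sum(incomplete), " row(s) contain missing values in modelling ",
           "variables (strict mode); use strict = FALSE to drop them")
    }
    message("dropping ", sum(incomplete), " row(s) with missing modelling variables")
    df <- df[!incomplete, , drop = FALSE]
  }
  if (!nrow(df)) stop("cohort is empty after validation")
  if (!all(df$smoking %in% SMOKING_LEVELS)) {
    stop("smoking must be one of: ", paste(SMOKING_LEVELS, collapse = ", "))
  }
  if (any(df$mld < 0)) stop("MLD must be nonnegative")
  for (v in intersect(c("v5", "v20", "v30"), names(df))) {
    if (any(df[[v]] < 0 | df[[v]] > 100)) stop(v, " must lie in [0, 100] (% lung volume)")
  }
  if (any(df$lymph <= 0)) stop("lymphocyte counts must be positive")
  if (!all(df$rp_grade %in% 0:5)) stop("rp_grade must be an integer grade 0-5")
  if (!all(df$stage %in% 1:4)) stop("stage must be coded 1-4")
  # derived markers and endpoint
  if (is.null(df$nlr)) df$nlr <- df$neut / df$lymph
  if (is.null(df$sii)) df$sii <- df$plt * df$neut / df$lymph
  if (is.null(df$event)) df$event <- as.integer(df$rp_grade >= 2)
  if (!all(df$event == as.integer(df$rp_grade >= 2))) {
    stop("event column inconsistent with rp_grade >= 2")
  }
  rownames(df) <- NULL
  df
}

new_cohort <- function(df, label = "cohort") {
  structure(df, class = c("rp_cohort", "data.frame"), label = label)
}

#' Read and validate a patient cohort from CSV
#'
#' Expects the canonical lowercase header names (`age, sex, stage, ps,
#' smoking, comorbidity, location3, histology, wbc, neut, lymph, plt, nlr,
#' sii, mld, v5, v20, v30, chemo, immuno, rp_grade`); `nlr`, `sii` and
#' `event` are derived when absent (`nlr = neut/lymph`,
#' `sii = plt*neut/lymph`, `event = rp_grade >= 2`).
#'
#' @param path CSV file path (UTF-8).
#' @param label cohort label used in printing.
#' @param strict if `TRUE` (default) any missing value in a modelling
#'   variable is an error; if `FALSE` the affected rows are dropped with a
#'   message.
#' @return an `rp_cohort` (a validated data frame).
#' @export
read_cohort <- function(path, label = basename(path), strict = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  new_cohort(validate_cohort_df(df, strict = strict), label = label)
}

#' Coerce a data frame to a validated cohort
#'
#' @param df data frame with canonical cohort columns.
#' @inheritParams read_cohort
#' @return an `rp_cohort`.
#' @export
as_cohort <- function(df, label = "cohort", strict = TRUE) {
  new_cohort(validate_cohort_df(as.data.frame(df), strict = strict), label = label)
}

#' @export
print.rp_cohort <- function(x, ...) {
  cat("<rp_cohort>", attr(x, "label"), "-", nrow(x), "patients,",
      sum(x$event), sprintf("events (%.1f%%)\n", 100 * mean(x$event)))
  invisible(x)
}

#' Encode a cohort for a specific risk model
#'
#' Produces the coded-covariate matrix holding exactly the model's term
#' columns under the canonical names: `MLD`, `V30` (and `V20`/`V5`), `NLR`,
#' `SII` from the corresponding lowercase cohort columns; `age` continuous in
#' years; `stage` numeric 1-4; `comorbidity` binary; smoking expanded to the
#' `smoke_former`/`smoke_current` indicator pair (never smoker is the
#' reference, so both are 0); `old_age` as the indicator `age >= age_cutoff`;
#' `loc_midinf` as the indicator `location3 %in% midinf_levels`; and
#' `seq_chemo` as chemotherapy given but not concurrently
#' (`chemo == 1 & chemo_concurrent == 0` when a `chemo_concurrent` column is
#' present, otherwise the `chemo` flag itself).
#'
#' @param cohort an `rp_cohort` (or validatable data frame).
#' @param model a [risk_model] whose terms are to be encoded.
#' @param age_cutoff years; threshold for the binary `old_age` indicator
#'   (default 63, close to the cohort median; the source model does not print
#'   its cutoff, so it is configurable).
#' @param midinf_levels which `location3` levels count as mid/inferior
#'   (default `c(1, 2)`); configurable because the three-level coding is
#'   site-specific.
#' @return data frame with one column per model term, rows aligned with the
#'   cohort.
#' @export
encode_for_model <- function(cohort, model, age_cutoff = 63, midinf_levels = c(1, 2)) {
  stopifnot(inherits(model, "risk_model"))
  df <- as.data.frame(cohort)
  cov <- encode_covariates(df, age_cutoff = age_cutoff, midinf_levels = midinf_levels)
  need <- names(model$terms)
  missing <- setdiff(need, names(cov))
  if (length(missing)) {
    stop("cannot encode term(s) ", paste(missing, collapse = ", "),
         " for model '", model$name, "'; available covariates: ",
         paste(names(cov), collapse = ", "))
  }
  cov[, need, drop = FALSE]
}

# Full coded covariate frame; encode_for_model subsets it per model.
encode_covariates <- function(df, age_cutoff = 63, midinf_levels = c(1, 2)) {
  out <- data.frame(
    MLD = df$mld,
    V30 = df$v30,
    NLR = df$nlr,
    SII = df$sii,
    age = df$age,
    stage = as.numeric(df$stage),
    comorbidity = as.numeric(df$comorbidity),
    smoke_former = as.numeric(df$smoking == "former"),
    smoke_current = as.numeric(df$smoking == "current"),
    old_age = as.numeric(df$age >= age_cutoff),
    loc_midinf = as.numeric(df$location3 %in% midinf_levels)
  )
  if (!is.null(df$v20)) out$V20 <- df$v20
  if (!is.null(df$v5)) out$V5 <- df$v5
  if (!is.null(df$chemo)) {
    out$seq_chemo <- if (!is.null(df$chemo_concurrent)) {
      as.numeric(df$chemo == 1 & df$chemo_concurrent == 0)
    } else {
      as.numeric(df$chemo == 1)
    }
  }
  out
}

#' Baseline characteristics summary
#'
#' Mean +/- SD for continuous variables and n (%) for categorical ones, in
#' the usual baseline-table style: means and SDs rounded to 2 decimals,
#' percentages to 1 decimal. For a single-patient cohort the SD is reported
#' as 0 with a warning (rather than NA) so the table stays total.
#'
#' @param cohort an `rp_cohort`.
#' @return data frame with columns `variable`, `level`, `n`, `mean`, `sd`,
#'   `pct`, `summary` (formatted string).
#' @export
summarize_cohort <- function(cohort) {
  df <- as.data.frame(cohort)
  if (!nrow(df)) stop("cohort is empty")
  continuous <- intersect(
    c("age", "wbc", "neut", "lymph", "plt", "nlr", "sii",
      "mld", "v5", "v20", "v30"), names(df))
  categorical <- intersect(
    c("sex", "stage", "ps", "smoking", "comorbidity", "location3",
      "histology", "chemo", "immuno", "event"), names(df))
  rows <- list()
  single <- nrow(df) == 1L
  if (single) warning("single-patient cohort: SDs reported as 0")
  for (v in continuous) {
    m <- mean(df[[v]])
    s <- if (single) 0 else stats::sd(df[[v]])
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, level = NA_character_, n = nrow(df),
      mean = round(m, 2), sd = round(s, 2), pct = NA_real_,
      summary = sprintf("%.2f ± %.2f", m, s))
  }
  for (v in categorical) {
    tab <- table(df[[v]])
    for (lev in names(tab)) {
      nlev <- as.integer(tab[[lev]])
      pct <- 100 * nlev / nrow(df)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = lev, n = nlev,
        mean = NA_real_, sd = NA_real_, pct = round(pct, 1),
        summary = sprintf("%d (%.1f%%)", nlev, pct))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
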