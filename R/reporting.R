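# Reporting: wide model-comparison tables and a thin command-line entry
# point over the package functions (installed as exec/rpntcp).

#' Wide model-comparison table
#'
#' One column per model, with coefficient rows (canonical term order,
#' rounded to 4 decimals, empty where a term is absent) followed by the
#' performance and calibration metric rows (3 decimals), mirroring the
#' usual published layout for model-updating comparisons. Re-exporting
#' identical results yields byte-identical files.
#'
#' @param reports named list of `validation_report` objects (see
#'   [validate_model()]); names become column headers.
#' @param models optional named list of [risk_model]s (same names) whose
#'   coefficients are included above the metrics.
#' @param path optional CSV output path.
#' @return data frame with a `row` column plus one column per model.
#' @export
table_export <- function(reports, models = NULL, path = NULL) {
  if (!length(reports)) stop("at least one validation report is required")
  stopifnot(all(vapply(reports, inherits, logical(1), "validation_report")))
  cols <- names(reports)
  if (is.null(cols) || any(cols == "")) stop("reports must be a named list")

  rows <- list()
  add_row <- function(label, values) {
    rows[[length(rows) + 1L]] <<- c(list(row = label), as.list(values))
  }
  if (!is.null(models)) {
    stopifnot(identical(names(models), cols))
    all_terms <- order_terms(unique(unlist(lapply(models, function(m) names(m$terms)))))
    add_row("Intercept", vapply(models, function(m) sprintf("%.4f", m$intercept),
                                character(1)))
    for (tm in all_terms) {
      add_row(tm, vapply(models, function(m) {
        if (tm %in% names(m$terms)) sprintf("%.4f", m$terms[[tm]]) else ""
      }, character(1)))
    }
  }
  metric <- function(label, field, digits = 3) {
    add_row(label, vapply(reports, function(r) {
      v <- r[[field]]
      if (is.null(v) || is.na(v)) "" else sprintf(paste0("%.", digits, "f"), v)
    }, character(1)))
  }
  metric("LL", "log_likelihood")
  metric("AIC", "aic")
  metric("BIC", "bic")
  metric("AUC", "auc")
  metric("Brier", "brier")
  metric("Nagelkerke R2", "nagelkerke_r2")
  metric("CITL", "citl")
  metric("Calibration slope", "calibration_slope")
  metric("HL chi2", "hl_chi2")
  metric("HL p", "hl_p")

  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
  names(out) <- c("row", cols)
  rownames(out) <- NULL
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}

# --- command-line entry point ------------------------------------------------

cli_usage <- function() {
  paste(
    "usage: rpntcp <subcommand> [--key value ...]",
    "",
    "subcommands:",
    "  simulate  --n N --seed S [--delta0 D --delta1 D --prevalence P] --out cohort.csv",
    "  predict   --model <registry-name|spec.json> --cohort cohort.csv --out pred.csv",
    "  summarize --cohort cohort.csv --out summary.csv",
    "  validate  --model <name|json> --cohort cohort.csv [--groups G --df-policy P]",
    "            [--bootstrap B] --seed S --out report.json [--curve curve.csv]",
    "  update    --model <name|json> --cohort cohort.csv [--alpha A] --out result.json",
    "  dca       --model <name|json> --cohort cohort.csv --out dca.csv",
    "  report    --cohort cohort.csv --out table.csv [--groups G --df-policy P]",
    sep = "\n"
  )
}

parse_cli_args <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    key <- args[[i]]
    if (!startsWith(key, "--")) stop("unexpected argument: ", key, "\n", cli_usage())
    if (i + 1L > length(args)) stop("missing value for ", key)
    out[[sub("^--", "", key)]] <- args[[i + 1L]]
    i <- i + 2L
  }
  out
}

cli_get_model <- function(spec) {
  reg <- model_registry()
  if (spec %in% names(reg)) reg[[spec]] else load_model(spec)
}

cli_num <- function(opts, key, default = NULL) {
  if (is.null(opts[[key]])) {
    if (is.null(default)) stop("--", key, " is required")
    default
  } else as.numeric(opts[[key]])
}

#' Command-line interface
#'
#' Dispatches the `rpntcp` shell command's subcommands (`simulate`,
#' `predict`, `summarize`, `validate`, `update`, `dca`, `report`) onto the
#' package functions; see `rpntcp_cli(character(0))` for usage. Intended to
#' be driven by the installed `exec/rpntcp` script but callable directly.
#'
#' @param args character vector of command-line arguments (subcommand
#'   first).
#' @return 0 invisibly on success; bad usage or downstream failures raise
#'   errors (the exec wrapper converts them to a nonzero exit status).
#' @export
rpntcp_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) { cat(cli_usage(), "\n"); return(invisible(1L)) }
  sub <- args[[1]]
  opts <- parse_cli_args(args[-1])
  out <- opts$out
  need_out <- function() if (is.null(out)) stop("--out is required")

  if (sub == "simulate") {
    need_out()
    cfg <- synthetic_config(
      n = cli_num(opts, "n", 580),
      seed = as.integer(cli_num(opts, "seed")),
      delta0 = cli_num(opts, "delta0", 0),
      delta1 = cli_num(opts, "delta1", 1),
      target_prevalence = cli_num(opts, "prevalence", 0.307)
    )
    cohort <- generate_cohort(cfg)
    utils::write.csv(as.data.frame(cohort), out, row.names = FALSE)
  } else if (sub == "predict") {
    need_out()
    model <- cli_get_model(opts$model %||% stop("--model is required"))
    cohort <- read_cohort(opts$cohort %||% stop("--cohort is required"))
    enc <- encode_for_model(cohort, model)
    utils::write.csv(
      data.frame(lp = linear_predictor(model, enc), risk = predict_risk(model, enc)),
      out, row.names = FALSE)
  } else if (sub == "summarize") {
    need_out()
    cohort <- read_cohort(opts$cohort %||% stop("--cohort is required"))
    utils::write.csv(summarize_cohort(cohort), out, row.names = FALSE)
  } else if (sub == "validate") {
    need_out()
    model <- cli_get_model(opts$model %||% stop("--model is required"))
    cohort <- read_cohort(opts$cohort %||% stop("--cohort is required"))
    B <- if (is.null(opts$bootstrap)) NULL else as.integer(opts$bootstrap)
    rep <- validate_model(
      model, cohort,
      groups = cli_num(opts, "groups", 10),
      df_policy = opts[["df-policy"]] %||% "development",
      B = B, seed = if (!is.null(B)) as.integer(cli_num(opts, "seed")) else NULL)
    curve <- rep$calibration_curve
    jsonlite::write_json(rep[setdiff(names(rep), "calibration_curve")], out,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(opts$curve)) utils::write.csv(curve, opts$curve, row.names = FALSE)
  } else if (sub == "update") {
    need_out()
    model <- cli_get_model(opts$model %||% stop("--model is required"))
    cohort <- read_cohort(opts$cohort %||% stop("--cohort is required"))
    res <- closed_test(model, cohort, alpha = cli_num(opts, "alpha", 0.05))
    jsonlite::write_json(list(
      selected_level = res$selected_level,
      alpha = res$alpha,
      tests = res$tests,
      models = lapply(res$models, function(m)
        list(name = m$name, intercept = m$intercept, terms = as.list(m$terms)))
    ), out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else if (sub == "dca") {
    need_out()
    model <- cli_get_model(opts$model %||% stop("--model is required"))
    cohort <- read_cohort(opts$cohort %||% stop("--cohort is required"))
    pred <- predict_risk(model, encode_for_model(cohort, model))
    dc <- decision_curve(pred, as.data.frame(cohort)$event)
    utils::write.csv(dc$curve, out, row.names = FALSE)
  } else if (sub == "report") {
    need_out()
    cohort <- read_cohort(opts$cohort %||% stop("--cohort is required"))
    reg <- model_registry()
    reports <- lapply(reg, function(m)
      validate_model(m, cohort,
                     groups = cli_num(opts, "groups", 10),
                     df_policy = opts[["df-policy"]] %||% "development"))
    table_export(reports, models = reg, path = out)
  } else {
    stop("unknown subcommand: ", sub, "\n", cli_usage())
  }
  invisible(0L)
}
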