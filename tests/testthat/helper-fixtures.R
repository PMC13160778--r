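# Shared fixtures: all test data is built in code.

# Minimal hand-written cohort data frame (3 patients) exercising each coded
# covariate; NLR/SII/event left for the reader to derive unless asked for.
toy_cohort_df <- function() {
  data.frame(
    age = c(70, 55, 63),
    sex = c(1, 2, 1),
    stage = c(3, 1, 4),
    ps = c(1, 0, 2),
    smoking = c("never", "former", "current"),
    comorbidity = c(1, 0, 1),
    location3 = c(1, 3, 2),
    histology = c(1, 2, 3),
    wbc = c(6, 5, 7),
    neut = c(4.2, 3.0, 5.5),
    lymph = c(1.2, 1.5, 1.0),
    plt = c(210, 180, 250),
    mld = c(12, 6, 18),
    v5 = c(40, 20, 60),
    v20 = c(20, 10, 35),
    v30 = c(15, 5, 30),
    chemo = c(1, 0, 1),
    chemo_concurrent = c(0, 0, 1),
    immuno = c(1, 0, 1),
    rp_grade = c(2, 0, 1),
    stringsAsFactors = FALSE
  )
}

toy_cohort <- function() as_cohort(toy_cohort_df(), label = "toy")

write_toy_csv <- function(df = toy_cohort_df()) {
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  path
}

# Small seeded synthetic cohort reused across tests.
small_synth <- function(n = 1500, seed = 7, ...) {
  generate_cohort(synthetic_config(n = n, seed = seed, ...))
}

# Pure-noise optimism experiment: outcome independent of all covariates,
# 10 candidate predictors at n = 100; returns apparent and optimism-
# corrected AUC per replicate.
noise_optimism_panel <- function(n_rep, B, seed_base) {
  terms <- c("MLD", "V30", "age", "stage", "NLR", "SII", "comorbidity",
             "smoke_former", "smoke_current", "loc_midinf")
  out <- vapply(seq_len(n_rep), function(i) {
    df <- as.data.frame(small_synth(n = 100, seed = seed_base + i))
    set.seed(seed_base + 500 + i)
    df$event <- rbinom(nrow(df), 1, 0.3)
    df$rp_grade <- ifelse(df$event == 1, 2L, 0L)
    rep <- suppressMessages(suppressWarnings(
      bootstrap_optimism(as_cohort(df), terms, B = B, seed = seed_base + i)))
    c(rep$apparent[["auc"]], rep$corrected[["auc"]])
  }, numeric(2))
  rownames(out) <- c("apparent", "corrected")
  out
}
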