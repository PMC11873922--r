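# End-to-end runner: generate/load -> prep -> fit model suite -> evaluate ->
# risk factors -> reports, with seeded determinism and a run manifest.

#' Load and validate a cohort CSV
#'
#' Reads a cohort table in the canonical CSV dialect and enforces the
#' cohort invariants: full column schema, attendance counts of at least 3
#' (the inclusion criterion), ordinals within their coded ranges, and the
#' long-term-condition sum identity. A missing `total_ltcs` column is
#' recomputed from the flags with a warning.
#'
#' @param path CSV file path.
#' @return Validated `fa_cohort` data.frame.
#' @export
load_cohort <- function(path) {
  if (!file.exists(path)) stop("no such cohort file: ", path)
  tab <- read.csv(path)
  if (!"total_ltcs" %in% names(tab) &&
      all(fa_ltc_flags() %in% names(tab))) {
    warning("total_ltcs missing; recomputed from the LTC flags")
    tab$total_ltcs <- as.integer(rowSums(tab[fa_ltc_flags()]))
  }
  missing_cols <- setdiff(fa_schema(), names(tab))
  if (length(missing_cols))
    stop("cohort schema mismatch; missing column(s): ",
         paste(missing_cols, collapse = ", "))
  tab <- tab[fa_schema()]
  bad <- which(tab$ae_attendances < 3)
  if (length(bad))
    stop("rows with fewer than three A&E visits violate the inclusion ",
         "criterion: rows ", paste(head(bad, 10), collapse = ", "))
  bad <- which(tab$age_group < 1 | tab$age_group > 6 |
                 tab$simd_quintile < 1 | tab$simd_quintile > 5)
  if (length(bad))
    stop("ordinal values out of range at rows ",
         paste(head(bad, 10), collapse = ", "))
  bad <- which(tab$total_ltcs != rowSums(tab[fa_ltc_flags()]))
  if (length(bad))
    stop("total_ltcs does not equal the sum of LTC flags at rows ",
         paste(head(bad, 10), collapse = ", "))
  structure(tab, class = c("fa_cohort", "data.frame"))
}

#' Assemble a pipeline configuration
#'
#' @param generator A [cohort_config()] or a path to a cohort CSV.
#' @param exclusions Columns dropped before modelling.
#' @param test_fraction,split_seed,stratified Train/test split controls.
#' @param families Model families to fit (default all five).
#' @param fit_seed Seed forwarded to every model fit.
#' @param explain_method,explain_cohorts,threshold,n_permutations,explain_seed
#'   Risk-factor stage controls.
#' @param output_dir Directory for the run outputs (created if needed).
#' @return List of class `fa_pipeline_config`.
#' @export
pipeline_config <- function(generator = cohort_config(),
                            exclusions = c("sparra_score", "local_authority"),
                            test_fraction = 0.30, split_seed = 1L,
                            stratified = FALSE,
                            families = fa_families, fit_seed = 1L,
                            explain_method = "zero_input",
                            explain_cohorts = c("low_mid", "high"),
                            threshold = 0.01, n_permutations = 100L,
                            explain_seed = 1L,
                            output_dir = tempfile("fa_run_")) {
  stopifnot(length(families) >= 1, all(families %in% fa_families))
  structure(list(generator = generator, exclusions = exclusions,
                 test_fraction = test_fraction, split_seed = split_seed,
                 stratified = stratified, families = families,
                 fit_seed = fit_seed, explain_method = explain_method,
                 explain_cohorts = explain_cohorts, threshold = threshold,
                 n_permutations = n_permutations,
                 explain_seed = explain_seed, output_dir = output_dir),
            class = "fa_pipeline_config")
}

#' Run the full attendance-modelling pipeline
#'
#' Executes generate/load, pre-processing, model fitting for every
#' configured family, test-set evaluation, and cohort-targeted risk-factor
#' identification, writing all reports to the configured output directory:
#' the cohort CSV, a split manifest (JSON), one evaluation JSON per model,
#' a combined confusion-matrix CSV (models stacked within actual-class
#' blocks), a metrics CSV (precision/recall/F1/AUC per model), one
#' risk-factor CSV per model and cohort, and a run manifest recording
#' seeds and configuration. Any stage failure aborts with the stage name;
#' outputs written before the failure are retained alongside a
#' `FAILED_<stage>` marker file.
#'
#' @param config An [pipeline_config()].
#' @return The run manifest (list), invisibly.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "fa_pipeline_config"))
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      file.create(file.path(out, paste0("FAILED_", name)))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  cohort <- stage("generate", {
    if (is.character(config$generator)) load_cohort(config$generator)
    else generate_cohort(config$generator)
  })
  write_cohort_csv(cohort, file.path(out, "cohort.csv"))

  prep <- stage("prep", {
    tab <- drop_excluded_variables(as.data.frame(cohort),
                                   config$exclusions)
    sp <- split_train_test(tab, config$test_fraction, config$split_seed,
                           config$stratified)
    jsonlite::write_json(
      list(seed = config$split_seed, test_fraction = config$test_fraction,
           stratified = config$stratified, test_idx = sp$test_idx),
      file.path(out, "split.json"), auto_unbox = TRUE, digits = NA)
    sp
  })
  feat <- setdiff(names(prep$train), "ae_attendances")
  y_tr <- bin_attendance(prep$train$ae_attendances)
  y_te <- bin_attendance(prep$test$ae_attendances)

  models <- list(); evals <- list()
  for (fam in config$families) {
    models[[fam]] <- stage(paste0("fit_", fam), {
      fa_fit(model_spec(fam), prep$train[feat], y_tr,
             visits = prep$train$ae_attendances, seed = config$fit_seed)
    })
    evals[[fam]] <- stage(paste0("evaluate_", fam), {
      ev <- evaluate_model(y_te, predict(models[[fam]], prep$test[feat]))
      write_eval_json(ev, file.path(out, paste0("eval_", fam, ".json")))
      ev
    })
  }

  stage("report", {
    conf <- do.call(rbind, lapply(names(evals), function(fam) {
      m <- evals[[fam]]$confusion
      data.frame(actual = rep(c("low", "mid", "high"), each = 1),
                 model = fam, predicted_low = m[, 1], predicted_mid = m[, 2],
                 predicted_high = m[, 3], total = rowSums(m))
    }))
    conf <- conf[order(match(conf$actual, c("low", "mid", "high"))), ]
    write.csv(conf, file.path(out, "confusion_combined.csv"),
              row.names = FALSE)
    metrics <- do.call(rbind, lapply(names(evals), function(fam) {
      ev <- evals[[fam]]
      data.frame(model = fam,
                 precision = ev$metrics$weighted["precision"],
                 recall = ev$metrics$weighted["recall"],
                 f1_weighted = ev$metrics$weighted["f1"],
                 f1_macro = ev$metrics$macro["f1"],
                 auc_macro = ev$auc_macro)
    }))
    write.csv(metrics, file.path(out, "metrics.csv"), row.names = FALSE)
  })

  risk <- list()
  for (fam in config$families) {
    for (ch in config$explain_cohorts) {
      key <- paste(fam, ch, sep = "_")
      risk[[key]] <- stage(paste0("explain_", key), {
        rf <- cohort_risk_factors(models[[fam]], as.data.frame(cohort),
                                  cohort = ch,
                                  method = config$explain_method,
                                  threshold = config$threshold,
                                  n_permutations = config$n_permutations,
                                  seed = config$explain_seed)
        write.csv(cbind(rf$table, method = rf$method, model = fam,
                        cohort = ch),
                  file.path(out, paste0("risk_factors_", key, ".csv")),
                  row.names = FALSE)
        rf
      })
    }
  }

  manifest <- list(
    n_patients = nrow(cohort),
    families = config$families,
    seeds = list(generator = if (is.character(config$generator)) NULL
                 else config$generator$seed,
                 split = config$split_seed, fit = config$fit_seed,
                 explain = config$explain_seed),
    test_fraction = config$test_fraction,
    explain = list(method = config$explain_method,
                   cohorts = config$explain_cohorts,
                   threshold = config$threshold),
    outputs = list.files(out),
    package_version = as.character(utils::packageVersion("facohort")))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, models = models, evals = evals,
                 risk_factors = risk, output_dir = out))
}
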