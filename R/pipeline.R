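#' Configuration of a full model-comparison study
#'
#' Bundles everything [run_study()] needs: the cohort source (a
#' [cohort_spec()] for synthesis, or a CSV path), the model registry, the
#' imputation, cross-validation and bootstrap sizes, the operating
#' specificity, the prevalence grid for rescaled predictive values, and one
#' master seed from which every stage's seed is derived deterministically.
#'
#' @param cohort A [cohort_spec()] or a path to a cohort CSV.
#' @param registry Named list of fitted-model covariate sets.
#' @param comparators Score ROMA and RMI-mod alongside the fitted models.
#' @param m Number of imputations.
#' @param imputation_iterations Chained-equation iterations per chain.
#' @param k Cross-validation folds.
#' @param stratified Stratify folds by outcome.
#' @param n_boot Bootstrap resamples for confidence intervals.
#' @param target_specificity Operating specificity.
#' @param prevalences Extra prevalences at which PPV/NPV are rescaled (the
#'   cohort's own prevalence is always included).
#' @param missing_volume_rate,missing_morphology_rate MCAR rates applied to
#'   a synthetic cohort (`NULL` = take them from the spec); ignored for CSV
#'   cohorts, which carry their own missingness.
#' @param seed Master seed.
#' @param out_dir Optional directory; when given, [run_study()] writes CSV
#'   and JSON reports plus a run manifest there.
#' @return An object of class `study_config`.
#' @export
study_config <- function(cohort = cohort_spec(),
                         registry = model_registry(),
                         comparators = TRUE,
                         m = 20L, imputation_iterations = 10L,
                         k = 10L, stratified = TRUE,
                         n_boot = 5000L,
                         target_specificity = 0.9,
                         prevalences = c(0.10, 0.15),
                         missing_volume_rate = NULL,
                         missing_morphology_rate = NULL,
                         seed = 1L, out_dir = NULL) {
  stopifnot(inherits(cohort, "cohort_spec") ||
              (is.character(cohort) && length(cohort) == 1))
  structure(
    list(cohort = cohort, registry = registry, comparators = comparators,
         m = as.integer(m),
         imputation_iterations = as.integer(imputation_iterations),
         k = as.integer(k), stratified = stratified,
         n_boot = as.integer(n_boot),
         target_specificity = target_specificity,
         prevalences = prevalences,
         missing_volume_rate = missing_volume_rate,
         missing_morphology_rate = missing_morphology_rate,
         seed = as.integer(seed), out_dir = out_dir),
    class = "study_config"
  )
}

#' Run the full model-construction and comparison study
#'
#' Orchestrates the pipeline end to end: generate (or read) the cohort,
#' build features, multiply impute the missing ultrasound variables,
#' cross-validate every registered Firth model over all imputations, score
#' the published comparators, and evaluate everything — the per-model
#' accuracy table, the subtype detection breakdown, paired DeLong/McNemar
#' comparisons against the full model, prevalence-rescaled predictive
#' values, and the Rubin-pooled full-data coefficients. Deterministic given
#' the master seed.
#'
#' @param config A [study_config()].
#' @return An object of class `study_result`: a list with `metrics`,
#'   `subtype_breakdown`, `comparisons`, `prevalence_pv`, `coefficients`,
#'   `predictions`, `cohort`, `config`. If `config$out_dir` is set the
#'   reports are also written as CSV/JSON with a run manifest.
#' @examples
#' \donttest{
#' cfg <- study_config(cohort = cohort_spec(n_subjects = 300, seed = 4),
#'                     m = 2, imputation_iterations = 2, k = 5,
#'                     n_boot = 50, seed = 4)
#' res <- run_study(cfg)
#' res$metrics
#' }
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  seed <- config$seed

  # --- cohort ---------------------------------------------------------
  if (inherits(config$cohort, "cohort_spec")) {
    spec <- config$cohort
    cohort <- generate_cohort(spec, seed = derive_seed(seed, 11L))
    vol_rate <- config$missing_volume_rate %||% spec$missing_volume_rate
    morph_rate <- config$missing_morphology_rate %||%
      spec$missing_morphology_rate
    cohort <- apply_missingness(cohort, vol_rate, morph_rate,
                                seed = derive_seed(seed, 12L))
  } else {
    cohort <- read_cohort(config$cohort)
  }
  if (sum(cohort$outcome) < 2) {
    abort("Stage cohort: fewer than two cases; the study cannot proceed.")
  }

  # --- features and imputation ---------------------------------------
  features <- build_features(cohort)
  imputation_set <- impute_cohort(
    features, m = config$m, iterations = config$imputation_iterations,
    seed = derive_seed(seed, 13L)
  )

  # --- cross-validated predictions -----------------------------------
  folds <- assign_folds(features$outcome, k = config$k,
                        stratified = config$stratified,
                        seed = derive_seed(seed, 14L))
  predictions <- cv_risk_models(imputation_set, folds,
                                registry = config$registry,
                                comparators = config$comparators)

  # --- full-data pooled coefficients ---------------------------------
  coefficients <- purrr::imap_dfr(config$registry, function(covs, nm) {
    fit <- fit_full_data(imputation_set, covs)
    dplyr::mutate(tidy(fit), model = nm, .before = 1)
  })

  # --- evaluation -----------------------------------------------------
  model_cols <- c(names(config$registry),
                  if (config$comparators) c("roma", "rmi_mod"))
  metrics <- evaluate_models(
    predictions, models = model_cols,
    target_specificity = config$target_specificity,
    n_boot = config$n_boot, seed = derive_seed(seed, 15L)
  )
  comparisons <- compare_models(
    predictions, reference = model_cols[1], models = model_cols[-1],
    target_specificity = config$target_specificity
  )

  cases <- dplyr::filter(predictions, .data$outcome == 1)
  breakdown <- purrr::map_dfr(model_cols, function(col) {
    cut <- cutoff_at_specificity(predictions[[col]], predictions$outcome,
                                 config$target_specificity)$cutoff
    dplyr::mutate(
      sensitivity_breakdown(cases[[col]] >= cut, cases$subtype),
      model = col, .before = 1
    )
  })

  prevalence_grid <- c(cohort = mean(predictions$outcome),
                       setNames(config$prevalences,
                                paste0("prev_", config$prevalences)))
  prevalence_pv <- purrr::map_dfr(model_cols, function(col) {
    row <- metrics[metrics$model == col, ]
    purrr::imap_dfr(prevalence_grid, function(prev, nm) {
      pv <- predictive_values_at_prevalence(
        row$sensitivity, config$target_specificity, prev)
      tibble::tibble(model = col, prevalence_label = nm, prevalence = prev,
                     ppv = pv$ppv, npv = pv$npv)
    })
  })

  result <- structure(
    list(metrics = metrics, subtype_breakdown = breakdown,
         comparisons = comparisons, prevalence_pv = prevalence_pv,
         coefficients = coefficients, predictions = predictions,
         cohort = cohort, config = config),
    class = "study_result"
  )
  if (!is.null(config$out_dir)) write_study_result(result, config$out_dir)
  result
}

#' Write the reports of a study run
#'
#' Emits the accuracy table, subtype breakdown, paired comparisons,
#' prevalence-rescaled predictive values and pooled coefficients as CSV
#' with JSON twins, the out-of-fold predictions as CSV, and a
#' `manifest.json` echoing the configuration and seeds.
#'
#' @param result A `study_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_result <- function(result, dir) {
  stopifnot(inherits(result, "study_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tables <- list(
    metrics = result$metrics,
    subtype_breakdown = result$subtype_breakdown,
    comparisons = result$comparisons,
    prevalence_pv = result$prevalence_pv,
    coefficients = result$coefficients,
    predictions = result$predictions
  )
  for (nm in names(tables)) {
    readr::write_csv(tables[[nm]], file.path(dir, paste0(nm, ".csv")),
                     na = "")
    if (nm != "predictions") {
      jsonlite::write_json(tables[[nm]], file.path(dir, paste0(nm, ".json")),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  }
  cfg <- result$config
  manifest <- list(
    seed = cfg$seed, m = cfg$m, k = cfg$k, n_boot = cfg$n_boot,
    target_specificity = cfg$target_specificity,
    prevalences = cfg$prevalences,
    models = names(cfg$registry),
    comparators = cfg$comparators,
    n_subjects = nrow(result$cohort),
    n_cases = sum(result$cohort$outcome),
    cohort_source = if (inherits(cfg$cohort, "cohort_spec")) "synthetic"
    else cfg$cohort
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf(
    "Study run: %d subjects (%d cases), %d model(s), m = %d, k = %d\n",
    nrow(x$cohort), sum(x$cohort$outcome), nrow(x$metrics), x$config$m,
    x$config$k))
  print(dplyr::select(x$metrics, "model", "sensitivity", "auc", "ppv",
                      "npv", "brier"))
  invisible(x)
}

#' @rdname run_study
#' @param x A `study_result`.
#' @param ... Unused.
#' @export
tidy.study_result <- function(x, ...) x$metrics

#' @rdname run_study
#' @export
glance.study_result <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$cohort), n_cases = sum(x$cohort$outcome),
    n_models = nrow(x$metrics), m = x$config$m, k = x$config$k,
    n_boot = x$config$n_boot, seed = x$config$seed
  )
}
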