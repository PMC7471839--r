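#' Registry of model covariate sets
#'
#' The seven fitted models compared in the analysis, all adjusted for age:
#' the full model (ultrasound + CA125 + HE4) and its subsets. Ultrasound
#' features are solid component, locularity, ascites volume and log
#' dominant volume. The two published comparators (ROMA, RMI-mod) bypass
#' fitting and are scored directly.
#'
#' @return A named list of covariate character vectors, in the reporting
#'   order of the study.
#' @examples
#' names(model_registry())
#' @export
model_registry <- function() {
  us <- c("solid_component", "locularity", "ascites_ml",
          "log_dominant_volume")
  list(
    us_ca125_he4 = c("age", us, "log_ca125", "log_he4"),
    us_ca125 = c("age", us, "log_ca125"),
    ca125_he4 = c("age", "log_ca125", "log_he4"),
    us_he4 = c("age", us, "log_he4"),
    ca125 = c("age", "log_ca125"),
    he4 = c("age", "log_he4"),
    us = c("age", us)
  )
}

model_formula <- function(covariates) {
  stats::reformulate(covariates, response = "outcome")
}

# Design matrix with the package's fixed factor codings, so every fold and
# imputation shares identical columns.
design_matrix <- function(tab, covariates) {
  mf <- stats::model.frame(stats::reformulate(covariates),
                           data = prepare_model_data(tab),
                           na.action = stats::na.fail)
  model.matrix(attr(mf, "terms"), mf)
}

# Fit on a row subset, dropping indicator columns that are identically zero
# there (a factor level unseen in the subset); their coefficients are fixed
# at zero, i.e. the unseen level is treated as reference.
fit_firth_subset <- function(x_list, y, rows, ...) {
  keep <- rep(TRUE, ncol(x_list[[1]]))
  for (x in x_list) {
    keep <- keep & colSums(abs(x[rows, , drop = FALSE])) > 0
  }
  fits <- lapply(x_list, function(x) {
    fit_firth(x[rows, keep, drop = FALSE], y[rows], ...)
  })
  beta <- if (length(fits) == 1L) fits[[1]]$coefficients else
    pool_rubin(fits)$estimates
  full <- setNames(numeric(ncol(x_list[[1]])), colnames(x_list[[1]]))
  full[keep] <- beta
  list(beta = full, fits = fits, dropped = colnames(x_list[[1]])[!keep])
}

#' Assign cross-validation folds
#'
#' Partitions subjects into `k` folds whose sizes differ by at most one;
#' with `stratified = TRUE` (the default) the cases are spread so per-fold
#' case counts also differ by at most one — essential with 78 cases over 10
#' folds. The assignment is keyed to the order of `outcomes` after seeding,
#' so a fixed seed gives a fixed assignment.
#'
#' @param outcomes Binary outcome vector.
#' @param k Number of folds; must not exceed the number of subjects.
#' @param stratified Balance case counts across folds.
#' @param seed Integer seed.
#' @return Integer vector of fold indices in `1..k`.
#' @examples
#' table(assign_folds(rbinom(100, 1, 0.1), k = 10, seed = 1))
#' @export
assign_folds <- function(outcomes, k, stratified = TRUE, seed = 1L) {
  n <- length(outcomes)
  k <- as.integer(k)
  if (k < 1 || k > n) abort("`k` must be between 1 and the number of subjects.")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  folds <- integer(n)
  if (stratified && length(unique(outcomes)) == 2L) {
    cases <- which(outcomes == max(outcomes))
    controls <- which(outcomes != max(outcomes))
    rc <- length(cases) %% k
    rn <- length(controls) %% k
    # place the "+1" folds of the two strata so that total fold sizes
    # still differ by at most one
    extra_case <- sample.int(k, rc)
    pool <- setdiff(seq_len(k), extra_case)
    extra_ctrl <- if (rn <= length(pool)) {
      pool[sample.int(length(pool), rn)]
    } else {
      c(pool, extra_case[sample.int(length(extra_case), rn - length(pool))])
    }
    assign_stratum <- function(idx, extra) {
      sizes <- rep(length(idx) %/% k, k)
      sizes[extra] <- sizes[extra] + 1L
      folds[idx[sample.int(length(idx))]] <<- rep(seq_len(k), times = sizes)
    }
    assign_stratum(cases, extra_case)
    assign_stratum(controls, extra_ctrl)
  } else {
    folds[sample.int(n)] <- rep(seq_len(k), length.out = n)
  }
  folds
}

#' Pooled Firth fit over all imputations
#'
#' Fits the Firth logistic model on every completed table and combines the
#' coefficients by Rubin's Rules. This is the model whose coefficients are
#' reported; out-of-sample performance comes from [cv_predict_mi()].
#'
#' @param imputation_set An [impute_cohort()] result.
#' @param covariates Character vector of covariate names (see
#'   [model_registry()]).
#' @param subset Optional row index restricting the fit (used by the CV
#'   loop).
#' @return A [pool_rubin()] `pooled_fit`; for `m = 1` the single
#'   `firth_fit` is returned unpooled.
#' @export
fit_full_data <- function(imputation_set, covariates, subset = NULL) {
  stopifnot(inherits(imputation_set, "imputation_set"))
  tables <- imputation_set$imputations
  x_list <- lapply(tables, design_matrix, covariates = covariates)
  y <- tables[[1]]$outcome
  rows <- subset %||% seq_along(y)
  if (sum(y[rows]) == 0) {
    warn("The analysis set contains no cases; the Firth fit tolerates this.")
  }
  fit <- fit_firth_subset(x_list, y, rows)
  if (length(fit$dropped) > 0) {
    warn(sprintf("Factor level(s) unseen in the data, coefficient fixed at 0: %s.",
                 paste(fit$dropped, collapse = ", ")))
  }
  if (length(fit$fits) == 1L) return(fit$fits[[1]])
  pool_rubin(fit$fits)
}

#' Out-of-fold risks under multiple imputation
#'
#' For each fold: the Firth model is fitted on the other k-1 folds within
#' every completed table, the per-imputation coefficients are pooled by
#' Rubin's Rules, the pooled coefficients are applied to each completed
#' version of the held-out subjects, and the resulting risks are averaged
#' across imputations (on the probability scale by default, on the linear
#' predictor scale with `average = "linear"`). No subject's prediction ever
#' uses a fit that saw its own fold.
#'
#' @inheritParams fit_full_data
#' @param folds Integer fold assignment from [assign_folds()].
#' @param average `"probability"` or `"linear"`.
#' @return A tibble `subject_id`, `fold`, `risk`.
#' @export
cv_predict_mi <- function(imputation_set, covariates, folds,
                          average = c("probability", "linear")) {
  stopifnot(inherits(imputation_set, "imputation_set"))
  average <- match.arg(average)
  tables <- imputation_set$imputations
  n <- nrow(tables[[1]])
  if (length(folds) != n) abort("`folds` must cover every subject.")
  x_list <- lapply(tables, design_matrix, covariates = covariates)
  y <- tables[[1]]$outcome
  risk <- numeric(n)
  for (f in sort(unique(folds))) {
    train <- which(folds != f)
    test <- which(folds == f)
    if (sum(y[train]) == 0) {
      warn(sprintf("Training data for fold %d contains no cases.", f))
    }
    fit <- fit_firth_subset(x_list, y, train)
    per_imp <- vapply(x_list, function(x) {
      eta <- drop(x[test, , drop = FALSE] %*% fit$beta)
      if (average == "probability") plogis(eta) else eta
    }, numeric(length(test)))
    per_imp <- matrix(per_imp, nrow = length(test))
    avg <- rowMeans(per_imp)
    risk[test] <- if (average == "probability") avg else plogis(avg)
  }
  tibble::tibble(
    subject_id = tables[[1]]$subject_id %||% as.character(seq_len(n)),
    fold = as.integer(folds),
    risk = risk
  )
}

#' Cross-validated risks for every registered model
#'
#' Runs [cv_predict_mi()] for each fitted model in the registry and scores
#' the two published comparators directly (averaging the RMI-mod score over
#' imputations where morphology was imputed; ROMA depends only on the
#' always-observed markers). Returns one wide tibble of out-of-fold risks.
#'
#' @inheritParams cv_predict_mi
#' @param registry Named list of covariate sets, default [model_registry()].
#' @param comparators Include `roma` and `rmi_mod` columns.
#' @return A tibble: `subject_id`, `fold`, `outcome`, `subtype`, one risk
#'   column per model.
#' @export
cv_risk_models <- function(imputation_set, folds,
                           registry = model_registry(),
                           comparators = TRUE,
                           average = "probability") {
  first <- imputation_set$imputations[[1]]
  out <- tibble::tibble(
    subject_id = first$subject_id,
    fold = as.integer(folds),
    outcome = first$outcome,
    subtype = first$subtype %||% NA_character_
  )
  for (nm in names(registry)) {
    out[[nm]] <- cv_predict_mi(imputation_set, registry[[nm]], folds,
                               average = average)$risk
  }
  if (comparators) {
    scored <- lapply(imputation_set$imputations,
                     function(tab) score_cohort(tab))
    out$roma <- scored[[1]]$roma
    out$rmi_mod <- rowMeans(
      vapply(scored, function(s) s$rmi_mod, numeric(nrow(first))))
  }
  out
}
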