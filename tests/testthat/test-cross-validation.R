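test_that("fold assignment balances sizes and case counts", {
  set.seed(1)
  f <- assign_folds(rbinom(100, 1, 0.2), k = 10, seed = 1)
  expect_true(all(table(f) == 10))

  # the cohort's configuration: 78 cases over 10 stratified folds
  y <- c(rep(1, 78), rep(0, 1512))
  f2 <- assign_folds(y, k = 10, stratified = TRUE, seed = 2)
  per_fold_cases <- tapply(y, f2, sum)
  expect_true(all(per_fold_cases %in% c(7, 8)))
  sizes <- table(f2)
  expect_lte(max(sizes) - min(sizes), 1)

  expect_identical(assign_folds(y, 10, seed = 9), assign_folds(y, 10, seed = 9))
  expect_false(identical(assign_folds(y, 10, seed = 9),
                         assign_folds(y, 10, seed = 10)))
  expect_error(assign_folds(c(0, 1), k = 5), "between 1 and")
})

test_that("with one imputation and no missing data CV reduces to plain k-fold", {
  fe <- build_features(small_cohort(n = 250, seed = 14, volume_rate = 0,
                                    morphology_rate = 0))
  set <- impute_cohort(fe, m = 1, iterations = 1, seed = 1)
  folds <- assign_folds(fe$outcome, k = 5, seed = 3)
  covs <- c("age", "log_ca125")
  cv <- cv_predict_mi(set, covs, folds)

  manual <- numeric(nrow(fe))
  for (f in 1:5) {
    fit <- firth_logit(fe[folds != f, ], outcome ~ age + log_ca125)
    manual[folds == f] <- predict(fit, fe[folds == f, ])
  }
  expect_equal(cv$risk, manual, tolerance = 1e-10)

  # multiple identical imputations change nothing for observed subjects
  set3 <- impute_cohort(fe, m = 3, iterations = 1, seed = 1)
  cv3 <- cv_predict_mi(set3, covs, folds)
  expect_equal(cv3$risk, cv$risk, tolerance = 1e-10)
})

test_that("every subject gets exactly one out-of-fold prediction", {
  fe <- build_features(small_cohort(n = 200, seed = 6))
  set <- impute_cohort(fe, m = 2, iterations = 2, seed = 2)
  folds <- assign_folds(fe$outcome, k = 4, seed = 4)
  pr <- cv_risk_models(set, folds,
                       registry = model_registry()[c("us_ca125", "ca125")])
  expect_equal(nrow(pr), nrow(fe))
  expect_equal(sort(unique(pr$fold)), 1:4)
  expect_false(anyNA(pr$us_ca125))
  expect_true(all(pr$us_ca125 > 0 & pr$us_ca125 < 1))
  expect_false(anyNA(pr$roma))
  expect_false(anyNA(pr$rmi_mod))
})

test_that("cross-validated AUC does not exceed apparent AUC on average", {
  set.seed(20)
  cv_aucs <- apparent_aucs <- numeric(60)
  for (i in seq_along(cv_aucs)) {
    sim <- simulate_logistic(150, c(-1.5, 0.6, 0.4), seed = 5000 + i)
    df <- tibble::tibble(subject_id = as.character(1:150),
                         outcome = sim$y, x1 = sim$x[, 2], x2 = sim$x[, 3])
    if (sum(df$outcome) < 10) next
    set <- chained_impute(df, m = 1, iterations = 1,
                          seed = i, exclude = "subject_id")
    set$imputations <- list(df)
    folds <- assign_folds(df$outcome, k = 5, seed = i)
    cv <- cv_predict_mi(set, c("x1", "x2"), folds)
    fit <- firth_logit(df, outcome ~ x1 + x2)
    cv_aucs[i] <- roc_auc(cv$risk, df$outcome)
    apparent_aucs[i] <- roc_auc(predict(fit, df), df$outcome)
  }
  keep <- cv_aucs > 0
  expect_lte(mean(cv_aucs[keep]), mean(apparent_aucs[keep]))
})

test_that("full-data pooled fit reduces and recovers correctly", {
  fe <- build_features(small_cohort(n = 300, seed = 18, volume_rate = 0,
                                    morphology_rate = 0))
  set1 <- impute_cohort(fe, m = 1, iterations = 1, seed = 1)
  single <- fit_full_data(set1, c("age", "log_ca125"))
  direct <- firth_logit(fe, outcome ~ age + log_ca125)
  expect_equal(coef(single), coef(direct), tolerance = 1e-10)

  # pooled over imputations on genuinely missing data: Rubin identity holds
  fe_miss <- build_features(small_cohort(n = 300, seed = 18,
                                         volume_rate = 0.2,
                                         morphology_rate = 0.1))
  set3 <- impute_cohort(fe_miss, m = 3, iterations = 3, seed = 2)
  pooled <- fit_full_data(set3, c("age", "log_ca125",
                                  "log_dominant_volume"))
  expect_s3_class(pooled, "pooled_fit")
  expect_true(all(pooled$t >= pooled$ubar))

  # parameter recovery from a large simulated logistic cohort
  sim <- simulate_logistic(5000, c(-2.5, 0.9, -0.4), seed = 77)
  df <- tibble::tibble(outcome = sim$y, x1 = sim$x[, 2], x2 = sim$x[, 3])
  fit <- firth_logit(df, outcome ~ x1 + x2)
  se <- sqrt(diag(vcov(fit)))
  expect_true(all(abs(coef(fit) - c(-2.5, 0.9, -0.4)) < 3 * se))
})

test_that("model registry mirrors the study's eight comparisons", {
  reg <- model_registry()
  expect_named(reg, c("us_ca125_he4", "us_ca125", "ca125_he4", "us_he4",
                      "ca125", "he4", "us"))
  # every fitted model is adjusted for age
  expect_true(all(vapply(reg, function(v) "age" %in% v, logical(1))))
  expect_true(all(c("log_ca125", "log_he4") %in% reg$us_ca125_he4))
  expect_false("log_he4" %in% reg$us_ca125)
})
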