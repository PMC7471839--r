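test_that("AUC is the Mann-Whitney pair statistic", {
  expect_equal(roc_auc(rep(0.4, 10), rep(c(1, 0), 5)), 0.5)
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  # cases {0.9, 0.4}, noncases {0.5, 0.1}: 3 of 4 pairs ordered
  expect_equal(roc_auc(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_error(roc_auc(1:4, rep(1, 4)), "one case and one noncase")

  # invariance under strictly monotone transforms; agreement with pROC
  set.seed(2)
  r <- runif(60)
  y <- rbinom(60, 1, 0.4)
  expect_equal(roc_auc(r, y), roc_auc(qlogis(r), y))
  expect_equal(roc_auc(r, y), roc_auc(r^3, y))
  expect_equal(
    roc_auc(r, y),
    as.numeric(pROC::auc(pROC::roc(y, r, quiet = TRUE, levels = c(0, 1),
                                   direction = "<")))
  )
})

test_that("DeLong variance equals the delete-one jackknife oracle", {
  set.seed(42)
  y <- rep(c(1, 0), each = 10)
  ra <- runif(20)
  rb <- runif(20)
  dl <- delong_test(ra, rb, y)

  theta <- function(yy, a, b) roc_auc(a, yy) - roc_auc(b, yy)
  jk <- 0
  for (cls in c(1, 0)) {
    idx <- which(y == cls)
    m <- length(idx)
    th <- vapply(idx, function(i) theta(y[-i], ra[-i], rb[-i]), numeric(1))
    jk <- jk + (m - 1) / m * sum((th - mean(th))^2)
  }
  expect_equal(dl$variance, jk, tolerance = 1e-8)

  # identical scores: no difference, p = 1
  same <- delong_test(ra, ra, y)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)

  # agreement with the independent pROC implementation
  tt <- pROC::roc.test(pROC::roc(y, ra, quiet = TRUE),
                       pROC::roc(y, rb, quiet = TRUE),
                       method = "delong", paired = TRUE)
  expect_equal(dl$z, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(dl$p, tt$p.value, tolerance = 1e-10)
})

test_that("operating cutoff implements the specificity floor rule", {
  op <- cutoff_at_specificity(runif(1590), c(rep(1, 78), rep(0, 1512)), 0.9)
  expect_equal(op$fp_allowed, 151)

  # all noncase risks zero: cutoff above zero, no false positives
  r <- c(0.3, 0.6, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0)
  y <- c(1, 1, rep(0, 10))
  op2 <- cutoff_at_specificity(r, y, 0.9)
  expect_gt(op2$cutoff, 0)
  expect_equal(op2$fp, 0L)

  # N_neg = 10, target 0.90: exactly one false positive allowed
  set.seed(4)
  r3 <- runif(12)
  y3 <- c(1, 1, rep(0, 10))
  op3 <- cutoff_at_specificity(r3, y3, 0.9)
  expect_equal(op3$fp_allowed, 1)
  expect_lte(op3$fp, 1)
  # specificity at the returned cutoff is at or above target
  spec <- mean(r3[y3 == 0] < op3$cutoff)
  expect_gte(spec, 0.9)

  expect_error(cutoff_at_specificity(r3, y3, 1.2), "inside")
})

test_that("sensitivity at a cutoff counts detected cases", {
  risks <- c(runif(59, 0.6, 1), runif(19, 0, 0.4))
  out <- rep(1, 78)
  risks <- c(risks, runif(10, 0, 0.4))
  out <- c(out, rep(0, 10))
  s <- sensitivity_at_cutoff(risks, out, 0.5)
  expect_equal(s$tp, 59)
  expect_equal(s$sensitivity, 59 / 78)
  expect_equal(round(100 * s$sensitivity, 1), 75.6)
  expect_equal(sensitivity_at_cutoff(risks, out, -Inf)$sensitivity, 1)
  expect_equal(sensitivity_at_cutoff(risks, out, 2)$sensitivity, 0)
  expect_error(sensitivity_at_cutoff(1, 0, 0.5), "case")
})

test_that("McNemar test switches between exact and corrected chi-square", {
  expect_equal(mcnemar_paired(c(1, 1, 0), c(1, 1, 0)), 1)
  # b = 10, c = 0: exact two-sided binomial tail
  a <- c(rep(1, 10), rep(1, 5))
  b <- c(rep(0, 10), rep(1, 5))
  expect_equal(mcnemar_paired(a, b), 2 * 0.5^10, tolerance = 1e-10)
  # symmetric discordance: p = 1 under the exact test
  a2 <- c(1, 1, 0, 0, 1)
  b2 <- c(0, 0, 1, 1, 1)
  expect_equal(mcnemar_paired(a2, b2), 1)
  # above the exact threshold: agrees with stats::mcnemar.test
  set.seed(9)
  a3 <- rbinom(200, 1, 0.5)
  b3 <- rbinom(200, 1, 0.5)
  expect_equal(
    mcnemar_paired(a3, b3),
    mcnemar.test(table(factor(a3, 0:1), factor(b3, 0:1)))$p.value
  )
})

test_that("predictive values reproduce the published operating point", {
  pv <- predictive_values(59, 151, 19, 1361)
  expect_equal(round(100 * pv$ppv, 1), 28.1)
  expect_equal(round(100 * pv$npv, 1), 98.6)
  expect_equal(pv$nnt, 1 / pv$ppv)

  expect_true(is.na(predictive_values(0, 0, 5, 10)$ppv))
  perfect <- predictive_values(10, 0, 0, 90)
  expect_equal(perfect$ppv, 1)
  expect_equal(perfect$npv, 1)
  expect_equal(perfect$nnt, 1)
})

test_that("prevalence rescaling follows the Bayes form", {
  # consistency with the count-based value at the cohort prevalence
  pv <- predictive_values_at_prevalence(59 / 78, 1361 / 1512, 78 / 1590)
  expect_equal(pv$ppv, 59 / 210, tolerance = 1e-12)
  expect_equal(pv$npv, 1361 / 1380, tolerance = 1e-12)

  expect_equal(predictive_values_at_prevalence(0.7, 0.9, 0)$npv, 1)
  expect_equal(
    round(100 * predictive_values_at_prevalence(0.756, 0.90, 0.10)$ppv, 1),
    45.7
  )
})

test_that("Brier score is the mean squared error", {
  expect_equal(brier_score(c(0, 1, 1), c(0, 1, 1)), 0)
  expect_equal(brier_score(rep(0.5, 8), rbinom(8, 1, 0.5)), 0.25)
  expect_equal(brier_score(c(0.2, 0.8), c(0, 1)), 0.04)
  expect_error(brier_score(c(-0.1, 0.5), c(0, 1)), "\\[0, 1\\]")
})

test_that("Hosmer-Lemeshow matches hand arithmetic on a two-group toy", {
  risks <- c(rep(0.1, 10), rep(0.9, 10))
  out <- c(rep(0, 9), 1, rep(1, 8), rep(0, 2))
  hl <- hosmer_lemeshow(risks, out, groups = 2)
  # group 1: O1=1, E1=1, O0=9, E0=9; group 2: O1=8, E1=9, O0=2, E0=1
  manual <- (1 - 1)^2 / 1 + (9 - 9)^2 / 9 + (8 - 9)^2 / 9 + (2 - 1)^2 / 1
  expect_equal(hl$chi2, manual, tolerance = 1e-10)

  # observed equal expected in every group: zero statistic, p = 1
  out2 <- c(rep(0, 9), 1, rep(1, 9), 0)
  hl2 <- hosmer_lemeshow(risks, out2, groups = 2)
  expect_equal(hl2$chi2, 0)
  expect_equal(hl2$p, 1)

  expect_error(hosmer_lemeshow(runif(5), rbinom(5, 1, 0.5), groups = 10),
               "at least as many")
})

test_that("bias-corrected bootstrap behaves at its anchor cases", {
  # degenerate data: zero-width interval
  d <- data.frame(x = rep(2.5, 30))
  ci <- bootstrap_bc_ci(d, function(df) mean(df$x), n_boot = 100, seed = 1)
  expect_equal(ci$lower, 2.5)
  expect_equal(ci$upper, 2.5)

  # Gaussian mean: endpoints near the analytic t-interval
  set.seed(55)
  d2 <- data.frame(x = rnorm(500, mean = 10, sd = 2))
  ci2 <- bootstrap_bc_ci(d2, function(df) mean(df$x), n_boot = 2000,
                         seed = 7)
  t_half <- qt(0.975, 499) * sd(d2$x) / sqrt(500)
  expect_equal(ci2$upper - ci2$lower, 2 * t_half, tolerance = 0.05)
  expect_equal(mean(c(ci2$lower, ci2$upper)), mean(d2$x), tolerance = 0.005)

  # z0 near zero reduces to the plain percentile interval
  expect_lt(abs(ci2$z0), 0.1)

  # determinism
  ci3 <- bootstrap_bc_ci(d2, function(df) mean(df$x), n_boot = 2000,
                         seed = 7)
  expect_identical(ci2, ci3)
})

test_that("subtype breakdown partitions the detected cancers", {
  subtypes <- c(rep("invasive_type1", 14), rep("invasive_type2", 34),
                rep("borderline", 24), rep("nonepithelial", 6))
  detected <- c(rep(TRUE, 11), rep(FALSE, 3),   # type I: 11/14
                rep(TRUE, 32), rep(FALSE, 2),   # type II: 32/34
                rep(TRUE, 14), rep(FALSE, 10),  # borderline: 14/24
                rep(TRUE, 2), rep(FALSE, 4))    # nonepithelial: 2/6
  bd <- sensitivity_breakdown(detected, subtypes)
  expect_equal(bd$detected[bd$group == "invasive"], 43)
  expect_equal(round(bd$detected_pct[bd$group == "invasive"], 1), 89.6)
  expect_equal(bd$detected[bd$group == "all"], 59)
  # detected counts across leaf subtypes sum to the all-cancers count
  leaves <- c("invasive_type1", "invasive_type2", "borderline",
              "nonepithelial")
  expect_equal(sum(bd$detected[bd$group %in% leaves]),
               bd$detected[bd$group == "all"])
  expect_equal(bd$detected + bd$missed, bd$total)

  none <- sensitivity_breakdown(rep(FALSE, 78), subtypes)
  expect_true(all(none$detected_pct == 0))

  expect_error(sensitivity_breakdown(TRUE, "mystery"), "Unknown subtype")
})

test_that("model evaluation assembles a consistent confusion matrix", {
  set.seed(77)
  n <- 500
  y <- rbinom(n, 1, 0.1)
  r <- plogis(-2 + 2.5 * y + rnorm(n))
  df <- tibble::tibble(risk = r, outcome = y)
  ev <- evaluate_model(df, n_boot = 200, seed = 3)
  expect_equal(ev$tp + ev$fn, sum(y))
  expect_equal(ev$fp + ev$tn, sum(y == 0))
  expect_equal(ev$ppv, ev$tp / (ev$tp + ev$fp))
  expect_equal(ev$npv, ev$tn / (ev$tn + ev$fn))
  expect_lte(ev$fp, floor(0.1 * sum(y == 0)))
  expect_true(ev$auc_lower <= ev$auc & ev$auc <= ev$auc_upper)
  td <- tidy(ev)
  expect_equal(nrow(td), 1)
})
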