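#' Area under the ROC curve
#'
#' Mann-Whitney form: the fraction of (case, noncase) pairs in which the
#' case has the higher risk, ties counted one half. Invariant under any
#' strictly monotone transform of the risks.
#'
#' @param risks Numeric risk scores.
#' @param outcomes Binary outcomes, same length.
#' @return AUC in \[0, 1\].
#' @examples
#' roc_auc(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0))
#' @export
roc_auc <- function(risks, outcomes) {
  check_two_class(outcomes)
  n1 <- sum(outcomes == 1)
  n0 <- sum(outcomes == 0)
  r <- rank(risks, ties.method = "average")
  (sum(r[outcomes == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

check_two_class <- function(outcomes) {
  if (!all(outcomes %in% c(0, 1)) || length(unique(outcomes)) < 2) {
    abort("Outcomes must contain at least one case and one noncase.")
  }
  invisible(outcomes)
}

# DeLong structural components: for each case the fraction of noncases it
# outranks (ties half), and symmetrically for noncases.
delong_components <- function(risks, outcomes) {
  case <- risks[outcomes == 1]
  ctrl <- risks[outcomes == 0]
  v10 <- vapply(case, function(x) {
    mean((x > ctrl) + 0.5 * (x == ctrl))
  }, numeric(1))
  v01 <- vapply(ctrl, function(x) {
    mean((case > x) + 0.5 * (case == x))
  }, numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong test for two correlated AUCs
#'
#' Paired comparison of the AUCs of two risk scores evaluated on the same
#' subjects, using the structural-components (jackknife) variance estimate
#' of the AUC difference and a two-sided normal reference.
#'
#' @param risks_a,risks_b Risk scores of the two models on the same
#'   subjects.
#' @param outcomes Binary outcomes.
#' @return A list with `auc_a`, `auc_b`, `difference`, `variance`, `z`, `p`.
#' @examples
#' o <- rep(c(1, 0), each = 10)
#' delong_test(runif(20), runif(20), o)
#' @export
delong_test <- function(risks_a, risks_b, outcomes) {
  check_two_class(outcomes)
  if (length(risks_a) != length(risks_b) ||
      length(risks_a) != length(outcomes)) {
    abort("Both models must be evaluated on the same subjects.")
  }
  ca <- delong_components(risks_a, outcomes)
  cb <- delong_components(risks_b, outcomes)
  n1 <- length(ca$v10)
  n0 <- length(ca$v01)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  d <- ca$auc - cb$auc
  z <- if (v <= 0) {
    if (abs(d) < .Machine$double.eps^0.5) 0 else sign(d) * Inf
  } else {
    d / sqrt(v)
  }
  list(auc_a = ca$auc, auc_b = cb$auc, difference = d, variance = v,
       z = z, p = 2 * pnorm(-abs(z)))
}

#' Risk cutoff achieving a target specificity
#'
#' Returns the smallest cutoff (subjects with `risk >= cutoff` test
#' positive) whose false-positive count does not exceed
#' \eqn{\lfloor (1 - target) N_{neg} \rfloor} — the floor rule, which keeps
#' specificity at or above the target while maximizing sensitivity. Ties
#' among equal risk values are resolved toward fewer positives. If no
#' finite cutoff achieves the bound (all noncases tied at the maximum),
#' `Inf` is returned with zero positives.
#'
#' @param risks Numeric risk scores.
#' @param outcomes Binary outcomes.
#' @param target_specificity Target in (0, 1).
#' @return A list with `cutoff`, `fp` (false positives at the cutoff) and
#'   `fp_allowed` (the floor bound).
#' @examples
#' cutoff_at_specificity(runif(100), rbinom(100, 1, 0.1), 0.9)
#' @export
cutoff_at_specificity <- function(risks, outcomes, target_specificity) {
  if (target_specificity <= 0 || target_specificity >= 1) {
    abort("`target_specificity` must be inside (0, 1).")
  }
  neg <- risks[outcomes == 0]
  if (length(neg) == 0) abort("At least one noncase is required.")
  # tolerance guards the floor against binary rounding of (1 - target)
  allowed <- floor((1 - target_specificity) * length(neg) + 1e-9)
  candidates <- sort(unique(risks))
  for (cut in candidates) {
    fp <- sum(neg >= cut)
    if (fp <= allowed) {
      return(list(cutoff = cut, fp = fp, fp_allowed = allowed))
    }
  }
  list(cutoff = Inf, fp = 0L, fp_allowed = allowed)
}

#' Sensitivity at a fixed cutoff
#'
#' @param risks,outcomes As in [cutoff_at_specificity()].
#' @param cutoff Risk threshold; subjects with `risk >= cutoff` are
#'   positive.
#' @return A list with `sensitivity` and `tp`.
#' @examples
#' sensitivity_at_cutoff(c(0.9, 0.2, 0.8), c(1, 1, 0), 0.5)
#' @export
sensitivity_at_cutoff <- function(risks, outcomes, cutoff) {
  n_case <- sum(outcomes == 1)
  if (n_case == 0) abort("At least one case is required.")
  tp <- sum(risks[outcomes == 1] >= cutoff)
  list(sensitivity = tp / n_case, tp = tp)
}

#' McNemar test for paired detection indicators
#'
#' Compares the per-case detection of two models at their operating points.
#' With 25 or fewer discordant pairs an exact binomial test is used;
#' otherwise the continuity-corrected chi-square.
#'
#' @param detected_a,detected_b Logical/binary detection per case (same
#'   cases).
#' @param exact_threshold Discordant-pair count at or below which the exact
#'   test is used.
#' @return Two-sided p-value.
#' @examples
#' mcnemar_paired(c(1, 1, 0, 1), c(1, 0, 0, 1))
#' @export
mcnemar_paired <- function(detected_a, detected_b, exact_threshold = 25L) {
  if (length(detected_a) != length(detected_b)) {
    abort("Detection vectors must cover the same cases.")
  }
  a <- as.logical(detected_a)
  b <- as.logical(detected_b)
  n10 <- sum(a & !b)
  n01 <- sum(!a & b)
  nd <- n10 + n01
  if (nd == 0) return(1)
  if (nd <= exact_threshold) {
    binom.test(n10, nd, p = 0.5)$p.value
  } else {
    stat <- (abs(n10 - n01) - 1)^2 / nd
    pchisq(stat, df = 1, lower.tail = FALSE)
  }
}

#' Predictive values and number needed to treat from a confusion matrix
#'
#' @param tp,fp,fn,tn Nonnegative counts.
#' @return A list with `ppv`, `npv` (proportions in \[0, 1\], `NA` when the
#'   denominator is zero) and `nnt` (= 1/PPV).
#' @examples
#' predictive_values(59, 151, 19, 1361)
#' @export
predictive_values <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  nnt <- if (!is.na(ppv) && ppv > 0) 1 / ppv else NA_real_
  list(ppv = ppv, npv = npv, nnt = nnt)
}

#' Predictive values at an arbitrary prevalence
#'
#' Bayes rescaling of an operating point to a population with different
#' disease prevalence — e.g. the 10% of symptomatic primary-care attenders
#' or the 15% of secondary-care referrals, against the ~5% of this
#' screening cohort.
#'
#' @param sensitivity,specificity,prevalence Proportions in \[0, 1\].
#' @return A list with `ppv` and `npv`.
#' @examples
#' predictive_values_at_prevalence(0.756, 0.90, 0.10)
#' @export
predictive_values_at_prevalence <- function(sensitivity, specificity,
                                            prevalence) {
  check_probability(sensitivity, "sensitivity")
  check_probability(specificity, "specificity")
  check_probability(prevalence, "prevalence")
  ppv_num <- sensitivity * prevalence
  ppv_den <- ppv_num + (1 - specificity) * (1 - prevalence)
  npv_num <- specificity * (1 - prevalence)
  npv_den <- npv_num + (1 - sensitivity) * prevalence
  list(
    ppv = if (ppv_den > 0) ppv_num / ppv_den else NA_real_,
    npv = if (npv_den > 0) npv_num / npv_den else 1
  )
}

#' Brier score
#'
#' Mean squared difference between predicted risk and the binary outcome;
#' lower is better, 0.25 for an uninformative constant 0.5.
#'
#' @param risks Predicted probabilities in \[0, 1\].
#' @param outcomes Binary outcomes.
#' @return The mean squared error.
#' @examples
#' brier_score(c(0.2, 0.8), c(0, 1))
#' @export
brier_score <- function(risks, outcomes) {
  if (any(risks < 0 | risks > 1)) abort("Risks must lie in [0, 1].")
  mean((risks - outcomes)^2)
}

#' Hosmer-Lemeshow calibration test
#'
#' Groups subjects into deciles of predicted risk (tied risks stay
#' together), sums \eqn{(O - E)^2 / E} over both outcome classes in every
#' group, and refers the statistic to chi-square with `groups - 2` degrees
#' of freedom (using the number of groups actually formed).
#'
#' @param risks Predicted probabilities.
#' @param outcomes Binary outcomes.
#' @param groups Number of risk groups, default 10.
#' @return A list with `chi2`, `df`, `p`, `groups`.
#' @examples
#' hosmer_lemeshow(runif(200), rbinom(200, 1, 0.3))
#' @export
hosmer_lemeshow <- function(risks, outcomes, groups = 10L) {
  n <- length(risks)
  if (n < groups) abort("Need at least as many subjects as groups.")
  breaks <- unique(quantile(risks, probs = seq(0, 1, length.out = groups + 1),
                            type = 7))
  if (length(breaks) < 3) abort("Risks are too tied to form groups.")
  g <- cut(risks, breaks = breaks, include.lowest = TRUE)
  obs1 <- tapply(outcomes, g, sum)
  expected1 <- tapply(risks, g, sum)
  size <- tapply(rep(1, n), g, sum)
  keep <- !is.na(size)
  obs1 <- obs1[keep]; expected1 <- expected1[keep]; size <- size[keep]
  expected0 <- size - expected1
  if (any(expected1 <= 0) || any(expected0 <= 0)) {
    abort("A risk group has zero expected count; use fewer groups.")
  }
  chi2 <- sum((obs1 - expected1)^2 / expected1 +
                ((size - obs1) - expected0)^2 / expected0)
  used <- length(size)
  df <- max(used - 2L, 1L)
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE),
       groups = used)
}

#' Bias-corrected percentile bootstrap confidence interval
#'
#' Resamples subjects (rows) with replacement, recomputes the statistic on
#' every resample, and returns the bias-corrected (BC, no acceleration)
#' percentile interval: with \eqn{z_0 = \Phi^{-1}} of the fraction of
#' bootstrap values below the observed statistic, the endpoints are the
#' \eqn{\Phi(2 z_0 \pm z_{\alpha/2})} percentiles of the bootstrap
#' distribution. Resamples on which the statistic is undefined (`NA` or an
#' error) are redrawn and counted.
#'
#' @param data A data frame of subjects.
#' @param statistic Function of a resampled data frame returning a scalar.
#' @param n_boot Number of bootstrap resamples.
#' @param level Confidence level.
#' @param seed Integer seed.
#' @return A list with `lower`, `upper`, `estimate` (observed statistic),
#'   `z0`, `n_boot`, `redraws`.
#' @examples
#' d <- data.frame(x = rnorm(50))
#' bootstrap_bc_ci(d, function(df) mean(df$x), n_boot = 200, seed = 1)
#' @export
bootstrap_bc_ci <- function(data, statistic, n_boot = 5000L, level = 0.95,
                            seed = 1L) {
  stopifnot(is.data.frame(data), n_boot >= 1)
  observed <- statistic(data)
  if (!is.finite(observed)) abort("Statistic is undefined on the data.")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  n <- nrow(data)
  values <- numeric(n_boot)
  redraws <- 0L
  for (i in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      val <- tryCatch(statistic(data[idx, , drop = FALSE]),
                      error = function(e) NA_real_)
      if (length(val) == 1 && is.finite(val)) break
      redraws <- redraws + 1L
      if (redraws > 100L * n_boot) {
        abort("Statistic undefined on too many bootstrap resamples.")
      }
    }
    values[i] <- val
  }
  alpha <- (1 - level) / 2
  prop_below <- mean(values < observed)
  # clamp so z0 stays finite on degenerate bootstrap distributions
  z0 <- qnorm(min(max(prop_below, 1 / (2 * n_boot)), 1 - 1 / (2 * n_boot)))
  if (all(values == values[1])) {
    return(list(lower = values[1], upper = values[1], estimate = observed,
                z0 = 0, n_boot = n_boot, redraws = redraws))
  }
  lo_p <- pnorm(2 * z0 + qnorm(alpha))
  hi_p <- pnorm(2 * z0 + qnorm(1 - alpha))
  qs <- quantile(values, probs = c(lo_p, hi_p), names = FALSE, type = 6)
  list(lower = qs[1], upper = qs[2], estimate = observed, z0 = z0,
       n_boot = n_boot, redraws = redraws)
}

#' Full diagnostic-accuracy evaluation of one model
#'
#' Computes the complete per-model report: AUC with bias-corrected
#' bootstrap CI, the operating point at the target specificity (cutoff
#' re-estimated inside every bootstrap resample, so the sensitivity CI
#' reflects cutoff variability), confusion counts, PPV/NPV/NNT, Brier score
#' and the Hosmer-Lemeshow test. The Brier score and calibration test only
#' make sense for scores on the probability scale; disable them via
#' `probability_scale = FALSE` (RMI-mod) and flag non-comparable
#' probabilities via `brier_comparable = FALSE` (ROMA, whose constant term
#' reflects a different prevalence).
#'
#' @param data A data frame with the risk and outcome columns.
#' @param risk_col,outcome_col Column names.
#' @param model Model label carried into the report.
#' @param target_specificity Operating specificity, default 0.90.
#' @param n_boot Bootstrap resamples for the CIs (0 disables CIs).
#' @param level Confidence level.
#' @param seed Integer seed for the bootstrap.
#' @param probability_scale Is the score a probability (or percent risk)?
#' @param brier_comparable Flag recorded in the report.
#' @return An object of class `model_evaluation`; `tidy()` renders it as a
#'   one-row tibble.
#' @export
evaluate_model <- function(data, risk_col = "risk", outcome_col = "outcome",
                           model = risk_col, target_specificity = 0.9,
                           n_boot = 5000L, level = 0.95, seed = 1L,
                           probability_scale = TRUE,
                           brier_comparable = probability_scale) {
  risks <- data[[risk_col]]
  outcomes <- data[[outcome_col]]
  check_two_class(outcomes)
  n_case <- sum(outcomes == 1)
  n_ctrl <- sum(outcomes == 0)

  auc <- roc_auc(risks, outcomes)
  op <- cutoff_at_specificity(risks, outcomes, target_specificity)
  sens <- sensitivity_at_cutoff(risks, outcomes, op$cutoff)
  tp <- sens$tp
  fn <- n_case - tp
  fp <- op$fp
  tn <- n_ctrl - fp
  pv <- predictive_values(tp, fp, fn, tn)

  # percent-risk scores (ROMA) are rescaled to [0, 1] for the Brier score
  prob <- if (probability_scale && max(risks) > 1) risks / 100 else risks
  brier <- if (probability_scale) brier_score(prob, outcomes) else NA_real_
  hl <- if (probability_scale) {
    tryCatch(hosmer_lemeshow(prob, outcomes),
             error = function(e) list(chi2 = NA_real_, df = NA_integer_,
                                      p = NA_real_, groups = NA_integer_))
  } else {
    list(chi2 = NA_real_, df = NA_integer_, p = NA_real_,
         groups = NA_integer_)
  }

  auc_ci <- sens_ci <- list(lower = NA_real_, upper = NA_real_)
  if (n_boot > 0) {
    df_boot <- data.frame(risk = risks, outcome = outcomes)
    auc_ci <- bootstrap_bc_ci(
      df_boot, function(d) roc_auc(d$risk, d$outcome),
      n_boot = n_boot, level = level, seed = derive_seed(seed, 1L))
    sens_ci <- bootstrap_bc_ci(
      df_boot,
      function(d) {
        cut <- cutoff_at_specificity(d$risk, d$outcome,
                                     target_specificity)$cutoff
        sensitivity_at_cutoff(d$risk, d$outcome, cut)$sensitivity
      },
      n_boot = n_boot, level = level, seed = derive_seed(seed, 2L))
  }

  structure(
    list(
      model = model, n = length(outcomes), n_case = n_case,
      n_noncase = n_ctrl,
      auc = auc, auc_lower = auc_ci$lower, auc_upper = auc_ci$upper,
      target_specificity = target_specificity,
      cutoff = op$cutoff,
      sensitivity = sens$sensitivity,
      sensitivity_lower = sens_ci$lower, sensitivity_upper = sens_ci$upper,
      tp = tp, fp = fp, fn = fn, tn = tn,
      ppv = pv$ppv, npv = pv$npv, nnt = pv$nnt,
      brier = brier, brier_comparable = brier_comparable,
      hl_chi2 = hl$chi2, hl_df = hl$df, hl_p = hl$p, hl_groups = hl$groups
    ),
    class = "model_evaluation"
  )
}

#' @rdname evaluate_model
#' @param x A `model_evaluation`.
#' @param ... Unused.
#' @export
tidy.model_evaluation <- function(x, ...) {
  tibble::as_tibble(x[c(
    "model", "sensitivity", "sensitivity_lower", "sensitivity_upper",
    "auc", "auc_lower", "auc_upper", "cutoff", "tp", "fp", "fn", "tn",
    "ppv", "npv", "nnt", "brier", "brier_comparable",
    "hl_chi2", "hl_df", "hl_p"
  )])
}

#' @export
print.model_evaluation <- function(x, ...) {
  cat(sprintf("Model %s: AUC %.3f (%.3f-%.3f)\n", x$model, x$auc,
              x$auc_lower, x$auc_upper))
  cat(sprintf("  sensitivity at %.0f%% specificity: %.1f%% (TP %d / %d)\n",
              100 * x$target_specificity, 100 * x$sensitivity, x$tp,
              x$n_case))
  cat(sprintf("  PPV %.1f%%, NPV %.1f%%, NNT %.2f, Brier %s\n",
              100 * x$ppv, 100 * x$npv, x$nnt,
              ifelse(is.na(x$brier), "n/a", sprintf("%.4f", x$brier))))
  invisible(x)
}

#' Evaluate several models on shared out-of-fold predictions
#'
#' Maps [evaluate_model()] over risk columns of a predictions tibble (as
#' produced by [cv_risk_models()]) and binds the tidied one-row reports.
#'
#' @param predictions Tibble with an outcome column and one risk column per
#'   model.
#' @param models Character vector of risk column names; defaults to every
#'   column except identifiers/outcome/subtype/fold.
#' @inheritParams evaluate_model
#' @return A tibble with one row per model.
#' @export
evaluate_models <- function(predictions, models = NULL,
                            outcome_col = "outcome",
                            target_specificity = 0.9, n_boot = 5000L,
                            level = 0.95, seed = 1L) {
  reserved <- c("subject_id", "fold", outcome_col, "subtype")
  models <- models %||% setdiff(names(predictions), reserved)
  rows <- purrr::imap(
    setNames(models, models),
    function(col, nm) {
      tidy(evaluate_model(
        predictions, risk_col = col, outcome_col = outcome_col, model = nm,
        target_specificity = target_specificity, n_boot = n_boot,
        level = level, seed = derive_seed(seed, match(col, models)),
        probability_scale = nm != "rmi_mod",
        brier_comparable = !nm %in% c("roma", "rmi_mod")
      ))
    }
  )
  dplyr::bind_rows(rows)
}

#' Paired comparisons against a reference model
#'
#' DeLong tests on the AUCs and McNemar tests on the per-case detection
#' indicators (at each model's own operating cutoff for the target
#' specificity) of every model against a reference model.
#'
#' @inheritParams evaluate_models
#' @param reference Risk column of the reference model.
#' @return A tibble: `model`, `reference`, `auc`, `auc_ref`,
#'   `auc_difference`, `delong_z`, `delong_p`, `sensitivity`,
#'   `sensitivity_ref`, `mcnemar_p`.
#' @export
compare_models <- function(predictions, reference = "us_ca125_he4",
                           models = NULL, outcome_col = "outcome",
                           target_specificity = 0.9) {
  reserved <- c("subject_id", "fold", outcome_col, "subtype")
  models <- models %||% setdiff(names(predictions),
                                c(reserved, reference))
  outcomes <- predictions[[outcome_col]]
  ref_risk <- predictions[[reference]]
  ref_cut <- cutoff_at_specificity(ref_risk, outcomes,
                                   target_specificity)$cutoff
  ref_detected <- ref_risk[outcomes == 1] >= ref_cut
  purrr::map_dfr(models, function(col) {
    risk <- predictions[[col]]
    dl <- delong_test(risk, ref_risk, outcomes)
    cut <- cutoff_at_specificity(risk, outcomes, target_specificity)$cutoff
    detected <- risk[outcomes == 1] >= cut
    tibble::tibble(
      model = col, reference = reference,
      auc = dl$auc_a, auc_ref = dl$auc_b, auc_difference = dl$difference,
      delong_z = dl$z, delong_p = dl$p,
      sensitivity = mean(detected), sensitivity_ref = mean(ref_detected),
      mcnemar_p = mcnemar_paired(detected, ref_detected)
    )
  })
}

#' Detected and missed cancers by histological subtype
#'
#' Splits per-case detection at the operating point into the subgroups of
#' the cohort's case mix: all cancers, invasive epithelial (all, type I,
#' type II), borderline epithelial and nonepithelial. Percentages are of
#' each subtype's total.
#'
#' @param detected Logical detection indicator per case.
#' @param subtypes Character subtype per case: `invasive_type1`,
#'   `invasive_type2`, `borderline`, `nonepithelial`.
#' @return A tibble: `group`, `total`, `detected`, `detected_pct`,
#'   `missed`, `missed_pct`.
#' @examples
#' sensitivity_breakdown(c(TRUE, FALSE, TRUE),
#'                       c("invasive_type2", "borderline", "invasive_type1"))
#' @export
sensitivity_breakdown <- function(detected, subtypes) {
  if (length(detected) != length(subtypes)) {
    abort("`detected` and `subtypes` must have the same length.")
  }
  bad <- setdiff(unique(subtypes), setdiff(SUBTYPE_LEVELS, "none"))
  if (length(bad) > 0) {
    abort(sprintf("Unknown subtype label(s): %s.", paste(bad, collapse = ", ")))
  }
  detected <- as.logical(detected)
  groups <- list(
    all = rep(TRUE, length(subtypes)),
    invasive = subtypes %in% c("invasive_type1", "invasive_type2"),
    invasive_type1 = subtypes == "invasive_type1",
    invasive_type2 = subtypes == "invasive_type2",
    borderline = subtypes == "borderline",
    nonepithelial = subtypes == "nonepithelial"
  )
  purrr::imap_dfr(groups, function(sel, nm) {
    total <- sum(sel)
    det <- sum(detected & sel)
    tibble::tibble(
      group = nm, total = total, detected = det,
      detected_pct = if (total > 0) 100 * det / total else 0,
      missed = total - det,
      missed_pct = if (total > 0) 100 * (total - det) / total else 0
    )
  })
}

#' ROC curve coordinates
#'
#' Sensitivity/specificity pairs over every distinct cutoff, for plotting
#' or export.
#'
#' @param risks,outcomes As in [roc_auc()].
#' @return A tibble `cutoff`, `sensitivity`, `specificity`.
#' @export
roc_coordinates <- function(risks, outcomes) {
  check_two_class(outcomes)
  cuts <- c(-Inf, sort(unique(risks)), Inf)
  n1 <- sum(outcomes == 1)
  n0 <- sum(outcomes == 0)
  purrr::map_dfr(cuts, function(ct) {
    tibble::tibble(
      cutoff = ct,
      sensitivity = sum(risks[outcomes == 1] >= ct) / n1,
      specificity = sum(risks[outcomes == 0] < ct) / n0
    )
  })
}
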