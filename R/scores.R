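#' ROMA score for postmenopausal women
#'
#' Risk of Ovarian Malignancy Algorithm: the postmenopausal predictive
#' index is \eqn{PI = -8.09 + 1.04\,\ln(HE4) + 0.732\,\ln(CA125)}, reported
#' as a percent risk \eqn{100\,e^{PI}/(1+e^{PI})}. Every subject in this
#' cohort is postmenopausal, so only the postmenopausal branch is
#' implemented; [roma_premenopausal()] is stubbed.
#'
#' @param ca125 Serum CA125 in kU/L (> 0).
#' @param he4 Serum HE4 in pmol/L (> 0).
#' @return Percent risk in \[0, 100\].
#' @examples
#' roma_postmenopausal(ca125 = 30, he4 = 60)
#' @export
roma_postmenopausal <- function(ca125, he4) {
  if (anyNA(ca125) || anyNA(he4) || any(ca125 <= 0) || any(he4 <= 0)) {
    abort("CA125 and HE4 must be positive for ROMA.")
  }
  pi <- -8.09 + 1.04 * log(he4) + 0.732 * log(ca125)
  100 * plogis(pi)
}

#' @rdname roma_postmenopausal
#' @export
roma_premenopausal <- function(ca125, he4) {
  abort("All subjects in this cohort are postmenopausal; the premenopausal ROMA branch is not implemented.")
}

#' Modified Risk of Malignancy Index
#'
#' The classic RMI is \eqn{U \times M \times CA125} with an ultrasound
#' feature count U and a menopausal score M. This modified version drops
#' the intraabdominal-metastasis feature (not recorded in this cohort), so
#' the count f runs over four flags: multilocular cyst, solid areas,
#' bilateral lesions, ascites. U is 0 for f = 0, 1 for f = 1 and 3 for
#' f >= 2; M = 3 because all subjects are postmenopausal.
#'
#' @param multilocular,solid_areas,bilateral,ascites Logical flags.
#' @param ca125 Serum CA125 in kU/L (> 0).
#' @return Nonnegative score vector.
#' @examples
#' rmi_modified(TRUE, FALSE, FALSE, TRUE, ca125 = 100)
#' @export
rmi_modified <- function(multilocular, solid_areas, bilateral, ascites,
                         ca125) {
  if (anyNA(ca125) || any(ca125 <= 0)) {
    abort("CA125 must be positive for the RMI.")
  }
  f <- as.integer(multilocular) + as.integer(solid_areas) +
    as.integer(bilateral) + as.integer(ascites)
  u <- ifelse(f == 0L, 0, ifelse(f == 1L, 1, 3))
  m <- 3
  u * m * ca125
}

#' Ultrasound flags feeding the modified RMI
#'
#' Maps this cohort's morphology coding onto the RMI feature flags:
#' multilocular = any ovary multilocular (with or without solid component);
#' solid areas = any solid component; bilateral = lesions in both ovaries;
#' ascites = ascites volume >= `ascites_threshold` mL.
#'
#' @param data A data frame with `morphology_left`, `morphology_right` and
#'   `ascites_ml` columns (a cohort or completed feature table).
#' @param ascites_threshold Volume (mL) above which ascites counts, default
#'   the 10 mL convention of the source cohort.
#' @return `data` with logical columns `rmi_multilocular`,
#'   `rmi_solid_areas`, `rmi_bilateral`, `rmi_ascites` added.
#' @export
rmi_flags <- function(data, ascites_threshold = 10) {
  multiloc <- c("multilocular", "multilocular_solid")
  data |>
    dplyr::mutate(
      rmi_multilocular = .data$morphology_left %in% multiloc |
        .data$morphology_right %in% multiloc,
      rmi_solid_areas = .data$morphology_left %in% SOLID_MORPHOLOGIES |
        .data$morphology_right %in% SOLID_MORPHOLOGIES,
      rmi_bilateral = .data$morphology_left %in% LESION_MORPHOLOGIES &
        .data$morphology_right %in% LESION_MORPHOLOGIES,
      rmi_ascites = .data$ascites_ml >= ascites_threshold
    )
}

#' Score a cohort with the published comparators
#'
#' Adds `roma` (percent risk) and `rmi_mod` columns to a cohort or
#' completed feature table. Rows with missing morphology get a missing
#' RMI-mod (score it on imputed copies instead); ROMA needs only the
#' markers, which are always observed.
#'
#' @param data A cohort tibble or completed feature table with marker
#'   columns (`ca125`/`he4` or `log_ca125`/`log_he4`).
#' @param ascites_threshold Passed to [rmi_flags()].
#' @return `data` with `roma` and `rmi_mod` columns appended.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_subjects = 50, seed = 5))
#' score_cohort(cohort)[, c("roma", "rmi_mod")]
#' @export
score_cohort <- function(data, ascites_threshold = 10) {
  ca125 <- if ("ca125" %in% names(data)) data$ca125 else exp(data$log_ca125)
  he4 <- if ("he4" %in% names(data)) data$he4 else exp(data$log_he4)
  flagged <- rmi_flags(data, ascites_threshold)
  any_na <- is.na(data$morphology_left) | is.na(data$morphology_right)
  rmi <- rmi_modified(flagged$rmi_multilocular, flagged$rmi_solid_areas,
                      flagged$rmi_bilateral, flagged$rmi_ascites, ca125)
  rmi[any_na] <- NA_real_
  data$roma <- roma_postmenopausal(ca125, he4)
  data$rmi_mod <- rmi
  data
}
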