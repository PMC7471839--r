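#' Classify the solid-component feature of a subject
#'
#' A morphology category carries a solid element if it is unilocular solid,
#' multilocular solid or entirely solid. The feature is `none` when neither
#' ovary carries one, `unilateral` for exactly one, `bilateral` for both.
#' Missing morphology on either side propagates to a missing result (the
#' imputation stage resolves it).
#'
#' @param morph_left,morph_right Character vectors of morphology categories.
#' @return Character vector in `c("none", "unilateral", "bilateral")`.
#' @examples
#' classify_solid_component("multilocular_solid", "normal")
#' @export
classify_solid_component <- function(morph_left, morph_right) {
  check_morphology(morph_left)
  check_morphology(morph_right)
  n_solid <- (morph_left %in% SOLID_MORPHOLOGIES) +
    (morph_right %in% SOLID_MORPHOLOGIES)
  out <- c("none", "unilateral", "bilateral")[n_solid + 1L]
  out[is.na(morph_left) | is.na(morph_right)] <- NA_character_
  out
}

#' Classify the locularity feature of a subject
#'
#' Locularity is present when either ovary is unilocular or multilocular,
#' irrespective of any solid component; it is absent when both ovaries are
#' normal, normal with an inclusion cyst, entirely solid or not visualized.
#'
#' @inheritParams classify_solid_component
#' @return Character vector in `c("absent", "present")`, `NA` where either
#'   morphology is missing.
#' @examples
#' classify_locularity("unilocular", "normal")
#' @export
classify_locularity <- function(morph_left, morph_right) {
  check_morphology(morph_left)
  check_morphology(morph_right)
  any_locular <- (morph_left %in% LOCULAR_MORPHOLOGIES) |
    (morph_right %in% LOCULAR_MORPHOLOGIES)
  out <- ifelse(any_locular, "present", "absent")
  out[is.na(morph_left) | is.na(morph_right)] <- NA_character_
  out
}

check_morphology <- function(x) {
  bad <- setdiff(unique(x[!is.na(x)]), MORPHOLOGY_LEVELS)
  if (length(bad) > 0) {
    abort(sprintf("Unknown morphology categories: %s.",
                  paste(bad, collapse = ", ")))
  }
  invisible(x)
}

#' Select the dominant lesion of a subject
#'
#' The dominant lesion is the one with the highest malignancy risk under
#' [morphology_dominance_rank()] — not necessarily the largest. Ties on
#' morphology are broken by the larger volume (a known volume beats an
#' unknown one). Lesions with missing morphology are ignored; if every
#' morphology is missing the result is missing.
#'
#' @param morphologies Character vector of lesion/ovary morphologies.
#' @param volumes Numeric vector of volumes (mL), same length.
#' @return A list with elements `morphology` and `volume` (both `NA` when no
#'   morphology is known).
#' @examples
#' select_dominant_lesion(c("solid", "multilocular_solid"), c(10, 2))
#' @export
select_dominant_lesion <- function(morphologies, volumes) {
  stopifnot(length(morphologies) == length(volumes))
  check_morphology(morphologies)
  known <- which(!is.na(morphologies))
  if (length(known) == 0) {
    return(list(morphology = NA_character_, volume = NA_real_))
  }
  rank <- morphology_dominance_rank()[morphologies[known]]
  # order by risk rank, then by volume descending with NA volumes last
  vol <- volumes[known]
  ord <- order(rank, -ifelse(is.na(vol), -Inf, vol), is.na(vol))
  pick <- known[ord[1]]
  list(morphology = morphologies[pick], volume = volumes[pick])
}

#' Build model covariates from raw subject records
#'
#' Applies the variable-construction rules mapping each scan record to the
#' model feature set: age; solid component (none/unilateral/bilateral);
#' locularity (absent/present); ascites volume in mL (0 when absent); the
#' natural-log volume of the dominant lesion (volumes floored at 0.1 mL);
#' and natural-log CA125 and HE4. Missing morphology or volume propagates
#' to missing features — never to silent defaults.
#'
#' @param cohort A cohort tibble (see [generate_cohort()]); markers and age
#'   must be present and markers strictly positive.
#' @return A tibble with columns `subject_id`, `outcome`, `subtype`, `age`,
#'   `solid_component`, `locularity`, `ascites_ml`, `log_dominant_volume`,
#'   `log_ca125`, `log_he4`, plus the raw per-ovary morphology and log
#'   volume columns used by the imputation stage (`morphology_left`,
#'   `morphology_right`, `log_volume_left`, `log_volume_right`).
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_subjects = 50, seed = 3))
#' build_features(cohort)
#' @export
build_features <- function(cohort) {
  required <- c("subject_id", "age_at_scan", "morphology_left",
                "morphology_right", "volume_left", "volume_right",
                "ascites_ml", "ca125", "he4", "outcome")
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols) > 0) {
    abort(sprintf("Cohort is missing columns: %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  if (anyNA(cohort$ca125) || anyNA(cohort$he4) || anyNA(cohort$age_at_scan)) {
    abort("Markers and age must be observed for every subject.")
  }
  if (any(cohort$ca125 <= 0) || any(cohort$he4 <= 0)) {
    abort("CA125 and HE4 must be strictly positive.")
  }
  dom <- purrr::map2(
    purrr::map2(cohort$morphology_left, cohort$morphology_right, c),
    purrr::map2(cohort$volume_left, cohort$volume_right, c),
    select_dominant_lesion
  )
  subtype <- if ("subtype" %in% names(cohort)) cohort$subtype else
    ifelse(cohort$outcome == 1L, NA_character_, "none")
  tibble::tibble(
    subject_id = cohort$subject_id,
    outcome = as.integer(cohort$outcome),
    subtype = subtype,
    age = cohort$age_at_scan,
    solid_component = classify_solid_component(cohort$morphology_left,
                                               cohort$morphology_right),
    locularity = classify_locularity(cohort$morphology_left,
                                     cohort$morphology_right),
    ascites_ml = cohort$ascites_ml,
    log_dominant_volume = log_volume(purrr::map_dbl(dom, "volume")),
    log_ca125 = log(cohort$ca125),
    log_he4 = log(cohort$he4),
    morphology_left = cohort$morphology_left,
    morphology_right = cohort$morphology_right,
    log_volume_left = log_volume(cohort$volume_left),
    log_volume_right = log_volume(cohort$volume_right)
  )
}

# natural log with a 0.1 mL floor so degenerate synthetic volumes cannot
# produce -Inf
log_volume <- function(volume) {
  log(pmax(volume, 0.1))
}

# Recompute derived ultrasound features from (possibly imputed) raw columns.
refresh_derived_features <- function(features) {
  dom <- purrr::pmap(
    list(features$morphology_left, features$morphology_right,
         features$log_volume_left, features$log_volume_right),
    function(ml, mr, vl, vr) {
      select_dominant_lesion(c(ml, mr), c(vl, vr))
    }
  )
  features$solid_component <- classify_solid_component(
    features$morphology_left, features$morphology_right)
  features$locularity <- classify_locularity(
    features$morphology_left, features$morphology_right)
  features$log_dominant_volume <- purrr::map_dbl(dom, "volume")
  features
}
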