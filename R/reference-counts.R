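#' Published operating-point detection counts of the UKCTOCS
#' adnexal-mass cohort
#'
#' The published study of 1590 postmenopausal women with adnexal masses (78
#' ovarian cancers: 48 invasive epithelial of which 14 type I and 34 type
#' II, 24 borderline, 6 nonepithelial; 1512 noncases) reports, for each of
#' its eight models at the cutoff fixing specificity at 90%, the number of
#' cancers detected overall and within each histological subgroup. These
#' integers, together with the subtype totals, determine every printed
#' sensitivity, PPV and NPV of the study's accuracy tables — the package
#' uses them as the reference inputs for its operating-point consistency
#' checks.
#'
#' @return A tibble with one row per model: `model`, `detected_all`,
#'   `detected_invasive`, `detected_type1`, `detected_type2`,
#'   `detected_borderline`, `detected_nonepithelial`.
#' @seealso [reference_cohort_counts()]
#' @examples
#' reference_detected_counts()
#' @export
reference_detected_counts <- function() {
  tibble::tribble(
    ~model,          ~detected_all, ~detected_invasive, ~detected_type1,
    ~detected_type2, ~detected_borderline, ~detected_nonepithelial,
    "us_ca125_he4",  59L, 43L, 11L, 32L, 14L, 2L,
    "us_ca125",      58L, 43L, 12L, 31L, 13L, 2L,
    "roma",          54L, 42L, 10L, 32L, 11L, 1L,
    "us_he4",        53L, 37L,  7L, 30L, 14L, 2L,
    "ca125",         52L, 39L, 11L, 28L, 12L, 1L,
    "rmi_mod",       50L, 39L, 10L, 29L, 10L, 1L,
    "us",            43L, 30L,  8L, 22L, 11L, 2L,
    "he4",           42L, 35L,  6L, 29L,  6L, 2L
  )
}

#' @rdname reference_detected_counts
#' @return `reference_cohort_counts()` returns a named integer vector with
#'   the cohort's subtype totals and noncase count.
#' @export
reference_cohort_counts <- function() {
  c(
    all = 78L, invasive = 48L, invasive_type1 = 14L, invasive_type2 = 34L,
    borderline = 24L, nonepithelial = 6L, noncases = 1512L
  )
}

#' Reconstruct the published accuracy table from detection counts
#'
#' Recomputes, from the published integer detection counts alone, the full
#' operating-point arithmetic of the accuracy table: the false-positive
#' count implied by the 90%-specificity floor rule (\eqn{\lfloor 0.10
#' \times 1512\rfloor = 151}), and per model the sensitivity, PPV, NPV and
#' NNT via [predictive_values()]. Percentages are rounded as printed (one
#' decimal).
#'
#' @param target_specificity Operating specificity of the published table.
#' @param counts,totals Published inputs; override to probe other tables.
#' @return A tibble with one row per model: `model`, `tp`, `fp`, `fn`,
#'   `tn`, `sensitivity_pct`, `ppv_pct`, `npv_pct`, `nnt`.
#' @examples
#' reconstruct_reference_table()
#' @export
reconstruct_reference_table <- function(target_specificity = 0.9,
                                        counts = reference_detected_counts(),
                                        totals = reference_cohort_counts()) {
  n_neg <- totals[["noncases"]]
  n_case <- totals[["all"]]
  fp <- floor((1 - target_specificity) * n_neg)
  purrr::pmap_dfr(counts, function(model, detected_all, ...) {
    tp <- detected_all
    fn <- n_case - tp
    tn <- n_neg - fp
    pv <- predictive_values(tp, fp, fn, tn)
    tibble::tibble(
      model = model, tp = tp, fp = fp, fn = fn, tn = tn,
      sensitivity_pct = round_half_up(100 * tp / n_case, 1),
      ppv_pct = round_half_up(100 * pv$ppv, 1),
      npv_pct = round_half_up(100 * pv$npv, 1),
      nnt = pv$nnt
    )
  })
}
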