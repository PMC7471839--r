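#' Log-normal parameters from a median and quartiles
#'
#' Inverts the log-normal quantile function so that the returned parameters
#' reproduce a printed three-number summary exactly: the distribution with
#' `meanlog = mu`, `sdlog = sigma` has median `median` and quartiles
#' `q1`, `q3`. Used to turn published biomarker summaries (median, 25th and
#' 75th centiles) into generator parameters.
#'
#' @param median,q1,q3 Positive reals with `0 < q1 < median < q3`.
#' @return A list with components `mu` and `sigma`.
#' @examples
#' lognormal_from_quartiles(15.3, 11.2, 22.1)
#' @export
lognormal_from_quartiles <- function(median, q1, q3) {
  ok <- is.numeric(median) && is.numeric(q1) && is.numeric(q3) &&
    length(median) == 1 && length(q1) == 1 && length(q3) == 1 &&
    is.finite(median) && is.finite(q1) && is.finite(q3)
  if (!ok || q1 <= 0 || !(q1 < median && median < q3)) {
    abort("`lognormal_from_quartiles()` requires 0 < q1 < median < q3.")
  }
  list(
    mu = log(median),
    sigma = (log(q3) - log(q1)) / (2 * qnorm(0.75))
  )
}

#' Specification of a synthetic adnexal-mass cohort
#'
#' Bundles every parameter of the cohort generator. The defaults are
#' calibrated to the published descriptive statistics of the UKCTOCS
#' adnexal-mass cohort: 1590 postmenopausal women, 78 ovarian cancers,
#' per-arm log-normal CA125 and HE4 (medians 85.0/15.3 kU/L and 92.6/55.3
#' pmol/L in cases/noncases), per-arm morphology frequencies, ascites >= 10
#' mL in 15.4% of cases vs 6.4% of noncases, and truncated-normal ages.
#' Missingness rates apply to ultrasound variables only (markers, age and
#' outcome are always observed) and default to the cohort's pooled
#' difficult-to-classify fraction for morphology.
#'
#' @param n_subjects Number of women to simulate.
#' @param prevalence Probability that a subject is a case.
#' @param ca125,he4 Per-arm log-normal parameters: a list with elements
#'   `case` and `noncase`, each a `list(mu, sigma)` as returned by
#'   [lognormal_from_quartiles()].
#' @param marker_correlation Gaussian-copula correlation between log CA125
#'   and log HE4 within each arm.
#' @param age Per-arm truncated-normal parameters: `list(case = list(mean,
#'   sd), noncase = list(mean, sd))`; ages are truncated to `age_range`.
#' @param age_range Lower and upper truncation bounds for age, in years.
#' @param morphology Per-arm category frequencies for the dominant-side
#'   morphology: `list(case = named vector, noncase = named vector)`; each
#'   vector must cover a subset of the morphology vocabulary and sum to 1.
#' @param contralateral_lesion_prob Probability that the other ovary also
#'   carries a lesion (drawn from the same arm's lesion frequencies).
#' @param contralateral_inclusion_prob Probability that an otherwise normal
#'   contralateral ovary shows an inclusion cyst.
#' @param dominant_volume Per-arm `list(mu, sigma)` for the dominant-side
#'   lesion/ovary volume (mL, log-normal).
#' @param normal_ovary_volume `list(mu, sigma)` for the volume of a normal
#'   postmenopausal ovary.
#' @param ascites_presence Per-arm probability of ascites >= 10 mL.
#' @param ascites_volume `list(mu, sigma)` of the log-normal excess over 10
#'   mL when ascites is present.
#' @param missing_volume_rate,missing_morphology_rate Default MCAR rates
#'   used by [apply_missingness()] when invoked through the pipeline.
#' @param seed Integer seed making [generate_cohort()] deterministic.
#' @return An object of class `cohort_spec`.
#' @examples
#' spec <- cohort_spec(n_subjects = 200, seed = 1)
#' spec$prevalence
#' @export
cohort_spec <- function(n_subjects = 1590,
                        prevalence = 78 / 1590,
                        ca125 = list(
                          case = lognormal_from_quartiles(85.0, 24.1, 231.6),
                          noncase = lognormal_from_quartiles(15.3, 11.2, 22.1)
                        ),
                        he4 = list(
                          case = lognormal_from_quartiles(92.6, 65.6, 215.0),
                          noncase = lognormal_from_quartiles(55.3, 47.1, 68.9)
                        ),
                        marker_correlation = 0.3,
                        age = list(
                          case = list(mean = 64.4, sd = 7.78),
                          noncase = list(mean = 60.8, sd = 7.49)
                        ),
                        age_range = c(50, 90),
                        morphology = default_morphology_frequencies(),
                        contralateral_lesion_prob = 0.05,
                        contralateral_inclusion_prob = 0.10,
                        dominant_volume = list(
                          case = lognormal_from_quartiles(29.9, 0.9, 40.9),
                          noncase = lognormal_from_quartiles(19.4, 3.9, 27.5)
                        ),
                        normal_ovary_volume = lognormal_from_quartiles(3, 1.5, 6),
                        ascites_presence = c(case = 0.154, noncase = 0.064),
                        ascites_volume = lognormal_from_quartiles(30, 10, 90),
                        missing_volume_rate = 0.05,
                        missing_morphology_rate = 47 / 1590,
                        seed = 20260101) {
  if (n_subjects < 0) abort("`n_subjects` must be nonnegative.")
  check_probability(prevalence, "prevalence")
  check_probability(marker_correlation, "marker_correlation")
  check_probability(contralateral_lesion_prob, "contralateral_lesion_prob")
  check_probability(missing_volume_rate, "missing_volume_rate")
  check_probability(missing_morphology_rate, "missing_morphology_rate")
  check_probability(unname(ascites_presence), "ascites_presence")
  for (arm in c("case", "noncase")) {
    f <- morphology[[arm]]
    if (is.null(names(f)) || !all(names(f) %in% MORPHOLOGY_LEVELS)) {
      abort("Morphology frequencies must be named with known categories.")
    }
    check_probability(unname(f), sprintf("morphology$%s", arm))
    if (abs(sum(f) - 1) > 1e-6) {
      abort(sprintf("Morphology frequencies for the %s arm must sum to 1.", arm))
    }
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects), prevalence = prevalence,
      ca125 = ca125, he4 = he4, marker_correlation = marker_correlation,
      age = age, age_range = age_range, morphology = morphology,
      contralateral_lesion_prob = contralateral_lesion_prob,
      contralateral_inclusion_prob = contralateral_inclusion_prob,
      dominant_volume = dominant_volume,
      normal_ovary_volume = normal_ovary_volume,
      ascites_presence = ascites_presence, ascites_volume = ascites_volume,
      missing_volume_rate = missing_volume_rate,
      missing_morphology_rate = missing_morphology_rate,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' Published per-arm morphology frequencies
#'
#' Frequencies of the dominant-side morphology category in cases and
#' noncases of the UKCTOCS adnexal-mass cohort, restricted to the seven
#' substantive categories (the difficult-to-classify/missing fraction is
#' handled separately by [apply_missingness()], and midline masses are not
#' generated by default) and renormalized to sum to 1.
#'
#' @return `list(case = named numeric, noncase = named numeric)`.
#' @export
default_morphology_frequencies <- function() {
  noncase <- c(
    unilocular = 0.132, multilocular = 0.402, unilocular_solid = 0.126,
    multilocular_solid = 0.184, solid = 0.022, not_visualized = 0.017,
    normal = 0.089
  )
  case <- c(
    unilocular = 0.090, multilocular = 0.128, unilocular_solid = 0.192,
    multilocular_solid = 0.423, solid = 0.038, not_visualized = 0.013,
    normal = 0.051
  )
  list(case = case / sum(case), noncase = noncase / sum(noncase))
}

# Case-mix of confirmed cancers: invasive type I/II, borderline,
# nonepithelial, as fractions of all cases (14, 34, 24, 6 of 78).
case_subtype_probs <- function() {
  c(invasive_type1 = 14, invasive_type2 = 34, borderline = 24,
    nonepithelial = 6) / 78
}

rtruncnorm <- function(n, mean, sd, lower, upper) {
  lo <- pnorm(lower, mean, sd)
  hi <- pnorm(upper, mean, sd)
  qnorm(runif(n, lo, hi), mean, sd)
}

#' Generate a synthetic adnexal-mass cohort
#'
#' Draws one subject record per woman from the arm-specific distributions in
#' `spec`: outcome from a Bernoulli with the cohort prevalence, cancer
#' subtype from the published case mix, CA125 and HE4 from correlated
#' log-normals, morphology of the dominant side from the arm's category
#' frequencies (the contralateral ovary is normal apart from a configurable
#' lesion/inclusion-cyst probability), ascites as a zero-inflated volume and
#' age from a truncated normal. The output contains no missing values; use
#' [apply_missingness()] to mask ultrasound variables.
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional integer overriding `spec$seed`.
#' @return A tibble with one row per subject: `subject_id`, `age_at_scan`,
#'   `morphology_left`, `morphology_right`, `volume_left`, `volume_right`,
#'   `ascites_ml`, `ca125`, `he4`, `outcome`, `subtype`. The spec and seed
#'   are attached as attributes `spec` and `seed`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_subjects = 100, seed = 7))
#' table(cohort$outcome)
#' @export
generate_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  seed <- as.integer(seed %||% spec$seed)
  n <- spec$n_subjects
  empty <- tibble::tibble(
    subject_id = character(), age_at_scan = numeric(),
    morphology_left = character(), morphology_right = character(),
    volume_left = numeric(), volume_right = numeric(),
    ascites_ml = numeric(), ca125 = numeric(), he4 = numeric(),
    outcome = integer(), subtype = character()
  )
  if (n == 0) {
    return(structure(empty, spec = spec, seed = seed))
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  outcome <- rbinom(n, 1L, spec$prevalence)
  subtype <- rep("none", n)
  n_case <- sum(outcome)
  if (n_case > 0) {
    probs <- case_subtype_probs()
    subtype[outcome == 1L] <- sample(names(probs), n_case, TRUE, probs)
  }
  arm <- ifelse(outcome == 1L, "case", "noncase")
  is_case <- outcome == 1L

  # per-subject parameter lookup, vectorized over the two arms
  by_arm <- function(field, what) {
    ifelse(is_case, spec[[field]][["case"]][[what]],
           spec[[field]][["noncase"]][[what]])
  }

  # correlated log-markers via a Gaussian copula on the log scale
  z1 <- rnorm(n)
  z2 <- spec$marker_correlation * z1 +
    sqrt(1 - spec$marker_correlation^2) * rnorm(n)
  ca125 <- exp(by_arm("ca125", "mu") + by_arm("ca125", "sigma") * z1)
  he4 <- exp(by_arm("he4", "mu") + by_arm("he4", "sigma") * z2)

  age <- rtruncnorm(
    n,
    mean = by_arm("age", "mean"), sd = by_arm("age", "sd"),
    lower = spec$age_range[1], upper = spec$age_range[2]
  )

  draw_categories <- function(freqs) {
    out <- character(n)
    for (a in c("case", "noncase")) {
      sel <- if (a == "case") is_case else !is_case
      if (any(sel)) {
        out[sel] <- sample(names(freqs[[a]]), sum(sel), replace = TRUE,
                           prob = freqs[[a]])
      }
    }
    out
  }
  dominant_morph <- draw_categories(spec$morphology)

  # contralateral ovary: normal bar a small lesion / inclusion-cyst chance
  lesion_freqs <- lapply(spec$morphology, function(f) {
    f[intersect(names(f), LESION_MORPHOLOGIES)]
  })
  contra_morph <- rep("normal", n)
  u <- runif(n)
  has_lesion <- u < spec$contralateral_lesion_prob
  contra_morph[has_lesion] <- draw_categories(lesion_freqs)[has_lesion]
  contra_morph[!has_lesion &
                 u < spec$contralateral_lesion_prob +
                 spec$contralateral_inclusion_prob] <- "normal_inclusion_cyst"
  # a persistently normal dominant side implies a normal contralateral ovary
  contra_morph[dominant_morph == "normal"] <- "normal"

  vol_for <- function(morph) {
    lesion <- morph %in% LESION_MORPHOLOGIES
    mu <- ifelse(lesion, by_arm("dominant_volume", "mu"),
                 spec$normal_ovary_volume$mu)
    sigma <- ifelse(lesion, by_arm("dominant_volume", "sigma"),
                    spec$normal_ovary_volume$sigma)
    exp(mu + sigma * rnorm(n))
  }
  dominant_vol <- vol_for(dominant_morph)
  contra_vol <- vol_for(contra_morph)
  # persistently normal subjects: dominant side is simply the larger ovary
  swap <- dominant_morph == "normal" & contra_vol > dominant_vol
  tmp <- dominant_vol[swap]
  dominant_vol[swap] <- contra_vol[swap]
  contra_vol[swap] <- tmp

  ascites_p <- spec$ascites_presence[arm]
  present <- runif(n) < ascites_p
  ascites <- ifelse(
    present,
    10 + exp(spec$ascites_volume$mu + spec$ascites_volume$sigma * rnorm(n)),
    0
  )

  left_is_dominant <- runif(n) < 0.5
  cohort <- tibble::tibble(
    subject_id = sprintf("S%05d", seq_len(n)),
    age_at_scan = age,
    morphology_left = ifelse(left_is_dominant, dominant_morph, contra_morph),
    morphology_right = ifelse(left_is_dominant, contra_morph, dominant_morph),
    volume_left = ifelse(left_is_dominant, dominant_vol, contra_vol),
    volume_right = ifelse(left_is_dominant, contra_vol, dominant_vol),
    ascites_ml = ascites,
    ca125 = ca125,
    he4 = he4,
    outcome = as.integer(outcome),
    subtype = subtype
  )
  structure(cohort, spec = spec, seed = seed)
}

#' Mask ultrasound variables completely at random
#'
#' Emulates the missingness the analysis has to cope with: per subject,
#' morphology (both sides jointly, mirroring a scan that was difficult to
#' classify) and/or volumes are set to `NA` with the given MCAR rates.
#' Markers, age, ascites and outcome are never masked.
#'
#' @param cohort A cohort tibble from [generate_cohort()] or [read_cohort()].
#' @param volume_rate,morphology_rate Per-subject masking probabilities.
#' @param seed Integer seed.
#' @return The cohort with `NA`s introduced.
#' @export
apply_missingness <- function(cohort, volume_rate, morphology_rate, seed = 1L) {
  check_probability(volume_rate, "volume_rate")
  check_probability(morphology_rate, "morphology_rate")
  n <- nrow(cohort)
  if (n == 0 || (volume_rate == 0 && morphology_rate == 0)) return(cohort)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  miss_morph <- runif(n) < morphology_rate
  miss_vol <- runif(n) < volume_rate
  cohort$morphology_left[miss_morph] <- NA_character_
  cohort$morphology_right[miss_morph] <- NA_character_
  cohort$volume_left[miss_vol] <- NA_real_
  cohort$volume_right[miss_vol] <- NA_real_
  cohort
}

#' Read and write cohort tables
#'
#' Cohorts are exchanged as plain CSV with a header row, one subject per
#' row and empty cells for missing values — the dialect every stage of the
#' pipeline consumes. `write_cohort()` records the generator seed (when the
#' cohort carries one) in a `# seed:` comment line.
#'
#' @param cohort A cohort tibble.
#' @param path File path.
#' @return `read_cohort()` returns a cohort tibble; `write_cohort()` returns
#'   `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  seed <- attr(cohort, "seed")
  con <- file(path, "w")
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", seed), con)
  close(con)
  readr::write_csv(cohort, path, na = "", append = !is.null(seed),
                   col_names = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  readr::read_csv(
    path, na = "", comment = "#", show_col_types = FALSE,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      morphology_left = readr::col_character(),
      morphology_right = readr::col_character(),
      subtype = readr::col_character(),
      outcome = readr::col_integer(),
      .default = readr::col_double()
    )
  )
}

#' Write or read a cohort specification as YAML
#'
#' @param spec A [cohort_spec()].
#' @param path File path.
#' @return `read_cohort_spec()` returns a `cohort_spec`.
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  out <- unclass(spec)
  # named vectors must become maps, or YAML drops the names
  out$morphology <- lapply(out$morphology, as.list)
  out$ascites_presence <- as.list(out$ascites_presence)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$ascites_presence <- unlist(raw$ascites_presence)
  raw$morphology <- lapply(raw$morphology, unlist)
  raw$age_range <- unlist(raw$age_range)
  do.call(cohort_spec, raw)
}
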