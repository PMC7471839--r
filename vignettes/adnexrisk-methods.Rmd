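---
title: "Methods: diagnostic risk models for adnexal masses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diagnostic risk models for adnexal masses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`adnexrisk` reconstructs a complete model-building and comparison workflow
for triaging adnexal masses in postmenopausal women: which combination of
transvaginal ultrasound (TVS) features, serum CA125 and serum HE4 best
discriminates ovarian cancer from benign disease? This vignette explains
the statistical machinery, the choices that were genuinely open, and what
the synthetic cohort can and cannot tell you.

## The modelling problem

Each subject contributes one scan record: age, a simple morphology
category per ovary (normal, normal with inclusion cyst, unilocular,
unilocular solid, multilocular, multilocular solid, solid, not
visualized), per-ovary volumes, ascites volume, and the two serum markers.
The outcome is primary ovarian cancer within one year of the scan, with
histological subtype (invasive type I/II, borderline, nonepithelial).

Raw records are mapped to model covariates by fixed construction rules:

* **Solid component** — none / unilateral / bilateral, where a category
  carries a solid element iff it is unilocular solid, multilocular solid
  or solid. Reference-coded with `none` as baseline, so bilateral disease
  may carry more than double the unilateral risk.
* **Locularity** — present iff either ovary is unilocular or multilocular,
  with or without a solid component; normal, inclusion-cyst, solid and
  not-visualized ovaries count as absent.
* **Dominant volume** — the natural-log volume of the *dominant* lesion,
  the one with the highest malignancy risk, not the largest. The dominance
  ranking (`morphology_dominance_rank()`) descends multilocular solid >
  solid > unilocular solid > midline mass > multilocular > unilocular >
  inclusion cyst > normal > not visualized. The four anchor positions
  follow the epithelial-cancer risks reported for these categories in the
  source screening trial (6.6%, 3.8%, 2.4%, 0.07%); the intermediate
  positions are interpolated, kept in one documented constant so they can
  be audited or replaced. For subjects with persistently normal ovaries
  the dominant "lesion" is the larger ovary. Volumes are floored at 0.1 mL
  before the log so degenerate synthetic volumes cannot produce `-Inf`.
* **Ascites** in mL (0 when absent), **log CA125**, **log HE4**, **age**.

Midline masses deserve a note: the record schema codes one morphology
category per ovary slot, with `midline_mass` as a category. A midline mass
therefore has no internal morphology of its own here, so it contributes
neither a solid component nor locularity and ranks between unilocular
solid and multilocular for dominance. This is a representational
compromise, documented rather than hidden; the default generator does not
emit midline masses.

## Firth penalized logistic regression

With 78 events and up to nine parameters, plain maximum likelihood is
biased and can diverge under separation. All models are therefore fitted
by Firth's bias-reduced logistic regression, maximizing

$$\ell^*(\beta) = \ell(\beta) + \tfrac12 \log\lvert I(\beta)\rvert,$$

the log-likelihood plus half the log-determinant of the Fisher
information (a Jeffreys prior). `fit_firth()` uses iteratively reweighted
least squares with the hat-adjusted score
$U^*(\beta) = X^\top\{y - \pi + h(\tfrac12 - \pi)\}$, step-halving
whenever a step would decrease $\ell^*$. Convergence requires the largest
absolute score component to fall below $10^{-6}$ within 50 iterations;
non-convergence yields a flagged result, not an error. Standard errors
come from the inverse penalized information at the maximum. Profile
likelihood intervals are deliberately out of scope: the workflow reports
bias-corrected bootstrap intervals for its headline metrics instead.
Intercept-corrected variants (FLIC/FLAC) are not implemented; plain Firth
is used throughout.

The test suite anchors the implementation three ways: the intercept-only
model must equal the closed-form "add one half" estimate; small fits must
agree with direct Nelder-Mead maximization of the explicitly coded
$\ell^*$ to $10^{-4}$; and simulated-data coefficients must be recovered
within three standard errors.

## Missing data: chained equations and Rubin's Rules

Morphology and volume can be missing (a scan that was difficult to
classify); markers, age and outcome never are. `impute_cohort()` fills the
per-ovary morphology categories by multinomial-logit draws
(`nnet::multinom`) and the per-ovary *log* volumes by predictive mean
matching with a donor pool of 5, cycling the conditionals for 10
iterations per chain, with 20 independent chains by default. Predictors
are age, ascites, both log markers, the outcome (deliberately included, to
avoid attenuating covariate-outcome associations) and the other imputed
variables. Derived features are rebuilt inside every completed copy, so
solid component, locularity and dominant volume are always mutually
consistent with the imputed morphologies. Whether to impute volumes on the
raw or log scale was an open choice; the log scale matches the scale the
model uses and keeps the PMM metric homoscedastic.

Per-imputation fits are combined by Rubin's Rules (`pool_rubin()`): pooled
estimate $\bar Q$, within variance $\bar U$, between variance $B$, total
$T = \bar U + (1 + 1/m)B$, with Barnard-Rubin small-sample degrees of
freedom. A 200-replicate recovery simulation checks that 95% intervals
built from $T$ cover at their nominal rate (90-98% band).

Missingness is MCAR by default, matching the testable contract of
`apply_missingness()`; the exact mechanism of the original cohort is not
recoverable from the published material.

## Cross-validation under multiple imputation

Out-of-sample performance uses 10-fold cross-validation entangled with the
imputations, not run per imputation: for each fold, the model is fitted on
the other nine folds *within every completed table*, the coefficients are
pooled by Rubin's Rules, the pooled coefficients are applied to each
completed version of the held-out subjects, and the resulting risks are
averaged across imputations on the probability scale (linear-predictor
averaging is available as an option). Folds are stratified on outcome —
with 78 cases over 10 folds, unstratified assignment risks fitting folds
with almost no events — and both fold sizes and per-fold case counts
differ by at most one. Imputation happens once, up front, on the full
cohort; re-imputing inside every training fold is statistically stricter
but was not the sequence the workflow describes, so it is not the default.

Seven fitted models are compared, all adjusted for age: ultrasound +
CA125 + HE4 (the full model), ultrasound + CA125, CA125 + HE4, ultrasound
+ HE4, CA125, HE4, and ultrasound alone. Two published comparators bypass
fitting and cross-validation entirely: ROMA's postmenopausal predictive
index $-8.09 + 1.04\ln\mathrm{HE4} + 0.732\ln\mathrm{CA125}$ expressed as
a percent risk, and a modified Risk of Malignancy Index
$U \times 3 \times \mathrm{CA125}$ whose feature count drops the
unavailable intraabdominal-metastasis flag (multilocular, solid areas,
bilateral lesions, ascites $\ge$ 10 mL; $U$ = 0, 1 or 3 for 0, 1, $\ge$ 2
features). RMI-mod flags are computed per imputed copy and the score
averaged; ROMA needs only the always-observed markers.

## Evaluation

`evaluate_model()` reports, per model: the Mann-Whitney AUC;
sensitivity at 90% specificity under the floor rule — the cutoff admits at
most $\lfloor 0.10 \times N_{neg} \rfloor$ false positives, keeping
specificity at or above target; confusion counts; PPV, NPV and number
needed to treat (1/PPV); the Brier score; and the 10-group
Hosmer-Lemeshow test. The floor-rule convention is not arbitrary: applied
to the published cohort (1512 noncases, so 151 false positives), it
reproduces every printed PPV and NPV of the source accuracy table to the
printed decimal from the integer detection counts alone — the package's
primary numeric acceptance check (`reconstruct_reference_table()`).
Published NNTs do not equal 1/PPV at this operating point (3.74 printed vs
3.56 = 210/59 for the full model); the computation behind the printed
values is not stated, so NNT is reported as 1/PPV and the discrepancy is
noted here rather than imitated.

Confidence intervals use the bias-corrected (BC, no acceleration)
percentile bootstrap with 5000 subject resamples by default; the operating
cutoff is re-estimated inside every resample, so sensitivity intervals
reflect cutoff variability. Paired model comparisons use DeLong's
structural-components test for correlated AUCs (verified exactly equal to
the grouped delete-one jackknife, and to an independent implementation)
and McNemar's test on per-case detection — exact binomial for 25 or fewer
discordant pairs, continuity-corrected chi-square above. Predictive
values are rescaled to 10% and 15% prevalence by the Bayes formula, the
prevalences of symptomatic primary-care and secondary-care populations.
The Brier score is reported for fitted models; for ROMA it is computed but
flagged non-comparable (its constant term encodes a different prevalence)
and for RMI-mod it is not computed at all (the score is not a
probability).

## The synthetic cohort

The original subject-level data are not deposited, so the package ships a
generator (`cohort_spec()`, `generate_cohort()`) that emulates the
cohort's published structure: 1590 women, prevalence 78/1590, and per-arm
distributions calibrated to the published descriptive table —

* **Markers** are log-normal per arm, parameterized by
  `lognormal_from_quartiles()` from the printed median and quartiles
  (CA125 85.0 [24.1, 231.6] / 15.3 [11.2, 22.1] kU/L; HE4 92.6 [65.6,
  215.0] / 55.3 [47.1, 68.9] pmol/L in cases/noncases). The printed
  case summaries are not exactly log-symmetric, so no log-normal can hit
  all three numbers; the convention here fixes the median exactly and
  takes the spread from the quartile ratio. CA125 and HE4 share a
  Gaussian copula on the log scale (correlation 0.3 by default) — the
  joint distribution is unpublished, so this is configurable, not
  asserted.
* **Morphology** of the dominant side is drawn from the published per-arm
  category frequencies over the seven substantive categories
  (renormalized after setting aside the difficult-to-classify fraction,
  which is modelled as missingness instead, and the midline row). The
  contralateral ovary is normal apart from a 5% lesion and 10%
  inclusion-cyst chance — invented plumbing, chosen once so that
  bilateral disease exists at a clinically plausible rate.
* **Ascites** is zero-inflated: present ($\ge$ 10 mL) with probability
  0.154 in cases and 0.064 in noncases, volume 10 mL plus a log-normal
  excess.
* **Ages** are truncated normal on [50, 90] years around the published
  medians (64.4 / 60.8), with spread matched to the printed IQRs.
* **Missingness** defaults to MCAR at 47/1590 for morphology (the pooled
  difficult-to-classify fraction) and 5% for volumes (unpublished;
  chosen once as a realistic rate).

What the generator does *not* emulate: the screening-episode structure,
any marker-morphology dependence within an arm beyond what the arm split
induces, midline masses, hormonal covariates, or time-to-event follow-up.
Two consequences matter for interpretation. First, passing tests
demonstrate that the *machinery* is correct, not that the published AUCs
are recovered — those depend on the real joint distribution, and the
synthetic full-model CV AUC (~0.84 at the published scale) sits near but
below the published 0.896. Second, because the case and noncase marker
variances differ substantially on the log scale, the true log-odds in the
synthetic world are mildly non-linear in the features, so on large
synthetic cohorts the Hosmer-Lemeshow test can legitimately reject a
linear-logit model — a property of the emulation, not a defect of the
calibration machinery (whose size is verified separately on correctly
specified simulations).

## Numerical conventions

* Natural logs everywhere; volumes floored at 0.1 mL before the log.
* Firth convergence at max |score| $\le 10^{-6}$, 50 iterations,
  step-halving; rank-deficient designs are an error naming the collinear
  columns, except that a factor level absent from a training subset has
  its coefficient fixed at zero (with a warning) inside cross-validation,
  where fixed factor codings must stay aligned across folds and
  imputations.
* The specificity floor uses a $10^{-9}$ tolerance before truncation so
  that binary representation of $(1 - 0.9) \times 10$ cannot lose a
  false positive.
* Printed-table comparisons round halves up, as clinical tables do; base
  R rounds half to even.
* Dominance ties are broken by larger volume, a known volume beating an
  unknown one.
* Every stage seed is derived deterministically from one master seed;
  identical configuration and seed give byte-identical reports.

## Problem sizes used by the checks

The packaged checks run the full pipeline at the published scale (n =
1590, m = 20 imputations, 10 folds) in the acceptance script, and smaller
configurations in the unit tests (cohorts of 200-400, m = 1-3, 5 folds;
simulation suites of 100-1000 replicates at n = 150-2000) — sizes chosen
so each property is tested at the smallest scale at which it is
informative. The null-signal and ordering bands use 20 and 10 pipeline
replicates respectively.
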