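test_that("lognormal_from_quartiles inverts the quantile function", {
  p <- lognormal_from_quartiles(15.3, 11.2, 22.1)
  expect_equal(p$mu, 2.728, tolerance = 1e-3)
  expect_equal(p$sigma, 0.504, tolerance = 1e-3)
  # the median is reproduced exactly and the quartile ratio is preserved;
  # the quartiles themselves are reproduced up to the slight log-asymmetry
  # of the printed summary
  expect_equal(qlnorm(0.5, p$mu, p$sigma), 15.3, tolerance = 1e-6)
  expect_equal(qlnorm(0.75, p$mu, p$sigma) / qlnorm(0.25, p$mu, p$sigma),
               22.1 / 11.2, tolerance = 1e-6)
  expect_equal(qlnorm(0.25, p$mu, p$sigma), 11.2, tolerance = 0.03)
  expect_equal(qlnorm(0.75, p$mu, p$sigma), 22.1, tolerance = 0.03)

  # a log-symmetric summary is reproduced exactly at all three quantiles
  sym <- lognormal_from_quartiles(10, 5, 20)
  expect_equal(qlnorm(c(0.25, 0.5, 0.75), sym$mu, sym$sigma), c(5, 10, 20),
               tolerance = 1e-6)

  p2 <- lognormal_from_quartiles(1.0, 0.5, 2.0)
  expect_equal(p2$mu, 0)
  expect_equal(p2$sigma, log(4) / (2 * 0.6744898), tolerance = 1e-6)

  expect_error(lognormal_from_quartiles(1, 1, 2), "q1 < median")
  expect_error(lognormal_from_quartiles(-1, -2, 2), "q1 < median")
})

test_that("generate_cohort is deterministic and matches its calibration", {
  spec <- cohort_spec(seed = 101)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(as.data.frame(a), as.data.frame(b))

  # case count within 3 binomial SDs of 78 at the cohort scale
  sd78 <- sqrt(1590 * (78 / 1590) * (1 - 78 / 1590))
  expect_lt(abs(sum(a$outcome) - 78), 3 * sd78)

  # noncase CA125 sample median within 10% of the calibrated 15.3 kU/L
  med <- median(a$ca125[a$outcome == 0])
  expect_lt(abs(med - 15.3) / 15.3, 0.10)

  # case marker medians exceed noncase medians (arm separation)
  expect_gt(median(a$ca125[a$outcome == 1]), median(a$ca125[a$outcome == 0]))
  expect_gt(median(a$he4[a$outcome == 1]), median(a$he4[a$outcome == 0]))

  # outcome-subtype coupling
  expect_true(all(a$subtype[a$outcome == 0] == "none"))
  expect_true(all(a$subtype[a$outcome == 1] != "none"))

  empty <- generate_cohort(cohort_spec(n_subjects = 0, seed = 1))
  expect_equal(nrow(empty), 0)
})

test_that("generator recovers the spec-implied marker quantiles at large n", {
  # the implied quantiles are those of the fitted log-normal; for the
  # noncase arms they coincide with the published three-number summaries,
  # which are log-symmetric
  spec <- cohort_spec(n_subjects = 2e5, prevalence = 0.5, seed = 77)
  big <- generate_cohort(spec)
  for (arm_label in c("case", "noncase")) {
    sel <- big$outcome == (arm_label == "case")
    for (marker in c("ca125", "he4")) {
      pars <- spec[[marker]][[arm_label]]
      implied <- qlnorm(c(.25, .5, .75), pars$mu, pars$sigma)
      expect_equal(unname(quantile(big[[marker]][sel], c(.25, .5, .75))),
                   implied, tolerance = 0.02)
    }
  }
  # and the published medians are reproduced as printed
  expect_equal(median(big$ca125[big$outcome == 0]), 15.3, tolerance = 0.02)
  expect_equal(median(big$ca125[big$outcome == 1]), 85.0, tolerance = 0.02)
  expect_equal(median(big$he4[big$outcome == 0]), 55.3, tolerance = 0.02)
  expect_equal(median(big$he4[big$outcome == 1]), 92.6, tolerance = 0.02)
})

test_that("apply_missingness is MCAR at the stated rates", {
  cohort <- generate_cohort(cohort_spec(seed = 5))

  unchanged <- apply_missingness(cohort, 0, 0, seed = 1)
  expect_identical(as.data.frame(unchanged), as.data.frame(cohort))

  masked <- apply_missingness(cohort, 0, 0.064, seed = 2)
  n_missing <- sum(is.na(masked$morphology_left))
  sd102 <- sqrt(1590 * 0.064 * (1 - 0.064))
  expect_lt(abs(n_missing - 1590 * 0.064), 3 * sd102)
  # both sides are masked jointly
  expect_identical(is.na(masked$morphology_left),
                   is.na(masked$morphology_right))

  all_vol <- apply_missingness(cohort, 1, 0, seed = 3)
  expect_true(all(is.na(all_vol$volume_left)))
  expect_false(anyNA(all_vol$ca125))
  expect_false(anyNA(all_vol$he4))
  expect_false(anyNA(all_vol$outcome))

  expect_error(apply_missingness(cohort, 1.5, 0), "probability")
})

test_that("cohort CSV and spec YAML round-trip exactly", {
  cohort <- small_cohort(n = 60, seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(cohort), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_identical(is.na(back$morphology_left), is.na(cohort$morphology_left))

  spec <- cohort_spec(n_subjects = 123, seed = 4)
  spath <- withr::local_tempfile(fileext = ".yaml")
  write_cohort_spec(spec, spath)
  spec2 <- read_cohort_spec(spath)
  expect_equal(spec2$n_subjects, 123L)
  expect_equal(
    as.data.frame(generate_cohort(spec2)),
    as.data.frame(generate_cohort(spec)),
    tolerance = 1e-8, ignore_attr = TRUE
  )
})
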