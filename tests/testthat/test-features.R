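test_that("solid component classification follows the morphology rules", {
  expect_equal(classify_solid_component("multilocular_solid", "normal"),
               "unilateral")
  expect_equal(classify_solid_component("unilocular_solid", "solid"),
               "bilateral")
  expect_equal(classify_solid_component("normal", "normal"), "none")
  expect_equal(classify_solid_component("multilocular", "unilocular"),
               "none")
  expect_true(is.na(classify_solid_component(NA, "solid")))
  expect_error(classify_solid_component("cystic", "normal"), "Unknown")
})

test_that("locularity classification follows the morphology rules", {
  expect_equal(classify_locularity("unilocular", "normal"), "present")
  expect_equal(classify_locularity("solid", "not_visualized"), "absent")
  expect_equal(classify_locularity("multilocular_solid", "multilocular"),
               "present")
  expect_equal(classify_locularity("normal_inclusion_cyst", "normal"),
               "absent")
  expect_true(is.na(classify_locularity("unilocular", NA)))
})

test_that("classification is symmetric in left and right", {
  set.seed(31)
  cats <- setdiff(
    c("normal", "normal_inclusion_cyst", "unilocular", "unilocular_solid",
      "multilocular", "multilocular_solid", "solid", "not_visualized"),
    NULL)
  for (i in 1:50) {
    l <- sample(cats, 1)
    r <- sample(cats, 1)
    expect_identical(classify_solid_component(l, r),
                     classify_solid_component(r, l))
    expect_identical(classify_locularity(l, r), classify_locularity(r, l))
  }
})

test_that("dominant lesion maximizes the risk ranking, ties by volume", {
  expect_equal(
    select_dominant_lesion(c("solid", "multilocular_solid"), c(10, 2)),
    list(morphology = "multilocular_solid", volume = 2)
  )
  expect_equal(
    select_dominant_lesion(c("unilocular_solid", "solid"), c(5, 1)),
    list(morphology = "solid", volume = 1)
  )
  expect_equal(
    select_dominant_lesion(c("multilocular", "unilocular_solid"), c(30, 5)),
    list(morphology = "unilocular_solid", volume = 5)
  )
  # same morphology: larger volume wins
  expect_equal(
    select_dominant_lesion(c("multilocular", "multilocular"), c(3, 30)),
    list(morphology = "multilocular", volume = 30)
  )
  # order invariance
  expect_equal(
    select_dominant_lesion(c("unilocular_solid", "multilocular"), c(5, 30)),
    select_dominant_lesion(c("multilocular", "unilocular_solid"), c(30, 5))
  )
  # known volume beats unknown on morphology ties
  expect_equal(
    select_dominant_lesion(c("solid", "solid"), c(NA, 2)),
    list(morphology = "solid", volume = 2)
  )
  # missing morphology ignored; all missing propagates
  expect_equal(
    select_dominant_lesion(c(NA, "unilocular"), c(10, 2)),
    list(morphology = "unilocular", volume = 2)
  )
  expect_true(is.na(select_dominant_lesion(c(NA, NA), c(1, 2))$morphology))
  # the documented rank order is total over the vocabulary
  rank <- morphology_dominance_rank()
  expect_setequal(names(rank),
                  c("normal", "normal_inclusion_cyst", "unilocular",
                    "unilocular_solid", "multilocular", "multilocular_solid",
                    "solid", "not_visualized", "midline_mass"))
  expect_equal(sort(unname(rank)), seq_along(rank))
})

test_that("feature construction applies natural logs and propagates NA", {
  cohort <- tibble::tibble(
    subject_id = c("a", "b", "c"),
    age_at_scan = c(60, 65, 70),
    morphology_left = c("multilocular_solid", "normal", NA),
    morphology_right = c("normal", "normal", NA),
    volume_left = c(1, 5, 4),
    volume_right = c(2, 3, 1),
    ascites_ml = c(0, 20, 0),
    ca125 = c(15.3, 40, 8),
    he4 = c(55, 60, 70),
    outcome = c(0L, 0L, 1L),
    subtype = c("none", "none", "borderline")
  )
  fe <- build_features(cohort)
  expect_equal(fe$log_ca125[1], log(15.3), tolerance = 1e-12)
  expect_equal(fe$log_ca125[1], 2.728, tolerance = 1e-3)
  # dominant lesion of subject a is the multilocular solid of 1 mL -> log 0
  expect_equal(fe$log_dominant_volume[1], 0)
  # persistent normal: dominant volume is the larger ovary
  expect_equal(fe$log_dominant_volume[2], log(5))
  expect_equal(fe$solid_component, c("unilateral", "none", NA))
  expect_equal(fe$locularity, c("present", "absent", NA))
  expect_true(is.na(fe$log_dominant_volume[3]))
  expect_equal(fe$ascites_ml, c(0, 20, 0))

  # purity: same record, same vector
  expect_identical(build_features(cohort), fe)

  cohort$ca125[1] <- -2
  expect_error(build_features(cohort), "positive")
})

test_that("volumes below 0.1 mL are floored before the log", {
  cohort <- small_cohort(n = 30, seed = 12, volume_rate = 0,
                         morphology_rate = 0)
  cohort$volume_left <- pmin(cohort$volume_left, 0.01)
  cohort$volume_right <- pmin(cohort$volume_right, 0.01)
  fe <- build_features(cohort)
  expect_true(all(is.finite(fe$log_dominant_volume)))
  expect_true(all(fe$log_dominant_volume >= log(0.1) - 1e-12))
})
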