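# Synthetic cohort generator: calibration, feature drawing, class
# assignment and end-to-end cohort properties.

test_that("count calibration matches the target mixture moments", {
  p <- calibrate_count_distributions()
  expect_s3_class(p, "fa_count_params")
  expect_equal(sum(p$class1_distribution), 1, tolerance = 1e-12)
  expect_equal(sum(p$class2_distribution), 1, tolerance = 1e-12)
  expect_lt(abs(p$achieved_mean - 4.14), 0.01)
  expect_lt(abs(p$achieved_sd - 2.81), 0.02)
  # mid+high visit total implied by the mean: 4.14 * 17437 - (9730*3 + 3744*4)
  m1 <- sum(p$class1_distribution * (5:10))
  m2 <- sum(p$class2_distribution * (11:60))
  expect_equal(3615 * m1 + 348 * m2,
               4.14 * 17437 - (9730 * 3 + 3744 * 4), tolerance = 1e-6)
})

test_that("calibration is deterministic and scales to other cohort sizes", {
  a <- calibrate_count_distributions()
  b <- calibrate_count_distributions()
  expect_identical(a, b)
  sc <- facohort:::scale_class_counts(4000)
  p <- calibrate_count_distributions(class_counts = sc$class_counts,
                                     class0_composition = sc$class0_composition)
  expect_lt(abs(p$achieved_mean - 4.14), 0.01)
  expect_lt(abs(p$achieved_sd - 2.81), 0.02)
})

test_that("degenerate single-class cohorts are handled exactly", {
  # all patients forced to three visits: mean 3, sd 0
  p <- calibrate_count_distributions(target_mean = 3, target_sd = 0,
                                     class_counts = c(100, 0, 0),
                                     class0_composition = c(100, 0))
  expect_equal(p$achieved_mean, 3)
  expect_equal(p$achieved_sd, 0)
  expect_error(
    calibrate_count_distributions(target_mean = 9, target_sd = 0,
                                  class_counts = c(100, 0, 0),
                                  class0_composition = c(100, 0)),
    "calibration failure.*mean")
})

test_that("infeasible moment targets raise a calibration error", {
  expect_error(
    calibrate_count_distributions(target_mean = 20, target_sd = 2.81),
    "calibration failure.*mean")
})

test_that("feature generation honours marginals and the LTC sum identity", {
  set.seed(7)
  f <- generate_features(500)
  expect_identical(names(f), fa_feature_names())
  expect_equal(f$total_ltcs, as.integer(rowSums(f[fa_ltc_flags()])))
  expect_true(all(f$age_group %in% 1:6))
  expect_true(all(f$simd_quintile %in% 1:5))
  expect_true(all(f$acute_inpatient_episodes >= 0))
  # empty cohort keeps the full schema
  f0 <- generate_features(0)
  expect_identical(names(f0), fa_feature_names())
  expect_identical(nrow(f0), 0L)
  # degenerate Bernoulli
  m <- default_feature_marginals()
  m$homeless_flag$prob <- 1
  expect_true(all(generate_features(50, m)$homeless_flag == 1))
  m$homeless_flag$prob <- 2
  expect_error(generate_features(10, m), "Bernoulli")
})

test_that("class assignment is rank-exact and plants effect directions", {
  set.seed(3)
  f <- generate_features(4000)
  cc <- c(3091L, 829L, 80L)
  lab <- assign_classes(f, class_counts = cc)
  expect_identical(tabulate(lab + 1L, 3), cc)
  expect_error(assign_classes(f, class_counts = c(1, 1, 1)),
               "must sum")
  # positive acute coefficient: class means strictly increasing, many seeds
  for (s in 1:10) {
    set.seed(s)
    f <- generate_features(4000)
    lab <- assign_classes(f, class_counts = cc)
    m <- tapply(f$acute_inpatient_episodes, lab, mean)
    expect_true(m[1] < m[2] && m[2] < m[3])
  }
})

test_that("zero coefficients leave labels independent of the features", {
  set.seed(5)
  f <- generate_features(17437)
  lab <- assign_classes(f, effect_coefficients = numeric(0),
                        class_counts = c(13474L, 3615L, 348L))
  drawn <- setdiff(fa_feature_names(), "total_ltcs")
  cors <- vapply(drawn, function(nm) {
    x <- f[[nm]]
    if (sd(x) == 0) return(0)
    abs(cor(x, lab))
  }, numeric(1))
  expect_true(all(cors <= 0.03))
})

test_that("visit counts respect class supports", {
  p <- calibrate_count_distributions()
  set.seed(2)
  lab <- c(rep(0L, 13474), rep(1L, 3615), rep(2L, 348))
  v <- draw_visit_counts(lab, c(9730L, 3744L), p)
  expect_true(all(v[lab == 0] %in% 3:4))
  expect_true(all(v[lab == 1] >= 5 & v[lab == 1] <= 10))
  expect_true(all(v[lab == 2] >= 11))
  expect_identical(sum(v == 3), 9730L)
  expect_error(draw_visit_counts(lab, c(1L, 1L), p), "class0_composition")
})

test_that("generated cohorts are deterministic and schema-complete", {
  a <- small_cohort(800, seed = 9)
  b <- small_cohort(800, seed = 9)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(names(a), fa_schema())
  expect_identical(nrow(a), 800L)
  expect_true(all(a$ae_attendances >= 3))
  d <- small_cohort(800, seed = 10)
  expect_false(identical(as.data.frame(a), as.data.frame(d)))
})

test_that("binned class sizes equal the configured counts for any seed", {
  for (s in c(1, 17, 99)) {
    cfg <- cohort_config(n_patients = 2000, seed = s)
    coh <- generate_cohort(cfg)
    cls <- tabulate(bin_attendance(coh$ae_attendances) + 1L, 3)
    expect_identical(cls, cfg$class_counts)
  }
})

test_that("attendance moments stay inside the calibration band over seeds", {
  ms <- vapply(1:20, function(s) {
    v <- generate_cohort(cohort_config(n_patients = 4000, seed = s))$ae_attendances
    c(mean(v), sd(v))
  }, numeric(2))
  expect_true(all(abs(ms[1, ] - 4.14) <= 0.05))
  expect_true(all(abs(ms[2, ] - 2.81) <= 0.10))
})

test_that("planted effect signs are recovered in raw class contrasts", {
  coefs <- default_effect_coefficients()
  strong <- coefs[abs(coefs) >= facohort:::fa_min_planted_effect()]
  hits <- setNames(integer(length(strong)), names(strong))
  n_seeds <- 20
  for (s in 1:n_seeds) {
    coh <- generate_cohort(cohort_config(seed = 100 + s))
    cls <- bin_attendance(coh$ae_attendances)
    for (nm in names(strong)) {
      d <- mean(coh[[nm]][cls == 2]) - mean(coh[[nm]][cls == 0])
      if (sign(d) == sign(strong[[nm]])) hits[nm] <- hits[nm] + 1L
    }
  }
  expect_true(all(hits >= n_seeds - 1))
})

test_that("cohort CSV round trip is exact", {
  coh <- small_cohort(400, seed = 4)
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(coh, path)
  back <- load_cohort(path)
  expect_identical(plain_df(back), plain_df(coh))
  unlink(path)
})

test_that("configuration invariants are enforced", {
  expect_error(cohort_config(n_patients = 100, class_counts = c(50, 30, 10)),
               "sum to n_patients")
  expect_error(cohort_config(n_patients = 100,
                             class_counts = c(80, 15, 5),
                             class0_composition = c(10, 10)),
               "class0_composition")
  expect_error(cohort_config(effect_coefficients = c(nope = 1)),
               "unknown features")
})
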