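# Shapley attribution: risk score, occlusion, permutation sampling, the
# exact oracle and cohort-targeted ranking.

test_that("expected-class risk score is the probability-weighted class", {
  p <- rbind(c(1, 0, 0), c(0, 0, 1), c(1, 1, 1) / 3, c(0.5, 0.25, 0.25))
  expect_equal(drop(p %*% 0:2), c(0, 2, 1, 0.75))
  toy <- blob_toy(seed = 1)
  m <- fa_fit(model_spec("RF"), toy[c("f1", "f2")], toy$y, seed = 1)
  s <- risk_score(m, toy[c("f1", "f2")])
  expect_true(all(s >= 0 & s <= 2))
  pr <- risk_score(m, toy[c("f1", "f2")], "class_probability", class = 2)
  expect_true(all(pr >= 0 & pr <= 1))
  expect_error(risk_score(m, toy[c("f1", "f2")], "class_probability"),
               "class in")
})

test_that("zero-input importance has the linear closed form", {
  set.seed(2)
  tab <- data.frame(x1 = rnorm(200, mean = 1.5), x2 = rnorm(200, 3))
  f <- function(d) 0.2 * d$x1 + 0.7 * d$x2
  expect_equal(zero_input_importance(f, tab, "x1"), 0.2 * mean(tab$x1),
               tolerance = 1e-12)
  # a feature the score ignores gets importance 0
  expect_equal(zero_input_importance(function(d) d$x2 * 0 + 1, tab, "x1"), 0)
  # a feature identically zero in the cohort gets importance 0
  tab$x3 <- 0
  expect_equal(zero_input_importance(function(d) d$x1 + d$x3, tab, "x3"), 0)
  expect_error(zero_input_importance(f, tab, "nope"), "unknown feature")
})

test_that("exact Shapley satisfies the axioms and the worked example", {
  f <- function(d) d$x1 + 2 * d$x2 + d$x1 * d$x2
  phi <- exact_shapley(f, data.frame(x1 = 1, x2 = 1))
  expect_equal(unname(phi[1:2]), c(1.5, 2.5), tolerance = 1e-12)
  # efficiency: contributions sum to v(full) - v(empty)
  expect_equal(sum(phi), f(data.frame(x1 = 1, x2 = 1)) -
                 f(data.frame(x1 = 0, x2 = 0)), tolerance = 1e-9)
  # dummy: an ignored feature gets zero
  g <- function(d) d$x1^2
  phig <- exact_shapley(g, data.frame(x1 = 2, x2 = 9))
  expect_equal(unname(phig["x2"]), 0, tolerance = 1e-12)
  # symmetry: exchangeable features share credit
  h <- function(d) d$x1 * d$x2
  phih <- exact_shapley(h, data.frame(x1 = 3, x2 = 3))
  expect_equal(unname(phih["x1"]), unname(phih["x2"]), tolerance = 1e-12)
  expect_error(exact_shapley(f, as.data.frame(as.list(setNames(1:13,
    paste0("x", 1:13))))), "guarded")
})

test_that("exact Shapley accepts non-zero backgrounds", {
  f <- function(d) d$x1 + 2 * d$x2 + d$x1 * d$x2
  phi <- exact_shapley(f, data.frame(x1 = 2, x2 = 3),
                       background = data.frame(x1 = 1, x2 = 1))
  expect_equal(sum(phi), f(data.frame(x1 = 2, x2 = 3)) -
                 f(data.frame(x1 = 1, x2 = 1)), tolerance = 1e-9)
})

test_that("permutation sampling converges to the exact oracle", {
  # interacting 4-feature value function, single instance, zero background
  f <- function(d) 3 * d$a + 2 * d$b * d$c - d$d + 0.5 * d$a * d$d^2
  inst <- data.frame(a = 1, b = 1, c = 1, d = 1)
  exact <- exact_shapley(f, inst)
  est <- permutation_shapley(f, inst, n_permutations = 2000, seed = 3,
                             background = "zeros")
  err <- abs(est$values$phi - unname(exact[est$values$feature]))
  expect_true(all(err <= 3 * est$values$se + 1e-9))
  # determinism under a fixed seed
  est2 <- permutation_shapley(f, inst, n_permutations = 2000, seed = 3,
                              background = "zeros")
  expect_identical(est$values, est2$values)
})

test_that("worked two-feature example recovers (1.5, 2.5)", {
  f <- function(d) d$x1 + 2 * d$x2 + d$x1 * d$x2
  est <- permutation_shapley(f, data.frame(x1 = 1, x2 = 1),
                             n_permutations = 500, seed = 1,
                             background = "zeros")
  expect_equal(est$values$phi, c(1.5, 2.5),
               tolerance = 0.2)
  err <- abs(est$values$phi - c(1.5, 2.5))
  expect_true(all(err <= 3 * est$values$se + 1e-9))
})

test_that("additive scores give matching zero-input, permutation and
          exact attributions under a zero background", {
  set.seed(9)
  tab <- data.frame(a = rnorm(50, 2), b = rnorm(50, -1), c = rnorm(50))
  beta <- c(a = 0.8, b = -0.5, c = 0.3)
  f <- function(d) 0.8 * d$a - 0.5 * d$b + 0.3 * d$c
  zi <- vapply(names(beta), function(j) zero_input_importance(f, tab, j),
               numeric(1))
  expect_equal(unname(zi), unname(beta * colMeans(tab)), tolerance = 1e-9)
  # exact, averaged over rows, equals the same closed form
  ex <- rowMeans(vapply(seq_len(nrow(tab)), function(i)
    exact_shapley(f, tab[i, ]), numeric(3)))
  expect_equal(unname(ex), unname(zi), tolerance = 1e-9)
  # permutation with zero background agrees within Monte-Carlo error
  est <- permutation_shapley(f, tab, n_permutations = 50, seed = 2,
                             background = "zeros")
  expect_equal(est$values$phi, unname(zi), tolerance = 1e-9)
})

test_that("marginal-background permutation values centre on zero for
          additive scores (contributions cancel across the cohort)", {
  set.seed(10)
  tab <- data.frame(a = rnorm(40, 2), b = rnorm(40))
  f <- function(d) 1.5 * d$a - 2 * d$b
  est <- permutation_shapley(f, tab, n_permutations = 300, seed = 5)
  expect_true(all(abs(est$values$phi) <= 3 * est$values$se + 1e-9))
})

test_that("constant scores yield zero attributions for every method", {
  tab <- data.frame(a = rnorm(30), b = rnorm(30))
  f <- function(d) rep(2.5, nrow(d))
  expect_equal(zero_input_importance(f, tab, "a"), 0)
  est <- permutation_shapley(f, tab, n_permutations = 20, seed = 1)
  expect_true(all(est$values$phi == 0))
  expect_equal(as.vector(exact_shapley(f, tab[1, ])), c(0, 0))
})

test_that("cohort risk factors are thresholded, ranked and cohort-aware", {
  coh <- small_cohort(600, seed = 21)
  f <- function(d) 0.05 * d$acute_inpatient_episodes -
    0.004 * d$simd_quintile
  rf <- cohort_risk_factors(f, as.data.frame(coh), cohort = "all")
  # 0.004 * mean(simd) ~ 0.008 < 0.01: excluded by the default threshold
  expect_true("acute_inpatient_episodes" %in% rf$table$feature)
  expect_false("simd_quintile" %in% rf$table$feature)
  expect_true(all(abs(rf$table$phi) > 0.01))
  expect_true(all(diff(rf$table$phi) <= 0))
  # sub-cohort selection restricts the evaluated rows
  rf_high <- cohort_risk_factors(f, as.data.frame(coh), cohort = "high")
  cls <- bin_attendance(coh$ae_attendances)
  expect_equal(rf_high$all_values[["acute_inpatient_episodes"]],
               0.05 * mean(coh$acute_inpatient_episodes[cls == 2]),
               tolerance = 1e-9)
  # all importances under threshold: empty table, no error
  rf_tiny <- cohort_risk_factors(function(d) 0.001 * d$gender_male,
                                 as.data.frame(coh), cohort = "all")
  expect_identical(nrow(rf_tiny$table), 0L)
  expect_error(cohort_risk_factors(f, coh[0, ], cohort = "all"),
               "no rows")
  expect_error(cohort_risk_factors(f, coh[fa_feature_names()]),
               "ae_attendances")
})
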