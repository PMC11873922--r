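# Generator configuration: the study conditions for the synthetic cohort.

#' Cohort table schema helpers
#'
#' `fa_schema()` returns the canonical column order of a cohort table
#' (`ae_attendances`, the target, last); `fa_feature_names()` the modelling
#' features (everything but the target); `fa_ltc_flags()` the ten
#' long-term-condition flag columns whose row sum defines `total_ltcs`.
#'
#' @return Character vector of column names.
#' @export
fa_schema <- function() {
  c("gender_male", "age_group", "simd_quintile", "homeless_flag",
    "deceased_flag", "home_care_episodes", "acute_inpatient_episodes",
    "mh_inpatient_episodes", "self_harm_episodes",
    "substance_misuse_episodes", "alcohol_episodes",
    "ltc_arthritis", "ltc_respiratory", "ltc_cardiac", "ltc_cancer",
    "ltc_cerebrovascular", "ltc_digestive", "ltc_neurological",
    "ltc_diabetes_endocrine", "ltc_renal", "ltc_other",
    "total_ltcs", "ae_attendances")
}

#' @rdname fa_schema
#' @export
fa_ltc_flags <- function() {
  c("ltc_arthritis", "ltc_respiratory", "ltc_cardiac", "ltc_cancer",
    "ltc_cerebrovascular", "ltc_digestive", "ltc_neurological",
    "ltc_diabetes_endocrine", "ltc_renal", "ltc_other")
}

#' @rdname fa_schema
#' @export
fa_feature_names <- function() setdiff(fa_schema(), "ae_attendances")

#' Default latent-risk effect coefficients
#'
#' Signed weights applied to standardised features when planting the
#' feature--attendance relationships of the synthetic cohort. Signs follow the
#' cross-model consensus of published frequent-attendance risk factors:
#' acute inpatient, digestive, respiratory, alcohol, self-harm and
#' mental-health episodes and male gender raise attendance risk; older age
#' group, higher (less deprived) SIMD quintile, death during the year, home
#' care and cancer/cardiac conditions lower it. Magnitudes were fixed once so
#' that all five model families recover the leading signs, and are part of
#' the package's frozen study conditions.
#'
#' @return Named numeric vector, one coefficient per modelling feature
#'   (features absent from the vector act as zero).
#' @export
default_effect_coefficients <- function() {
  c(acute_inpatient_episodes = 1.00,
    age_group                = -0.60,
    simd_quintile            = -0.55,
    ltc_digestive            = 0.50,
    alcohol_episodes         = 0.45,
    deceased_flag            = -0.40,
    self_harm_episodes       = 0.40,
    gender_male              = 0.35,
    ltc_respiratory          = 0.35,
    mh_inpatient_episodes    = 0.30,
    ltc_cardiac              = -0.25,
    home_care_episodes       = -0.25,
    ltc_cancer               = -0.25,
    ltc_diabetes_endocrine   = 0.15,
    ltc_neurological         = 0.10,
    homeless_flag            = 0.10,
    ltc_other                = 0.05)
}

# Minimum |coefficient| above which sign recovery is guaranteed by the
# generator's calibration (see vignette).
fa_min_planted_effect <- function() 0.25

#' Default feature marginal distributions
#'
#' One entry per drawn feature (total_ltcs is computed, not drawn). Binary
#' flags are Bernoulli, ordinals categorical, and episode counts
#' negative-binomial (over-dispersed), mimicking the variable types of a
#' routinely-collected A&E cohort: an SIMD distribution skewed towards the
#' most deprived quintiles, rare homelessness/death flags, and sparse
#' right-skewed episode counts.
#'
#' @return Named list; each element is a list with a `family` field
#'   (`"bernoulli"`, `"categorical"` or `"nbinom"`) and its parameters.
#' @export
default_feature_marginals <- function() {
  bern <- function(p) list(family = "bernoulli", prob = p)
  nbin <- function(mu, size) list(family = "nbinom", mu = mu, size = size)
  cate <- function(values, probs) list(family = "categorical",
                                       values = values, probs = probs)
  list(
    gender_male = bern(0.50),
    age_group = cate(1:6, c(0.14, 0.22, 0.20, 0.17, 0.14, 0.13)),
    simd_quintile = cate(1:5, c(0.45, 0.25, 0.13, 0.10, 0.07)),
    homeless_flag = bern(0.03),
    deceased_flag = bern(0.04),
    home_care_episodes = nbin(0.30, 0.25),
    acute_inpatient_episodes = nbin(0.60, 0.40),
    mh_inpatient_episodes = nbin(0.05, 0.15),
    self_harm_episodes = nbin(0.06, 0.15),
    substance_misuse_episodes = nbin(0.08, 0.15),
    alcohol_episodes = nbin(0.10, 0.15),
    ltc_arthritis = bern(0.15),
    ltc_respiratory = bern(0.22),
    ltc_cardiac = bern(0.12),
    ltc_cancer = bern(0.06),
    ltc_cerebrovascular = bern(0.05),
    ltc_digestive = bern(0.16),
    ltc_neurological = bern(0.07),
    ltc_diabetes_endocrine = bern(0.13),
    ltc_renal = bern(0.03),
    ltc_other = bern(0.10)
  )
}

# Scale the printed class structure to an arbitrary cohort size, preserving
# proportions (rounded; residual absorbed by class 0).
scale_class_counts <- function(n_patients) {
  ref <- c(13474L, 3615L, 348L)
  ref0 <- c(9730L, 3744L)
  n_ref <- sum(ref)
  if (n_patients == n_ref) {
    return(list(class_counts = ref, class0_composition = ref0))
  }
  c2 <- as.integer(round(ref[3] / n_ref * n_patients))
  c1 <- as.integer(round(ref[2] / n_ref * n_patients))
  c0 <- n_patients - c1 - c2
  c03 <- as.integer(round(ref0[1] / ref[1] * c0))
  list(class_counts = c(c0, c1, c2),
       class0_composition = c(c03, c0 - c03))
}

#' Construct a synthetic cohort generator configuration
#'
#' Defaults reproduce the printed statistics of the study cohort: 17,437
#' patients with at least three A&E attendances in a year, attendance classes
#' of 13,474 / 3,615 / 348 (low \verb{< 5}, mid 5--10, high \verb{> 10}
#' visits), 9,730 patients with exactly three visits, and an attendance-count
#' mixture with mean 4.14 and standard deviation 2.81. For other cohort sizes
#' the class structure is scaled proportionally and the within-class count
#' distributions are recalibrated to the same moments.
#'
#' @param n_patients Cohort size (default 17,437).
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the configuration and this seed.
#' @param class_counts Integer vector of patients per attendance class
#'   (low, mid, high); must sum to `n_patients`.
#' @param class0_composition Counts of exactly-3 and exactly-4 visit patients
#'   inside the low class; must sum to `class_counts[1]`.
#' @param target_mean,target_sd Attendance-count moments the full mixture is
#'   calibrated to (defaults 4.14 and 2.81 visits).
#' @param effect_coefficients Named numeric vector of signed latent-risk
#'   weights; see [default_effect_coefficients()].
#' @param feature_marginals Per-feature marginal specifications; see
#'   [default_feature_marginals()].
#' @param noise_sd Standard deviation of the Gaussian noise added to the
#'   latent risk before rank-based class assignment (default 1).
#' @param max_visits Upper support bound for the high-class visit-count
#'   distribution (default 60; the heavy tail is needed to reach SD 2.81
#'   given the mass at 3--4 visits).
#' @return An object of class `fa_cohort_config` (a validated list).
#' @seealso [generate_cohort()]
#' @export
#' @examples
#' cfg <- cohort_config(n_patients = 2000, seed = 1)
#' cfg$class_counts
cohort_config <- function(n_patients = 17437L,
                          seed = 1L,
                          class_counts = NULL,
                          class0_composition = NULL,
                          target_mean = 4.14,
                          target_sd = 2.81,
                          effect_coefficients = default_effect_coefficients(),
                          feature_marginals = default_feature_marginals(),
                          noise_sd = 1,
                          max_visits = 60L) {
  n_patients <- as.integer(n_patients)
  stopifnot(n_patients >= 0, noise_sd >= 0, max_visits > 10)
  if (is.null(class_counts) || is.null(class0_composition)) {
    sc <- scale_class_counts(n_patients)
    if (is.null(class_counts)) class_counts <- sc$class_counts
    if (is.null(class0_composition)) {
      class0_composition <- c(
        as.integer(round(9730 / 13474 * class_counts[1])), 0L)
      class0_composition[2] <- class_counts[1] - class0_composition[1]
    }
  }
  class_counts <- as.integer(class_counts)
  class0_composition <- as.integer(class0_composition)
  if (length(class_counts) != 3 || any(class_counts < 0))
    stop("class_counts must be three non-negative integers")
  if (sum(class_counts) != n_patients)
    stop("class_counts must sum to n_patients (",
         sum(class_counts), " != ", n_patients, ")")
  if (length(class0_composition) != 2 ||
      sum(class0_composition) != class_counts[1])
    stop("class0_composition must sum to class_counts[1]")
  unknown <- setdiff(names(effect_coefficients), fa_feature_names())
  if (length(unknown))
    stop("unknown features in effect_coefficients: ",
         paste(unknown, collapse = ", "))
  missing_marg <- setdiff(setdiff(fa_feature_names(), "total_ltcs"),
                          names(feature_marginals))
  if (length(missing_marg))
    stop("feature_marginals missing entries for: ",
         paste(missing_marg, collapse = ", "))
  structure(
    list(n_patients = n_patients, seed = as.integer(seed),
         class_counts = class_counts,
         class0_composition = class0_composition,
         target_mean = target_mean, target_sd = target_sd,
         effect_coefficients = effect_coefficients,
         feature_marginals = feature_marginals,
         noise_sd = noise_sd, max_visits = as.integer(max_visits)),
    class = "fa_cohort_config")
}

#' @export
print.fa_cohort_config <- function(x, ...) {
  cat("Synthetic A&E cohort configuration\n")
  cat("  patients:    ", x$n_patients, "\n")
  cat("  class counts:", paste(x$class_counts, collapse = " / "),
      "(low / mid / high)\n")
  cat("  low class:   ", x$class0_composition[1], "threes,",
      x$class0_composition[2], "fours\n")
  cat("  target moments: mean", x$target_mean, ", sd", x$target_sd, "\n")
  cat("  seed:        ", x$seed, "\n")
  invisible(x)
}
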