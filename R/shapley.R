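# Feature attribution for attendance risk: zero-input occlusion and
# permutation-sampling approximations to Shapley values, an exact
# subset-enumeration oracle for validation, and cohort-targeted risk-factor
# ranking.

# A "model" in this module is either a fitted fa_model (scored through the
# configured risk-score mode) or a plain function mapping a feature
# data.frame/matrix to a numeric score vector (used by the toy oracles).
score_function <- function(model, mode = "expected_class", class = NULL) {
  if (is.function(model)) return(function(x) model(x))
  stopifnot(inherits(model, "fa_model"))
  function(x) risk_score(model, x, mode = mode, class = class)
}

#' Scalar risk score from a fitted model
#'
#' Collapses the three-class probability rows to one signed scalar per
#' patient. The default `expected_class` mode returns the expected
#' attendance class \eqn{\sum_c c \, p_c(x) \in [0, 2]}, yielding one
#' signed importance value per feature when used for attribution;
#' `class_probability` returns \eqn{p_c(x)} for a chosen class.
#'
#' @param model An `fa_model`.
#' @param newdata Feature `data.frame` (raw scale).
#' @param mode `"expected_class"` or `"class_probability"`.
#' @param class Class index for `class_probability` mode.
#' @return Numeric score vector.
#' @export
risk_score <- function(model, newdata,
                       mode = c("expected_class", "class_probability"),
                       class = NULL) {
  mode <- match.arg(mode)
  p <- predict(model, newdata, type = "prob")
  if (mode == "expected_class") {
    drop(p %*% c(0, 1, 2))
  } else {
    if (is.null(class) || !class %in% 0:2)
      stop("class_probability mode needs class in {0, 1, 2}")
    p[, class + 1L]
  }
}

#' Zero-input (occlusion) feature importance
#'
#' Average change in the risk score when the feature is set to 0 for every
#' row: \eqn{\phi_j = \mathrm{mean}[s(x) - s(x \mid x_j = 0)]}. The
#' substitution happens in raw feature space before re-standardisation, so
#' zero means "absent" rather than "at the cohort mean". Positive values
#' mean the feature's presence raises predicted attendance risk. Ordinal
#' features (age group, SIMD quintile) are zeroed as-is even though 0 lies
#' outside their coded range; the occlusion is applied uniformly to every
#' feature.
#'
#' @param model `fa_model` or scoring function.
#' @param table Feature `data.frame` (an `ae_attendances` column, if
#'   present, is ignored).
#' @param feature Feature column name.
#' @param mode,class Risk-score mode, see [risk_score()].
#' @return Signed scalar importance.
#' @export
zero_input_importance <- function(model, table, feature,
                                  mode = "expected_class", class = NULL) {
  x <- as.data.frame(table)
  x$ae_attendances <- NULL
  if (!feature %in% names(x)) stop("unknown feature: ", feature)
  sf <- score_function(model, mode, class)
  x0 <- x
  x0[[feature]] <- 0
  mean(sf(x) - sf(x0))
}

#' Permutation-sampling Shapley estimate
#'
#' Monte-Carlo estimate of each feature's average marginal contribution to
#' the risk score. For each sampled feature ordering, features not yet
#' added take background values (by default drawn independently from the
#' cohort's empirical per-feature marginals, re-drawn per permutation);
#' features are then switched to their true values in order, and
#' \eqn{\phi_j} accumulates the mean change in score when feature j is
#' added, averaged over cohort rows and permutations.
#'
#' @param model `fa_model` or scoring function.
#' @param table Feature `data.frame` (target column ignored).
#' @param mode,class Risk-score mode.
#' @param n_permutations Number of sampled orderings (\eqn{\ge 1}).
#' @param seed Integer seed; identical seeds give identical estimates.
#' @param background `"marginal"` (empirical resampling, default) or
#'   `"zeros"` (all-absent baseline, matching the zero-input semantics).
#' @return Object of class `fa_importance`: data.frame `values` with
#'   feature, phi and Monte-Carlo standard error, plus provenance fields.
#' @export
permutation_shapley <- function(model, table, mode = "expected_class",
                                class = NULL, n_permutations = 200L,
                                seed = 1L,
                                background = c("marginal", "zeros")) {
  background <- match.arg(background)
  stopifnot(n_permutations >= 1)
  x <- as.data.frame(table)
  x$ae_attendances <- NULL
  feats <- names(x)
  d <- length(feats)
  n <- nrow(x)
  sf <- score_function(model, mode, class)
  local_seed(seed)
  contrib <- matrix(0, n_permutations, d, dimnames = list(NULL, feats))
  for (p in seq_len(n_permutations)) {
    cur <- x
    for (nm in feats) {
      cur[[nm]] <- if (background == "zeros") rep(0, n)
        else sample(x[[nm]], n, replace = TRUE)
    }
    s_prev <- sf(cur)
    for (j in sample.int(d)) {
      cur[[feats[j]]] <- x[[feats[j]]]
      s_new <- sf(cur)
      contrib[p, j] <- mean(s_new - s_prev)
      s_prev <- s_new
    }
  }
  phi <- colMeans(contrib)
  se <- apply(contrib, 2, sd) / sqrt(n_permutations)
  structure(list(values = data.frame(feature = feats, phi = unname(phi),
                                     se = unname(se)),
                 method = "permutation", n_permutations = n_permutations,
                 seed = seed, background = background),
            class = "fa_importance")
}

#' Exact Shapley values by subset enumeration
#'
#' Computes \eqn{\phi_j = \sum_{S \subseteq F \setminus \{j\}}
#' \frac{|S|!\,(d-|S|-1)!}{d!} [v(S \cup \{j\}) - v(S)]} where the value
#' \eqn{v(S)} of a coalition is the risk score of the instance with
#' features outside S replaced by background values. Enumeration is
#' \eqn{2^d}, guarded at 12 features; this is the validation oracle for the
#' approximations, not a production method. The default all-zero background
#' matches the zero-input notion of feature absence.
#'
#' @param model `fa_model` or scoring function.
#' @param instance Single-row `data.frame` (or coercible named list).
#' @param background Background values: `"zeros"`, or a single-row
#'   `data.frame`/named vector aligned with the instance's features.
#' @param mode,class Risk-score mode.
#' @return Named numeric vector of exact Shapley values, with attribute
#'   `values` giving v(S) per subset.
#' @export
#' @examples
#' f <- function(x) x[[1]] + 2 * x[[2]] + x[[1]] * x[[2]]
#' exact_shapley(f, data.frame(x1 = 1, x2 = 1))  # 1.5, 2.5
exact_shapley <- function(model, instance, background = "zeros",
                          mode = "expected_class", class = NULL) {
  inst <- as.data.frame(instance)
  inst$ae_attendances <- NULL
  stopifnot(nrow(inst) == 1)
  feats <- names(inst)
  d <- length(feats)
  if (d > 12)
    stop("exact Shapley enumeration is guarded at 12 features (got ", d,
         "); use permutation_shapley() instead")
  bg <- if (identical(background, "zeros")) {
    as.data.frame(setNames(as.list(rep(0, d)), feats))
  } else {
    b <- as.data.frame(rbind(background))
    b$ae_attendances <- NULL
    b[feats]
  }
  sf <- score_function(model, mode, class)
  n_sub <- 2^d
  masks <- matrix(FALSE, n_sub, d)
  for (j in seq_len(d))
    masks[, j] <- bitwAnd(seq_len(n_sub) - 1L, bitwShiftL(1L, j - 1L)) > 0
  # one vectorised scoring call over all 2^d coalition rows
  rows <- bg[rep(1, n_sub), , drop = FALSE]
  for (j in seq_len(d)) rows[masks[, j], j] <- inst[[j]]
  vals <- sf(rows)
  sizes <- rowSums(masks)
  wts <- factorial(0:(d - 1)) * factorial(d - 1 - 0:(d - 1)) / factorial(d)
  phi <- setNames(numeric(d), feats)
  for (j in seq_len(d)) {
    without <- which(!masks[, j])
    with_j <- without + bitwShiftL(1L, j - 1L)
    phi[j] <- sum(wts[sizes[without] + 1L] * (vals[with_j] - vals[without]))
  }
  attr(phi, "values") <- vals
  phi
}

#' Cohort-targeted risk-factor table
#'
#' Restricts the cohort to the selected actual attendance classes --
#' `"low_mid"` (classes 0 and 1: which factors push patients towards higher
#' attendance, i.e. escalation risks) or `"high"` (class 2: which factors,
#' if mitigated, could reduce attendance) or `"all"` -- then computes one
#' signed importance per feature on those rows with the chosen method, and
#' returns the features with absolute importance above the reporting
#' threshold, ranked by importance (descending, ties broken by feature
#' name). The model is never refitted per cohort: it is trained once and
#' probed on each sub-cohort.
#'
#' @param model `fa_model` or scoring function.
#' @param table Cohort `data.frame` including `ae_attendances` (needed to
#'   select cohorts by actual class).
#' @param cohort `"all"`, `"low_mid"` or `"high"`.
#' @param method `"zero_input"` (default, the selected method) or
#'   `"permutation"`.
#' @param threshold Reporting threshold on |importance| (default 0.01).
#' @param mode,class Risk-score mode.
#' @param n_permutations,seed Permutation-method controls.
#' @return Object of class `fa_risk_factors`: ranked data.frame `table`
#'   (feature, phi) plus provenance fields.
#' @export
cohort_risk_factors <- function(model, table,
                                cohort = c("all", "low_mid", "high"),
                                method = c("zero_input", "permutation"),
                                threshold = 0.01,
                                mode = "expected_class", class = NULL,
                                n_permutations = 100L, seed = 1L) {
  cohort <- match.arg(cohort)
  method <- match.arg(method)
  if (!"ae_attendances" %in% names(table))
    stop("table must carry ae_attendances to select cohorts by class")
  cls <- bin_attendance(table$ae_attendances)
  keep <- switch(cohort, all = rep(TRUE, nrow(table)),
                 low_mid = cls %in% c(0L, 1L), high = cls == 2L)
  if (!any(keep)) stop("cohort '", cohort, "' selects no rows")
  sub <- table[keep, , drop = FALSE]
  feats <- setdiff(names(sub), "ae_attendances")
  phi <- if (method == "zero_input") {
    vapply(feats, function(f)
      zero_input_importance(model, sub, f, mode, class), numeric(1))
  } else {
    res <- permutation_shapley(model, sub, mode, class,
                               n_permutations = n_permutations, seed = seed)
    setNames(res$values$phi, res$values$feature)[feats]
  }
  keep_f <- abs(phi) > threshold
  tab <- data.frame(feature = feats[keep_f], phi = unname(phi[keep_f]))
  tab <- tab[order(-tab$phi, tab$feature), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, all_values = setNames(unname(phi), feats),
                 method = method, cohort = cohort, threshold = threshold,
                 mode = mode),
            class = "fa_risk_factors")
}

#' @export
print.fa_risk_factors <- function(x, digits = 3, ...) {
  cat("Risk factors (", x$method, ", cohort = ", x$cohort,
      ", |phi| > ", x$threshold, ")\n", sep = "")
  if (nrow(x$table) == 0) {
    cat("  none above threshold\n")
  } else {
    tab <- x$table
    tab$phi <- round(tab$phi, digits)
    print(tab)
  }
  invisible(x)
}

#' @export
print.fa_importance <- function(x, digits = 4, ...) {
  cat("Feature importances (", x$method, ", ", x$n_permutations,
      " permutations, seed ", x$seed, ")\n", sep = "")
  tab <- x$values[order(-abs(x$values$phi)), ]
  tab$phi <- round(tab$phi, digits)
  tab$se <- signif(tab$se, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}
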