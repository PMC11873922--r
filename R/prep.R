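# Pre-modelling steps: variable removal, attendance binning, sample
# weighting, train/test splitting and standardisation.

#' Drop excluded variables from a cohort table
#'
#' Removes interdependent variables before modelling. The default exclusion
#' list contains the SPARRA 12-month risk score (computed from variables
#' already in the table) and local council authority (redundant with SIMD);
#' neither is produced by the synthetic generator, so on synthetic cohorts
#' the default is a no-op -- the operation exists for externally supplied
#' tables. The target column can never be removed.
#'
#' @param table A cohort `data.frame`.
#' @param exclusions Character vector of column names to drop if present.
#' @return The table without the excluded columns.
#' @export
drop_excluded_variables <- function(table,
                                    exclusions = c("sparra_score",
                                                   "local_authority")) {
  if ("ae_attendances" %in% exclusions)
    stop("ae_attendances is the modelling target and cannot be excluded")
  keep <- setdiff(names(table), exclusions)
  table[keep]
}

#' Bin attendance counts into three classes
#'
#' Low attendance (class 0): fewer than 5 visits; mid attendance (class 1):
#' 5 to 10 visits; high attendance (class 2): more than 10 visits. Cohort
#' inclusion requires at least three visits, so counts below 3 are an error.
#'
#' @param v Integer vector of attendance counts.
#' @return Integer vector of classes in \{0, 1, 2\}.
#' @export
#' @examples
#' bin_attendance(c(3, 4, 5, 10, 11))  # 0 0 1 1 2
bin_attendance <- function(v) {
  if (any(v < 3))
    stop("attendance counts below 3 violate the cohort inclusion criterion ",
         "(patients with fewer than three visits are excluded)")
  ifelse(v > 10, 2L, ifelse(v >= 5, 1L, 0L))
}

#' Compute per-sample training weights
#'
#' Two strategies: `"inverse_class_frequency"` assigns each sample of class
#' c the weight \eqn{w_c = N / (K n_c)} (K = 3 classes), the balanced
#' convention in which every class carries equal total weight and the
#' weights sum to N; `"visit_value"` weights each sample by its attendance
#' count relative to the cohort mean, \eqn{w_i = v_i / \bar v}, so the loss
#' emphasises numerically important (high-attendance) patients.
#'
#' @param x Integer class labels (inverse_class_frequency) or visit counts
#'   (visit_value).
#' @param strategy One of `"inverse_class_frequency"`, `"visit_value"`.
#' @return List of class `fa_weights` with `strategy` and per-sample
#'   `weights`.
#' @export
#' @examples
#' w <- compute_sample_weights(c(0, 0, 1, 2), "inverse_class_frequency")
#' sum(w$weights)  # equals the number of samples
compute_sample_weights <- function(x,
                                   strategy = c("inverse_class_frequency",
                                                "visit_value")) {
  strategy <- match.arg(strategy)
  if (!length(x)) stop("empty input")
  if (strategy == "inverse_class_frequency") {
    k <- 3L
    counts <- tabulate(as.integer(x) + 1L, nbins = k)
    if (any(counts == 0))
      stop("class ", paste(which(counts == 0) - 1L, collapse = ", "),
           " has no samples; inverse-frequency weights undefined")
    w_class <- length(x) / (k * counts)
    weights <- w_class[as.integer(x) + 1L]
  } else {
    weights <- x / mean(x)
  }
  structure(list(strategy = strategy, weights = weights),
            class = "fa_weights")
}

#' Split a cohort into train and test partitions
#'
#' Seeded random partition; by default 70/30 and non-stratified. With
#' `stratified = TRUE` the test fraction is applied within each attendance
#' class (floor convention per class).
#'
#' @param table Cohort `data.frame` (must carry `ae_attendances` when
#'   stratifying).
#' @param test_fraction Fraction of rows held out (default 0.30).
#' @param seed Integer seed.
#' @param stratified Stratify by attendance class?
#' @return List with `train`, `test` (disjoint, exhaustive row subsets) and
#'   `test_idx` (the held-out row indices).
#' @export
split_train_test <- function(table, test_fraction = 0.30, seed = 1L,
                             stratified = FALSE) {
  if (test_fraction < 0 || test_fraction >= 1)
    stop("test_fraction must be in [0, 1)")
  n <- nrow(table)
  local_seed(seed)
  if (stratified) {
    cls <- bin_attendance(table$ae_attendances)
    test_idx <- unlist(lapply(sort(unique(cls)), function(c) {
      rows <- which(cls == c)
      sample(rows, floor(length(rows) * test_fraction))
    }), use.names = FALSE)
    test_idx <- sort(test_idx)
  } else {
    test_idx <- sort(sample.int(n, floor(n * test_fraction)))
  }
  list(train = table[setdiff(seq_len(n), test_idx), , drop = FALSE],
       test = table[test_idx, , drop = FALSE],
       test_idx = test_idx)
}

#' Standardise features, fitting on the training rows only
#'
#' Centres and scales every feature column using training-set means and
#' standard deviations, applying the same transform to the test rows (no
#' test-set leakage). Zero-variance training columns get scale 1 with a
#' warning. The untransformed matrices are retained so that zero-input
#' occlusion can act in raw feature space before re-encoding.
#'
#' @param train,test Feature `data.frame`s with identical columns.
#' @return List of class `fa_design` with standardised matrices
#'   `train`/`test`, raw matrices `train_raw`/`test_raw`, and the fitted
#'   `center`/`scale` vectors.
#' @export
encode_features <- function(train, test = train[0, , drop = FALSE]) {
  if (!identical(names(train), names(test)))
    stop("train and test schemas differ")
  xtr <- data.matrix(train)
  xte <- data.matrix(test)
  center <- colMeans(xtr)
  scale <- apply(xtr, 2, sd)
  zero <- !is.finite(scale) | scale == 0
  if (any(zero)) {
    warning("zero-variance column(s): ",
            paste(colnames(xtr)[zero], collapse = ", "),
            "; scale set to 1")
    scale[zero] <- 1
  }
  std <- function(m) sweep(sweep(m, 2, center), 2, scale, "/")
  structure(list(train = std(xtr), test = std(xte),
                 train_raw = xtr, test_raw = xte,
                 center = center, scale = scale),
            class = "fa_design")
}
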