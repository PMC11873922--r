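# Shared fixtures: small cohorts and toy classification problems built in
# code at test time.

small_cohort <- function(n = 1000, seed = 1) {
  generate_cohort(cohort_config(n_patients = n, seed = seed))
}

# Strip generator provenance attributes for value-level table comparison.
plain_df <- function(x) {
  x <- as.data.frame(x)
  attributes(x) <- attributes(x)[c("names", "row.names")]
  class(x) <- "data.frame"
  x
}

# Three well-separated Gaussian blobs in two features; labels 0/1/2.
blob_toy <- function(n_per_class = 60, sep = 6, noise = 1, seed = 1) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(sep, 0), c(0, sep))
  x <- do.call(rbind, lapply(1:3, function(k)
    cbind(rnorm(n_per_class, centers[k, 1], noise),
          rnorm(n_per_class, centers[k, 2], noise))))
  data.frame(f1 = x[, 1], f2 = x[, 2],
             y = rep(0:2, each = n_per_class))
}

# Imbalanced noisy linear toy: class along one direction, minority class 2.
imbalanced_toy <- function(n = 900, seed = 1) {
  set.seed(seed)
  x1 <- rnorm(n)
  x2 <- rnorm(n)
  score <- x1 + 0.5 * x2 + rnorm(n, sd = 0.8)
  q <- quantile(score, c(0.70, 0.95))
  y <- ifelse(score > q[2], 2L, ifelse(score > q[1], 1L, 0L))
  data.frame(f1 = x1, f2 = x2, y = y)
}
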