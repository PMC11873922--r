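# Value-hot focal cross-entropy: the one-hot target indicator is replaced by
# the patient's actual attendance count (scaled by a normaliser), and the
# focal factor (1 - p_true)^gamma down-weights easy examples.

#' Value-hot focal cross-entropy loss
#'
#' Mean over samples of
#' \deqn{L_i = \frac{v_i}{\nu} (1 - p_{i,c_i})^\gamma (-\log p_{i,c_i})}
#' where \eqn{v_i} is the attendance count, \eqn{\nu} the value normaliser,
#' \eqn{c_i} the true class and \eqn{p_{i,c_i}} the predicted probability of
#' the true class. With \eqn{\gamma = 0} and all \eqn{v_i = \nu} this is
#' exactly the standard cross entropy; \eqn{\gamma > 0} focuses training on
#' hard examples and the value weights prioritise numerically important
#' (high-attendance) patients over frequent ones.
#'
#' @param prob Numeric matrix (n x 3) of class probabilities, rows summing
#'   to 1.
#' @param true_class Integer class labels in \{0, 1, 2\}.
#' @param v Attendance counts (all \eqn{\ge 3} in cohort use; any positive
#'   values accepted).
#' @param gamma Focusing parameter \eqn{\gamma \ge 0} (default 2, the focal
#'   loss convention).
#' @param value_normaliser Positive normaliser \eqn{\nu} (default
#'   `mean(v)`, keeping loss magnitudes comparable to unit-weight training).
#' @return Non-negative scalar loss. True-class probabilities of exactly 0
#'   are clamped at 1e-12 with a warning.
#' @export
#' @examples
#' p <- matrix(c(0.5, 0.3, 0.2), 1)
#' value_hot_focal_loss(p, 0L, v = 1, gamma = 0, value_normaliser = 1)
#' # -log(0.5)
value_hot_focal_loss <- function(prob, true_class, v, gamma = 2,
                                 value_normaliser = mean(v)) {
  prob <- rbind(prob)
  stopifnot(gamma >= 0, value_normaliser > 0,
            nrow(prob) == length(true_class), length(v) == length(true_class))
  p_true <- prob[cbind(seq_along(true_class), as.integer(true_class) + 1L)]
  if (any(p_true <= 0)) {
    warning("true-class probabilities of 0 clamped at 1e-12")
    p_true <- pmax(p_true, 1e-12)
  }
  w <- v / value_normaliser
  mean(w * (1 - p_true)^gamma * (-log(p_true)))
}

#' Gradient of the value-hot focal loss with respect to logits
#'
#' Analytic gradient of [value_hot_focal_loss()] where the probabilities are
#' the softmax of the supplied logits. Used by the MLP training loop and
#' verifiable against central finite differences.
#'
#' @param logits Numeric matrix (n x 3) of unnormalised scores.
#' @inheritParams value_hot_focal_loss
#' @return Matrix of the same shape as `logits`: the gradient of the mean
#'   loss.
#' @export
value_hot_focal_grad <- function(logits, true_class, v, gamma = 2,
                                 value_normaliser = mean(v)) {
  logits <- rbind(logits)
  n <- nrow(logits)
  p <- softmax_rows(logits)
  idx <- cbind(seq_len(n), as.integer(true_class) + 1L)
  p_true <- pmax(p[idx], 1e-12)
  w <- v / value_normaliser
  # dL/dp_true for L = -w (1-p)^gamma log p
  one_m <- 1 - p_true
  focal_term <- if (gamma > 0) {
    ifelse(one_m < 1e-12, 0, gamma * one_m^(gamma - 1) * log(p_true))
  } else 0
  dldp <- w * (focal_term - one_m^gamma / p_true)
  # chain through softmax: dp_true/dz_c = p_true (1[c = true] - p_c)
  grad <- -p * (dldp * p_true)   # row i scaled by dL/dp_true * p_true
  grad[idx] <- grad[idx] + dldp * p_true
  grad / n
}

# Row-wise numerically stable softmax.
softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}
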