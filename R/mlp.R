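# Feed-forward network for three-class attendance prediction, trained with
# the value-hot focal loss. Hidden layers use batch normalisation + ReLU +
# dropout; optimisation is mini-batch Adam with L1/L2 weight penalties and
# early stopping on a held-out validation split. Implemented directly in
# base R matrix operations so the loss, its gradient and the training loop
# stay fully inspectable.

mlp_init <- function(d_in, hidden, d_out = 3L) {
  sizes <- c(d_in, hidden, d_out)
  n_lay <- length(sizes) - 1L
  layers <- vector("list", n_lay)
  for (l in seq_len(n_lay)) {
    fan_in <- sizes[l]; fan_out <- sizes[l + 1]
    # He initialisation, suited to ReLU units
    W <- matrix(rnorm(fan_in * fan_out, sd = sqrt(2 / fan_in)),
                fan_in, fan_out)
    if (l < n_lay) {
      layers[[l]] <- list(W = W, g = rep(1, fan_out), b = rep(0, fan_out),
                          run_mean = rep(0, fan_out),
                          run_var = rep(1, fan_out))
    } else {
      layers[[l]] <- list(W = W, b = rep(0, fan_out))
    }
  }
  layers
}

mlp_forward <- function(layers, x, dropout = 0, training = FALSE,
                        bn_eps = 1e-5, bn_momentum = 0.9) {
  n_lay <- length(layers)
  h <- x
  cache <- vector("list", n_lay)
  for (l in seq_len(n_lay)) {
    lay <- layers[[l]]
    a <- h %*% lay$W
    if (l < n_lay) {
      if (training) {
        mu <- colMeans(a)
        va <- colMeans(sweep(a, 2, mu)^2)
        layers[[l]]$run_mean <- bn_momentum * lay$run_mean +
          (1 - bn_momentum) * mu
        layers[[l]]$run_var <- bn_momentum * lay$run_var +
          (1 - bn_momentum) * va
      } else {
        mu <- lay$run_mean
        va <- lay$run_var
      }
      inv_sd <- 1 / sqrt(va + bn_eps)
      ahat <- sweep(sweep(a, 2, mu), 2, inv_sd, "*")
      z <- sweep(sweep(ahat, 2, lay$g, "*"), 2, lay$b, "+")
      act <- pmax(z, 0)
      mask <- NULL
      if (training && dropout > 0) {
        mask <- matrix(runif(length(act)) >= dropout, nrow(act)) /
          (1 - dropout)
        act <- act * mask
      }
      cache[[l]] <- list(h_in = h, a = a, mu = mu, va = va,
                         inv_sd = inv_sd, ahat = ahat, z = z, mask = mask)
      h <- act
    } else {
      z <- sweep(a, 2, lay$b, "+")
      cache[[l]] <- list(h_in = h)
      h <- z
    }
  }
  list(logits = h, cache = cache, layers = layers)
}

mlp_backward <- function(layers, cache, dlogits, dropout, l1, l2) {
  n_lay <- length(layers)
  grads <- vector("list", n_lay)
  dh <- dlogits
  for (l in rev(seq_len(n_lay))) {
    lay <- layers[[l]]
    cc <- cache[[l]]
    if (l == n_lay) {
      grads[[l]] <- list(W = crossprod(cc$h_in, dh) + l2 * lay$W +
                           l1 * sign(lay$W),
                         b = colSums(dh))
      dh <- dh %*% t(lay$W)
    } else {
      if (!is.null(cc$mask)) dh <- dh * cc$mask
      dz <- dh
      dz[cc$z <= 0] <- 0                       # ReLU
      dg <- colSums(dz * cc$ahat)
      db <- colSums(dz)
      dahat <- sweep(dz, 2, lay$g, "*")
      m <- nrow(dz)
      a_c <- sweep(cc$a, 2, cc$mu)
      dva <- colSums(dahat * a_c) * (-0.5) * cc$inv_sd^3
      dmu <- colSums(dahat) * (-cc$inv_sd) +
        dva * colMeans(-2 * a_c)
      da <- sweep(dahat, 2, cc$inv_sd, "*") +
        sweep(a_c, 2, 2 * dva / m, "*") +
        matrix(dmu / m, m, length(dmu), byrow = TRUE)
      grads[[l]] <- list(W = crossprod(cc$h_in, da) + l2 * lay$W +
                           l1 * sign(lay$W),
                         g = dg, b = db)
      dh <- da %*% t(lay$W)
    }
  }
  grads
}

adam_step <- function(layers, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in seq_along(layers)) {
    for (nm in intersect(names(grads[[l]]), c("W", "g", "b"))) {
      gr <- grads[[l]][[nm]]
      key <- paste0(l, ".", nm)
      if (is.null(state[[key]]))
        state[[key]] <- list(m = gr * 0, v = gr * 0)
      st <- state[[key]]
      st$m <- beta1 * st$m + (1 - beta1) * gr
      st$v <- beta2 * st$v + (1 - beta2) * gr^2
      state[[key]] <- st
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      layers[[l]][[nm]] <- layers[[l]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(layers = layers, state = state)
}

#' Train a multilayer perceptron with the value-hot focal loss
#'
#' Feed-forward network (input, hidden layers with batch normalisation +
#' ReLU + dropout, softmax over the three attendance classes) trained by
#' mini-batch Adam on [value_hot_focal_loss()] plus L1/L2 weight penalties,
#' with seeded initialisation and early stopping on a held-out validation
#' split. With `hidden = integer(0)` the network reduces to plain softmax
#' (multinomial logistic) regression.
#'
#' @param x Numeric matrix of (standardised) features.
#' @param y Integer class labels in \{0, 1, 2\}.
#' @param v Attendance counts used as value weights (default all 1, i.e.
#'   unweighted).
#' @param hidden Hidden layer widths (default `c(64, 32)`).
#' @param dropout Dropout rate between hidden layers (default 0.2).
#' @param l1,l2 L1/L2 penalty strengths on the weight matrices (defaults 0
#'   and 1e-4).
#' @param lr Adam learning rate (default 1e-3).
#' @param batch_size Mini-batch size (default 256).
#' @param epochs Maximum training epochs (default 200).
#' @param gamma Focal focusing parameter (default 2).
#' @param value_normaliser Value-weight normaliser (default `mean(v)`).
#' @param val_fraction Fraction of rows held out for early stopping
#'   (default 0.15; 0 disables early stopping).
#' @param patience Epochs without validation improvement before stopping
#'   (default 20).
#' @param seed Integer seed controlling initialisation, shuffling and
#'   dropout.
#' @return List of class `fa_mlp` with the fitted layers and training
#'   history; use [mlp_predict_proba()] or wrap via [fa_fit()].
#' @export
train_mlp <- function(x, y, v = rep(1, length(y)),
                      hidden = c(64L, 32L), dropout = 0.2,
                      l1 = 0, l2 = 1e-4, lr = 1e-3,
                      batch_size = 256L, epochs = 200L,
                      gamma = 2, value_normaliser = mean(v),
                      val_fraction = 0.15, patience = 20L, seed = 1L) {
  x <- as.matrix(x)
  y <- as.integer(y)
  stopifnot(nrow(x) == length(y), length(v) == length(y))
  local_seed(seed)
  n <- nrow(x)
  if (val_fraction > 0 && n >= 20) {
    val_idx <- sample.int(n, max(1L, floor(n * val_fraction)))
  } else {
    val_idx <- integer(0)
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  layers <- mlp_init(ncol(x), hidden)
  state <- list()
  t_step <- 0L
  best <- list(loss = Inf, layers = layers, epoch = 0L)
  wait <- 0L
  history <- numeric(0)
  for (ep in seq_len(epochs)) {
    ord <- sample(tr_idx)
    for (start in seq(1, length(ord), by = batch_size)) {
      bi <- ord[start:min(start + batch_size - 1L, length(ord))]
      if (length(bi) < 2) next
      fw <- mlp_forward(layers, x[bi, , drop = FALSE], dropout,
                        training = TRUE)
      layers <- fw$layers
      dlog <- value_hot_focal_grad(fw$logits, y[bi], v[bi], gamma,
                                   value_normaliser)
      grads <- mlp_backward(layers, fw$cache, dlog, dropout, l1, l2)
      t_step <- t_step + 1L
      upd <- adam_step(layers, grads, state, lr, t_step)
      layers <- upd$layers
      state <- upd$state
    }
    eval_idx <- if (length(val_idx)) val_idx else tr_idx
    p_eval <- softmax_rows(
      mlp_forward(layers, x[eval_idx, , drop = FALSE],
                  training = FALSE)$logits)
    ep_loss <- value_hot_focal_loss(p_eval, y[eval_idx], v[eval_idx],
                                    gamma, value_normaliser)
    if (!is.finite(ep_loss))
      stop("MLP training diverged at epoch ", ep,
           ": non-finite validation loss (lr = ", lr, ", gamma = ", gamma,
           ")")
    history <- c(history, ep_loss)
    if (ep_loss < best$loss - 1e-6) {
      best <- list(loss = ep_loss, layers = layers, epoch = ep)
      wait <- 0L
    } else if (length(val_idx)) {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  structure(list(layers = best$layers, hidden = hidden, gamma = gamma,
                 value_normaliser = value_normaliser, dropout = dropout,
                 l1 = l1, l2 = l2, history = history,
                 best_epoch = best$epoch, seed = seed),
            class = "fa_mlp")
}

#' Class probabilities from a fitted MLP
#'
#' Inference-mode forward pass (batch-norm running statistics, no dropout)
#' followed by a softmax.
#'
#' @param fit An `fa_mlp` from [train_mlp()].
#' @param x Feature matrix on the training scale.
#' @return n x 3 probability matrix.
#' @export
mlp_predict_proba <- function(fit, x) {
  stopifnot(inherits(fit, "fa_mlp"))
  softmax_rows(mlp_forward(fit$layers, as.matrix(x),
                           training = FALSE)$logits)
}
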