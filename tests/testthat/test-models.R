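# Model suite: specs honour stated hyperparameters; fits are seeded,
# weighted and produce valid probability rows.

test_that("model specs carry the stated hyperparameters", {
  expect_identical(model_spec("LR")$hyper$max_iterations, 100000L)
  rf <- model_spec("RF")$hyper
  expect_identical(rf$n_trees, 100L)
  expect_identical(rf$split_criterion, "gini")
  knn <- model_spec("KNN")$hyper
  expect_identical(knn$k, 18L)
  expect_identical(knn$metric, "euclidean")
  expect_identical(model_spec("SVM")$hyper$cost, 1)
  expect_error(model_spec("LR", bogus = 1), "unknown")
  expect_error(model_spec("KNN", k = -1), "positive")
})

test_that("every family emits valid probability rows and hard labels", {
  toy <- blob_toy(seed = 2)
  for (fam in c("LR", "RF", "SVM", "KNN", "MLP")) {
    spec <- if (fam == "MLP")
      model_spec(fam, epochs = 60L, hidden = c(16L), batch_size = 64L)
    else model_spec(fam)
    m <- fa_fit(spec, toy[c("f1", "f2")], toy$y, seed = 3)
    p <- predict(m, toy[c("f1", "f2")])
    expect_identical(dim(p), c(nrow(toy), 3L))
    expect_true(all(p >= 0))
    expect_true(all(abs(rowSums(p) - 1) < 1e-9))
    cl <- predict(m, toy[c("f1", "f2")], type = "class")
    expect_true(all(cl %in% 0:2))
  }
})

test_that("random forest separates a clean toy perfectly in training", {
  toy <- blob_toy(sep = 10, noise = 0.5, seed = 4)
  m <- fa_fit(model_spec("RF"), toy[c("f1", "f2")], toy$y, seed = 1)
  expect_identical(predict(m, toy[c("f1", "f2")], type = "class"), toy$y)
})

test_that("duplicating every row leaves the LR decision function unchanged", {
  toy <- imbalanced_toy(seed = 6)
  x <- toy[c("f1", "f2")]
  m1 <- fa_fit(model_spec("LR"), x, toy$y, seed = 1)
  m2 <- fa_fit(model_spec("LR"), rbind(x, x), c(toy$y, toy$y), seed = 1)
  grid <- data.frame(f1 = seq(-3, 3, length.out = 25),
                     f2 = seq(3, -3, length.out = 25))
  # analytic equivalence; quasi-Newton stopping leaves ~1e-4 numeric slack
  expect_equal(predict(m1, grid), predict(m2, grid), tolerance = 1e-2)
})

test_that("inverse-class-frequency weighting lifts minority recall", {
  toy <- imbalanced_toy(n = 1200, seed = 8)
  test <- imbalanced_toy(n = 600, seed = 9)
  x <- toy[c("f1", "f2")]
  rec2 <- function(weighting) {
    m <- fa_fit(model_spec("LR"), x, toy$y, weighting = weighting, seed = 1)
    pred <- predict(m, test[c("f1", "f2")], type = "class")
    sum(pred == 2 & test$y == 2) / sum(test$y == 2)
  }
  expect_gte(rec2("inverse_class_frequency"), rec2("none"))
})

test_that("fits are deterministic given the seed", {
  toy <- blob_toy(seed = 5)
  x <- toy[c("f1", "f2")]
  for (fam in c("RF", "SVM", "MLP")) {
    spec <- if (fam == "MLP")
      model_spec(fam, epochs = 30L, hidden = c(8L), batch_size = 64L)
    else model_spec(fam)
    p1 <- predict(fa_fit(spec, x, toy$y, seed = 7), x)
    p2 <- predict(fa_fit(spec, x, toy$y, seed = 7), x)
    expect_equal(p1, p2, tolerance = 1e-6)
  }
})

test_that("degenerate inputs are rejected with clear errors", {
  toy <- blob_toy(seed = 1)
  x <- toy[c("f1", "f2")]
  expect_error(fa_fit(model_spec("LR"), x, rep(0L, nrow(x))),
               "single class")
  expect_error(fa_fit(model_spec("LR"), x, toy$y[-1]), "label count")
  m <- fa_fit(model_spec("RF"), x, toy$y, seed = 1)
  expect_error(predict(m, data.frame(f1 = 1, wrong = 2)),
               "schema mismatch.*f2")
})

test_that("knn probabilities are neighbour class fractions", {
  x <- data.frame(f1 = c(0, 0.1, 0.2, 5, 5.1, 5.2),
                  f2 = c(0.1, -0.1, 0, 0.1, -0.1, 0))
  y <- c(0L, 0L, 1L, 2L, 2L, 2L)
  m <- fa_fit(model_spec("KNN", k = 3L), x, y, seed = 1)
  p <- predict(m, data.frame(f1 = c(0.05, 5.05), f2 = 0))
  expect_equal(p[1, ], c("0" = 2 / 3, "1" = 1 / 3, "2" = 0))
  expect_equal(p[2, ], c("0" = 0, "1" = 0, "2" = 1))
})

test_that("the MLP reduces to multinomial logistic regression", {
  # no hidden layers, gamma 0, unit values, no regularisation or dropout:
  # training loss should approach the softmax-regression optimum
  toy <- blob_toy(n_per_class = 50, sep = 3, noise = 1.2, seed = 10)
  x <- scale(as.matrix(toy[c("f1", "f2")]))
  fit <- train_mlp(x, toy$y, v = rep(1, nrow(toy)), hidden = integer(0),
                   dropout = 0, l1 = 0, l2 = 0, lr = 0.1,
                   batch_size = 150L, epochs = 400L, gamma = 0,
                   value_normaliser = 1, val_fraction = 0, seed = 2)
  p_mlp <- mlp_predict_proba(fit, x)
  loss_mlp <- value_hot_focal_loss(p_mlp, toy$y, rep(1, nrow(toy)),
                                   gamma = 0, value_normaliser = 1)
  ref <- nnet::multinom(y ~ f1 + f2, data = cbind(as.data.frame(x),
                                                  y = factor(toy$y)),
                        maxit = 1000, trace = FALSE)
  p_ref <- predict(ref, type = "probs")
  loss_ref <- value_hot_focal_loss(p_ref, toy$y, rep(1, nrow(toy)),
                                   gamma = 0, value_normaliser = 1)
  expect_lt(abs(loss_mlp - loss_ref), 0.05)
})

test_that("the MLP drives training loss down on a separable toy", {
  toy <- blob_toy(n_per_class = 60, sep = 8, noise = 0.8, seed = 12)
  x <- scale(as.matrix(toy[c("f1", "f2")]))
  fit <- train_mlp(x, toy$y, hidden = c(16L), dropout = 0, l2 = 0,
                   lr = 0.02, batch_size = 64L, epochs = 150L, gamma = 0,
                   v = rep(1, nrow(toy)), value_normaliser = 1,
                   val_fraction = 0, seed = 1)
  p <- mlp_predict_proba(fit, x)
  loss <- value_hot_focal_loss(p, toy$y, rep(1, nrow(toy)), gamma = 0,
                               value_normaliser = 1)
  expect_lt(loss, 0.1)
})
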