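# Three-class evaluation: confusion matrices, precision/recall/F1
# aggregates, and one-vs-rest ROC with macro-averaged AUC.

#' Three-class confusion matrix
#'
#' Entry (r, c) counts rows with actual class r predicted as class c
#' (rows = actual, columns = predicted).
#'
#' @param actual,predicted Integer labels in \{0, 1, 2\} of equal length.
#' @return 3 x 3 integer matrix with dimnames `actual` x `predicted`.
#' @export
confusion_matrix <- function(actual, predicted) {
  if (length(actual) != length(predicted))
    stop("actual and predicted must have equal length")
  if (!all(c(actual, predicted) %in% 0:2))
    stop("labels must lie in {0, 1, 2}")
  m <- table(factor(actual, levels = 0:2), factor(predicted, levels = 0:2))
  m <- matrix(as.integer(m), 3, 3,
              dimnames = list(actual = 0:2, predicted = 0:2))
  m
}

#' Precision, recall and F1 from a confusion matrix
#'
#' One-vs-rest precision and recall per class with the F1 harmonic mean,
#' plus both macro (unweighted) and support-weighted aggregates. A class
#' that is never predicted gets precision 0 with a warning (keeping the
#' aggregates finite); a class with no actual members gets recall 0
#' likewise.
#'
#' @param confusion 3 x 3 count matrix (rows = actual).
#' @return List with `per_class` (data.frame of precision/recall/f1/support),
#'   `macro` and `weighted` (named vectors), and `accuracy`.
#' @export
classification_metrics <- function(confusion) {
  stopifnot(is.matrix(confusion), all(dim(confusion) == 3),
            sum(confusion) > 0)
  tp <- diag(confusion)
  pred_pos <- colSums(confusion)
  support <- rowSums(confusion)
  if (any(pred_pos == 0 & support > 0))
    warning("class(es) ",
            paste(which(pred_pos == 0 & support > 0) - 1L, collapse = ", "),
            " never predicted; precision set to 0")
  precision <- ifelse(pred_pos > 0, tp / pred_pos, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  wts <- support / sum(support)
  list(per_class = data.frame(class = 0:2, precision = precision,
                              recall = recall, f1 = f1, support = support,
                              row.names = NULL),
       macro = c(precision = mean(precision), recall = mean(recall),
                 f1 = mean(f1)),
       weighted = c(precision = sum(wts * precision),
                    recall = sum(wts * recall), f1 = sum(wts * f1)),
       accuracy = sum(tp) / sum(confusion))
}

#' One-vs-rest ROC curve and AUC
#'
#' Treats the positive class against the union of the other classes,
#' sweeping thresholds over the positive-class probability. Tied scores are
#' grouped into single thresholds; the AUC is the trapezoidal area under
#' the resulting TPR/FPR staircase (equivalently, the concordance
#' probability with ties counted half).
#'
#' @param actual Integer labels in \{0, 1, 2\}.
#' @param prob n x 3 probability matrix (or, for binary problems, a vector
#'   of positive-class scores).
#' @param positive_class Class treated as positive (0, 1 or 2).
#' @return List of class `fa_roc`: `points` (data.frame with threshold,
#'   fpr, tpr) and `auc`.
#' @export
#' @examples
#' roc_curve_ovr(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8), 1)$auc  # 0.75
roc_curve_ovr <- function(actual, prob, positive_class) {
  scores <- if (is.matrix(prob)) prob[, positive_class + 1L] else prob
  stopifnot(length(scores) == length(actual))
  pos <- actual == positive_class
  if (!any(pos))
    stop("positive class ", positive_class,
         " absent from actual labels; AUC undefined")
  if (all(pos))
    stop("no negative examples for class ", positive_class,
         "; AUC undefined")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- pos[ord]
  # group tied scores into single thresholds
  last_of_group <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last_of_group]
  fp <- cumsum(!y)[last_of_group]
  tpr <- c(0, tp / sum(pos))
  fpr <- c(0, fp / sum(!pos))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(list(points = data.frame(threshold = c(Inf, s[last_of_group]),
                                     fpr = fpr, tpr = tpr),
                 auc = auc, positive_class = positive_class),
            class = "fa_roc")
}

#' Macro-average AUC
#'
#' Unweighted mean of the per-class one-vs-rest AUCs.
#'
#' @param aucs Numeric vector of finite per-class AUCs.
#' @return Scalar mean AUC.
#' @export
auc_macro <- function(aucs) {
  stopifnot(all(is.finite(aucs)))
  mean(aucs)
}

#' Evaluate a probability classifier on labelled data
#'
#' Hard labels are the arg-max of the probability rows (ties to the
#' smallest class index); the report combines the confusion matrix,
#' per-class and aggregate precision/recall/F1, per-class one-vs-rest ROC
#' curves and the macro AUC.
#'
#' @param actual Integer labels in \{0, 1, 2\}.
#' @param prob n x 3 probability matrix.
#' @return Object of class `fa_eval`.
#' @export
evaluate_model <- function(actual, prob) {
  prob <- rbind(prob)
  predicted <- max.col(prob, ties.method = "first") - 1L
  conf <- confusion_matrix(actual, predicted)
  metrics <- classification_metrics(conf)
  roc <- lapply(0:2, function(c) {
    if (any(actual == c) && !all(actual == c))
      roc_curve_ovr(actual, prob, c)
    else NULL
  })
  aucs <- vapply(roc, function(r) if (is.null(r)) NA_real_ else r$auc,
                 numeric(1))
  structure(list(confusion = conf, metrics = metrics, roc = roc,
                 auc_per_class = aucs,
                 auc_macro = if (all(is.finite(aucs))) auc_macro(aucs)
                 else NA_real_),
            class = "fa_eval")
}

#' @export
print.fa_eval <- function(x, digits = 3, ...) {
  cat("Three-class evaluation (", sum(x$confusion), " records)\n", sep = "")
  print(x$confusion)
  cat("\nPer class:\n")
  print(cbind(round(x$metrics$per_class[2:4], digits),
              support = x$metrics$per_class$support,
              auc = round(x$auc_per_class, digits)))
  cat(sprintf("\nmacro    P %.3f  R %.3f  F1 %.3f\n",
              x$metrics$macro["precision"], x$metrics$macro["recall"],
              x$metrics$macro["f1"]))
  cat(sprintf("weighted P %.3f  R %.3f  F1 %.3f\n",
              x$metrics$weighted["precision"], x$metrics$weighted["recall"],
              x$metrics$weighted["f1"]))
  cat(sprintf("accuracy %.3f  macro AUC %.3f\n", x$metrics$accuracy,
              x$auc_macro))
  invisible(x)
}

#' Serialise an evaluation report to JSON
#'
#' @param x An `fa_eval`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_eval_json <- function(x, path) {
  stopifnot(inherits(x, "fa_eval"))
  out <- list(confusion = unclass(x$confusion),
              per_class = x$metrics$per_class,
              macro = as.list(x$metrics$macro),
              weighted = as.list(x$metrics$weighted),
              accuracy = x$metrics$accuracy,
              auc_per_class = x$auc_per_class,
              auc_macro = x$auc_macro)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
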