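#' Regression metrics for one target
#'
#' Root-mean-squared error, mean absolute error and the coefficient of
#' determination,
#' `R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`.
#' With zero-variance truth R2 is undefined and returned as `NA` with a
#' warning flag — in that situation use [r2_star()] instead.
#'
#' @param y_true,y_pred Numeric vectors of equal length >= 1.
#' @return List with `rmse`, `mae`, `r2`, and logical `r2_defined`.
#' @examples
#' regression_metrics(c(1, 2, 3), c(2, 2, 2))  # rmse sqrt(2/3), R2 = 0
#' @export
regression_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) < 1)
    stop("y_true and y_pred must have equal positive length")
  r <- y_true - y_pred
  sst <- sum((y_true - mean(y_true))^2)
  list(rmse = sqrt(mean(r^2)), mae = mean(abs(r)),
       r2 = if (sst == 0) NA_real_ else 1 - sum(r^2) / sst,
       r2_defined = sst > 0)
}

#' Adapted coefficient of determination (R2*)
#'
#' `R2* = 1 - sum((y - yhat)^2) / sum(y^2)`: the residual sum of squares is
#' normalized by the raw (uncentered) sum of squares of the truth rather
#' than its variance. Intended for blocks of test records that share a
#' single true label (e.g. 100 noise environments of one subject), where
#' the between-record variance is zero and ordinary R2 is undefined.
#'
#' @param y_true,y_pred Numeric vectors of equal length.
#' @return A scalar <= 1.
#' @examples
#' r2_star(c(2, 2), c(1, 1))  # 1 - 2/8 = 0.75
#' @export
r2_star <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) < 1)
    stop("y_true and y_pred must have equal positive length")
  ss <- sum(y_true^2)
  if (ss == 0) stop("sum of squared truth is zero: R2* undefined")
  1 - sum((y_true - y_pred)^2) / ss
}

#' Classification metrics with confusion matrix
#'
#' Confusion matrix (rows = truth, columns = prediction), overall accuracy
#' (trace / N), and one-vs-rest precision, recall and F1 per class,
#' macro-averaged without weights. A class absent from the truth has
#' undefined recall; its per-class entries are `NaN` and are excluded from
#' the macro averages (flagged via `complete`).
#'
#' @param y_true,y_pred Integer class labels in `1..n_classes` (or factors
#'   with identical levels).
#' @param n_classes Number of classes (default: max observed).
#' @return List with `confusion`, `accuracy`, per-class `precision`,
#'   `recall`, `f1`, their macro averages, and `complete`.
#' @examples
#' classification_metrics(c(1, 2, 3), c(1, 2, 3))$accuracy  # 1
#' @export
classification_metrics <- function(y_true, y_pred, n_classes = NULL) {
  if (is.factor(y_true)) y_true <- as.integer(y_true)
  if (is.factor(y_pred)) y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  n_classes <- n_classes %||% max(y_true, y_pred)
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(y_true)) cm[y_true[i], y_pred[i]] <-
      cm[y_true[i], y_pred[i]] + 1L
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  precision <- tp / (tp + fp)   # NaN when the class is never predicted
  recall <- tp / (tp + fn)      # NaN when the class is absent from truth
  f1 <- 2 * precision * recall / (precision + recall)
  f1[is.nan(f1)] <- NaN
  present <- (tp + fn) > 0
  macro <- function(v) mean(v[present & !is.nan(v)])
  list(confusion = cm, accuracy = sum(tp) / length(y_true),
       precision = precision, recall = recall, f1 = f1,
       precision_macro = macro(precision), recall_macro = macro(recall),
       f1_macro = macro(f1), complete = all(present))
}

#' Binary confusion-cell metrics
#'
#' Precision, recall and F1 straight from true/false positive/negative
#' counts — the textbook contingency form.
#'
#' @param tp,fp,fn,tn Non-negative counts.
#' @return List with `accuracy`, `precision`, `recall`, `f1`.
#' @examples
#' confusion_cell_metrics(tp = 40, fp = 10, fn = 20, tn = 30)
#' @export
confusion_cell_metrics <- function(tp, fp, fn, tn) {
  precision <- tp / (tp + fp)
  recall <- tp / (tp + fn)
  list(accuracy = (tp + tn) / (tp + tn + fp + fn),
       precision = precision, recall = recall,
       f1 = 2 * recall * precision / (recall + precision))
}
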