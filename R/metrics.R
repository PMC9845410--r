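#' Confusion counts for binary predictions
#'
#' @param y_true,y_pred binary (0/1) vectors of equal length; class 1 is
#'   the positive class.
#' @return A list of class `confusion_counts` with integer fields `tp`
#'   (positives judged positive), `fp` (negatives judged positive), `tn`,
#'   `fn` and `n`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("confusion_counts: unequal lengths")
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1)))
    stop("confusion_counts: inputs must be binary 0/1")
  structure(list(tp = sum(y_true == 1 & y_pred == 1),
                 fp = sum(y_true == 0 & y_pred == 1),
                 tn = sum(y_true == 0 & y_pred == 0),
                 fn = sum(y_true == 1 & y_pred == 0),
                 n = length(y_true)),
            class = "confusion_counts")
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' Accuracy = (TP + TN) / n; precision = TP / (TP + FP); recall =
#' TP / (TP + FN); F1 = 2 TP / (2 TP + FP + FN). When no sample is judged
#' positive (TP + FP = 0) precision is undefined: it is reported as `NA`
#' with `precision_defined = FALSE` and F1 is set to 0. Recall is treated
#' the same way when there are no true positives in the evaluation set.
#'
#' @param counts a [confusion_counts()] object.
#' @return A list of class `classification_metrics` with fields
#'   `accuracy`, `precision`, `recall`, `f1`, `precision_defined`,
#'   `recall_defined`.
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (counts$n == 0) stop("classification_metrics: no samples")
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  prec_def <- (tp + fp) > 0
  rec_def <- (tp + fn) > 0
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
  structure(list(
    accuracy = (tp + tn) / counts$n,
    precision = if (prec_def) tp / (tp + fp) else NA_real_,
    recall = if (rec_def) tp / (tp + fn) else NA_real_,
    f1 = if (prec_def && rec_def) f1 else 0,
    precision_defined = prec_def,
    recall_defined = rec_def), class = "classification_metrics")
}

#' Cohen's kappa for binary predictions
#'
#' Chance-corrected agreement `kappa = (p0 - pe) / (1 - pe)`, where p0 is
#' the observed agreement (accuracy) and pe the chance agreement from the
#' marginal class frequencies of truth and prediction. When pe = 1 (both
#' marginals degenerate) kappa is defined as 1 if agreement is perfect and
#' otherwise 0 with a `degenerate` attribute.
#'
#' @param y_true,y_pred binary (0/1) vectors of equal length.
#' @return kappa, with attributes `p0` and `pe`.
#' @export
cohen_kappa <- function(y_true, y_pred) {
  cc <- confusion_counts(y_true, y_pred)
  n <- cc$n
  p0 <- (cc$tp + cc$tn) / n
  pe <- ((cc$tp + cc$fn) / n) * ((cc$tp + cc$fp) / n) +
    ((cc$fp + cc$tn) / n) * ((cc$fn + cc$tn) / n)
  if (pe == 1) {
    k <- if (p0 == 1) 1 else 0
    return(structure(k, p0 = p0, pe = pe,
                     degenerate = !(p0 == 1)))
  }
  structure((p0 - pe) / (1 - pe), p0 = p0, pe = pe, degenerate = FALSE)
}

#' ROC curve and AUC by threshold sweep
#'
#' Thresholds sweep the unique scores in descending order; at each
#' threshold a sample is predicted positive when its score is at least the
#' threshold, giving one (FPR, TPR) point, with tied scores grouped at a
#' single threshold. The curve starts at (0, 0) (threshold above every
#' score) and ends at (1, 1); AUC is computed by the trapezoid rule.
#'
#' @param y_true binary (0/1) vector with both classes present.
#' @param scores numeric scores, larger meaning more positive.
#' @return A list of class `roc_curve`: `fpr`, `tpr`, `thresholds`
#'   (leading `Inf` for the (0,0) point) and `auc`.
#' @export
roc_curve <- function(y_true, scores) {
  if (length(y_true) != length(scores)) stop("roc_curve: unequal lengths")
  if (!all(y_true %in% c(0, 1))) stop("roc_curve: y_true must be binary")
  n_pos <- sum(y_true == 1)
  n_neg <- sum(y_true == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("roc_curve: both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- y_true[ord]
  # group ties: last index of each run of equal scores
  last <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(y == 1)[last]
  fp <- cumsum(y == 0)[last]
  structure(list(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos),
                 thresholds = c(Inf, s[last]),
                 auc = sum(diff(c(0, fp / n_neg)) *
                             (utils::head(c(0, tp / n_pos), -1) +
                                utils::tail(c(0, tp / n_pos), -1)) / 2)),
            class = "roc_curve")
}

#' Regression error metrics
#'
#' MAE = mean absolute error, MSE = mean squared error, and the
#' coefficient of determination `R2 = 1 - SS_res / SS_tot`. A constant
#' truth vector leaves R2 undefined (`NA` with `r2_defined = FALSE`).
#'
#' @param y_true,y_pred numeric vectors of equal length.
#' @return A list of class `regression_metrics` with fields `mae`, `mse`,
#'   `r2`, `r2_defined`.
#' @export
regression_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("regression_metrics: unequal lengths")
  res <- y_true - y_pred
  ss_tot <- sum((y_true - mean(y_true))^2)
  structure(list(mae = mean(abs(res)), mse = mean(res^2),
                 r2 = if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_,
                 r2_defined = ss_tot > 0),
            class = "regression_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf(
    "accuracy %.4f  precision %s  recall %s  f1 %.4f\n", x$accuracy,
    if (x$precision_defined) sprintf("%.4f", x$precision) else "NA",
    if (x$recall_defined) sprintf("%.4f", x$recall) else "NA", x$f1))
  invisible(x)
}

#' @export
print.regression_metrics <- function(x, ...) {
  cat(sprintf("MAE %.4f  MSE %.4f  R2 %s\n", x$mae, x$mse,
              if (x$r2_defined) sprintf("%.4f", x$r2) else "NA"))
  invisible(x)
}
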