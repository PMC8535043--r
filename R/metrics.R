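# Confusion-count metrics and the classification report.

#' Confusion counts of binary predictions
#'
#' Positive class is label 1.
#'
#' @param y_true 0/1 vector of reference labels.
#' @param y_pred 0/1 vector of predictions, same length.
#' @return object of class `confusion_counts`: list with `tp`, `fp`, `tn`,
#'   `fn`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stopf("y_true and y_pred lengths differ (%d vs %d)",
          length(y_true), length(y_pred))
  if (!all(y_true %in% 0:1) || !all(y_pred %in% 0:1))
    stopf("labels and predictions must be coded 0/1")
  structure(list(tp = sum(y_true == 1 & y_pred == 1),
                 fp = sum(y_true == 0 & y_pred == 1),
                 tn = sum(y_true == 0 & y_pred == 0),
                 fn = sum(y_true == 1 & y_pred == 0)),
            class = "confusion_counts")
}

rate <- function(num, den, what) {
  if (den == 0) {
    warning(sprintf("%s undefined (0/0); returning 0", what), call. = FALSE)
    return(0)
  }
  num / den
}

#' Sensitivity (true-positive rate): TP / (TP + FN)
#' @param cc [confusion()] counts.
#' @return rate in \[0, 1\]; 0 with a warning when TP + FN = 0.
#' @export
sensitivity <- function(cc) rate(cc$tp, cc$tp + cc$fn, "sensitivity")

#' Specificity (true-negative rate): TN / (TN + FP)
#' @param cc [confusion()] counts.
#' @return rate in \[0, 1\]; 0 with a warning when TN + FP = 0.
#' @export
specificity <- function(cc) rate(cc$tn, cc$tn + cc$fp, "specificity")

#' AUC from hard-prediction rates
#'
#' The closed form `(1 + TPR - FPR) / 2`: the area under the two-segment
#' ROC curve through the single operating point of a hard classifier.
#'
#' @param tpr true-positive rate (sensitivity) in \[0, 1\].
#' @param fpr false-positive rate (1 - specificity) in \[0, 1\].
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' auc_from_rates(0.94, 0) # 0.97
auc_from_rates <- function(tpr, fpr) {
  if (any(tpr < 0 | tpr > 1) || any(fpr < 0 | fpr > 1))
    stopf("tpr and fpr must lie in [0, 1]")
  (1 + tpr - fpr) / 2
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2PR / (P + R)`; 0 when both inputs are 0.
#'
#' @param precision,recall rates in \[0, 1\].
#' @return F1 in \[0, 1\].
#' @export
#' @examples
#' f1_score(0.92, 0.79) # 0.85 at two decimals
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Per-class precision/recall/F1 report
#'
#' Mirrors the familiar two-class classification report: per-class
#' precision, recall, F1 and support, overall accuracy, and macro
#' (unweighted) and weighted (support-weighted) averages.
#'
#' @inheritParams confusion
#' @return object of class `class_report`: list with `per_class`
#'   (data.frame, classes "0" and "1"), `accuracy`, `macro`, `weighted`.
#' @export
class_report <- function(y_true, y_pred) {
  cc <- confusion(y_true, y_pred)
  per_class <- do.call(rbind, lapply(c(0, 1), function(cl) {
    tp <- if (cl == 1) cc$tp else cc$tn
    fp <- if (cl == 1) cc$fp else cc$fn
    fn <- if (cl == 1) cc$fn else cc$fp
    prec <- rate(tp, tp + fp, sprintf("precision of class %d", cl))
    rec <- rate(tp, tp + fn, sprintf("recall of class %d", cl))
    f1 <- f1_score(prec, rec)
    data.frame(class = as.character(cl), precision = prec, recall = rec,
               f1 = f1, support = sum(y_true == cl),
               stringsAsFactors = FALSE)
  }))
  n <- length(y_true)
  w <- per_class$support / n
  structure(list(
    per_class = per_class,
    accuracy = (cc$tp + cc$tn) / n,
    macro = colMeans(per_class[, c("precision", "recall", "f1")]),
    weighted = colSums(per_class[, c("precision", "recall", "f1")] * w)),
    class = "class_report")
}

#' @export
print.class_report <- function(x, ...) {
  df <- x$per_class
  df[, 2:4] <- round_half_away(as.matrix(df[, 2:4]), 2)
  print(df, row.names = FALSE)
  cat(sprintf("accuracy: %.2f   macro f1: %.2f   weighted f1: %.2f\n",
              round_half_away(x$accuracy, 2), round_half_away(x$macro["f1"], 2),
              round_half_away(x$weighted["f1"], 2)))
  invisible(x)
}
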