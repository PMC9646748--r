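#' Confusion matrix of frame-level predictions
#'
#' Rows are true labels, columns predicted labels, in the fixed class
#' order of [well_classes()] (or a supplied level set).
#'
#' @param true,predicted equal-length label vectors.
#' @param classes class order (default the four well classes).
#' @return Integer `k x k` matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(true, predicted, classes = well_classes()) {
  check(length(true) == length(predicted),
        "true and predicted must have equal length")
  true <- factor(as.character(true), levels = classes)
  predicted <- factor(as.character(predicted), levels = classes)
  check(!anyNA(true) && !anyNA(predicted), "labels outside the class set")
  cm <- table(true = true, predicted = predicted)
  structure(unclass(cm), class = c("confusion_matrix", "matrix", "array"))
}

#' Overall accuracy
#'
#' Fraction of correctly classified items: the trace of the confusion
#' matrix over its total.  In the binary case this reduces to
#' `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param cm a [confusion_matrix()] (any square count matrix).
#' @return Fraction in [0, 1].
#' @export
accuracy <- function(cm) {
  cm <- as.matrix(cm)
  check(nrow(cm) == ncol(cm) && all(cm >= 0), "need a square count matrix")
  total <- sum(cm)
  check(total > 0, "empty confusion matrix")
  sum(diag(cm)) / total
}

#' Per-class recall and precision (one-vs-rest)
#'
#' `Recall = TP / (TP + FN)` and `Precision = TP / (TP + FP)` for one
#' class, with TP the diagonal entry, FN the rest of its row and FP the
#' rest of its column.  A 0/0 ratio (class absent from the truth, or never
#' predicted) is reported as `NA`, not silently as zero.
#'
#' @param cm a [confusion_matrix()].
#' @param class class name or index.
#' @return Named numeric vector `c(recall, precision)`.
#' @export
recall_precision <- function(cm, class) {
  cm <- as.matrix(cm)
  i <- if (is.character(class)) match(class, rownames(cm)) else as.integer(class)
  check(!is.na(i) && i >= 1 && i <= nrow(cm), "class not in matrix")
  tp <- cm[i, i]
  fn <- sum(cm[i, ]) - tp
  fp <- sum(cm[, i]) - tp
  c(recall = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp))
}

#' Full per-class score table
#'
#' TP / FP / FN / TN counts plus recall and precision for every class of a
#' confusion matrix.
#'
#' @param cm a [confusion_matrix()].
#' @return Data frame with one row per class.
#' @export
class_scores <- function(cm) {
  cm <- as.matrix(cm)
  total <- sum(cm)
  out <- lapply(seq_len(nrow(cm)), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    rp <- recall_precision(cm, i)
    data.frame(class = rownames(cm)[i], TP = tp, FP = fp, FN = fn,
               TN = total - tp - fp - fn,
               recall = rp[["recall"]], precision = rp[["precision"]])
  })
  do.call(rbind, out)
}
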