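#' Confusion matrix
#'
#' @param truth True group labels.
#' @param predicted Predicted group labels. Predicted labels outside the set
#'   of true levels are rejected.
#' @return Contingency table with true groups as rows and predicted groups
#'   as columns, over the union of levels.
#' @export
confusion_matrix <- function(truth, predicted) {
  truth <- as.factor(truth)
  predicted <- as.factor(predicted)
  unseen <- setdiff(levels(droplevels(predicted)), levels(truth))
  if (length(unseen))
    stop("predicted label(s) not in the true label set: ",
         paste(unseen, collapse = ", "), call. = FALSE)
  lev <- levels(truth)
  table(truth = factor(truth, levels = lev),
        predicted = factor(predicted, levels = lev))
}

#' Balanced accuracy
#'
#' For a binary outcome, `(sensitivity + specificity) / 2`; for a multiclass
#' outcome, the mean per-group recall. Both are the mean of the per-group
#' recalls, so a single formula serves.
#'
#' @param truth True labels, or a square confusion matrix (true groups in
#'   rows) if `predicted` is missing.
#' @param predicted Predicted labels.
#' @return Balanced accuracy in `[0, 1]`.
#' @export
#' @examples
#' balanced_accuracy(matrix(c(8, 4, 2, 6), 2)) # recalls 0.8 and 0.6 -> 0.7
balanced_accuracy <- function(truth, predicted) {
  cm <- if (missing(predicted)) as.matrix(truth)
        else confusion_matrix(truth, predicted)
  rs <- rowSums(cm)
  if (any(rs == 0))
    stop("every true group needs at least one sample", call. = FALSE)
  mean(diag(cm) / rs)
}

#' Classification report
#'
#' Confusion-derived metrics: overall accuracy, per-group recall and
#' precision, F1, their macro averages, and balanced accuracy. Precision for
#' a group that was never predicted is counted as 0.
#'
#' @inheritParams confusion_matrix
#' @return An object of class `"classification_report"`: a list with
#'   `confusion`, `accuracy`, `recall`, `precision`, `f1` (per group),
#'   `macro_recall`, `macro_precision`, `macro_f1`, `balanced_accuracy`.
#' @export
classification_report <- function(truth, predicted) {
  cm <- confusion_matrix(truth, predicted)
  rs <- rowSums(cm)
  cs <- colSums(cm)
  if (any(rs == 0))
    stop("every true group needs at least one sample", call. = FALSE)
  recall <- diag(cm) / rs
  precision <- ifelse(cs > 0, diag(cm) / cs, 0)
  f1 <- ifelse(recall + precision > 0,
               2 * recall * precision / (recall + precision), 0)
  structure(list(
    confusion = cm,
    accuracy = sum(diag(cm)) / sum(cm),
    recall = recall,
    precision = precision,
    f1 = f1,
    macro_recall = mean(recall),
    macro_precision = mean(precision),
    macro_f1 = mean(f1),
    balanced_accuracy = mean(recall)
  ), class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("classification report\n")
  print(x$confusion)
  cat(sprintf("accuracy %.4f | balanced accuracy %.4f | macro F1 %.4f\n",
              x$accuracy, x$balanced_accuracy, x$macro_f1))
  invisible(x)
}

#' Feature-selection sensitivity and specificity
#'
#' Compares selected feature indices with the planted truth, per block and
#' pooled over blocks. Sensitivity is `TP / (TP + FN)` over the truly
#' relevant features, specificity `TN / (TN + FP)` over the irrelevant ones.
#' "Pooled" rates sum the counts over blocks; the per-block mean of the
#' rates is also reported.
#'
#' @param selected List (one element per block) of selected feature indices.
#' @param truth List (same shape) of truly relevant feature indices; no
#'   block may have an empty truth set.
#' @param m_per_block Integer vector of per-block feature counts.
#' @return An object of class `"selection_metrics"`: per-block data frame
#'   `per_block` (TP/FP/TN/FN, sensitivity, specificity), pooled
#'   `sensitivity`/`specificity`, and `mean_sensitivity`/`mean_specificity`
#'   (average of the block-level rates).
#' @export
selection_metrics <- function(selected, truth, m_per_block) {
  B <- length(m_per_block)
  if (length(selected) != B || length(truth) != B)
    stop("'selected' and 'truth' must have one element per block",
         call. = FALSE)
  rows <- vector("list", B)
  for (b in seq_len(B)) {
    m <- m_per_block[b]
    sel <- unique(as.integer(selected[[b]]))
    tru <- unique(as.integer(truth[[b]]))
    if (length(tru) == 0L)
      stop("block ", b, ": empty truth set; sensitivity undefined",
           call. = FALSE)
    if (length(sel) && (min(sel) < 1L || max(sel) > m))
      stop("block ", b, ": selected index out of range", call. = FALSE)
    if (min(tru) < 1L || max(tru) > m)
      stop("block ", b, ": truth index out of range", call. = FALSE)
    tp <- length(intersect(sel, tru))
    fp <- length(setdiff(sel, tru))
    fn <- length(setdiff(tru, sel))
    tn <- m - tp - fp - fn
    rows[[b]] <- data.frame(block = b, TP = tp, FP = fp, TN = tn, FN = fn,
                            sensitivity = tp / (tp + fn),
                            specificity = if (tn + fp > 0) tn / (tn + fp)
                                          else NA_real_)
  }
  per_block <- do.call(rbind, rows)
  tot <- colSums(per_block[, c("TP", "FP", "TN", "FN")])
  structure(list(
    per_block = per_block,
    sensitivity = tot[["TP"]] / (tot[["TP"]] + tot[["FN"]]),
    specificity = tot[["TN"]] / (tot[["TN"]] + tot[["FP"]]),
    mean_sensitivity = mean(per_block$sensitivity),
    mean_specificity = mean(per_block$specificity)
  ), class = "selection_metrics")
}

#' @export
print.selection_metrics <- function(x, ...) {
  print(x$per_block, row.names = FALSE)
  cat(sprintf("pooled sensitivity %.4f | pooled specificity %.4f\n",
              x$sensitivity, x$specificity))
  invisible(x)
}
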