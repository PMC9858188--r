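# Evaluation machinery: binary classification metrics, ROC/AUC, PR/AP,
# and multi-class confusion matrices.

#' Confusion counts from binary labels
#'
#' @param truth,pred logical (or 0/1) vectors of equal length.
#' @returns Named list with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  truth <- as.logical(truth)
  pred <- as.logical(pred)
  list(
    tp = sum(truth & pred), fp = sum(!truth & pred),
    tn = sum(!truth & !pred), fn = sum(truth & !pred)
  )
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' `accuracy = (TP+TN)/(TP+FP+TN+FN)`, `precision = TP/(TP+FP)`,
#' `recall = TP/(TP+FN)`, `f1` the harmonic mean of precision and recall.
#' A zero denominator makes the metric undefined: it is reported as `NaN`
#' with a warning, never silently as 0.
#'
#' @param tp,fp,tn,fn non-negative counts, or pass a list (as returned by
#'   [confusion_counts()]) as `tp`.
#' @returns One-row tibble with `accuracy`, `precision`, `recall`, `f1`.
#' @examples
#' binary_metrics(tp = 3, fp = 1, tn = 5, fn = 1)
#' @export
binary_metrics <- function(tp, fp = NULL, tn = NULL, fn = NULL) {
  if (is.list(tp)) {
    c0 <- tp
    tp <- c0$tp; fp <- c0$fp; tn <- c0$tn; fn <- c0$fn
  }
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reporting NaN",
              call. = FALSE)
      return(NaN)
    }
    num / den
  }
  acc <- safe_div(tp + tn, tp + fp + tn + fn, "accuracy")
  prec <- safe_div(tp, tp + fp, "precision")
  rec <- safe_div(tp, tp + fn, "recall")
  f1 <- if (is.nan(prec) || is.nan(rec) || prec + rec == 0) {
    if (!is.nan(prec) && !is.nan(rec)) {
      warning("f1 undefined (precision + recall = 0); reporting NaN",
              call. = FALSE)
    }
    NaN
  } else {
    2 * prec * rec / (prec + rec)
  }
  tibble::tibble(accuracy = acc, precision = prec, recall = rec, f1 = f1)
}

#' ROC curve and AUC
#'
#' Sweeps the prediction threshold over the unique scores (predict
#' positive iff `score >= t`); equal scores are grouped so ties move along
#' a straight segment. AUC is the trapezoidal area under the curve.
#'
#' @param scores numeric prediction scores.
#' @param labels logical (or 0/1) ground-truth labels; both classes must
#'   be present.
#' @returns Object of class `her2_roc`: list with `points` (tibble
#'   `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  if (!any(labels) || all(labels)) {
    stop("both classes must be present to compute a ROC curve",
         call. = FALSE)
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  l <- labels[o]
  # group ties: cumulative counts at the last index of each distinct score
  last <- which(!duplicated(s, fromLast = TRUE))
  n1 <- sum(l)
  n0 <- sum(!l)
  tp <- cumsum(l)[last]
  fp <- cumsum(!l)[last]
  points <- tibble::tibble(
    threshold = c(Inf, s[last]),
    fpr = c(0, fp / n0),
    tpr = c(0, tp / n1)
  )
  auc <- sum(diff(points$fpr) * (head(points$tpr, -1) + points$tpr[-1]) / 2)
  structure(list(points = points, auc = auc), class = "her2_roc")
}

#' Precision-recall curve and average precision
#'
#' Threshold sweep as in [roc_curve()]; average precision uses step
#' interpolation, `AP = sum((R_i - R_(i-1)) * P_i)`.
#'
#' @inheritParams roc_curve
#' @returns Object of class `her2_pr`: list with `points` (tibble
#'   `threshold`, `recall`, `precision`) and `ap`.
#' @export
pr_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  if (!any(labels) || all(labels)) {
    stop("both classes must be present to compute a PR curve",
         call. = FALSE)
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  l <- labels[o]
  last <- which(!duplicated(s, fromLast = TRUE))
  n1 <- sum(l)
  tp <- cumsum(l)[last]
  fp <- cumsum(!l)[last]
  recall <- tp / n1
  precision <- tp / (tp + fp)
  ap <- sum(diff(c(0, recall)) * precision)
  structure(
    list(
      points = tibble::tibble(threshold = s[last], recall = recall,
                              precision = precision),
      ap = ap
    ),
    class = "her2_pr"
  )
}

#' Multi-class confusion matrix
#'
#' @param truth,pred equal-length vectors of class labels.
#' @param classes ordered class set; defaults to the sorted union of the
#'   observed labels. Labels outside `classes` are an error.
#' @returns Object of class `her2_confusion`: list with `table` (K x K
#'   count matrix, rows = truth, columns = prediction), `accuracy`
#'   (trace / total) and `classes`.
#' @export
confusion_matrix <- function(truth, pred, classes = NULL) {
  truth <- as.character(truth)
  pred <- as.character(pred)
  stopifnot(length(truth) == length(pred))
  if (is.null(classes)) classes <- sort(unique(c(truth, pred)))
  bad <- setdiff(unique(c(truth, pred)), classes)
  if (length(bad)) {
    stop("unknown class label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  tab <- table(factor(truth, classes), factor(pred, classes))
  m <- matrix(as.integer(tab), length(classes), length(classes),
              dimnames = list(truth = classes, pred = classes))
  structure(
    list(table = m, accuracy = sum(diag(m)) / sum(m), classes = classes),
    class = "her2_confusion"
  )
}

#' @export
print.her2_roc <- function(x, ...) {
  cat(sprintf("<her2_roc> %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' @export
print.her2_pr <- function(x, ...) {
  cat(sprintf("<her2_pr> %d points, AP = %.4f\n", nrow(x$points), x$ap))
  invisible(x)
}

#' @export
print.her2_confusion <- function(x, ...) {
  cat(sprintf("<her2_confusion> accuracy = %.4f\n", x$accuracy))
  print(x$table)
  invisible(x)
}

#' @method tidy her2_roc
#' @export
tidy.her2_roc <- function(x, ...) x$points

#' @method glance her2_roc
#' @export
glance.her2_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_points = nrow(x$points))
}

#' @method tidy her2_pr
#' @export
tidy.her2_pr <- function(x, ...) x$points

#' @method glance her2_pr
#' @export
glance.her2_pr <- function(x, ...) {
  tibble::tibble(ap = x$ap, n_points = nrow(x$points))
}

#' @method tidy her2_confusion
#' @export
tidy.her2_confusion <- function(x, ...) {
  tibble::as_tibble(as.data.frame(as.table(x$table), stringsAsFactors = FALSE)) |>
    stats::setNames(c("truth", "pred", "n"))
}

#' @method glance her2_confusion
#' @export
glance.her2_confusion <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, n = sum(x$table),
                 n_classes = length(x$classes))
}

#' Write a metrics tibble (or list) as JSON
#' @param metrics named list or one-row data frame.
#' @param path output file.
#' @export
write_metrics_json <- function(metrics, path) {
  jsonlite::write_json(as.list(metrics), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write a ROC or PR curve as CSV
#' @param curve `her2_roc` or `her2_pr` object.
#' @param path output file.
#' @export
write_curve_csv <- function(curve, path) {
  utils::write.csv(curve$points, path, row.names = FALSE)
  invisible(path)
}

#' Write a confusion matrix as CSV with class-labeled headers
#' @param cm `her2_confusion` object.
#' @param path output file.
#' @export
write_confusion_csv <- function(cm, path) {
  utils::write.csv(as.data.frame(cm$table[, , drop = FALSE]), path)
  invisible(path)
}
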