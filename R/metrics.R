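# Confusion matrices and the full panel of classification statistics:
# accuracy, recall (TPR), specificity (TNR), precision (PPV), NPV,
# balanced accuracy, F1, Matthews correlation coefficient and
# Fowlkes-Mallows index, each reported as a percentage rounded half-up
# to one decimal.

#' Confusion matrix from label vectors
#'
#' Rows are true classes, columns predicted classes, in the order given
#' by \code{class_order}.
#'
#' @param true_labels,predicted_labels Vectors of class labels.
#' @param class_order Character vector fixing the class ordering.
#' @return Integer count matrix of class \code{confusion_matrix}.
#' @export
confusion_matrix <- function(true_labels, predicted_labels, class_order) {
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  bad <- setdiff(unique(c(true_labels, predicted_labels)), class_order)
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors differ in length")
  tt <- table(factor(true_labels, levels = class_order),
              factor(predicted_labels, levels = class_order))
  cm <- matrix(as.integer(tt), nrow = length(class_order),
               dimnames = list(true = class_order, predicted = class_order))
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> (rows = true, cols = predicted)\n")
  print(unclass(x))
  invisible(x)
}

# one-vs-rest cell counts for class i of an NxN matrix
ovr_counts <- function(cm, i) {
  tp <- cm[i, i]
  fn <- sum(cm[i, ]) - tp
  fp <- sum(cm[, i]) - tp
  tn <- sum(cm) - tp - fn - fp
  c(tp = tp, fn = fn, fp = fp, tn = tn)
}

safe_ratio <- function(num, den) if (den > 0) num / den else NA_real_

metrics_from_counts <- function(cn) {
  tp <- cn[["tp"]]; fn <- cn[["fn"]]; fp <- cn[["fp"]]; tn <- cn[["tn"]]
  tpr <- safe_ratio(tp, tp + fn)
  tnr <- safe_ratio(tn, tn + fp)
  ppv <- safe_ratio(tp, tp + fp)
  npv <- safe_ratio(tn, tn + fn)
  ba <- if (!is.na(tpr) && !is.na(tnr)) (tpr + tnr) / 2 else NA_real_
  f1 <- safe_ratio(2 * tp, 2 * tp + fp + fn)
  mcc_den <- sqrt(as.double(tp + fp)) * sqrt(as.double(tp + fn)) *
    sqrt(as.double(tn + fp)) * sqrt(as.double(tn + fn))
  mcc <- if (mcc_den > 0) (as.double(tp) * tn - as.double(fp) * fn) / mcc_den
  else NA_real_
  fm <- if (!is.na(ppv) && !is.na(tpr)) sqrt(ppv * tpr) else NA_real_
  c(tpr = tpr, tnr = tnr, ppv = ppv, npv = npv, balanced_accuracy = ba,
    f1 = f1, mcc = mcc, fowlkes_mallows = fm)
}

report_build <- function(cm) {
  classes <- rownames(cm)
  acc <- sum(diag(cm)) / sum(cm)
  per <- lapply(seq_along(classes), function(i) metrics_from_counts(ovr_counts(cm, i)))
  names(per) <- classes
  raw <- list(accuracy = 100 * acc,
              per_class = lapply(per, function(v) 100 * v))
  rounded <- list(accuracy = round_half_up(raw$accuracy),
                  per_class = lapply(raw$per_class, round_half_up))
  structure(list(confusion = cm, raw = raw, rounded = rounded,
                 classes = classes),
            class = "metric_report")
}

#' Full metric panel for a binary confusion matrix
#'
#' Each class in turn is treated as positive; by symmetry the TNR of
#' class 1 equals the TPR of class 2 and the NPV of class 1 equals the
#' PPV of class 2. A statistic with a zero denominator is reported as
#' \code{NA} rather than silently zero.
#'
#' @param cm A 2x2 \code{\link{confusion_matrix}}.
#' @return A \code{metric_report}: overall accuracy plus, per class,
#'   TPR, TNR, PPV, NPV, balanced accuracy, F1, MCC and
#'   Fowlkes-Mallows, as percentages. \code{$rounded} holds the values
#'   rounded half-up to one decimal; \code{$raw} the unrounded ones.
#' @export
binary_metrics <- function(cm) {
  if (!is.matrix(cm) || any(dim(cm) != 2)) stop("`cm` must be 2x2")
  if (any(cm < 0)) stop("counts must be non-negative")
  report_build(cm)
}

#' Full metric panel for an NxN confusion matrix
#'
#' Overall accuracy is \code{trace / total}; per-class statistics come
#' from the one-vs-rest collapsed 2x2 matrices.
#'
#' @param cm An NxN \code{\link{confusion_matrix}}, N >= 2.
#' @return A \code{metric_report} (see \code{\link{binary_metrics}}).
#' @export
multiclass_metrics <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm) || nrow(cm) < 2)
    stop("`cm` must be square, N >= 2")
  if (any(cm < 0)) stop("counts must be non-negative")
  report_build(cm)
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report> accuracy ", format(x$rounded$accuracy, nsmall = 1),
      "%\n", sep = "")
  tab <- do.call(cbind, x$rounded$per_class)
  rownames(tab) <- c("recall (TPR)", "specificity (TNR)", "precision (PPV)",
                     "NPV", "balanced accuracy", "F1", "MCC",
                     "Fowlkes-Mallows")
  print(tab)
  invisible(x)
}

#' Reconstruct a binary confusion matrix from printed recalls
#'
#' Given per-class recalls (percent) and test-set sizes, the diagonal is
#' \code{round(recall * n / 100)} (half away from zero) and the residual
#' counts fall in the off-diagonal cells — the unique binary matrix
#' consistent with a printed pair of recalls.
#'
#' @param recalls_pct Numeric length-2 vector of recalls in percent.
#' @param class_sizes Integer length-2 vector of per-class totals.
#' @param classes Optional class names (default \code{c("pos", "neg")}).
#' @return A 2x2 \code{\link{confusion_matrix}}.
#' @export
cm_from_recalls <- function(recalls_pct, class_sizes,
                            classes = c("pos", "neg")) {
  if (length(recalls_pct) != 2 || length(class_sizes) != 2)
    stop("binary case only: give 2 recalls and 2 sizes")
  if (any(recalls_pct < 0 | recalls_pct > 100))
    stop("recalls must lie in [0, 100]")
  tp <- as.integer(round_half_up(recalls_pct * class_sizes / 100, 0))
  cm <- matrix(c(tp[1], class_sizes[2] - tp[2],
                 class_sizes[1] - tp[1], tp[2]),
               2, 2, dimnames = list(true = classes, predicted = classes))
  structure(cm, class = c("confusion_matrix", "matrix"))
}
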