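# Binary classification metric core: confusion matrices, Se/Sp/Acc/Youden,
# AUC, and Youden-optimal cutoff search on the integer score grid.

#' Confusion matrix counts
#'
#' @param tp,fp,tn,fn non-negative integer counts.
#' @return a `clinstage_confusion` list.
#' @export
confusion <- function(tp, fp, tn, fn) {
  for (v in list(tp, fp, tn, fn)) {
    if (!is_count1(v)) stopf("confusion counts must be single non-negative integers")
  }
  if (tp + fp + tn + fn < 1) stopf("confusion matrix must contain at least one observation")
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 tn = as.integer(tn), fn = as.integer(fn)),
            class = "clinstage_confusion")
}

#' @export
print.clinstage_confusion <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  TN %d  FN %d  (n = %d)\n",
              x$tp, x$fp, x$tn, x$fn, x$tp + x$fp + x$tn + x$fn))
  invisible(x)
}

check_scores_labels <- function(scores, labels) {
  if (length(scores) == 0) stopf("empty input")
  if (length(scores) != length(labels)) {
    stopf("scores (%d) and labels (%d) differ in length",
          length(scores), length(labels))
  }
  if (anyNA(scores) || anyNA(labels)) stopf("scores/labels must not contain NA")
  as.logical(labels)
}

#' Confusion matrix at a score cutoff
#'
#' Prediction convention: predicted positive when `score >= cutoff`, the
#' higher-intensity side of the scale (higher ClinFIT = greater
#' functional limitation).
#'
#' @param scores integer score vector.
#' @param labels logical (or 0/1) vector; `TRUE` = positive
#'   (higher-intensity) class.
#' @param cutoff integer threshold.
#' @return a [confusion()].
#' @export
#' @examples
#' confusion_at_cutoff(c(100, 200), c(FALSE, TRUE), 150)
confusion_at_cutoff <- function(scores, labels, cutoff) {
  labels <- check_scores_labels(scores, labels)
  pred <- scores >= cutoff
  confusion(tp = sum(pred & labels), fp = sum(pred & !labels),
            tn = sum(!pred & !labels), fn = sum(!pred & labels))
}

#' Diagnostic metrics from a confusion matrix
#'
#' Sensitivity tp/(tp+fn), specificity tn/(tn+fp), accuracy
#' (tp+tn)/total, and the Youden index (sensitivity + specificity - 1).
#' A class with no members makes its metric undefined and is an error,
#' never a silent 0 — downstream steps must detect empty classes, not
#' average over them.
#'
#' @param cm a [confusion()] (or a list with tp/fp/tn/fn).
#' @return list with `sensitivity`, `specificity`, `accuracy`, `youden`
#'   (unrounded).
#' @export
#' @examples
#' metrics_from_confusion(confusion(12, 93, 162, 3))
metrics_from_confusion <- function(cm) {
  tp <- cm$tp; fp <- cm$fp; tn <- cm$tn; fn <- cm$fn
  if (tp + fn == 0) stopf("no positives: sensitivity undefined",
                          class = "clinstage_undefined_metric")
  if (tn + fp == 0) stopf("no negatives: specificity undefined",
                          class = "clinstage_undefined_metric")
  se <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  list(sensitivity = se, specificity = sp,
       accuracy = (tp + tn) / (tp + fp + tn + fn),
       youden = se + sp - 1)
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive
#' outscores a random negative, ties counted one half — identical to the
#' trapezoidal area under the empirical all-thresholds ROC curve.
#' Computed from midranks in O(n log n).
#'
#' @inheritParams confusion_at_cutoff
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- check_scores_labels(scores, labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stopf("both classes must be present to compute AUC",
          class = "clinstage_undefined_metric")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Youden-optimal cutoff over the integer score grid
#'
#' Evaluates every candidate integer cutoff (default all 301 values
#' 0-300, since ClinFIT totals are integer sums — not observed-score
#' midpoints) and returns the one maximizing the Youden index; ties are
#' broken toward the smallest cutoff. The comparison's AUC is attached.
#'
#' @inheritParams confusion_at_cutoff
#' @param candidates integer cutoffs to evaluate, ascending
#'   (default `0:300`).
#' @return a `clinstage_cutoff_metrics` list: `cutoff`, `sensitivity`,
#'   `specificity`, `accuracy`, `youden`, `auc`, `n`.
#' @export
#' @examples
#' optimal_cutoff_youden(c(10, 20, 200, 210), c(FALSE, FALSE, TRUE, TRUE))
optimal_cutoff_youden <- function(scores, labels, candidates = 0:300) {
  labels <- check_scores_labels(scores, labels)
  if (length(candidates) == 0) stopf("no candidate cutoffs")
  candidates <- sort(unique(as.integer(candidates)))
  grid <- youden_grid(scores, labels, candidates)
  best <- which.max(grid$youden)  # first max = smallest cutoff on ties
  cm <- confusion_at_cutoff(scores, labels, candidates[best])
  structure(
    list(cutoff = candidates[best],
         sensitivity = grid$sensitivity[best],
         specificity = grid$specificity[best],
         accuracy = grid$accuracy[best],
         youden = grid$youden[best],
         auc = roc_auc(scores, labels),
         n = length(scores),
         confusion = cm),
    class = "clinstage_cutoff_metrics"
  )
}

# Vectorized Se/Sp over all candidate cutoffs via score tabulation.
youden_grid <- function(scores, labels, candidates) {
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stopf("both classes must be present for cutoff search",
          class = "clinstage_undefined_metric")
  }
  # positives predicted positive at cutoff c: count of positive scores >= c
  pos_ge <- vapply(candidates, function(c) sum(scores[labels] >= c), 0L)
  neg_ge <- vapply(candidates, function(c) sum(scores[!labels] >= c), 0L)
  se <- pos_ge / n_pos
  sp <- (n_neg - neg_ge) / n_neg
  list(sensitivity = se, specificity = sp,
       accuracy = (pos_ge + n_neg - neg_ge) / (n_pos + n_neg),
       youden = se + sp - 1)
}

#' @export
print.clinstage_cutoff_metrics <- function(x, ...) {
  cat(sprintf(
    "cutoff %d: Se %.3f  Sp %.3f  Acc %.3f  Youden %.3f  AUC %.3f  (n = %d)\n",
    x$cutoff, round_half_up(x$sensitivity, 3), round_half_up(x$specificity, 3),
    round_half_up(x$accuracy, 3), round_half_up(x$youden, 3),
    round_half_up(x$auc, 3), x$n))
  invisible(x)
}
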