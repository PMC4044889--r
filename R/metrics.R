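# Confusion-matrix statistics, ROC curves and AUC.
# Positive class is cancer throughout.

#' Construct a confusion matrix
#'
#' @param tp,fp,fn,tn nonnegative integer counts (positive class = cancer).
#' @return list of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != floor(counts)))
    pf_stop("pf_validation_error", "counts must be nonnegative integers")
  structure(as.list(setNames(as.integer(counts), names(counts))),
            class = "confusion_matrix")
}

#' Performance metrics of a confusion matrix
#'
#' Computes sensitivity = tp/(tp+fn), specificity = tn/(tn+fp), precision =
#' tp/(tp+fp) and accuracy = (tp+tn)/total, returned as percentages at full
#' precision (round to two decimals for display). A metric whose denominator
#' is zero is `NA` (undefined), never silently 0.
#'
#' @param cm a [confusion_matrix()].
#' @return named numeric vector of percentages: `sensitivity`,
#'   `specificity`, `precision`, `accuracy`.
#' @export
confusion_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tp + cm$fp + cm$fn + cm$tn
  if (total == 0)
    pf_stop("pf_validation_error", "all-zero confusion matrix: metrics undefined")
  frac <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  c(sensitivity = frac(cm$tp, cm$tp + cm$fn),
    specificity = frac(cm$tn, cm$tn + cm$fp),
    precision = frac(cm$tp, cm$tp + cm$fp),
    accuracy = frac(cm$tp + cm$tn, total))
}

check_two_classes <- function(labels) {
  labels <- as.character(labels)
  if (!all(labels %in% c("cancer", "control")))
    pf_stop("pf_validation_error",
            "labels must be 'cancer' or 'control'")
  if (length(unique(labels)) < 2)
    pf_stop("pf_validation_error", "both classes must be present")
  labels
}

#' Confusion matrix from continuous scores
#'
#' Predicted class is cancer iff score > threshold (ties predict control).
#'
#' @param scores numeric scores, larger = more cancer-like.
#' @param labels `"cancer"` / `"control"` per score.
#' @param threshold decision threshold (default 0, matching
#'   [predict_score()]'s symmetric encoding).
#' @return a [confusion_matrix()].
#' @export
confusion_from_scores <- function(scores, labels, threshold = 0) {
  labels <- as.character(labels)
  pred_cancer <- scores > threshold
  confusion_matrix(tp = sum(pred_cancer & labels == "cancer"),
                   fp = sum(pred_cancer & labels == "control"),
                   fn = sum(!pred_cancer & labels == "cancer"),
                   tn = sum(!pred_cancer & labels == "control"))
}

#' ROC curve by descending threshold sweep
#'
#' One vertex per distinct score (ties grouped, giving diagonal segments),
#' plus the exact endpoints (0,0) and (1,1). The grouped-tie convention
#' makes the trapezoidal AUC equal the Mann-Whitney statistic with the
#' 1/2-tie rule.
#'
#' @inheritParams confusion_from_scores
#' @return list of class `roc_curve` with `fpr`, `tpr`, `thresholds`
#'   (threshold `Inf` for the (0,0) endpoint).
#' @export
roc_curve <- function(scores, labels) {
  labels <- check_two_classes(labels)
  if (length(scores) != length(labels))
    pf_stop("pf_validation_error", "scores and labels differ in length")
  n1 <- sum(labels == "cancer")
  n0 <- sum(labels == "control")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, cumsum(vapply(thr, function(t)
    sum(scores == t & labels == "cancer"), numeric(1))) / n1)
  fpr <- c(0, cumsum(vapply(thr, function(t)
    sum(scores == t & labels == "control"), numeric(1))) / n0)
  structure(list(fpr = fpr, tpr = tpr, thresholds = c(Inf, thr)),
            class = "roc_curve")
}

#' Area under a ROC curve (trapezoidal rule)
#'
#' @param curve a [roc_curve()].
#' @return AUC in \[0, 1\].
#' @export
auc <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  sum(diff(curve$fpr) * (head(curve$tpr, -1) + curve$tpr[-1]) / 2)
}

#' AUC straight from scores and labels
#' @inheritParams roc_curve
#' @export
auc_scores <- function(scores, labels) auc(roc_curve(scores, labels))

# Fast Mann-Whitney AUC used in inner loops (identical value to
# auc_scores; rank-based, 1/2-tie convention).
#' @noRd
auc_rank <- function(scores, labels) {
  pos <- labels == "cancer"
  n1 <- sum(pos)
  n0 <- sum(!pos)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
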