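#' Confusion counts
#'
#' Lightweight container for a two-class confusion matrix.
#'
#' @param tp,fp,fn,tn non-negative integer counts.
#' @return A named list of class "ConfusionCounts".
#' @export
confusionCounts <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be non-negative")
  if (sum(counts) == 0) stop("all counts are zero")
  structure(as.list(counts), class = "ConfusionCounts")
}

#' Accuracy, sensitivity, specificity and MCC from a confusion matrix
#'
#' The two-class performance measures used throughout:
#' \deqn{Ac = (tp+tn)/(tp+fp+fn+tn)}
#' \deqn{Sn = tp/(tp+fn), \quad Sp = tn/(tn+fp)}
#' \deqn{MCC = (tp \cdot tn - fp \cdot fn) /
#'   \sqrt{(tp+fp)(tp+fn)(tn+fp)(tn+fn)}}
#' MCC with a zero denominator is defined as 0 (the standard
#' convention for a degenerate confusion matrix).
#'
#' @param counts a "ConfusionCounts" object, or \code{tp} given as the
#'   first of four counts.
#' @param fp,fn,tn remaining counts when given individually.
#' @return list with elements \code{ac}, \code{sn}, \code{sp} (in
#'   [0, 1]) and \code{mcc} (in [-1, 1]).
#' @examples
#' evalMetrics(confusionCounts(tp = 275, fp = 18, fn = 102, tn = 924))
#' @export
evalMetrics <- function(counts, fp = NULL, fn = NULL, tn = NULL) {
  if (!inherits(counts, "ConfusionCounts"))
    counts <- confusionCounts(counts, fp, fn, tn)
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  if (tp + fn == 0) stop("no positives evaluated: sensitivity undefined")
  if (tn + fp == 0) stop("no negatives evaluated: specificity undefined")
  den2 <- prod(c(tp + fp, tp + fn, tn + fp, tn + fn))
  mcc <- if (den2 == 0) 0 else (tp * tn - fp * fn) / sqrt(den2)
  list(ac = (tp + tn) / (tp + fp + fn + tn),
       sn = tp / (tp + fn),
       sp = tn / (tn + fp),
       mcc = mcc)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold alpha over all distinct prediction
#' scores; an item is predicted positive when its score is strictly
#' greater than alpha, matching the classifier's decision rule. Points
#' are reported as cumulative false/true positive counts and rates; the
#' AUC is the trapezoidal area under the (fpr, tpr) curve, which for
#' the strict-inequality sweep equals the normalized Mann-Whitney rank
#' statistic (ties counted half).
#'
#' @param scores numeric vector of prediction scores.
#' @param labels logical (TRUE = positive) or character ("OMP" =
#'   positive) vector, same length as scores.
#' @return list with \code{points} (data.frame alpha, fp, tp, fpr, tpr)
#'   and \code{auc}.
#' @export
rocCurve <- function(scores, labels) {
  if (is.character(labels) || is.factor(labels))
    labels <- as.character(labels) == "OMP"
  stopifnot(length(scores) == length(labels), !anyNA(scores),
            !anyNA(labels))
  nPos <- sum(labels); nNeg <- sum(!labels)
  if (nPos == 0 || nNeg == 0)
    stop("ROC needs at least one positive and one negative")
  alpha <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(alpha, function(a) sum(scores > a & labels), numeric(1L))
  fp <- vapply(alpha, function(a) sum(scores > a & !labels), numeric(1L))
  ## close the curve: everything called positive below the minimum score
  tp <- c(0, tp, nPos)
  fp <- c(0, fp, nNeg)
  alpha <- c(Inf, alpha, -Inf)
  pts <- data.frame(alpha = alpha, fp = fp, tp = tp,
                    fpr = fp / nNeg, tpr = tp / nPos)
  auc <- sum(diff(pts$fpr) * (pts$tpr[-1L] + pts$tpr[-nrow(pts)]) / 2)
  list(points = pts, auc = auc)
}
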