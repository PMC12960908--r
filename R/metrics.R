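#' Binary cross-entropy loss
#'
#' Mean of `-(y log s + (1-y) log(1-s))` with scores clipped to
#' `[1e-7, 1 - 1e-7]`.
#'
#' @param scores Predicted probabilities.
#' @param labels 0/1 labels of the same length.
#' @return Nonnegative scalar loss.
#' @examples
#' bceLoss(c(0.5, 0.5), c(1, 0))  # log 2
#' @export
bceLoss <- function(scores, labels) {
  if (length(scores) != length(labels))
    stopf("scores and labels differ in length")
  s <- pmin(pmax(scores, 1e-7), 1 - 1e-7)
  y <- as.numeric(labels)
  -mean(y * log(s) + (1 - y) * log(1 - s))
}

#' Confusion counts at a decision threshold
#'
#' @param scores Predicted probabilities (or 0/1 predictions).
#' @param labels True 0/1 labels.
#' @param threshold Decision threshold (default 0.5).
#' @return Named numeric vector with `TP`, `FP`, `TN`, `FN`.
#' @export
confusionCounts <- function(scores, labels, threshold = 0.5) {
  pred <- as.integer(scores > threshold)
  y <- as.integer(labels)
  c(TP = sum(pred == 1L & y == 1L), FP = sum(pred == 1L & y == 0L),
    TN = sum(pred == 0L & y == 0L), FN = sum(pred == 0L & y == 1L))
}

#' Classification metrics from confusion counts
#'
#' `ACC = (TP+TN)/total`, `SN = TP/(TP+FN)`, `SP = TN/(TN+FP)`, and the
#' Matthews correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' When any MCC denominator factor is zero the MCC is reported as 0
#' (continuity convention); SN/SP are `NaN` when their denominators are 0.
#'
#' @param counts Named vector or list with `TP`, `FP`, `TN`, `FN`
#'   (e.g. from [confusionCounts()]).
#' @return Named numeric vector `ACC`, `MCC`, `SN`, `SP`.
#' @examples
#' computeMetrics(c(TP = 30, FP = 10, TN = 20, FN = 40))
#' @export
computeMetrics <- function(counts) {
  TP <- as.numeric(counts[["TP"]]); FP <- as.numeric(counts[["FP"]])
  TN <- as.numeric(counts[["TN"]]); FN <- as.numeric(counts[["FN"]])
  if (any(c(TP, FP, TN, FN) < 0)) stopf("confusion counts must be nonnegative")
  total <- TP + FP + TN + FN
  if (total == 0) stopf("confusion counts are all zero")
  den <- c(TP + FP, TP + FN, TN + FP, TN + FN)
  mcc <- if (any(den == 0)) 0 else (TP * TN - FP * FN) / sqrt(prod(den))
  c(ACC = (TP + TN) / total,
    MCC = mcc,
    SN = if (TP + FN == 0) NaN else TP / (TP + FN),
    SP = if (TN + FP == 0) NaN else TN / (TN + FP))
}

#' Area under the ROC curve
#'
#' Rank-statistic (Mann-Whitney) formulation with midrank tie correction:
#' identical scores for a positive/negative pair count one half.
#'
#' @param scores Predicted scores.
#' @param labels True 0/1 labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
computeAuc <- function(scores, labels) {
  y <- as.integer(labels)
  np <- sum(y == 1L); nn <- sum(y == 0L)
  if (np == 0L || nn == 0L)
    stopf("AUC requires both classes to be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - np * (np + 1) / 2) / (np * nn)
}
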