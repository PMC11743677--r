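#' Confusion-matrix metrics
#'
#' PMCI is the positive class. Exact formula evaluation:
#' `ACC = (TP+TN)/(TP+FN+TN+FP)`, `SEN = TP/(TP+FN)`, `SPE = TN/(FP+TN)`,
#' `PPV = TP/(TP+FP)`, `F1 = 2TP/(2TP+FP+FN)`. Zero denominators give `NA`.
#'
#' @param predicted factor/character of predicted labels (SMCI/PMCI)
#' @param truth factor/character of true labels
#' @return named list with counts TP/FN/FP/TN and metrics ACC/SEN/SPE/PPV/F1
#' @export
confusion_metrics <- function(predicted, truth) {
  if (length(predicted) != length(truth)) stop("label vectors differ in length")
  predicted <- as.character(predicted); truth <- as.character(truth)
  tp <- sum(predicted == "PMCI" & truth == "PMCI")
  fn <- sum(predicted == "SMCI" & truth == "PMCI")
  fp <- sum(predicted == "PMCI" & truth == "SMCI")
  tn <- sum(predicted == "SMCI" & truth == "SMCI")
  sdiv <- function(num, den) if (den > 0) num / den else NA_real_
  list(TP = tp, FN = fn, FP = fp, TN = tn, M = tp + fn, N = tn + fp,
       ACC = sdiv(tp + tn, tp + fn + tn + fp),
       SEN = sdiv(tp, tp + fn),
       SPE = sdiv(tn, fp + tn),
       PPV = sdiv(tp, tp + fp),
       F1 = sdiv(2 * tp, 2 * tp + fp + fn))
}

#' Rank-based AUC (Mann-Whitney form)
#'
#' `AUC = (sum of pooled ranks of the positive-class scores - M(M+1)/2) /
#' (M N)` with average ranks for ties, equal to the concordance probability
#' `P(score_pos > score_neg) + P(tie)/2`.
#'
#' @param scores numeric, higher = more PMCI-like
#' @param truth labels (SMCI/PMCI)
#' @return AUC in `[0, 1]`, `NA` when one class is absent
#' @export
auc_rank <- function(scores, truth) {
  truth <- as.character(truth)
  pos <- truth == "PMCI"
  m <- sum(pos); n <- sum(!pos)
  if (m == 0 || n == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - m * (m + 1) / 2) / (m * n)
}
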