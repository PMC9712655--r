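# Confusion counts and the classification metric suite used throughout:
# sensitivity, specificity, accuracy, balanced accuracy, Matthews
# correlation coefficient, and rank-based AUC.

#' Confusion counts from predicted and true labels
#'
#' @param predicted,truth Vectors of labels in {0, 1} (or logical), equal
#'   length, non-empty. 1 means active.
#' @return Object of class `confusion_counts`: list TP, TN, FP, FN.
#' @export
confusion_counts <- function(predicted, truth) {
  if (length(predicted) != length(truth)) stop("length mismatch")
  if (length(predicted) == 0L) stop("empty input")
  predicted <- as.integer(predicted); truth <- as.integer(truth)
  if (any(!predicted %in% c(0L, 1L)) || any(!truth %in% c(0L, 1L)))
    stop("labels must be 0/1")
  structure(list(TP = sum(predicted == 1L & truth == 1L),
                 TN = sum(predicted == 0L & truth == 0L),
                 FP = sum(predicted == 1L & truth == 0L),
                 FN = sum(predicted == 0L & truth == 1L)),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Computes sensitivity SE = TP/(TP+FN), specificity SP = TN/(TN+FP),
#' accuracy Acc = (TP+TN)/n, balanced accuracy bAcc = (SE+SP)/2, and the
#' Matthews correlation coefficient
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' A zero denominator in the MCC yields 0 (the conventional value for a
#' degenerate single-class predictor); an undefined SE or SP is reported
#' as NA.
#'
#' @param cc A `confusion_counts` object (or list with TP, TN, FP, FN).
#' @return Object of class `metrics_report`: list SE, SP, Acc, bAcc, MCC.
#' @export
compute_metrics <- function(cc) {
  TP <- cc$TP; TN <- cc$TN; FP <- cc$FP; FN <- cc$FN
  n <- TP + TN + FP + FN
  if (n == 0L) stop("empty confusion table")
  SE <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  SP <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  Acc <- (TP + TN) / n
  bAcc <- (SE + SP) / 2
  denom <- sqrt(as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  MCC <- if (denom == 0) 0 else
    (as.numeric(TP) * TN - as.numeric(FP) * FN) / denom
  structure(list(SE = SE, SP = SP, Acc = Acc, bAcc = bAcc, MCC = MCC),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  fields <- vapply(x, function(v)
    if (is.na(v)) "NA" else sprintf("%.3f", v), character(1))
  cat(paste(names(x), fields, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Rank-based AUC
#'
#' Area under the ROC curve by the Mann-Whitney statistic; tied
#' probabilities receive half credit.
#'
#' @param probabilities Predicted probabilities of the active class.
#' @param labels True labels in {0, 1}; both classes must be present.
#' @return AUC in [0, 1].
#' @export
auc_rank <- function(probabilities, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUC requires both classes")
  r <- rank(probabilities, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Cohen's kappa from a confusion table (alternative GHOST tuning metric)
.kappa_metric <- function(cc) {
  n <- cc$TP + cc$TN + cc$FP + cc$FN
  po <- (cc$TP + cc$TN) / n
  pe <- ((cc$TP + cc$FP) * (cc$TP + cc$FN) +
           (cc$TN + cc$FN) * (cc$TN + cc$FP)) / n^2
  if (pe == 1) 0 else (po - pe) / (1 - pe)
}
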