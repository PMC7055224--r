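#' Confusion counts from labels and predictions
#'
#' @param truth,pred Binary vectors (logical, or coercible via `== positive`).
#' @param positive Value counted as the positive (active) class when inputs
#'   are not logical.
#' @return Named numeric vector `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(truth, pred, positive = TRUE) {
  stopifnot(length(truth) == length(pred))
  t <- if (is.logical(truth)) truth else truth == positive
  p <- if (is.logical(pred)) pred else pred == positive
  c(TP = sum(t & p), FP = sum(!t & p), TN = sum(!t & !p), FN = sum(t & !p))
}

#' Five classification performance metrics
#'
#' Exact evaluation of the standard confusion-matrix formulas:
#' `Acc = (TP+TN)/(TP+TN+FP+FN)`, `Se = TP/(TP+FN)`, `Sp = TN/(TN+FP)`,
#' `Acc_b = (Se+Sp)/2`, and
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`,
#' with MCC defined as 0 when any factor of the denominator is 0.
#'
#' @param TP,FP,TN,FN Non-negative counts, or `TP` may be a named vector
#'   from [confusion_counts()].
#' @return Named numeric vector `Acc`, `Acc_b`, `Se`, `Sp`, `MCC`.
#' @export
classification_metrics <- function(TP, FP = NULL, TN = NULL, FN = NULL) {
  if (is.null(FP) && length(TP) == 4L) {
    FP <- TP[["FP"]]; TN <- TP[["TN"]]; FN <- TP[["FN"]]; TP <- TP[["TP"]]
  }
  TP <- as.numeric(TP); FP <- as.numeric(FP); TN <- as.numeric(TN); FN <- as.numeric(FN)
  total <- TP + FP + TN + FN
  if (total <= 0) stop("empty evaluation set")
  se <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  sp <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  denom <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (denom > 0) (TP * TN - FP * FN) / sqrt(denom) else 0
  c(Acc = (TP + TN) / total, Acc_b = mean(c(se, sp)), Se = se, Sp = sp, MCC = mcc)
}
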