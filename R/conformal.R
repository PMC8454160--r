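## Inductive conformal prediction with the ensemble-standard-deviation (ESD)
## nonconformity function, used as the comparison baseline for NLL
## calibration in interval estimation.

#' ESD nonconformity scores
#'
#' `alpha_i = |y_i - yhat_i| / exp(sqrt(Q_E(x_i)))`: absolute residuals
#' scaled down for samples with large ensemble disagreement.  The
#' denominator is at least one, so the scores are always finite.
#'
#' @param labels,preds aligned observed and predicted values.
#' @param qe nonnegative epistemic (ensemble-variance) estimates.
#' @return Nonnegative scores.
#' @examples
#' esdNonconformity(2, 0, 1)  # 2 / e
#' @export
esdNonconformity <- function(labels, preds, qe) {
  .assertNumericVector(labels, "labels")
  .assertSameLength(labels, preds, "labels", "preds")
  .assertSameLength(labels, qe, "labels", "qe")
  .assertNumericVector(qe, "qe", allowNegative = FALSE)
  abs(labels - preds) / exp(sqrt(qe))
}

#' Inductive conformal prediction intervals
#'
#' The calibration quantile is the `ceiling((n + 1) * confidence)`-th
#' smallest calibration nonconformity; each test interval is
#' `pred +/- alpha* . exp(sqrt(qe))`.  When the required order statistic
#' exceeds the calibration-set size the interval is infinite and flagged by
#' an `Inf` half-width (with a warning).
#'
#' @param calibrationAlphas positive nonconformity scores of the calibration
#'   set (typically the validation set).
#' @param preds predicted means of the test samples.
#' @param qe epistemic variance estimates of the test samples.
#' @param confidence nominal confidence level (the framework's standard
#'   is 0.9).
#' @return A [PredictionIntervals-class].
#' @export
cpIntervals <- function(calibrationAlphas, preds, qe, confidence = 0.9) {
  .assertNumericVector(calibrationAlphas, "calibrationAlphas",
                       allowNegative = FALSE)
  n <- length(calibrationAlphas)
  if (n == 0L) stop("the calibration set must be non-empty", call. = FALSE)
  .assertSameLength(preds, qe, "preds", "qe")
  k <- max(1L, as.integer(ceiling((n + 1) * confidence)))
  if (k > n) {
    warning(sprintf(
      "confidence %.3g needs order statistic %d of %d calibration scores; intervals are infinite",
      confidence, k, n))
    alphaStar <- Inf
  } else {
    alphaStar <- sort(calibrationAlphas)[k]
  }
  methods::new("PredictionIntervals", center = as.numeric(preds),
               halfWidth = pmax(alphaStar, .Machine$double.xmin) * exp(sqrt(qe)),
               confidence = confidence)
}

#' Validity and efficiency of prediction intervals
#'
#' Validity is the fraction of labels inside their interval (a predictor is
#' conventionally called valid at 90% confidence when this falls in
#' `[0.85, 0.95]`); efficiency is the mean interval range
#' (2 x half-width) -- smaller is better once validity holds.
#'
#' @param intervals a [PredictionIntervals-class].
#' @param labels aligned observed values.
#' @return A list with `validity` and `efficiency`.
#' @export
validityEfficiency <- function(intervals, labels) {
  .assertNumericVector(labels, "labels")
  .assertSameLength(labels, intervals@center, "labels", "intervals")
  inside <- abs(labels - intervals@center) <= intervals@halfWidth
  list(validity = mean(inside), efficiency = mean(2 * intervals@halfWidth))
}

setMethod("show", "PredictionIntervals", function(object) {
  cat(sprintf("PredictionIntervals: %d intervals at %.0f%% confidence, mean range %.4g\n",
              length(object@center), 100 * object@confidence,
              mean(2 * object@halfWidth)))
})
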