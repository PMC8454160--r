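## Evaluation of uncertainty estimates: ranking ability (Spearman
## correlation, confidence curves) and calibration (ENCE over
## equal-occupancy bins, ECE over Gaussian confidence intervals, plus the
## underlying plot data).

#' Spearman correlation between uncertainties and absolute errors
#'
#' Rank correlation with average ranks for ties; the standard measure of an
#' uncertainty estimator's ranking ability.  A constant input has no defined
#' rank correlation and returns 0 with a warning.
#'
#' @param uncertainties numeric vector.
#' @param absErrors aligned nonnegative numeric vector.
#' @return Correlation in `[-1, 1]`.
#' @export
spearmanScc <- function(uncertainties, absErrors) {
  .assertNumericVector(uncertainties, "uncertainties")
  .assertNumericVector(absErrors, "absErrors", allowNegative = FALSE)
  .assertSameLength(uncertainties, absErrors, "uncertainties", "absErrors")
  if (length(unique(uncertainties)) < 2L || length(unique(absErrors)) < 2L) {
    warning("rank correlation undefined for a constant vector; returning 0")
    return(0)
  }
  cor(uncertainties, absErrors, method = "spearman")
}

#' Confidence (error-retention) curve
#'
#' Removes the most uncertain sample one at a time (ties broken by stable
#' input order) and records the mean absolute error of the remainder.  The
#' area under the curve over the removed-fraction axis summarises ranking
#' ability: when two curves are compared, the smaller AUC is the better
#' estimator.
#'
#' @param uncertainties numeric vector.
#' @param absErrors aligned nonnegative absolute errors (length >= 2).
#' @return A [ConfidenceCurve-class] with `percentiles` `0, 1/n, ...,
#'   (n-1)/n`.
#' @examples
#' confidenceCurve(c(3, 2, 1), c(3, 2, 1))@mae  # 2, 1.5, 1
#' @export
confidenceCurve <- function(uncertainties, absErrors) {
  .assertNumericVector(absErrors, "absErrors", allowNegative = FALSE)
  .assertSameLength(uncertainties, absErrors, "uncertainties", "absErrors")
  n <- length(absErrors)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  ## most uncertain removed first; order() is stable, so ties keep input order
  removal <- order(uncertainties, decreasing = TRUE)
  kept <- rev(absErrors[removal])          # kept[1..j]: last j to be removed
  mae <- rev(cumsum(kept) / seq_len(n))    # mae[j]: after removing j - 1
  percentiles <- (seq_len(n) - 1) / n
  auc <- sum(diff(percentiles) * (head(mae, -1) + tail(mae, -1)) / 2)
  methods::new("ConfidenceCurve", percentiles = percentiles, mae = mae,
               auc = auc)
}

#' @describeIn confidenceCurve tidy data frame of a curve.
#' @param x a `ConfidenceCurve`.
#' @param ... unused.
#' @export
setMethod("as.data.frame", "ConfidenceCurve", function(x, ...) {
  data.frame(percentile = x@percentiles, mae = x@mae)
})

## equal-occupancy bin ids over uncertainty-sorted samples; the last bin
## absorbs the remainder
.uncertaintyBins <- function(uncertainties, binSize) {
  n <- length(uncertainties)
  if (n < binSize)
    stop(sprintf("need at least binSize = %d samples", binSize), call. = FALSE)
  nBins <- n %/% binSize
  ord <- order(uncertainties)
  bin <- pmin(ceiling(seq_len(n) / binSize), nBins)
  list(ord = ord, bin = bin, nBins = nBins)
}

#' Error-based calibration bins
#'
#' Sorts samples by predicted uncertainty into bins of `binSize` (the last
#' bin absorbs the remainder) and records the mean predicted variance and the
#' mean squared error per bin: the scatter data of an error-based calibration
#' plot, where a calibrated model lies on the diagonal of
#' (sqrt(mVAR), sqrt(MSE)).
#'
#' @param uncertainties positive variance-scale estimates.
#' @param signedErrors aligned residuals.
#' @param binSize samples per bin (default 20).
#' @return A [CalibrationBins-class].
#' @export
errorCalibrationBins <- function(uncertainties, signedErrors, binSize = 20L) {
  .assertNumericVector(uncertainties, "uncertainties", allowNegative = FALSE)
  .assertSameLength(uncertainties, signedErrors, "uncertainties", "signedErrors")
  b <- .uncertaintyBins(uncertainties, binSize)
  u <- uncertainties[b$ord]; e2 <- signedErrors[b$ord]^2
  methods::new("CalibrationBins",
               mVAR = as.numeric(tapply(u, b$bin, mean)),
               MSE = as.numeric(tapply(e2, b$bin, mean)),
               count = as.integer(tabulate(b$bin, b$nBins)))
}

#' @describeIn errorCalibrationBins tidy data frame with root columns for
#'   plotting.
#' @param x a `CalibrationBins`.
#' @param ... unused.
#' @export
setMethod("as.data.frame", "CalibrationBins", function(x, ...) {
  data.frame(mVAR = x@mVAR, MSE = x@MSE, count = x@count,
             rmVAR = sqrt(x@mVAR), rMSE = sqrt(x@MSE))
})

#' Expected normalized calibration error
#'
#' `mean(|sqrt(mVAR) - sqrt(MSE)| / sqrt(mVAR))` over uncertainty-sorted
#' bins of `binSize` samples.  Zero only when every bin's mean predicted
#' variance matches its mean squared error; note that finite bins carry an
#' irreducible chi-squared sampling floor (about 0.13 for 20-sample bins)
#' even for perfectly calibrated estimates.
#'
#' @param uncertainties positive variance-scale estimates.
#' @param squaredErrors aligned nonnegative squared errors.
#' @param binSize samples per bin (default 20).
#' @param floor protective floor applied to a zero bin mVAR (with warning).
#' @return Nonnegative scalar.
#' @export
ence <- function(uncertainties, squaredErrors, binSize = 20L, floor = 1e-12) {
  .assertNumericVector(uncertainties, "uncertainties", allowNegative = FALSE)
  .assertNumericVector(squaredErrors, "squaredErrors", allowNegative = FALSE)
  .assertSameLength(uncertainties, squaredErrors, "uncertainties", "squaredErrors")
  b <- .uncertaintyBins(uncertainties, binSize)
  u <- uncertainties[b$ord]; e2 <- squaredErrors[b$ord]
  mVAR <- as.numeric(tapply(u, b$bin, mean))
  MSE <- as.numeric(tapply(e2, b$bin, mean))
  if (any(mVAR <= 0)) {
    warning("bins with zero mean predicted variance floored before division")
    mVAR <- pmax(mVAR, floor)
  }
  mean(abs(sqrt(mVAR) - sqrt(MSE)) / sqrt(mVAR))
}

#' Reliability curve (confidence-based calibration)
#'
#' For each nominal level i/100, the empirical coverage of the two-sided
#' zero-mean Gaussian interval `|e| <= z * sqrt(Q)` with
#' `z = qnorm((1 + i/100) / 2)`.
#'
#' @param uncertainties positive variance-scale estimates.
#' @param signedErrors aligned residuals.
#' @return A [ReliabilityCurve-class].
#' @export
reliabilityCurve <- function(uncertainties, signedErrors) {
  .assertNumericVector(uncertainties, "uncertainties", allowNegative = FALSE)
  .assertSameLength(uncertainties, signedErrors, "uncertainties", "signedErrors")
  level <- seq_len(100) / 100
  z <- qnorm((1 + level) / 2)
  absE <- abs(signedErrors); s <- sqrt(uncertainties)
  acc <- vapply(z, function(zz) mean(absE <= zz * s), numeric(1))
  methods::new("ReliabilityCurve", level = level, accuracy = acc)
}

#' @describeIn reliabilityCurve tidy data frame of the curve.
#' @param x a `ReliabilityCurve`.
#' @param ... unused.
#' @export
setMethod("as.data.frame", "ReliabilityCurve", function(x, ...) {
  data.frame(level = x@level, accuracy = x@accuracy)
})

#' Expected calibration error
#'
#' Mean absolute gap between the reliability curve and the diagonal:
#' `mean(|acc(i%) - i/100|)` over i = 1..100, with two-sided symmetric
#' zero-mean Gaussian confidence intervals.
#'
#' @inheritParams reliabilityCurve
#' @return Nonnegative scalar (at most 0.495).
#' @export
ece <- function(uncertainties, signedErrors) {
  rc <- reliabilityCurve(uncertainties, signedErrors)
  mean(abs(rc@accuracy - rc@level))
}

setMethod("show", "ConfidenceCurve", function(object) {
  cat(sprintf("ConfidenceCurve: %d steps, full-set MAE %.4g, AUC %.4g\n",
              length(object@mae), object@mae[1], object@auc))
})
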