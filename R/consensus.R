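## Consensus strategies: normalized weighted averaging (ranking-oriented) and
## post-hoc NLL calibration on the validation set (calibration-oriented).
## Both are linear combinations of the individual estimates; weighted
## averaging normalizes each input first, NLL calibration works on the raw
## (denormalized) values.

.NORM_KINDS <- c("zscore", "minmax", "rank")

#' Normalize an uncertainty vector
#'
#' `zscore` uses the population standard deviation; `minmax` maps onto
#' `[0, 1]`; `rank` maps onto average-tie ascending ranks divided by n
#' (range `(0, 1]`).  Zero-spread input yields all zeros with a warning.
#'
#' @param values numeric vector.
#' @param kind `"zscore"`, `"minmax"` or `"rank"`.
#' @return The normalized vector.
#' @examples
#' normalizeValues(c(2, 4, 6), "minmax")
#' @export
normalizeValues <- function(values, kind = .NORM_KINDS) {
  kind <- match.arg(kind)
  .assertNumericVector(values, "values")
  if (kind == "rank")
    return(rank(values, ties.method = "average") / length(values))
  if (length(values) < 2L)
    stop(sprintf("'%s' normalization needs at least 2 values", kind),
         call. = FALSE)
  spread <- if (kind == "zscore") .popSd(values) else diff(range(values))
  if (spread == 0) {
    warning("degenerate input with zero spread; returning zeros")
    return(numeric(length(values)))
  }
  if (kind == "zscore") (values - mean(values)) / spread
  else (values - min(values)) / spread
}

#' Ranking-based consensus weights from validation performance
#'
#' Each method's weight is its Spearman correlation with the validation
#' absolute errors, clipped at zero.  If every correlation is nonpositive
#' the arithmetic mean (all weights one) is used instead and the strategy is
#' recorded as `"unweighted"`.
#'
#' @param valUncertainties list of [UncertaintyVector-class] on the
#'   validation set.
#' @param valAbsErrors nonnegative validation absolute errors.
#' @return A [ConsensusWeights-class] with zero bias.
#' @export
sccWeights <- function(valUncertainties, valAbsErrors) {
  .assertNumericVector(valAbsErrors, "valAbsErrors", allowNegative = FALSE)
  w <- vapply(valUncertainties, function(u) {
    .assertSameLength(u@values, valAbsErrors, "uncertainties", "valAbsErrors")
    max(0, spearmanScc(u@values, valAbsErrors))
  }, numeric(1))
  strategy <- "scc_weighted"
  if (all(w == 0)) {
    w <- rep(1, length(w))
    strategy <- "unweighted"
  }
  methods::new("ConsensusWeights", w0 = 0, w = w,
               methods = vapply(valUncertainties, methodName, character(1)),
               strategy = strategy)
}

#' @describeIn sccWeights unit weights (arithmetic mean) for the given
#'   methods.
#' @param methods character vector of method names.
#' @export
unweightedWeights <- function(methods) {
  methods::new("ConsensusWeights", w0 = 0, w = rep(1, length(methods)),
               methods = methods, strategy = "unweighted")
}

#' Normalized weighted average of uncertainty vectors
#'
#' `w0 + sum_i w_i * H(U_i)` elementwise, where `H` is the chosen
#' normalization fitted on the vector being scored.  The output is a
#' relative (ranking-scale) score, not a variance.
#'
#' @param uncertaintySets list of aligned [UncertaintyVector-class] objects.
#' @param weights a [ConsensusWeights-class] with one weight per input.
#' @param normalization normalization kind passed to [normalizeValues()].
#' @return An [UncertaintyVector-class] named
#'   `<Strategy>_<Normalization>` (e.g. `Unweighted_Rank`).
#' @export
weightedAverage <- function(uncertaintySets, weights,
                            normalization = c("rank", "zscore", "minmax")) {
  normalization <- match.arg(normalization)
  t <- length(uncertaintySets)
  if (t != length(weights@w))
    stop("one weight per uncertainty vector is required", call. = FALSE)
  n <- length(uncertaintySets[[1]]@values)
  out <- rep(weights@w0, n)
  for (i in seq_len(t)) {
    .assertSameLength(uncertaintySets[[i]]@values, uncertaintySets[[1]]@values,
                      "uncertainties", "uncertainties")
    out <- out + weights@w[i] * normalizeValues(uncertaintySets[[i]]@values,
                                                normalization)
  }
  normLabel <- c(zscore = "Zscore", minmax = "MinMax", rank = "Rank")
  label <- paste0(if (weights@strategy == "scc_weighted") "Weighted"
                  else "Unweighted",
                  "_", normLabel[[normalization]])
  ## normalized scores can be negative (zscore); shift is irrelevant for
  ## ranking, so store the positive-shifted values
  uncertaintyVector(label, out - min(out, 0), FALSE)
}

## NLL objective and gradient for the calibration fit; Q floored for the log
.nllObjective <- function(par, U, e2, floor) {
  q <- pmax(par[1] + as.numeric(U %*% par[-1]), floor)
  sum(log(q) + e2 / q)
}
.nllGradient <- function(par, U, e2, floor) {
  raw <- par[1] + as.numeric(U %*% par[-1])
  q <- pmax(raw, floor)
  dq <- (1 / q - e2 / q^2) * (raw >= floor)
  c(sum(dq), as.numeric(crossprod(U, dq)))
}

#' Fit post-hoc NLL calibration on the validation set
#'
#' Learns a bias `w0` and nonnegative weights `w` so that the combined
#' uncertainty `Q(x) = w0 + sum_j w_j U_j(x)` minimises the Gaussian NLL
#' `sum_i [log Q(x_i) + e_i^2 / Q(x_i)]` of the validation residuals.
#' Inputs enter unnormalized.  The fit is a deterministic multi-start
#' L-BFGS-B: one start per single-method moment match plus a constant-only
#' start, with `Q` floored at a small positive value.
#'
#' @param valUncertainties list of [UncertaintyVector-class] on the
#'   validation set (raw values).
#' @param valSignedErrors validation residuals (predicted minus observed).
#' @param floor positive floor on the combined variance.
#' @return A [CalibrationModel-class].
#' @examples
#' u <- uncertaintyVector("U", rep(1, 3), FALSE)
#' m <- fitNllCalibration(list(u), c(1, -1, 2))
#' applyCalibration(m, list(u))  # constant mean(e^2) = 2
#' @export
fitNllCalibration <- function(valUncertainties, valSignedErrors, floor = 1e-6) {
  .assertNumericVector(valSignedErrors, "valSignedErrors")
  t <- length(valUncertainties)
  n <- length(valSignedErrors)
  if (n < t + 2L)
    stop("NLL calibration needs at least t + 2 validation samples", call. = FALSE)
  U <- do.call(cbind, lapply(valUncertainties, uncertaintyValues))
  if (nrow(U) != n)
    stop("uncertainty vectors and errors must be aligned", call. = FALSE)
  e2 <- valSignedErrors^2
  mse <- max(mean(e2), floor)

  ## deterministic multi-starts: constant-only, per-method moment matches,
  ## and an equal-share split across methods
  colMeansU <- pmax(colMeans(U), 1e-12)
  starts <- list(c(mse, rep(0, t)))
  for (j in seq_len(t)) {
    s <- c(floor, rep(0, t)); s[j + 1] <- mse / colMeansU[j]
    starts[[length(starts) + 1]] <- s
  }
  starts[[length(starts) + 1]] <- c(mse / 2, (mse / 2) / colMeansU / t)

  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      optim(s, .nllObjective, .nllGradient, U = U, e2 = e2, floor = floor,
            method = "L-BFGS-B", lower = c(-Inf, rep(0, t)),
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best))
    stop("NLL calibration failed to converge from every start", call. = FALSE)
  weights <- methods::new("ConsensusWeights", w0 = best$par[1],
                          w = pmax(best$par[-1], 0),
                          methods = vapply(valUncertainties, methodName,
                                           character(1)),
                          strategy = "nll_calibrated")
  methods::new("CalibrationModel", weights = weights, floor = floor,
               nValidation = as.integer(n), optimumLoss = best$value)
}

#' Apply a fitted calibration model
#'
#' `Q(x) = w0 + sum_j w_j U_j(x)`, floored at the stored positive floor; the
#' output is on the variance scale of the labels.
#'
#' @param model a [CalibrationModel-class].
#' @param uncertaintySets list of [UncertaintyVector-class] with the same
#'   methods, in the same order, as at fit time.
#' @param method output label.
#' @return An [UncertaintyVector-class] (variance scale).
#' @export
applyCalibration <- function(model, uncertaintySets, method = "NLLCAL") {
  got <- vapply(uncertaintySets, methodName, character(1))
  if (!identical(got, model@weights@methods))
    stop(sprintf("method list mismatch: fitted on (%s), given (%s)",
                 paste(model@weights@methods, collapse = ", "),
                 paste(got, collapse = ", ")), call. = FALSE)
  U <- do.call(cbind, lapply(uncertaintySets, uncertaintyValues))
  q <- pmax(model@weights@w0 + as.numeric(U %*% model@weights@w), model@floor)
  uncertaintyVector(method, q, TRUE)
}

#' Serialize / restore a calibration model
#'
#' Writes the fitted methods, bias, weights, floor and provenance as a small
#' JSON document.
#'
#' @param model a [CalibrationModel-class].
#' @param path file path.
#' @return `readCalibrationModel` returns the restored
#'   [CalibrationModel-class].
#' @export
writeCalibrationModel <- function(model, path) {
  jsonlite::write_json(
    list(methods = model@weights@methods, w0 = model@weights@w0,
         w = model@weights@w, floor = model@floor,
         nValidation = model@nValidation, optimumLoss = model@optimumLoss),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCalibrationModel
#' @export
readCalibrationModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  weights <- methods::new("ConsensusWeights", w0 = x$w0, w = as.numeric(x$w),
                          methods = as.character(x$methods),
                          strategy = "nll_calibrated")
  methods::new("CalibrationModel", weights = weights, floor = x$floor,
               nValidation = as.integer(x$nValidation),
               optimumLoss = x$optimumLoss)
}

setMethod("show", "CalibrationModel", function(object) {
  cat(sprintf("CalibrationModel (n = %d): w0 = %.4g\n", object@nValidation,
              object@weights@w0))
  for (i in seq_along(object@weights@w))
    cat(sprintf("  %-8s %.4g\n", object@weights@methods[i], object@weights@w[i]))
})
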