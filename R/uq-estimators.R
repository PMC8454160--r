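## The four individual uncertainty estimators and the additive Bayesian
## total-uncertainty baseline.  MVE and LDIST depend on the model weights and
## are averaged over the ensemble members; FDIST is model-independent and
## computed once; ENS is the ensemble disagreement itself.

#' Construct an UncertaintyVector
#'
#' @param method method label.
#' @param values nonnegative per-sample estimates.
#' @param varianceScale TRUE for variance-scale estimates, FALSE for relative
#'   scores such as distances.
#' @return An [UncertaintyVector-class].
#' @export
uncertaintyVector <- function(method, values, varianceScale) {
  methods::new("UncertaintyVector", method = method,
               values = as.numeric(values), varianceScale = varianceScale)
}

#' @describeIn uncertaintyVector the numeric estimates.
#' @param x an `UncertaintyVector`.
#' @export
uncertaintyValues <- function(x) x@values

#' @describeIn uncertaintyVector the method label.
#' @export
methodName <- function(x) x@method

#' @describeIn uncertaintyVector whether values are on the variance scale.
#' @export
isVarianceScale <- function(x) x@varianceScale

setMethod("show", "UncertaintyVector", function(object) {
  cat(sprintf("UncertaintyVector '%s' (%s scale), %d samples\n",
              object@method,
              if (object@varianceScale) "variance" else "relative",
              length(object@values)))
})

#' Aleatoric uncertainty from the mean-variance heads
#'
#' Per sample, the mean of the ensemble members' predicted aleatoric
#' variances.  Only available for ensembles trained with the mean-variance
#' loss.
#'
#' @param bundle a [PredictionBundle-class].
#' @return An [UncertaintyVector-class] (`MVE`, variance scale).
#' @export
estimateAleatoric <- function(bundle) {
  if (bundle@lossKind != "mean_variance" || is.null(bundle@memberVariances))
    stop("MVE uncertainty requires an ensemble trained with the mean-variance loss",
         call. = FALSE)
  uncertaintyVector("MVE", rowMeans(bundle@memberVariances), TRUE)
}

#' Epistemic uncertainty from ensemble disagreement
#'
#' Population variance (divisor K) of the member means around the ensemble
#' mean; zero for a single-member ensemble.
#'
#' @param bundle a [PredictionBundle-class].
#' @return An [UncertaintyVector-class] (`ENS`, variance scale).
#' @export
estimateEpistemic <- function(bundle) {
  dev2 <- (bundle@memberMeans - bundle@ensembleMean)^2
  uncertaintyVector("ENS", rowMeans(dev2), TRUE)
}

#' Fingerprint-space distance to the training set
#'
#' Per test sample, the Tanimoto distance to its nearest training-set
#' neighbour.  Model-independent.
#'
#' @param testFps,trainFps lists of fingerprints of the same family and
#'   parameters, or numeric 0/1 feature matrices.
#' @return An [UncertaintyVector-class] (`FDIST`, relative scale).
#' @export
estimateFdist <- function(testFps, trainFps) {
  nTrain <- if (is.list(trainFps) && !is.data.frame(trainFps))
    length(trainFps) else nrow(as.matrix(trainFps))
  if (is.null(nTrain) || nTrain == 0L)
    stop("the training fingerprint set must be non-empty", call. = FALSE)
  isMinhash <- is.list(testFps) && methods::is(testFps[[1]], "MinHashFingerprint")
  if (isMinhash) {
    vals <- vapply(testFps, nearestDistance, numeric(1),
                   references = trainFps, metric = tanimotoDistance)
  } else {
    d <- tanimotoDistanceMatrix(testFps, trainFps)
    vals <- apply(d, 1, min)
  }
  uncertaintyVector("FDIST", vals, FALSE)
}

## min cosine distance from each row of A to any row of B (nonzero rows)
.minCosineCross <- function(A, B) {
  na <- sqrt(rowSums(A^2)); nb <- sqrt(rowSums(B^2))
  if (any(na == 0) || any(nb == 0))
    stop("cosine distance is undefined for a zero latent vector", call. = FALSE)
  sim <- (A / na) %*% t(B / nb)
  1 - apply(sim, 1, max)
}

#' Latent-space distance to the training set
#'
#' For each ensemble member, the minimum cosine distance between the test
#' sample's latent vector and all training-set latent vectors of that member;
#' the estimate is the mean over members.
#'
#' @param bundle test-set [PredictionBundle-class].
#' @param trainBundle training-set [PredictionBundle-class] from the same
#'   ensemble.
#' @return An [UncertaintyVector-class] (`LDIST`, relative scale).
#' @export
estimateLdist <- function(bundle, trainBundle) {
  K <- ncol(bundle@memberMeans)
  if (K != ncol(trainBundle@memberMeans))
    stop("bundles come from different ensembles", call. = FALSE)
  perMember <- vapply(seq_len(K), function(k) {
    A <- bundle@memberLatents[[k]]; B <- trainBundle@memberLatents[[k]]
    if (ncol(A) != ncol(B))
      stop("latent dimensions differ between bundles", call. = FALSE)
    .minCosineCross(A, B)
  }, numeric(nrow(bundle@memberMeans)))
  perMember <- matrix(perMember, nrow = nrow(bundle@memberMeans))
  vals <- pmax(rowMeans(perMember), 0)  # clip tiny negative rounding noise
  uncertaintyVector("LDIST", vals, FALSE)
}

#' Bayesian total-uncertainty baseline
#'
#' Elementwise sum of the aleatoric and epistemic estimates, approximating
#' the posterior predictive variance (expectation of the noise variance plus
#' variance of the predicted mean).
#'
#' @param qa,qe aligned variance-scale [UncertaintyVector-class] objects.
#' @return An [UncertaintyVector-class] (`BYS`, variance scale).
#' @export
estimateBys <- function(qa, qe) {
  if (!qa@varianceScale || !qe@varianceScale)
    stop("BYS requires variance-scale inputs; distances must be calibrated first",
         call. = FALSE)
  .assertSameLength(qa@values, qe@values, "qa", "qe")
  uncertaintyVector("BYS", qa@values + qe@values, TRUE)
}
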