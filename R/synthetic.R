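## Chemistry-free synthetic fixtures: clustered binary feature vectors with
## heteroskedastic Gaussian labels whose noise variance is known exactly.
## These emulate the statistical structure of clustered bioactivity datasets
## (families of similar molecules, noise that varies across the dataset) so
## that every stage of the uncertainty pipeline can be tested end to end.

#' Specification of a synthetic heteroskedastic dataset
#'
#' Samples are noisy copies of per-cluster prototype bit vectors; the label is
#' a linear function of the bits plus Gaussian noise whose variance follows
#' sigma^2(x) = noiseBase + noiseScale * g(x), where the covariate g is tied
#' to cluster identity (equally spaced on `[0, 1]`) and stored with the data,
#' so aleatoric uncertainty has learnable structure and calibration can be
#' checked against the exact truth.
#'
#' @slot nSamples number of molecules to generate.
#' @slot nFeatures bit-vector length.
#' @slot nClusters number of prototype clusters.
#' @slot flipRate within-cluster bit-flip probability.
#' @slot margin required minimum Jaccard distance between samples of
#'   different clusters.
#' @slot noiseBase,noiseScale parameters (a, b) of sigma^2 = a + b * g(x).
#' @slot betaSd standard deviation of the linear label weights.
#' @slot seed RNG seed; the dataset is fully reproducible from it.
#' @export
setClass("SyntheticSpec",
  representation(nSamples = "integer", nFeatures = "integer",
                 nClusters = "integer", flipRate = "numeric",
                 margin = "numeric", noiseBase = "numeric",
                 noiseScale = "numeric", betaSd = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (object@nSamples < 1L || object@nFeatures < 1L || object@nClusters < 1L)
      return("nSamples, nFeatures and nClusters must be positive")
    if (object@flipRate < 0 || object@flipRate >= 0.5)
      return("flipRate must lie in [0, 0.5)")
    if (object@noiseBase <= 0)
      return("noiseBase must be positive so sigma^2(x) > 0 everywhere")
    if (object@noiseScale < 0) return("noiseScale must be nonnegative")
    TRUE
  })

#' @describeIn SyntheticSpec constructor with the package's study defaults.
#' @param nSamples,nFeatures,nClusters,flipRate,margin,noiseBase,noiseScale,betaSd,seed
#'   see the class slots.
#' @export
syntheticSpec <- function(nSamples = 2000L, nFeatures = 128L, nClusters = 8L,
                          flipRate = 0.05, margin = 0.4, noiseBase = 0.05,
                          noiseScale = 0.95, betaSd = NULL, seed = 1L) {
  if (is.null(betaSd)) betaSd <- 2 / sqrt(nFeatures)
  methods::new("SyntheticSpec", nSamples = as.integer(nSamples),
               nFeatures = as.integer(nFeatures),
               nClusters = as.integer(nClusters), flipRate = flipRate,
               margin = margin, noiseBase = noiseBase,
               noiseScale = noiseScale, betaSd = betaSd,
               seed = as.integer(seed))
}

.generateOnce <- function(spec) {
  n <- spec@nSamples; d <- spec@nFeatures; C <- spec@nClusters
  proto <- matrix(rbinom(C * d, 1L, 0.5), C, d)
  cluster <- sample(rep(seq_len(C), length.out = n))
  X <- proto[cluster, , drop = FALSE]
  if (spec@flipRate > 0) {
    flip <- matrix(rbinom(n * d, 1L, spec@flipRate), n, d)
    X <- abs(X - flip)
  }
  g <- if (C == 1L) 0.5 else (cluster - 1) / (C - 1)
  sigma2 <- spec@noiseBase + spec@noiseScale * g
  beta <- rnorm(d, 0, spec@betaSd)
  f <- as.numeric(X %*% beta)
  y <- f + rnorm(n, 0, sqrt(sigma2))
  list(X = X, y = y, f = f, sigma2 = sigma2, g = g, cluster = cluster)
}

## smallest Jaccard distance between samples of different clusters,
## computed in row blocks to keep memory bounded at large n
.minInterClusterDistance <- function(X, cluster) {
  if (length(unique(cluster)) < 2L) return(Inf)
  n <- nrow(X)
  best <- Inf
  for (start in seq(1L, n, by = 1000L)) {
    rows <- start:min(start + 999L, n)
    d <- tanimotoDistanceMatrix(X[rows, , drop = FALSE], X)
    diff <- outer(cluster[rows], cluster, "!=")
    best <- min(best, d[diff])
  }
  best
}

#' Generate a synthetic dataset
#'
#' Draws cluster prototypes once, perturbs them into samples at the spec's
#' flip rate, and adds heteroskedastic Gaussian label noise.  If the realised
#' clusters are closer (in Jaccard distance) than the spec's margin the draw
#' is rejected and regenerated from a shifted seed, up to `maxRetries` times.
#'
#' @param spec a [SyntheticSpec-class].
#' @param maxRetries bounded retries when the margin is infeasible.
#' @return A [MoleculeSet-class] with ground-truth columns `trueMean`,
#'   `trueVar`, `gValue` and `cluster`.
#' @examples
#' ms <- generateSynthetic(syntheticSpec(nSamples = 100, seed = 7))
#' @export
generateSynthetic <- function(spec, maxRetries = 3L) {
  for (attempt in 0:maxRetries) {
    dat <- withSeed(spec@seed + attempt * 104729L, .generateOnce(spec))
    sep <- .minInterClusterDistance(dat$X, dat$cluster)
    if (sep >= spec@margin)
      return(moleculeSet(dat$X, dat$y, trueMean = dat$f, trueVar = dat$sigma2,
                         gValue = dat$g, cluster = dat$cluster))
    message(sprintf(
      "synthetic draw %d: inter-cluster distance %.3f below margin %.3f; regenerating",
      attempt + 1L, sep, spec@margin))
  }
  stop("could not realise the requested cluster margin; ",
       "lower 'margin', 'flipRate' or 'nClusters'", call. = FALSE)
}

#' Generate an in-domain / out-of-domain dataset pair
#'
#' Splits one synthetic draw by cluster identity: the last `heldOutClusters`
#' clusters form the out-of-domain set, whose samples are guaranteed to lie
#' at least the spec margin away (Jaccard) from every in-domain sample.
#'
#' @param spec a [SyntheticSpec-class].
#' @param heldOutClusters number of clusters reserved for the
#'   out-of-domain set; must be smaller than `spec@nClusters`.
#' @return A list with elements `inDomain` and `outOfDomain`, both
#'   [MoleculeSet-class].
#' @export
domainShiftPair <- function(spec, heldOutClusters) {
  heldOutClusters <- as.integer(heldOutClusters)
  if (heldOutClusters >= spec@nClusters)
    stop("'heldOutClusters' must be smaller than the number of clusters")
  ms <- generateSynthetic(spec)
  out <- clusterIds(ms) > spec@nClusters - heldOutClusters
  list(inDomain = ms[, !out], outOfDomain = ms[, out])
}
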