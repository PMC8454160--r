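# Shared fixtures and independent oracles used across the test files.

# A small set of drug-like SMILES for the chemistry-dependent paths.
exampleSmiles <- c(
  "CCO", "CC(=O)Oc1ccccc1C(=O)O", "c1ccccc1", "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
  "CN1CCC[C@H]1c1cccnc1", "Clc1ccccc1", "OCC(O)CO", "CC(=O)Nc1ccc(O)cc1",
  "c1ccc2c(c1)cccc2", "CCN(CC)CC", "CC(C)(C)c1ccc(O)cc1", "OC(=O)c1ccccc1O",
  "CCCCCCCCO", "Nc1ccc(cc1)S(=O)(=O)N", "COc1ccc(CCN)cc1", "CC1=CC(=O)CC(C)(C)C1",
  "O=C(O)CCCCC(=O)O", "c1ccsc1", "C1CCOC1", "CC(N)Cc1ccccc1",
  "FC(F)(F)c1ccccc1", "O=C1NC(=O)NC(=O)C1", "CCOC(=O)C", "CN(C)c1ccccc1"
)

# random sparse bit-set fingerprint in a fixed space
randomFingerprint <- function(nBits = 64L, density = 0.25) {
  featureFingerprint(rbinom(nBits, 1L, density))
}

# brute-force union-find over all thresholded pairs: the independent oracle
# for single-linkage clustering
unionFindClusters <- function(d, cutoff) {
  n <- nrow(d)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && d[i, j] <= cutoff) {
      a <- find(i); b <- find(j)
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  as.integer(factor(roots, levels = unique(roots)))
}

# canonical relabelling so two cluster assignments can be compared
canonicalClusters <- function(cl) as.integer(factor(cl, levels = unique(cl)))

# hand-built PredictionBundle for estimator unit tests
manualBundle <- function(means, variances = NULL, latents = NULL) {
  means <- as.matrix(means)
  if (is.null(latents))
    latents <- replicate(ncol(means),
                         matrix(rnorm(nrow(means) * 3), ncol = 3),
                         simplify = FALSE)
  new("PredictionBundle", memberMeans = means,
      memberVariances = if (is.null(variances)) NULL else as.matrix(variances),
      memberLatents = latents, ensembleMean = rowMeans(means),
      lossKind = if (is.null(variances)) "mse" else "mean_variance")
}

# a small, quickly trained mean-variance ensemble shared by several tests
sharedFixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    ms <- generateSynthetic(syntheticSpec(nSamples = 400, nFeatures = 64,
                                          nClusters = 4, seed = 11))
    plan <- randomFivefold(nMolecules(ms), seed = 2)[[1]]
    cfg <- regressorConfig(hiddenSizes = 24L, maxEpochs = 150L,
                           meanOnlyEpochs = 30L, seed = 7L)
    ens <- trainEnsemble(ms[, trainIndices(plan)], ms[, validationIndices(plan)],
                         cfg, K = 2L)
    cache <<- list(ms = ms, plan = plan, ens = ens)
    cache
  }
})
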