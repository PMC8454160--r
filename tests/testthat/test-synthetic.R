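test_that("generation is reproducible and respects the flip rate", {
  spec <- syntheticSpec(nSamples = 120, nFeatures = 48, nClusters = 3, seed = 5)
  a <- generateSynthetic(spec)
  b <- generateSynthetic(spec)
  expect_identical(featureMatrix(a), featureMatrix(b))
  expect_identical(activities(a), activities(b))

  frozen <- generateSynthetic(syntheticSpec(nSamples = 60, nFeatures = 32,
                                            nClusters = 3, flipRate = 0,
                                            seed = 5))
  X <- featureMatrix(frozen)
  for (cl in unique(clusterIds(frozen))) {
    rows <- X[clusterIds(frozen) == cl, , drop = FALSE]
    expect_true(all(rows == rep(rows[1, ], each = nrow(rows))))
  }
})

test_that("residuals realise the declared noise variance", {
  spec <- syntheticSpec(nSamples = 10000, nFeatures = 32, nClusters = 4,
                        flipRate = 0.02, margin = 0.1,
                        noiseBase = 0.49, noiseScale = 0, seed = 8)
  ms <- generateSynthetic(spec)
  resid <- activities(ms) - trueMeans(ms)
  expect_lt(abs(var(resid) - 0.49) / 0.49, 0.05)
  expect_true(all(trueVariance(ms) == 0.49))
})

test_that("heteroskedastic truth follows sigma^2 = a + b * g", {
  ms <- generateSynthetic(syntheticSpec(nSamples = 200, seed = 2))
  expect_equal(trueVariance(ms), 0.05 + 0.95 * gValues(ms))
  expect_true(all(trueVariance(ms) > 0))
})

test_that("clusters keep the declared separation margin", {
  ms <- generateSynthetic(syntheticSpec(nSamples = 150, nClusters = 5, seed = 3))
  d <- tanimotoDistanceMatrix(featureMatrix(ms))
  cl <- clusterIds(ms)
  inter <- d[outer(cl, cl, "!=")]
  expect_gte(min(inter), 0.4)
})

test_that("the exact noise variance scores as calibrated uncertainty", {
  ms <- generateSynthetic(syntheticSpec(nSamples = 2000, seed = 21))
  resid <- activities(ms) - trueMeans(ms)
  truth <- trueVariance(ms)
  expect_lte(ece(truth, resid), 0.02)
  # 20-sample bins carry an irreducible chi-squared sampling floor of ~0.13
  # in ENCE, so the oracle lands in that noise band rather than at zero
  expect_lte(ence(truth, resid^2), 0.15)
})

test_that("NLL calibration on the oracle covariate recovers (a, b)", {
  ms <- generateSynthetic(syntheticSpec(nSamples = 5000, seed = 22))
  resid <- activities(ms) - trueMeans(ms)
  fit <- fitNllCalibration(list(uncertaintyVector("g", gValues(ms), FALSE)),
                           resid)
  expect_lt(abs(fit@weights@w0 - 0.05) / 0.05, 0.10)
  expect_lt(abs(fit@weights@w[1] - 0.95) / 0.95, 0.10)
})

test_that("domain-shift pairs isolate the held-out clusters", {
  spec <- syntheticSpec(nSamples = 300, nClusters = 6, seed = 9)
  pair <- domainShiftPair(spec, heldOutClusters = 2)
  expect_equal(nMolecules(pair$inDomain) + nMolecules(pair$outOfDomain), 300)
  expect_length(intersect(unique(clusterIds(pair$inDomain)),
                          unique(clusterIds(pair$outOfDomain))), 0)

  # out-of-domain FDIST to the in-domain set is at least the margin
  fd <- estimateFdist(featureMatrix(pair$outOfDomain),
                      featureMatrix(pair$inDomain))
  expect_gte(min(uncertaintyValues(fd)), spec@margin)

  # cluster CV at cutoff 0.3 keeps held-out clusters in their own groups
  all <- cbind(t(featureMatrix(pair$inDomain)), t(featureMatrix(pair$outOfDomain)))
  cl <- singleLinkageClusters(tanimotoDistanceMatrix(t(all)), 0.3)
  nIn <- nMolecules(pair$inDomain)
  expect_length(intersect(unique(cl[seq_len(nIn)]), unique(cl[-seq_len(nIn)])), 0)

  none <- domainShiftPair(spec, 0)
  expect_equal(nMolecules(none$outOfDomain), 0L)
})
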