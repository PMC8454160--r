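test_that("aleatoric uncertainty is the member-average predicted variance", {
  b <- manualBundle(cbind(c(1, 1), c(1, 1)), cbind(c(0.2, 0.7), c(0.4, 0.7)))
  qa <- estimateAleatoric(b)
  expect_equal(uncertaintyValues(qa), c(0.3, 0.7))
  expect_true(isVarianceScale(qa))

  single <- manualBundle(matrix(1, 1, 1), matrix(0.7, 1, 1))
  expect_equal(uncertaintyValues(estimateAleatoric(single)), 0.7)
})

test_that("epistemic uncertainty is the population ensemble variance", {
  b <- manualBundle(cbind(0, 2))
  expect_equal(uncertaintyValues(estimateEpistemic(b)), 1)  # ((1-0)^2+(1-2)^2)/2
  expect_equal(uncertaintyValues(estimateEpistemic(manualBundle(cbind(3, 3)))), 0)
  expect_equal(uncertaintyValues(estimateEpistemic(manualBundle(matrix(2, 2, 1)))),
               c(0, 0))

  set.seed(10)
  means <- matrix(rnorm(15), 5, 3)
  qe <- uncertaintyValues(estimateEpistemic(manualBundle(means)))
  perm <- uncertaintyValues(estimateEpistemic(manualBundle(means[, c(3, 1, 2)])))
  expect_equal(qe, perm)
})

test_that("FDIST is the nearest-neighbour training distance", {
  train <- matrix(c(1, 1, 0, 0,
                    0, 0, 1, 1), 2, byrow = TRUE)
  test <- matrix(c(1, 1, 0, 0,
                   1, 0, 1, 0), 2, byrow = TRUE)
  fd <- estimateFdist(test, train)
  expect_equal(uncertaintyValues(fd)[1], 0)        # present in training set
  expect_false(isVarianceScale(fd))
  expect_error(estimateFdist(test, matrix(0, 0, 4)), "non-empty")

  disjoint <- estimateFdist(matrix(c(0, 0, 0, 1), 1), matrix(c(1, 1, 0, 0), 1))
  expect_equal(uncertaintyValues(disjoint), 1)

  # 30 x 100 random case equals the exhaustive scan
  set.seed(3)
  tr <- matrix(rbinom(100 * 32, 1, 0.3), 100)
  te <- matrix(rbinom(30 * 32, 1, 0.3), 30)
  got <- uncertaintyValues(estimateFdist(te, tr))
  trFp <- featureFingerprints(tr)
  oracle <- vapply(featureFingerprints(te), nearestDistance, numeric(1),
                   references = trFp)
  expect_equal(got, oracle)
})

test_that("LDIST averages per-member nearest cosine distances", {
  lat <- list(matrix(c(0, 1), 1), matrix(c(1, 1), 1))
  trainLat <- list(matrix(c(0, 1), 1), matrix(c(1, 1), 1))
  b <- manualBundle(matrix(0, 1, 2), latents = lat)
  tb <- manualBundle(matrix(0, 1, 2), latents = trainLat)
  expect_equal(uncertaintyValues(estimateLdist(b, tb)), 0)

  one <- manualBundle(matrix(0, 1, 1), latents = list(matrix(c(0, 1), 1)))
  oneTrain <- manualBundle(matrix(0, 1, 1), latents = list(matrix(c(1, 0), 1)))
  expect_equal(uncertaintyValues(estimateLdist(one, oneTrain)), 1)

  # random 20 x 50 with K = 3 equals the brute-force per-member scan
  set.seed(6)
  K <- 3
  testLat <- replicate(K, matrix(rnorm(20 * 4), 20), simplify = FALSE)
  trainLat <- replicate(K, matrix(rnorm(50 * 4), 50), simplify = FALSE)
  bt <- manualBundle(matrix(0, 20, K), latents = testLat)
  btr <- manualBundle(matrix(0, 50, K), latents = trainLat)
  got <- uncertaintyValues(estimateLdist(bt, btr))
  oracle <- rowMeans(vapply(seq_len(K), function(k)
    vapply(seq_len(20), function(i)
      min(vapply(seq_len(50), function(j)
        cosineDistance(testLat[[k]][i, ], trainLat[[k]][j, ]), numeric(1))),
      numeric(1)), numeric(20)))
  expect_equal(got, oracle, tolerance = 1e-10)

  bad <- manualBundle(matrix(0, 5, K),
                      latents = replicate(K, matrix(rnorm(10), 5), simplify = FALSE))
  expect_error(estimateLdist(bt, bad), "latent dimensions")
})

test_that("BYS adds aleatoric and epistemic estimates", {
  qa <- uncertaintyVector("MVE", c(0.3, 0), TRUE)
  qe <- uncertaintyVector("ENS", c(0.2, 0.5), TRUE)
  bys <- estimateBys(qa, qe)
  expect_equal(uncertaintyValues(bys), c(0.5, 0.5))
  expect_true(all(uncertaintyValues(bys) >=
                    pmax(uncertaintyValues(qa), uncertaintyValues(qe))))
  dist <- uncertaintyVector("FDIST", c(0.1, 0.2), FALSE)
  expect_error(estimateBys(qa, dist), "variance-scale")
})

test_that("the posterior-variance decomposition sums to BYS", {
  set.seed(12)
  means <- matrix(rnorm(12), 4, 3)
  vars <- matrix(runif(12, 0.1, 1), 4, 3)
  b <- manualBundle(means, vars)
  qa <- estimateAleatoric(b); qe <- estimateEpistemic(b)
  # expectation of the member variances + variance of the member means
  expected <- rowMeans(vars) +
    rowMeans((means - rowMeans(means))^2)
  expect_equal(uncertaintyValues(estimateBys(qa, qe)), expected)
})
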