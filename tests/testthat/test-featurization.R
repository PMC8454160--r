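test_that("Tanimoto distance matches the Jaccard definition", {
  a <- featureFingerprint(c(0, 1, 1, 1, 0))  # bits {1,2,3}
  b <- featureFingerprint(c(0, 0, 1, 1, 1))  # bits {2,3,4}
  expect_equal(tanimotoDistance(a, b), 0.5)  # J = 2/4
  expect_equal(tanimotoDistance(a, a), 0)
  disjoint <- featureFingerprint(c(1, 0, 0, 0, 0))
  expect_equal(tanimotoDistance(b, disjoint), 1)
  short <- featureFingerprint(c(1, 0))
  expect_error(tanimotoDistance(a, short), "different lengths")
})

test_that("cosine distance covers orthogonal, identical and antiparallel", {
  expect_equal(cosineDistance(c(1, 0), c(0, 1)), 1)
  expect_equal(cosineDistance(c(2, 3), c(2, 3)), 0)
  expect_equal(cosineDistance(c(1, 0), c(-1, 0)), 2)
  expect_error(cosineDistance(c(0, 0), c(1, 0)), "zero vector")
})

test_that("distances are symmetric and zero on identical inputs", {
  set.seed(41)
  for (i in 1:10) {
    f1 <- randomFingerprint(); f2 <- randomFingerprint()
    expect_equal(tanimotoDistance(f1, f2), tanimotoDistance(f2, f1))
    expect_equal(tanimotoDistance(f1, f1), 0)
    v1 <- rnorm(5); v2 <- rnorm(5)
    expect_equal(cosineDistance(v1, v2), cosineDistance(v2, v1))
  }
})

test_that("nearestDistance is the exhaustive minimum and shrinks with references", {
  q <- featureFingerprint(c(1, 1, 0, 0))
  refs <- list(featureFingerprint(c(1, 1, 0, 0)), featureFingerprint(c(0, 0, 1, 1)))
  expect_equal(nearestDistance(q, refs), 0)
  expect_error(nearestDistance(q, list()), "non-empty")

  set.seed(7)
  refs <- replicate(50, randomFingerprint(), simplify = FALSE)
  query <- randomFingerprint()
  oracle <- min(vapply(refs, function(r) tanimotoDistance(query, r), numeric(1)))
  expect_equal(nearestDistance(query, refs), oracle)
  # monotone non-increasing as references accumulate
  running <- vapply(seq_along(refs), function(k)
    nearestDistance(query, refs[seq_len(k)]), numeric(1))
  expect_true(all(diff(running) <= 0))
})

test_that("the distance matrix agrees with pairwise scans", {
  set.seed(13)
  A <- matrix(rbinom(8 * 16, 1, 0.3), 8)
  B <- matrix(rbinom(5 * 16, 1, 0.3), 5)
  d <- tanimotoDistanceMatrix(A, B)
  fa <- featureFingerprints(A); fb <- featureFingerprints(B)
  for (i in seq_len(8)) for (j in seq_len(5))
    expect_equal(d[i, j], tanimotoDistance(fa[[i]], fb[[j]]))
})

test_that("circular fingerprints are deterministic and reject bad SMILES", {
  fp <- binaryFingerprint("C", radius = 2, nBits = 2048)
  expect_s4_class(fp, "BinaryFingerprint")
  expect_gte(length(fp@bits), 1L)
  expect_identical(binaryFingerprint("CC(=O)O")@bits,
                   binaryFingerprint("CC(=O)O")@bits)
  expect_error(binaryFingerprint("not_a_smiles"), "cannot parse SMILES")
  folded <- binaryFingerprint("c1ccccc1O", nBits = 64)
  expect_true(all(folded@bits >= 0 & folded@bits < 64))
})

test_that("minhash fingerprints satisfy the signature contracts", {
  m1 <- minhashFingerprint("CCO", nPermutations = 256)
  expect_length(m1@hashes, 256)
  expect_identical(m1@hashes, minhashFingerprint("CCO", nPermutations = 256)@hashes)
  expect_equal(tanimotoDistance(m1, m1), 0)
  expect_error(tanimotoDistance(m1, binaryFingerprint("CCO")), "same family")
})

test_that("minhash Jaccard estimates converge to the exact set Jaccard", {
  set.seed(5)
  pairs <- matrix(sample(exampleSmiles, 40, replace = TRUE), ncol = 2)
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  dev <- apply(pairs, 1, function(p) {
    exact <- tanimotoDistance(binaryFingerprint(p[1], radius = 3, nBits = 0),
                              binaryFingerprint(p[2], radius = 3, nBits = 0))
    est <- tanimotoDistance(minhashFingerprint(p[1], 2048),
                            minhashFingerprint(p[2], 2048))
    abs(exact - est)
  })
  expect_lt(mean(dev), 0.05)
})
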