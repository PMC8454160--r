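test_that("random fivefold plans are 60/20/20 partitions", {
  plans <- randomFivefold(100, seed = 3)
  expect_length(plans, 5)
  for (p in plans) {
    expect_length(trainIndices(p), 60)
    expect_length(validationIndices(p), 20)
    expect_length(testIndices(p), 20)
    expect_length(intersect(trainIndices(p), testIndices(p)), 0)
  }
  expect_setequal(unlist(lapply(plans, testIndices)), 1:100)
  expect_identical(lapply(randomFivefold(100, seed = 3), testIndices),
                   lapply(plans, testIndices))
  expect_error(randomFivefold(5), "at least 10")
})

test_that("single-linkage clustering cuts the thresholded graph", {
  d <- matrix(0, 4, 4)
  d[1, 2] <- d[2, 1] <- 0.1
  d[2, 3] <- d[3, 2] <- 0.2
  d[1, 3] <- d[3, 1] <- 0.5
  d[1, 4] <- d[4, 1] <- d[2, 4] <- d[4, 2] <- d[3, 4] <- d[4, 3] <- 0.45
  cl <- singleLinkageClusters(d, 0.3)
  expect_equal(canonicalClusters(cl), c(1, 1, 1, 2))

  far <- matrix(0.9, 5, 5); diag(far) <- 0
  expect_length(unique(singleLinkageClusters(far, 0.3)), 5)
  near <- matrix(0, 5, 5)
  expect_length(unique(singleLinkageClusters(near, 0.3)), 1)

  asym <- matrix(runif(16), 4); diag(asym) <- 0
  expect_error(singleLinkageClusters(asym, 0.3), "symmetric")
})

test_that("clustering agrees with brute-force union-find on random instances", {
  set.seed(55)
  for (i in 1:25) {
    n <- sample(3:40, 1)
    d <- matrix(runif(n * n), n)
    d <- (d + t(d)) / 2; diag(d) <- 0
    cutoff <- runif(1, 0.1, 0.6)
    got <- canonicalClusters(singleLinkageClusters(d, cutoff))
    expect_identical(got, canonicalClusters(unionFindClusters(d, cutoff)))
  }
})

test_that("greedy fold assembly balances cluster sizes", {
  clusters <- rep(1:5, times = c(5, 4, 3, 2, 1))
  folds <- assembleFolds(clusters, k = 2, seed = 1)
  expect_setequal(as.integer(table(folds)), c(8L, 7L))
  # clusters never split across folds
  expect_true(all(tapply(folds, clusters, function(f) length(unique(f))) == 1))

  equal <- rep(1:6, each = 10)
  expect_true(all(table(assembleFolds(equal, k = 3, seed = 2)) == 20))

  singletons <- 1:40
  sizes <- table(assembleFolds(singletons, k = 5, seed = 3))
  expect_true(all(sizes == 8))
  expect_error(assembleFolds(rep(1:3, 5), k = 5), "at least 5 clusters")
})

test_that("OVOT rotations hold out whole folds for validation and test", {
  folds <- rep(1:5, each = 8)
  plans <- makeOvot(folds)
  expect_length(plans, 5)
  expect_setequal(vapply(plans, function(p) unique(folds[testIndices(p)]),
                         integer(1)), 1:5)
  for (p in plans) {
    expect_length(intersect(validationIndices(p), testIndices(p)), 0)
    expect_length(unique(folds[validationIndices(p)]), 1)
    expect_length(trainIndices(p), 24)
  }
})

test_that("IVOT pools the remaining folds for an in-domain validation set", {
  folds <- rep(1:5, each = 20)
  plans <- makeIvot(folds, seed = 7)
  p <- plans[[1]]
  expect_length(trainIndices(p), 60)
  expect_length(validationIndices(p), 20)
  expect_length(testIndices(p), 20)
  # validation spans several source folds (in-domain w.r.t. training)
  expect_gt(length(unique(folds[validationIndices(p)])), 1)
  expect_identical(lapply(makeIvot(folds, seed = 7), validationIndices),
                   lapply(plans, validationIndices))
})

test_that("OVOT folds respect the distance cutoff by brute force", {
  ms <- generateSynthetic(syntheticSpec(nSamples = 200, nClusters = 10, seed = 13))
  d <- tanimotoDistanceMatrix(featureMatrix(ms))
  folds <- assembleFolds(singleLinkageClusters(d, 0.3), k = 5, seed = 1)
  for (p in makeOvot(folds)) {
    sets <- list(trainIndices(p), validationIndices(p), testIndices(p))
    for (i in 1:2) for (j in (i + 1):3)
      expect_gt(min(d[sets[[i]], sets[[j]]]), 0.3)
  }
})
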