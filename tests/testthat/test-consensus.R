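test_that("normalizations match their closed forms", {
  expect_equal(normalizeValues(c(2, 4, 6), "minmax"), c(0, 0.5, 1))
  expect_equal(normalizeValues(c(1, 2, 3), "zscore"),
               c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(normalizeValues(c(0.3, 0.1, 0.2), "rank"), c(1, 1 / 3, 2 / 3))
  expect_warning(z <- normalizeValues(c(2, 2, 2), "zscore"), "zero spread")
  expect_equal(z, c(0, 0, 0))
})

test_that("SCC weights clip at zero and fall back to the arithmetic mean", {
  err <- c(1, 2, 3, 4, 5)
  good <- uncertaintyVector("A", c(1, 2, 3, 4, 5), FALSE)       # SCC = 1
  bad <- uncertaintyVector("B", c(5, 4, 3, 2, 1), FALSE)        # SCC = -1
  mixed <- uncertaintyVector("C", c(1, 3, 2, 5, 4), FALSE)
  w <- sccWeights(list(good, bad, mixed), err)
  expect_equal(w@w[1], 1)
  expect_equal(w@w[2], 0)
  expect_equal(w@w[3], spearmanScc(c(1, 3, 2, 5, 4), err))
  expect_identical(w@strategy, "scc_weighted")

  allNeg <- sccWeights(list(bad, bad), err)
  expect_equal(allNeg@w, c(1, 1))
  expect_identical(allNeg@strategy, "unweighted")
})

test_that("weighted averaging is the normalized linear combination", {
  set.seed(4)
  u1 <- uncertaintyVector("A", runif(10), FALSE)
  u2 <- uncertaintyVector("B", runif(10), FALSE)
  w <- new("ConsensusWeights", w0 = 0.25, w = c(2, 0.5),
           methods = c("A", "B"), strategy = "unweighted")
  got <- weightedAverage(list(u1, u2), w, "rank")
  manual <- 0.25 + 2 * normalizeValues(u1@values, "rank") +
    0.5 * normalizeValues(u2@values, "rank")
  expect_equal(uncertaintyValues(got), manual)

  # single input with unit weight reduces to the normalization itself
  single <- weightedAverage(list(u1), unweightedWeights("A"), "rank")
  expect_equal(uncertaintyValues(single), normalizeValues(u1@values, "rank"))

  # zero weight removes a method
  w2 <- new("ConsensusWeights", w0 = 0, w = c(2, 0),
            methods = c("A", "B"), strategy = "unweighted")
  expect_equal(uncertaintyValues(weightedAverage(list(u1, u2), w2, "rank")),
               2 * normalizeValues(u1@values, "rank"))
  expect_error(weightedAverage(list(u1), w2, "rank"), "one weight per")
})

test_that("rank-normalized averaging ignores monotone transforms", {
  set.seed(9)
  u1 <- uncertaintyVector("A", runif(20), FALSE)
  u2 <- uncertaintyVector("B", runif(20), FALSE)
  w <- unweightedWeights(c("A", "B"))
  base <- weightedAverage(list(u1, u2), w, "rank")
  warped <- weightedAverage(
    list(uncertaintyVector("A", exp(3 * u1@values), FALSE),
         uncertaintyVector("B", u2@values^3, FALSE)), w, "rank")
  expect_equal(uncertaintyValues(base), uncertaintyValues(warped))
})

test_that("NLL calibration of a constant input returns the mean squared error", {
  u <- uncertaintyVector("U", rep(1, 3), FALSE)
  fit <- fitNllCalibration(list(u), c(1, -1, 2))
  expect_equal(uncertaintyValues(applyCalibration(fit, list(u))),
               rep(2, 3), tolerance = 1e-6)

  fit2 <- fitNllCalibration(list(uncertaintyVector("U", rep(1, 5), FALSE)),
                            rep(0.7, 5))
  expect_equal(uncertaintyValues(applyCalibration(
    fit2, list(uncertaintyVector("U", rep(1, 5), FALSE))))[1],
    0.49, tolerance = 1e-6)
})

test_that("NLL calibration recovers a planted linear noise model", {
  set.seed(31)
  n <- 5000
  g <- runif(n)
  sigma2 <- 0.1 + 0.5 * g
  e <- rnorm(n, 0, sqrt(sigma2))
  fit <- fitNllCalibration(list(uncertaintyVector("g", g, FALSE)), e)
  expect_lt(abs(fit@weights@w0 - 0.1) / 0.1, 0.10)
  expect_lt(abs(fit@weights@w[1] - 0.5) / 0.5, 0.10)

  # round trip: applying to the fit inputs reproduces the stored optimum
  q <- uncertaintyValues(applyCalibration(fit, list(uncertaintyVector("g", g, FALSE))))
  expect_equal(sum(log(q) + e^2 / q), fit@optimumLoss, tolerance = 1e-6)
})

test_that("the joint fit never loses to the best single-method calibration", {
  set.seed(17)
  n <- 400
  u1 <- runif(n); u2 <- runif(n)
  e <- rnorm(n, 0, sqrt(0.2 + 0.6 * u1))
  joint <- fitNllCalibration(list(uncertaintyVector("A", u1, FALSE),
                                  uncertaintyVector("B", u2, FALSE)), e)
  single <- vapply(list(u1, u2), function(u)
    fitNllCalibration(list(uncertaintyVector("X", u, FALSE)), e)@optimumLoss,
    numeric(1))
  expect_lte(joint@optimumLoss, min(single) + 1e-6)
})

test_that("calibration application enforces the fitted method list", {
  u <- uncertaintyVector("A", runif(10), FALSE)
  fit <- fitNllCalibration(list(u), rnorm(10))
  expect_error(applyCalibration(fit, list(uncertaintyVector("B", runif(10), FALSE))),
               "method list mismatch")
  expect_error(fitNllCalibration(list(u), rnorm(2)), "at least")
})

test_that("calibration models survive a JSON round trip", {
  set.seed(2)
  u <- list(uncertaintyVector("MVE", runif(30), TRUE),
            uncertaintyVector("FDIST", runif(30), FALSE))
  fit <- fitNllCalibration(u, rnorm(30))
  path <- tempfile(fileext = ".json")
  writeCalibrationModel(fit, path)
  back <- readCalibrationModel(path)
  expect_equal(back@weights@w, fit@weights@w)
  expect_equal(back@weights@w0, fit@weights@w0)
  expect_identical(back@weights@methods, fit@weights@methods)
  expect_equal(uncertaintyValues(applyCalibration(back, u)),
               uncertaintyValues(applyCalibration(fit, u)))
})
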