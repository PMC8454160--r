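## Reference regressor: a small fully connected tanh network on fixed-length
## feature vectors, with a mean head and (for the mean-variance loss) a
## log-variance head trained by Gaussian negative log-likelihood.  It fills
## the trainable-model contract -- (mean, aleatoric variance, latent vector)
## per sample -- that any external regressor can also satisfy.

#' Regressor configuration
#'
#' @param hiddenSizes sizes of the tanh hidden layers.
#' @param maxEpochs maximum training epochs.
#' @param patience early-stopping patience in epochs.
#' @param learningRate Adam step size.
#' @param lrWarmup epochs of linear learning-rate warm-up.
#' @param meanOnlyEpochs initial epochs with the variance head frozen
#'   (squared-error training), which keeps heteroskedastic NLL training from
#'   collapsing early; ignored for `lossKind = "mse"`.
#' @param lossKind `"mean_variance"` or `"mse"`.
#' @param seed initialisation seed.
#' @param varianceFloor positive floor on predicted variances
#'   (standardised-label units).
#' @param latentKind `"activation"` or `"preactivation"` penultimate layer.
#' @return A [RegressorConfig-class].
#' @export
regressorConfig <- function(hiddenSizes = 48L, maxEpochs = 400L,
                            patience = min(50L, maxEpochs), learningRate = 0.01,
                            lrWarmup = 10L, meanOnlyEpochs = 50L,
                            lossKind = c("mean_variance", "mse"), seed = 1L,
                            varianceFloor = 1e-6,
                            latentKind = c("activation", "preactivation")) {
  methods::new("RegressorConfig", hiddenSizes = as.integer(hiddenSizes),
               maxEpochs = as.integer(maxEpochs), patience = as.integer(patience),
               learningRate = learningRate, lrWarmup = as.integer(lrWarmup),
               meanOnlyEpochs = as.integer(meanOnlyEpochs),
               lossKind = match.arg(lossKind), seed = as.integer(seed),
               varianceFloor = varianceFloor, latentKind = match.arg(latentKind))
}

#' Gaussian mean-variance (heteroskedastic NLL) loss
#'
#' `mean((y - mu)^2 / (2 v) + log(v) / 2)`, the negative log-likelihood of
#' independent Gaussians up to an additive constant.  For fixed means it is
#' minimised in each variance at the squared residual.
#'
#' @param labels,means aligned numeric vectors.
#' @param variances strictly positive numeric vector.
#' @return The scalar loss.
#' @examples
#' mveLoss(0, 1, 1)  # 0.5
#' @export
mveLoss <- function(labels, means, variances) {
  .assertNumericVector(labels, "labels")
  .assertSameLength(labels, means, "labels", "means")
  .assertSameLength(labels, variances, "labels", "variances")
  if (any(variances <= 0))
    stop("variances must be strictly positive", call. = FALSE)
  mean((labels - means)^2 / (2 * variances) + 0.5 * log(variances))
}

## ---------------------------------------------------------------------------
## network internals
## ---------------------------------------------------------------------------

.mlpInit <- function(d, hidden, seed) {
  withSeed(seed, {
    sizes <- c(d, hidden)
    p <- list()
    for (i in seq_along(hidden)) {
      p[[paste0("W", i)]] <- matrix(
        rnorm(sizes[i] * sizes[i + 1], sd = sqrt(1 / sizes[i])),
        sizes[i], sizes[i + 1])
      p[[paste0("b", i)]] <- numeric(sizes[i + 1])
    }
    h <- sizes[length(sizes)]
    p$wMu <- matrix(rnorm(h, sd = sqrt(1 / h)), h, 1)
    p$bMu <- 0
    p$wS <- matrix(0, h, 1)  # start from unit predicted variance
    p$bS <- 0
    p
  })
}

.mlpForward <- function(p, X, nh) {
  A <- vector("list", nh); Pre <- vector("list", nh)
  Z <- X
  for (i in seq_len(nh)) {
    H <- sweep(Z %*% p[[paste0("W", i)]], 2, p[[paste0("b", i)]], "+")
    Pre[[i]] <- H
    Z <- tanh(H)
    A[[i]] <- Z
  }
  list(A = A, Pre = Pre,
       mu = as.numeric(Z %*% p$wMu) + p$bMu,
       s = as.numeric(Z %*% p$wS) + p$bS)
}

.mlpVariance <- function(s, floor) exp(pmin(pmax(s, -12), 12)) + floor

.mlpLoss <- function(y, fwd, floor, lossKind) {
  r <- y - fwd$mu
  if (lossKind == "mse") return(mean(r^2))
  v <- .mlpVariance(fwd$s, floor)
  mean(r^2 / (2 * v) + 0.5 * log(v))
}

## gradient of the epoch loss wrt all parameters
.mlpGrad <- function(p, X, y, fwd, floor, lossKind, meanOnly) {
  n <- length(y); nh <- length(fwd$A)
  r <- y - fwd$mu
  if (lossKind == "mse") {
    dmu <- matrix(-2 * r / n, ncol = 1)
    ds <- matrix(0, n, 1)
  } else {
    v <- .mlpVariance(fwd$s, floor)
    if (meanOnly) {
      dmu <- matrix(-2 * r / n, ncol = 1)  # squared-error phase
      ds <- matrix(0, n, 1)
    } else {
      dmu <- matrix(-r / v / n, ncol = 1)
      mask <- abs(fwd$s) < 12
      ds <- matrix((0.5 / v - r^2 / (2 * v^2)) * exp(pmin(pmax(fwd$s, -12), 12)) *
                     mask / n, ncol = 1)
    }
  }
  g <- list()
  Zl <- fwd$A[[nh]]
  g$wMu <- crossprod(Zl, dmu); g$bMu <- sum(dmu)
  g$wS <- crossprod(Zl, ds); g$bS <- sum(ds)
  dZ <- dmu %*% t(p$wMu) + ds %*% t(p$wS)
  for (i in nh:1) {
    dPre <- dZ * (1 - fwd$A[[i]]^2)
    inp <- if (i == 1L) X else fwd$A[[i - 1L]]
    g[[paste0("W", i)]] <- crossprod(inp, dPre)
    g[[paste0("b", i)]] <- colSums(dPre)
    if (i > 1L) dZ <- dPre %*% t(p[[paste0("W", i)]])
  }
  g
}

.adamStep <- function(p, g, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  corr1 <- 1 - beta1^state$t; corr2 <- 1 - beta2^state$t
  for (nm in names(g)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g[[nm]]^2
    p[[nm]] <- p[[nm]] - lr * (state$m[[nm]] / corr1) /
      (sqrt(state$v[[nm]] / corr2) + eps)
  }
  list(p = p, state = state)
}

.standardize <- function(m, center, scale) sweep(sweep(m, 2, center), 2, scale, "/")

.asFeatures <- function(x) {
  if (methods::is(x, "MoleculeSet")) featureMatrix(x) else as.matrix(x)
}
.asLabels <- function(x) {
  if (methods::is(x, "MoleculeSet")) activities(x) else stop("labels required")
}

## ---------------------------------------------------------------------------
## training
## ---------------------------------------------------------------------------

#' Train the reference regressor
#'
#' Full-batch Adam with linear learning-rate warm-up and early stopping: the
#' checkpoint with the best validation loss is returned, and training stops
#' once the validation loss has not improved for `patience` epochs.  With the
#' mean-variance loss the first `meanOnlyEpochs` epochs train the mean head
#' on squared error before the variance head is unfrozen (the early-stopping
#' counter starts after that phase).  Fully reproducible from the config
#' seed.
#'
#' @param train,validation non-empty [MoleculeSet-class] objects (disjoint).
#' @param config a [RegressorConfig-class].
#' @return A [TrainedRegressor-class].
#' @export
trainRegressor <- function(train, validation, config = regressorConfig()) {
  X <- .asFeatures(train); y <- .asLabels(train)
  Xv <- .asFeatures(validation); yv <- .asLabels(validation)
  if (nrow(X) == 0L || nrow(Xv) == 0L)
    stop("train and validation sets must be non-empty", call. = FALSE)

  xc <- colMeans(X)
  xs <- apply(X, 2, sd); xs[xs == 0] <- 1
  yc <- mean(y); ys <- sd(y); if (is.na(ys) || ys == 0) ys <- 1
  Xs <- .standardize(X, xc, xs); Xvs <- .standardize(Xv, xc, xs)
  yt <- (y - yc) / ys; yvt <- (yv - yc) / ys

  nh <- length(config@hiddenSizes)
  p <- .mlpInit(ncol(X), config@hiddenSizes, config@seed)
  state <- list(t = 0, m = lapply(p, function(x) x * 0),
                v = lapply(p, function(x) x * 0))
  meanOnlyUntil <- if (config@lossKind == "mean_variance")
    min(config@meanOnlyEpochs, config@maxEpochs) else 0L

  best <- list(loss = Inf, p = p, epoch = 0L)
  wait <- 0L
  for (epoch in seq_len(config@maxEpochs)) {
    meanOnly <- epoch <= meanOnlyUntil
    lr <- config@learningRate * min(1, epoch / max(1L, config@lrWarmup))
    fwd <- .mlpForward(p, Xs, nh)
    loss <- .mlpLoss(yt, fwd, config@varianceFloor,
                     if (meanOnly) "mse" else config@lossKind)
    if (!is.finite(loss))
      stop(sprintf("non-finite training loss at epoch %d; lower the learning rate",
                   epoch), call. = FALSE)
    g <- .mlpGrad(p, Xs, yt, fwd, config@varianceFloor, config@lossKind, meanOnly)
    upd <- .adamStep(p, g, state, lr)
    p <- upd$p; state <- upd$state

    vloss <- .mlpLoss(yvt, .mlpForward(p, Xvs, nh), config@varianceFloor,
                      config@lossKind)
    if (vloss < best$loss) {
      best <- list(loss = vloss, p = p, epoch = epoch)
      wait <- 0L
    } else if (!meanOnly) {
      wait <- wait + 1L
      if (wait >= config@patience) break
    }
  }

  methods::new("TrainedRegressor", params = best$p, config = config,
               xCenter = xc, xScale = xs, yCenter = yc, yScale = ys,
               bestEpoch = best$epoch, epochsTrained = epoch,
               valLoss = best$loss)
}

#' Predict mean, variance and latent vector
#'
#' @param model a [TrainedRegressor-class].
#' @param x a [MoleculeSet-class] or feature matrix with the training
#'   dimensionality.
#' @return A list with `mean` (label scale), `variance` (label-variance
#'   scale; `NULL` for MSE-trained models) and `latent` (n x h matrix of the
#'   penultimate representation).
#' @export
predictRegressor <- function(model, x) {
  X <- .asFeatures(x)
  if (ncol(X) != length(model@xCenter))
    stop(sprintf("feature dimensionality %d does not match the trained model (%d)",
                 ncol(X), length(model@xCenter)), call. = FALSE)
  nh <- length(model@config@hiddenSizes)
  fwd <- .mlpForward(model@params, .standardize(X, model@xCenter, model@xScale), nh)
  latent <- if (model@config@latentKind == "activation") fwd$A[[nh]] else fwd$Pre[[nh]]
  variance <- if (model@config@lossKind == "mean_variance")
    .mlpVariance(fwd$s, model@config@varianceFloor) * model@yScale^2 else NULL
  list(mean = fwd$mu * model@yScale + model@yCenter,
       variance = variance, latent = latent)
}

#' Train a deep ensemble
#'
#' Trains `K` members on identical data with seeds `config@seed + 0 ...
#' config@seed + K - 1` (or an explicit `seeds` vector).
#'
#' @param train,validation as in [trainRegressor()].
#' @param config a [RegressorConfig-class].
#' @param K ensemble size; the framework's standard practice is 10.
#' @param seeds optional explicit member seeds (length `K`).
#' @return An [EnsembleModel-class].
#' @export
trainEnsemble <- function(train, validation, config = regressorConfig(),
                          K = 10L, seeds = NULL) {
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  if (is.null(seeds)) seeds <- config@seed + seq_len(K) - 1L
  if (length(seeds) != K) stop("'seeds' must have length K", call. = FALSE)
  members <- vector("list", K)
  for (k in seq_len(K)) {
    cfg <- config
    cfg@seed <- as.integer(seeds[k])
    members[[k]] <- tryCatch(trainRegressor(train, validation, cfg),
      error = function(e)
        stop(sprintf("ensemble member %d failed: %s", k, conditionMessage(e)),
             call. = FALSE))
  }
  methods::new("EnsembleModel", members = members, K = K)
}

#' Ensemble predictions for a set of samples
#'
#' Runs every member and records per-member means, aleatoric variances and
#' latent vectors; the ensemble mean is the arithmetic mean of the member
#' means.
#'
#' @param model an [EnsembleModel-class].
#' @param samples a [MoleculeSet-class] or feature matrix.
#' @return A [PredictionBundle-class].
#' @export
predictBundle <- function(model, samples) {
  preds <- lapply(model@members, predictRegressor, x = samples)
  means <- do.call(cbind, lapply(preds, `[[`, "mean"))
  lossKind <- model@members[[1]]@config@lossKind
  variances <- if (lossKind == "mean_variance")
    do.call(cbind, lapply(preds, `[[`, "variance")) else NULL
  methods::new("PredictionBundle", memberMeans = means,
               memberVariances = variances,
               memberLatents = lapply(preds, `[[`, "latent"),
               ensembleMean = rowMeans(means), lossKind = lossKind)
}

setMethod("show", "EnsembleModel", function(object) {
  cat(sprintf("EnsembleModel with %d members (%s loss)\n", object@K,
              object@members[[1]]@config@lossKind))
})

setMethod("show", "PredictionBundle", function(object) {
  cat(sprintf("PredictionBundle: %d samples, %d members, %s loss\n",
              nrow(object@memberMeans), ncol(object@memberMeans),
              object@lossKind))
})
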