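## Fivefold cross-validation regimes with controlled domain shift:
## IVIT (random), IVOT (in-domain validation, out-of-domain test) and OVOT
## (both out-of-domain), the latter two built from single-linkage clusters
## of fingerprint distances.  Every plan uses a 60/20/20
## train/validation/test ratio.

.splitPlan <- function(regime, fold, train, validation, test) {
  methods::new("SplitPlan", regime = regime, fold = as.integer(fold),
               train = as.integer(sort(train)),
               validation = as.integer(sort(validation)),
               test = as.integer(sort(test)))
}

#' @describeIn randomFivefold accessors for the three index sets.
#' @param plan a `SplitPlan`.
#' @export
trainIndices <- function(plan) plan@train
#' @rdname randomFivefold
#' @export
validationIndices <- function(plan) plan@validation
#' @rdname randomFivefold
#' @export
testIndices <- function(plan) plan@test

setMethod("show", "SplitPlan", function(object) {
  cat(sprintf("SplitPlan %s fold %d: train %d / validation %d / test %d\n",
              object@regime, object@fold, length(object@train),
              length(object@validation), length(object@test)))
})

## n indices partitioned into k near-equal shuffled folds
.randomFolds <- function(n, k, seed) {
  perm <- withSeed(seed, sample(n))
  split(perm, rep(seq_len(k), length.out = n))
}

#' Random fivefold split (IVIT)
#'
#' Standard random cross-validation: each rotation takes one fold as the
#' test set (20%), the next fold as the validation set (20%) and the
#' remaining three as the training set (60%).
#'
#' @param n dataset size (>= 10).
#' @param seed RNG seed; the same seed reproduces the plans.
#' @return A list of 5 [SplitPlan-class] objects whose test sets partition
#'   the indices.
#' @export
randomFivefold <- function(n, seed = 1L) {
  if (n < 10L) stop("need at least 10 samples for a fivefold split", call. = FALSE)
  folds <- .randomFolds(n, 5L, seed)
  lapply(seq_len(5L), function(i) {
    vi <- i %% 5L + 1L
    .splitPlan("IVIT", i, unlist(folds[-c(i, vi)]), folds[[vi]], folds[[i]])
  })
}

#' Single-linkage clusters at a distance cutoff
#'
#' Cuts a single-linkage dendrogram at `cutoff`, which is equivalent to the
#' connected components of the graph with an edge wherever the pairwise
#' distance is at most `cutoff`; consequently the minimum distance between
#' any two clusters exceeds `cutoff`.  For molecules the intended distance
#' is the Tanimoto distance on binarized ECFP4 fingerprints
#' (see [tanimotoDistanceMatrix()]).
#'
#' @param distances a `dist` object or symmetric zero-diagonal matrix.
#' @param cutoff distance threshold (the framework's standard is 0.3).
#' @return Integer vector of cluster ids, one per sample.
#' @export
singleLinkageClusters <- function(distances, cutoff = 0.3) {
  if (is.matrix(distances)) {
    if (nrow(distances) != ncol(distances) ||
        max(abs(distances - t(distances))) > 1e-12 ||
        any(diag(distances) != 0))
      stop("'distances' must be symmetric with a zero diagonal", call. = FALSE)
    n <- nrow(distances)
    if (n == 1L) return(1L)
    distances <- as.dist(distances)
  } else if (inherits(distances, "dist")) {
    n <- attr(distances, "Size")
    if (n == 1L) return(1L)
  } else {
    stop("'distances' must be a matrix or dist object", call. = FALSE)
  }
  tree <- hclust(distances, method = "single")
  unname(cutree(tree, h = cutoff))
}

#' Unite clusters into k balanced folds
#'
#' Greedy assignment: clusters are taken largest first (ties shuffled by
#' `seed`) and placed into the currently smallest fold, so clusters are
#' never split across folds and fold sizes stay approximately equal.  A
#' warning is raised when one giant cluster forces a fold above twice the
#' target size.
#'
#' @param clusters integer cluster id per sample, e.g. from
#'   [singleLinkageClusters()].
#' @param k number of folds (>= number of clusters is an error).
#' @param seed tie-break seed.
#' @return Integer fold id per sample.
#' @export
assembleFolds <- function(clusters, k = 5L, seed = 1L) {
  ids <- unique(clusters)
  if (length(ids) < k)
    stop(sprintf("need at least %d clusters for %d folds", k, k), call. = FALSE)
  sizes <- as.integer(table(factor(clusters, levels = ids)))
  ord <- withSeed(seed, {
    jitter <- runif(length(ids))       # random tie-break among equal sizes
    order(-sizes, jitter)
  })
  foldSize <- numeric(k)
  foldOf <- integer(length(ids))
  for (ci in ord) {
    target <- which.min(foldSize)
    foldOf[ci] <- target
    foldSize[target] <- foldSize[target] + sizes[ci]
  }
  n <- length(clusters)
  if (max(foldSize) > 2 * n / k)
    warning(sprintf("largest fold has %d of %d samples; clusters are very unbalanced",
                    max(foldSize), n))
  foldOf[match(clusters, ids)]
}

#' Out-of-domain validation and test splits (OVOT)
#'
#' Per rotation, one fold is the test set, the next the validation set and
#' the remaining three the training set, so both held-out sets come from
#' clusters disjoint from training.
#'
#' @param folds integer fold id per sample (5 folds).
#' @return A list of 5 [SplitPlan-class] objects.
#' @export
makeOvot <- function(folds) {
  if (length(unique(folds)) != 5L) stop("exactly 5 folds are required", call. = FALSE)
  idx <- seq_along(folds)
  lapply(seq_len(5L), function(i) {
    vi <- i %% 5L + 1L
    .splitPlan("OVOT", i, idx[!folds %in% c(i, vi)], idx[folds == vi],
               idx[folds == i])
  })
}

#' In-domain validation, out-of-domain test splits (IVOT)
#'
#' Per rotation, one fold is the test set; the remaining four folds are
#' pooled and randomly split 60:20 (of the full dataset) into training and
#' validation, so the validation set shares the training domain while the
#' test set does not.
#'
#' @param folds integer fold id per sample (5 folds).
#' @param seed RNG seed for the pooled random split.
#' @return A list of 5 [SplitPlan-class] objects.
#' @export
makeIvot <- function(folds, seed = 1L) {
  if (length(unique(folds)) != 5L) stop("exactly 5 folds are required", call. = FALSE)
  idx <- seq_along(folds)
  lapply(seq_len(5L), function(i) {
    pool <- idx[folds != i]
    pool <- withSeed(seed + i, sample(pool))
    nVal <- round(length(pool) / 4)      # 20 of the 80 pooled percent
    .splitPlan("IVOT", i, pool[-seq_len(nVal)], pool[seq_len(nVal)],
               idx[folds == i])
  })
}
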