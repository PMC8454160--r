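## Molecule featurization: circular fingerprints, MinHash fingerprints, and
## the distance functions used by the fingerprint-distance estimator, the
## latent-distance estimator and cluster cross-validation.

.MH_PRIME <- 2147483647  # 2^31 - 1; hash arithmetic stays exact in doubles

## Set-bit indices (0-based) of an OpenBabel circular fingerprint.
## radius 2 reproduces the ECFP4 convention (diameter = 2 * radius).
.smilesToBits <- function(smiles, radius = 2L) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE))
    stop("SMILES featurization requires the ChemmineOB package; ",
         "use feature-vector inputs for a chemistry-free run", call. = FALSE)
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles))
    stop("'smiles' must be a single non-empty string", call. = FALSE)
  fp <- tryCatch(
    suppressWarnings(ChemmineOB::fingerprint_OB(
      ChemmineOB::forEachMol("SMILES", smiles, identity),
      paste0("ECFP", 2L * radius))),
    error = function(e) NULL)
  if (!is.numeric(fp) || length(fp) == 0L || sum(fp) == 0)
    stop(sprintf("cannot parse SMILES '%s'", smiles), call. = FALSE)
  which(fp != 0) - 1L
}

#' Circular binary fingerprint of a molecule
#'
#' Computes a circular-substructure (Morgan-type) presence/absence fingerprint
#' with OpenBabel; `radius = 2` reproduces the ECFP4 convention.  The
#' generator's native 4096-bit space is folded to `nBits` by taking indices
#' modulo `nBits`; `nBits = 0` keeps the unfolded sparse indices.
#'
#' @param smiles a single SMILES string.
#' @param radius circular substructure radius (ECFP diameter = 2 * radius).
#' @param nBits folded fingerprint length, or 0 for unfolded.
#' @return A [BinaryFingerprint-class].
#' @examples
#' \dontrun{binaryFingerprint("c1ccccc1O")}
#' @export
binaryFingerprint <- function(smiles, radius = 2L, nBits = 2048L) {
  bits <- .smilesToBits(smiles, radius = as.integer(radius))
  nBits <- as.integer(nBits)
  if (nBits > 0L) bits <- sort(unique(bits %% nBits))
  methods::new("BinaryFingerprint", bits = bits, nBits = nBits)
}

#' Binary fingerprint from a numeric feature vector
#'
#' Thresholds a precomputed feature vector into a presence/absence
#' fingerprint, so the whole framework (fingerprint distances, cluster
#' cross-validation) runs without chemistry.
#'
#' @param x numeric feature vector.
#' @param threshold features strictly above this value count as set bits.
#' @return A [BinaryFingerprint-class] of length `length(x)`.
#' @export
featureFingerprint <- function(x, threshold = 0.5) {
  .assertNumericVector(x, "x")
  methods::new("BinaryFingerprint",
               bits = as.integer(which(x > threshold) - 1L),
               nBits = length(x))
}

#' @describeIn featureFingerprint one fingerprint per row of a matrix.
#' @param m numeric matrix, samples in rows.
#' @export
featureFingerprints <- function(m, threshold = 0.5) {
  m <- as.matrix(m)
  lapply(seq_len(nrow(m)), function(i) featureFingerprint(m[i, ], threshold))
}

## MinHash of a sparse bit set with k universal hash functions
## h_j(x) = (a_j * (x + 1) + b_j) mod p.
.minhashOfBits <- function(bits, nPermutations, seed) {
  if (length(bits) == 0L)
    stop("cannot minhash an empty substructure set", call. = FALSE)
  p <- .MH_PRIME
  ab <- withSeed(seed, list(a = sample(p - 1, nPermutations),
                            b = sample(p, nPermutations) - 1))
  hashes <- Reduce(pmin, lapply(as.numeric(bits),
                                function(x) (ab$a * (x + 1) + ab$b) %% p))
  methods::new("MinHashFingerprint", hashes = hashes,
               nPermutations = as.integer(nPermutations))
}

#' MinHash fingerprint of a molecule
#'
#' MinHash signature over the molecule's circular-substructure shingle set
#' (the unfolded set bits of a radius-3 circular fingerprint, following the
#' MHFP6 idea).  The estimated Jaccard similarity between two signatures is
#' the fraction of matching hash positions, which converges to the exact
#' Jaccard similarity of the shingle sets as `nPermutations` grows.
#'
#' @param smiles a single SMILES string.
#' @param nPermutations signature length (number of hash permutations).
#' @param radius substructure radius of the underlying shingles.
#' @param seed seed of the hash family; must match across compared
#'   fingerprints.
#' @return A [MinHashFingerprint-class].
#' @export
minhashFingerprint <- function(smiles, nPermutations = 2048L, radius = 3L,
                               seed = 42L) {
  bits <- .smilesToBits(smiles, radius = as.integer(radius))
  .minhashOfBits(bits, as.integer(nPermutations), seed)
}

#' @describeIn minhashFingerprint MinHash a [BinaryFingerprint-class]
#'   (typically unfolded), for chemistry-free use.
#' @param fingerprint a `BinaryFingerprint`.
#' @export
minhashOfFingerprint <- function(fingerprint, nPermutations = 2048L,
                                 seed = 42L) {
  stopifnot(methods::is(fingerprint, "BinaryFingerprint"))
  .minhashOfBits(fingerprint@bits, as.integer(nPermutations), seed)
}

#' Tanimoto (Jaccard) distance between two fingerprints
#'
#' For binary fingerprints this is 1 minus the exact Jaccard similarity of
#' the set bits; for MinHash fingerprints it is 1 minus the fraction of
#' matching hash positions (the MinHash estimate of the Jaccard similarity).
#' Fingerprints of different families or parameters cannot be compared.
#'
#' @param a,b fingerprints of the same class and parameters.
#' @return Distance in `[0, 1]`.
#' @examples
#' a <- featureFingerprint(c(0, 1, 1, 1, 0))
#' b <- featureFingerprint(c(0, 0, 1, 1, 1))
#' tanimotoDistance(a, b)  # 1 - 2/4
#' @export
setGeneric("tanimotoDistance", function(a, b) standardGeneric("tanimotoDistance"))

#' @rdname tanimotoDistance
setMethod("tanimotoDistance", signature("BinaryFingerprint", "BinaryFingerprint"),
  function(a, b) {
    if (a@nBits != b@nBits)
      stop("fingerprints have different lengths and cannot be compared")
    ni <- length(intersect(a@bits, b@bits))
    nu <- length(a@bits) + length(b@bits) - ni
    if (nu == 0L) return(0)  # two empty sets are identical
    1 - ni / nu
  })

#' @rdname tanimotoDistance
setMethod("tanimotoDistance", signature("MinHashFingerprint", "MinHashFingerprint"),
  function(a, b) {
    if (a@nPermutations != b@nPermutations)
      stop("MinHash fingerprints have different signature lengths")
    1 - mean(a@hashes == b@hashes)
  })

#' @rdname tanimotoDistance
setMethod("tanimotoDistance", signature("ANY", "ANY"), function(a, b)
  stop("tanimotoDistance requires two fingerprints of the same family"))

#' Cosine distance between two latent vectors
#'
#' @param a,b numeric vectors of equal dimension with nonzero norm.
#' @return 1 minus the cosine similarity, in `[0, 2]`.
#' @export
cosineDistance <- function(a, b) {
  .assertNumericVector(a, "a"); .assertNumericVector(b, "b")
  .assertSameLength(a, b, "a", "b")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop("cosine distance is undefined for a zero vector", call. = FALSE)
  1 - sum(a * b) / (na * nb)
}

#' Distance to the nearest reference
#'
#' Minimum of `metric(query, r)` over all references; the nearest-neighbour
#' count is fixed at one.
#'
#' @param query a fingerprint or numeric vector.
#' @param references non-empty list of objects comparable with `query`.
#' @param metric distance function, e.g. [tanimotoDistance()] or
#'   [cosineDistance()].
#' @return The minimum distance.
#' @export
nearestDistance <- function(query, references, metric = tanimotoDistance) {
  if (!is.list(references) || length(references) == 0L)
    stop("'references' must be a non-empty list", call. = FALSE)
  min(vapply(references, function(r) metric(query, r), numeric(1)))
}

## Dense 0/1 indicator matrix from a list of BinaryFingerprints sharing the
## same bit space; unfolded fingerprints are mapped over the union of their
## observed indices.
.bitMatrix <- function(fps, space = NULL) {
  nBits <- unique(vapply(fps, function(f) f@nBits, integer(1)))
  if (length(nBits) != 1L)
    stop("fingerprints must share the same length", call. = FALSE)
  if (is.null(space))
    space <- if (nBits > 0L) seq_len(nBits) - 1L
             else sort(unique(unlist(lapply(fps, function(f) f@bits))))
  m <- matrix(0, nrow = length(fps), ncol = length(space))
  lookup <- seq_along(space)
  names(lookup) <- as.character(space)
  for (i in seq_along(fps)) {
    hit <- lookup[as.character(fps[[i]]@bits)]
    m[i, hit[!is.na(hit)]] <- 1
  }
  m
}

#' Pairwise Tanimoto distance matrix
#'
#' Exact Jaccard distances between all pairs of binary fingerprints (or rows
#' of thresholded feature matrices), computed by matrix algebra.  Used for
#' single-linkage cluster cross-validation and the fingerprint-distance
#' uncertainty estimator.
#'
#' @param x list of [BinaryFingerprint-class] objects, or a numeric matrix
#'   whose rows are thresholded at `threshold`.
#' @param y optional second set; defaults to `x`.
#' @param threshold threshold used when `x`/`y` are matrices.
#' @return A `length(x)` by `length(y)` matrix of distances.
#' @export
tanimotoDistanceMatrix <- function(x, y = NULL, threshold = 0.5) {
  toMat <- function(obj, space) {
    if (is.matrix(obj) || is.data.frame(obj))
      (as.matrix(obj) > threshold) * 1
    else .bitMatrix(obj, space)
  }
  if (is.list(x) && !is.data.frame(x)) {
    nb <- x[[1]]@nBits
    space <- if (nb > 0L) seq_len(nb) - 1L
             else sort(unique(unlist(lapply(c(x, y), function(f) f@bits))))
    A <- toMat(x, space); B <- if (is.null(y)) A else toMat(y, space)
  } else {
    A <- toMat(x, NULL); B <- if (is.null(y)) A else toMat(y, NULL)
  }
  if (ncol(A) != ncol(B))
    stop("'x' and 'y' must live in the same bit space", call. = FALSE)
  inter <- A %*% t(B)
  uni <- outer(rowSums(A), rowSums(B), "+") - inter
  d <- 1 - inter / uni
  d[uni == 0] <- 0  # pairs of empty fingerprints are identical
  d
}
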