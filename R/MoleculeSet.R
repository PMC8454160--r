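#' Construct a MoleculeSet
#'
#' @param features numeric matrix, molecules in rows and features in columns
#'   (stored transposed in the `"features"` assay).
#' @param activity numeric label per molecule (e.g. pIC50).
#' @param smiles optional character vector of SMILES strings.
#' @param trueMean,trueVar,gValue optional ground-truth columns written by the
#'   synthetic generator: noiseless label, noise variance, and the known
#'   covariate g(x) that drives the variance.
#' @param cluster optional integer cluster id per molecule.
#' @param ids molecule identifiers; defaults to `mol1, mol2, ...`.
#' @return A [MoleculeSet-class].
#' @examples
#' ms <- moleculeSet(matrix(rbinom(60, 1, 0.5), 10), rnorm(10))
#' nMolecules(ms)
#' @export
moleculeSet <- function(features, activity, smiles = NULL, trueMean = NULL,
                        trueVar = NULL, gValue = NULL, cluster = NULL,
                        ids = NULL) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (length(activity) != n)
    stop("'activity' must have one value per row of 'features'")
  if (is.null(ids)) ids <- paste0("mol", seq_len(n))
  cd <- S4Vectors::DataFrame(activity = as.numeric(activity), row.names = ids)
  for (col in c("smiles", "trueMean", "trueVar", "gValue", "cluster")) {
    v <- get(col)
    if (!is.null(v)) {
      if (length(v) != n) stop(sprintf("'%s' must have length %d", col, n))
      cd[[col]] <- v
    }
  }
  fm <- t(features)
  colnames(fm) <- ids
  if (is.null(rownames(fm))) rownames(fm) <- paste0("f", seq_len(nrow(fm)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = fm), colData = cd)
  methods::new("MoleculeSet", se)
}

#' @describeIn moleculeSet molecules x features matrix.
#' @param x a `MoleculeSet`.
#' @export
featureMatrix <- function(x) t(SummarizedExperiment::assay(x, "features"))

#' @describeIn moleculeSet numeric label vector.
#' @export
activities <- function(x) SummarizedExperiment::colData(x)$activity

#' @describeIn moleculeSet number of molecules.
#' @export
nMolecules <- function(x) ncol(x)

#' @describeIn moleculeSet ground-truth noise variance (or NULL).
#' @export
trueVariance <- function(x) SummarizedExperiment::colData(x)$trueVar

#' @describeIn moleculeSet ground-truth noiseless label (or NULL).
#' @export
trueMeans <- function(x) SummarizedExperiment::colData(x)$trueMean

#' @describeIn moleculeSet known variance covariate g(x) (or NULL).
#' @export
gValues <- function(x) SummarizedExperiment::colData(x)$gValue

#' @describeIn moleculeSet cluster id per molecule (or NULL).
#' @export
clusterIds <- function(x) SummarizedExperiment::colData(x)$cluster

#' @describeIn moleculeSet SMILES strings (or NULL).
#' @export
moleculeSmiles <- function(x) SummarizedExperiment::colData(x)$smiles

#' @describeIn moleculeSet concatenate the molecules of several sets sharing
#'   the same features.
#' @param ... `MoleculeSet` objects.
#' @export
combineMolecules <- function(...) {
  parts <- list(...)
  fm <- do.call(cbind, lapply(parts, SummarizedExperiment::assay, "features"))
  cd <- do.call(rbind, lapply(parts, function(p)
    as.data.frame(SummarizedExperiment::colData(p))))
  ids <- make.unique(rownames(cd))
  rownames(cd) <- ids
  colnames(fm) <- ids
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = fm),
    colData = S4Vectors::DataFrame(cd))
  methods::new("MoleculeSet", se)
}

setMethod("show", "MoleculeSet", function(object) {
  cat(sprintf("MoleculeSet with %d molecules, %d features\n",
              ncol(object), nrow(object)))
  cd <- SummarizedExperiment::colData(object)
  extras <- setdiff(colnames(cd), "activity")
  cat(sprintf("  activity range: [%.3g, %.3g]\n",
              min(cd$activity), max(cd$activity)))
  if (length(extras))
    cat("  extra colData:", paste(extras, collapse = ", "), "\n")
})
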