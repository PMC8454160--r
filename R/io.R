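## Dataset reading and small tidy writers.

.canonicalSmiles <- function(smiles) {
  if (requireNamespace("ChemmineOB", quietly = TRUE)) {
    out <- vapply(smiles, function(s) {
      r <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN", source = s),
                    error = function(e) NA_character_)
      if (is.na(r)) return(NA_character_)
      strsplit(trimws(r), "[ \t\n]")[[1]][1]
    }, character(1), USE.NAMES = FALSE)
    bad <- which(is.na(out) | !nzchar(out))
    if (length(bad))
      stop(sprintf("cannot parse SMILES in row(s) %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    out
  } else {
    smiles  # chemistry unavailable: fall back to literal string identity
  }
}

#' Read a molecule dataset from CSV
#'
#' Accepts either a chemistry schema (`id`, `smiles`, `activity`) or a
#' chemistry-free schema (`id`, numeric feature columns, `activity`).  Rows
#' describing the same molecule (identical canonical SMILES, or identical
#' feature vectors) are collapsed into one record whose label is the mean of
#' their activities.  SMILES datasets are featurized into folded binary
#' circular fingerprints.
#'
#' @param path CSV file path.
#' @param radius,nBits fingerprint parameters for SMILES featurization.
#' @return A [MoleculeSet-class].
#' @export
readDataset <- function(path, radius = 2L, nBits = 2048L) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("dataset is empty", call. = FALSE)
  if (!"activity" %in% names(df))
    stop("dataset must contain an 'activity' column", call. = FALSE)
  activity <- suppressWarnings(as.numeric(df$activity))
  if (anyNA(activity))
    stop(sprintf("non-numeric activity in row(s) %s",
                 paste(which(is.na(activity)), collapse = ", ")), call. = FALSE)
  ids <- if ("id" %in% names(df)) as.character(df$id)
         else paste0("mol", seq_len(nrow(df)))

  if ("smiles" %in% names(df)) {
    canon <- .canonicalSmiles(df$smiles)
    key <- canon
  } else {
    featCols <- setdiff(names(df), c("id", "activity"))
    if (length(featCols) == 0L)
      stop("dataset must contain a 'smiles' column or feature columns",
           call. = FALSE)
    feats <- as.matrix(df[, featCols, drop = FALSE])
    if (!is.numeric(feats) || anyNA(feats))
      stop("feature columns must be numeric without NA", call. = FALSE)
    key <- apply(feats, 1, paste, collapse = ",")
  }

  keep <- !duplicated(key)
  label <- as.numeric(tapply(activity, key, mean)[key[keep]])
  ids <- ids[keep]

  if ("smiles" %in% names(df)) {
    smiles <- df$smiles[keep]
    fps <- lapply(smiles, binaryFingerprint, radius = radius, nBits = nBits)
    features <- .bitMatrix(fps)
    colnames(features) <- paste0("bit", seq_len(ncol(features)) - 1L)
    moleculeSet(features, label, smiles = smiles, ids = ids)
  } else {
    moleculeSet(feats[keep, , drop = FALSE], label, ids = ids)
  }
}

#' Tidy per-sample uncertainty table
#'
#' @param uncertaintySets list of [UncertaintyVector-class] objects.
#' @param ids sample identifiers.
#' @return A long data frame with columns `id`, `method`, `value`.
#' @export
uncertaintyTable <- function(uncertaintySets, ids = NULL) {
  n <- length(uncertaintySets[[1]]@values)
  if (is.null(ids)) ids <- seq_len(n)
  do.call(rbind, lapply(uncertaintySets, function(u)
    data.frame(id = ids, method = u@method, value = u@values)))
}

#' Cache binary fingerprints to a columnar text file
#'
#' One row per record: id, fingerprint length, and the set-bit indices
#' joined by spaces.
#'
#' @param fps named list of [BinaryFingerprint-class] objects.
#' @param path file path.
#' @return `readFingerprints` returns the restored named list.
#' @export
writeFingerprints <- function(fps, path) {
  ids <- names(fps)
  if (is.null(ids)) ids <- paste0("mol", seq_along(fps))
  df <- data.frame(
    id = ids,
    nBits = vapply(fps, function(f) f@nBits, integer(1)),
    bits = vapply(fps, function(f) paste(f@bits, collapse = " "), character(1)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFingerprints
#' @export
readFingerprints <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  fps <- lapply(seq_len(nrow(df)), function(i)
    methods::new("BinaryFingerprint",
                 bits = as.integer(strsplit(df$bits[i], " ")[[1]]),
                 nBits = as.integer(df$nBits[i])))
  names(fps) <- df$id
  fps
}
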