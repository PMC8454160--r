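## End-to-end benchmark runner: split -> train ensemble -> individual
## estimators -> consensus -> metrics, per fold and averaged across folds.

#' Pipeline configuration
#'
#' @param regime `"IVIT"`, `"IVOT"` or `"OVOT"`.
#' @param cutoff single-linkage distance cutoff for the cluster-based
#'   regimes.
#' @param K ensemble size.
#' @param methods individual estimators to compute, a subset of
#'   `c("MVE", "ENS", "LDIST", "FDIST")`; ablations drop entries.
#' @param normalization normalization for the weighted-averaging consensus.
#' @param conformalConfidence confidence level of the conformal comparator.
#' @param threshold feature threshold used to binarize feature vectors into
#'   fingerprints.
#' @param seed master seed for splitting and training.
#' @param regressor a [RegressorConfig-class] (its seed is overridden from
#'   `seed`).
#' @return A named list of settings for [runPipeline()].
#' @export
runConfig <- function(regime = c("IVIT", "IVOT", "OVOT"), cutoff = 0.3,
                      K = 10L, methods = c("MVE", "ENS", "LDIST", "FDIST"),
                      normalization = "rank", conformalConfidence = 0.9,
                      threshold = 0.5, seed = 1L,
                      regressor = regressorConfig()) {
  regime <- match.arg(regime)
  bad <- setdiff(methods, c("MVE", "ENS", "LDIST", "FDIST"))
  if (length(bad))
    stop("unknown methods: ", paste(bad, collapse = ", "), call. = FALSE)
  if ("MVE" %in% methods && regressor@lossKind != "mean_variance")
    stop("MVE requires a mean-variance regressor", call. = FALSE)
  list(regime = regime, cutoff = cutoff, K = as.integer(K), methods = methods,
       normalization = normalization,
       conformalConfidence = conformalConfidence, threshold = threshold,
       seed = as.integer(seed), regressor = regressor)
}

.splitPlansFor <- function(dataset, config) {
  n <- nMolecules(dataset)
  if (config$regime == "IVIT") return(randomFivefold(n, config$seed))
  d <- tanimotoDistanceMatrix(featureMatrix(dataset),
                              threshold = config$threshold)
  folds <- assembleFolds(singleLinkageClusters(d, config$cutoff),
                         k = 5L, seed = config$seed)
  if (config$regime == "OVOT") makeOvot(folds) else makeIvot(folds, config$seed)
}

## individual + consensus uncertainty vectors for one fitted fold
.foldUncertainties <- function(dataset, plan, config) {
  cfg <- config$regressor
  cfg@seed <- as.integer(config$seed + 1000L * plan@fold)
  trainSet <- dataset[, plan@train]
  valSet <- dataset[, plan@validation]
  testSet <- dataset[, plan@test]
  ens <- trainEnsemble(trainSet, valSet, cfg, K = config$K)
  bTrain <- predictBundle(ens, trainSet)
  bVal <- predictBundle(ens, valSet)
  bTest <- predictBundle(ens, testSet)

  indiv <- function(bundle, where) {
    out <- list()
    if ("MVE" %in% config$methods) out$MVE <- estimateAleatoric(bundle)
    if ("ENS" %in% config$methods) out$ENS <- estimateEpistemic(bundle)
    if ("LDIST" %in% config$methods) out$LDIST <- estimateLdist(bundle, bTrain)
    if ("FDIST" %in% config$methods)
      out$FDIST <- estimateFdist(
        featureFingerprints(featureMatrix(where), config$threshold),
        featureFingerprints(featureMatrix(trainSet), config$threshold))
    out
  }
  uVal <- indiv(bVal, valSet)
  uTest <- indiv(bTest, testSet)

  valErr <- bVal@ensembleMean - activities(valSet)
  testErr <- bTest@ensembleMean - activities(testSet)

  consensus <- list()
  if (all(c("MVE", "ENS") %in% config$methods))
    consensus$BYS <- estimateBys(uTest$MVE, uTest$ENS)
  wU <- unweightedWeights(names(uTest))
  consensus[[paste0("Unweighted_", c(zscore = "Zscore", minmax = "MinMax",
                                     rank = "Rank")[[config$normalization]])]] <-
    weightedAverage(unname(uTest), wU, config$normalization)
  wS <- sccWeights(unname(uVal), abs(valErr))
  wAvg <- weightedAverage(unname(uTest), wS, config$normalization)
  consensus[[wAvg@method]] <- wAvg
  calib <- fitNllCalibration(unname(uVal), valErr)
  consensus$NLLCAL <- applyCalibration(calib, unname(uTest))

  list(ensemble = ens, bundles = list(train = bTrain, validation = bVal,
                                      test = bTest),
       uncertainties = c(uTest, consensus), valUncertainties = uVal,
       valErrors = valErr, testErrors = testErr, calibration = calib)
}

.foldMetrics <- function(uncertainties, testErr) {
  rows <- lapply(uncertainties, function(u) {
    cc <- confidenceCurve(u@values, abs(testErr))
    data.frame(
      method = u@method,
      SCC = spearmanScc(u@values, abs(testErr)),
      AUC = cc@auc,
      ECE = if (u@varianceScale) ece(u@values, testErr) else NA_real_,
      ENCE = if (u@varianceScale && length(testErr) >= 20L)
        ence(u@values, testErr^2) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full uncertainty-quantification benchmark
#'
#' For each of the five folds of the chosen regime: trains a deep ensemble,
#' computes the requested individual estimators on the validation and test
#' sets, builds the consensus estimates (BYS, unweighted and SCC-weighted
#' averaging, NLL calibration fitted on the validation set), scores every
#' method (SCC, confidence-curve AUC, and ECE/ENCE where the estimate is on
#' the variance scale -- distance methods get NA there), and evaluates the
#' conformal comparator calibrated on the validation set.  A failing fold is
#' skipped with a warning; the summary averages the completed folds.
#'
#' @param dataset a [MoleculeSet-class].
#' @param config from [runConfig()].
#' @param outputDir optional directory for tidy CSV outputs.
#' @return A list with `folds` (per-fold results), `metrics` (per-fold
#'   method x metric table), `summary` (cross-fold means) and `conformal`
#'   (per-fold validity/efficiency).
#' @export
runPipeline <- function(dataset, config = runConfig(), outputDir = NULL) {
  plans <- .splitPlansFor(dataset, config)
  metrics <- list(); conformal <- list(); folds <- list()
  for (plan in plans) {
    res <- tryCatch({
      fold <- .foldUncertainties(dataset, plan, config)
      m <- .foldMetrics(fold$uncertainties, fold$testErrors)
      m$fold <- plan@fold

      qeVal <- estimateEpistemic(fold$bundles$validation)
      alphas <- esdNonconformity(
        activities(dataset[, plan@validation]),
        fold$bundles$validation@ensembleMean, qeVal@values)
      qeTest <- estimateEpistemic(fold$bundles$test)
      ints <- cpIntervals(alphas, fold$bundles$test@ensembleMean,
                          qeTest@values, config$conformalConfidence)
      ve <- validityEfficiency(ints, activities(dataset[, plan@test]))

      list(fold = fold, metrics = m,
           conformal = data.frame(fold = plan@fold, validity = ve$validity,
                                  efficiency = ve$efficiency))
    }, error = function(e) {
      warning(sprintf("fold %d failed: %s", plan@fold, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) next
    folds[[length(folds) + 1L]] <- res$fold
    metrics[[length(metrics) + 1L]] <- res$metrics
    conformal[[length(conformal) + 1L]] <- res$conformal
  }
  if (length(metrics) == 0L) stop("every fold failed", call. = FALSE)
  metrics <- do.call(rbind, metrics)
  conformal <- do.call(rbind, conformal)

  summarise <- function(col) {
    agg <- aggregate(metrics[[col]], by = list(method = metrics$method),
                     FUN = function(x) mean(x))
    names(agg)[2] <- col
    agg
  }
  summary <- Reduce(function(a, b) merge(a, b, by = "method"),
                    lapply(c("SCC", "AUC", "ECE", "ENCE"), summarise))
  summary <- summary[order(match(summary$method, unique(metrics$method))), ]
  rownames(summary) <- NULL

  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    write.csv(metrics, file.path(outputDir, "fold_metrics.csv"),
              row.names = FALSE)
    write.csv(summary, file.path(outputDir, "summary.csv"), row.names = FALSE)
    write.csv(conformal, file.path(outputDir, "conformal.csv"),
              row.names = FALSE)
    writeCalibrationModel(folds[[1]]$calibration,
                          file.path(outputDir, "nll_calibration_fold1.json"))
  }
  list(folds = folds, metrics = metrics, summary = summary,
       conformal = conformal, config = config)
}
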