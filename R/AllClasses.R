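#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats cor optim qnorm rbinom rnorm runif as.dist cutree hclust
#'   optimize predict quantile sd var aggregate
#' @importFrom utils head read.csv tail write.csv
NULL

setClassUnion("matrixOrNULL", members = c("matrix", "NULL"))

## ---------------------------------------------------------------------------
## Fingerprints
## ---------------------------------------------------------------------------

#' Binary circular fingerprint
#'
#' A presence/absence substructure fingerprint stored sparsely as the sorted
#' 0-based indices of its set bits.  `nBits == 0` marks an unfolded (sparse)
#' fingerprint whose indices live in the hashing space of the generator.
#'
#' @slot bits integer vector of sorted, unique, 0-based set-bit indices.
#' @slot nBits fingerprint length; 0 for unfolded/sparse fingerprints.
#' @export
setClass("BinaryFingerprint",
  representation(bits = "integer", nBits = "integer"),
  validity = function(object) {
    if (length(object@nBits) != 1L || object@nBits < 0L)
      return("nBits must be a single nonnegative integer")
    if (is.unsorted(object@bits, strictly = TRUE))
      return("bits must be sorted and unique")
    if (length(object@bits) && any(object@bits < 0L))
      return("bit indices must be >= 0")
    if (object@nBits > 0L && length(object@bits) &&
        max(object@bits) >= object@nBits)
      return("bit indices must lie in [0, nBits)")
    TRUE
  })

#' MinHash fingerprint
#'
#' An ordered vector of minimum hash values over a molecule's substructure
#' shingle set; the estimated Jaccard similarity of two molecules is the
#' fraction of matching hash positions.
#'
#' @slot hashes numeric vector of minimum hash values (one per permutation).
#' @slot nPermutations number of hash permutations; equals `length(hashes)`.
#' @export
setClass("MinHashFingerprint",
  representation(hashes = "numeric", nPermutations = "integer"),
  validity = function(object) {
    if (length(object@nPermutations) != 1L || object@nPermutations < 1L)
      return("nPermutations must be a positive integer")
    if (length(object@hashes) != object@nPermutations)
      return("length(hashes) must equal nPermutations")
    TRUE
  })

## ---------------------------------------------------------------------------
## Dataset container
## ---------------------------------------------------------------------------

#' Molecules with features and a real-valued label
#'
#' `MoleculeSet` extends [SummarizedExperiment::SummarizedExperiment] with one
#' assay, `"features"` (features x molecules), and a required numeric
#' `activity` column in `colData` holding the regression label (e.g. pIC50).
#' Synthetic datasets additionally carry ground-truth columns `trueMean`,
#' `trueVar`, `gValue` and `cluster`; chemistry-backed datasets may carry a
#' `smiles` column.  Molecules are columns, so `x[, idx]` subsets samples.
#'
#' @export
setClass("MoleculeSet", contains = "SummarizedExperiment",
  validity = function(object) {
    if (!"features" %in% SummarizedExperiment::assayNames(object))
      return("MoleculeSet requires an assay named 'features'")
    cd <- SummarizedExperiment::colData(object)
    if (!"activity" %in% colnames(cd))
      return("colData must contain an 'activity' column")
    if (!is.numeric(cd$activity) || anyNA(cd$activity))
      return("'activity' must be numeric without NA")
    TRUE
  })

## ---------------------------------------------------------------------------
## Regressor
## ---------------------------------------------------------------------------

#' Configuration of the reference mean-variance regressor
#'
#' @slot hiddenSizes sizes of the fully connected tanh hidden layers.
#' @slot maxEpochs maximum number of training epochs.
#' @slot patience early-stopping patience: training stops when the validation
#'   loss has not improved for this many epochs (default 50).
#' @slot learningRate Adam step size after warm-up.
#' @slot lrWarmup epochs of linear learning-rate warm-up (a simple monotone
#'   replacement for cyclical schedules; recorded here for reproducibility).
#' @slot meanOnlyEpochs epochs trained on squared error only before the
#'   variance head is unfrozen; stabilises heteroskedastic NLL training.
#' @slot lossKind `"mean_variance"` (Gaussian NLL) or `"mse"`.
#' @slot seed RNG seed for weight initialisation.
#' @slot varianceFloor additive floor keeping predicted variances positive,
#'   in standardised-label variance units.
#' @slot latentKind `"activation"` (post-tanh penultimate layer, default) or
#'   `"preactivation"`.
#' @export
setClass("RegressorConfig",
  representation(hiddenSizes = "integer", maxEpochs = "integer",
                 patience = "integer", learningRate = "numeric",
                 lrWarmup = "integer", meanOnlyEpochs = "integer",
                 lossKind = "character", seed = "integer",
                 varianceFloor = "numeric", latentKind = "character"),
  validity = function(object) {
    if (any(object@hiddenSizes < 1L))
      return("hiddenSizes must be positive")
    if (object@patience > object@maxEpochs)
      return("patience must not exceed maxEpochs")
    if (!object@lossKind %in% c("mean_variance", "mse"))
      return("lossKind must be 'mean_variance' or 'mse'")
    if (!object@latentKind %in% c("activation", "preactivation"))
      return("latentKind must be 'activation' or 'preactivation'")
    if (object@varianceFloor <= 0)
      return("varianceFloor must be positive")
    TRUE
  })

#' A fitted reference regressor
#'
#' Opaque fitted state of the feedforward mean-variance network, plus the
#' input/label standardisation statistics needed at prediction time.
#'
#' @slot params list of weight matrices and bias vectors.
#' @slot config the [RegressorConfig-class] used for training.
#' @slot xCenter,xScale per-feature standardisation statistics.
#' @slot yCenter,yScale label standardisation statistics.
#' @slot bestEpoch epoch whose checkpoint was retained.
#' @slot epochsTrained total epochs run before early stopping.
#' @slot valLoss validation loss of the retained checkpoint.
#' @export
setClass("TrainedRegressor",
  representation(params = "list", config = "RegressorConfig",
                 xCenter = "numeric", xScale = "numeric",
                 yCenter = "numeric", yScale = "numeric",
                 bestEpoch = "integer", epochsTrained = "integer",
                 valLoss = "numeric"))

#' Deep ensemble of reference regressors
#'
#' @slot members list of [TrainedRegressor-class] objects trained on the same
#'   data with seeds `seed + 0 ... seed + K - 1`.
#' @slot K ensemble size.
#' @export
setClass("EnsembleModel",
  representation(members = "list", K = "integer"),
  validity = function(object) {
    if (object@K < 1L) return("K must be >= 1")
    if (length(object@members) != object@K)
      return("length(members) must equal K")
    TRUE
  })

#' Per-sample ensemble predictions
#'
#' @slot memberMeans n x K matrix of member predicted means.
#' @slot memberVariances n x K matrix of member aleatoric variances, or NULL
#'   for MSE-trained ensembles.
#' @slot memberLatents list of K latent matrices (n x latent dimension).
#' @slot ensembleMean arithmetic mean of the member means.
#' @slot lossKind loss the members were trained with.
#' @export
setClass("PredictionBundle",
  representation(memberMeans = "matrix", memberVariances = "matrixOrNULL",
                 memberLatents = "list", ensembleMean = "numeric",
                 lossKind = "character"),
  validity = function(object) {
    n <- nrow(object@memberMeans)
    if (length(object@ensembleMean) != n)
      return("ensembleMean length must match nrow(memberMeans)")
    if (!is.null(object@memberVariances) &&
        !identical(dim(object@memberVariances), dim(object@memberMeans)))
      return("memberVariances must match memberMeans in shape")
    if (length(object@memberLatents) != ncol(object@memberMeans))
      return("one latent matrix per ensemble member is required")
    if (max(abs(object@ensembleMean - rowMeans(object@memberMeans))) > 1e-8)
      return("ensembleMean must be the arithmetic mean of member means")
    TRUE
  })

## ---------------------------------------------------------------------------
## Uncertainty values and consensus
## ---------------------------------------------------------------------------

#' Per-sample uncertainty estimates from one method
#'
#' @slot method method label (MVE, ENS, LDIST, FDIST, BYS, or a consensus).
#' @slot values nonnegative estimates aligned with sample order.
#' @slot varianceScale TRUE when the values live on the variance scale of the
#'   labels (MVE/ENS/BYS/calibrated); FALSE for relative scores (distances,
#'   weighted averages).
#' @export
setClass("UncertaintyVector",
  representation(method = "character", values = "numeric",
                 varianceScale = "logical"),
  validity = function(object) {
    if (anyNA(object@values)) return("uncertainty values must not be NA")
    if (any(object@values < 0)) return("uncertainty values must be >= 0")
    TRUE
  })

#' Linear consensus weights
#'
#' @slot w0 bias added once to the combination.
#' @slot w nonnegative weight per input method.
#' @slot methods names of the input methods, in order.
#' @slot strategy `"unweighted"`, `"scc_weighted"` or `"nll_calibrated"`.
#' @export
setClass("ConsensusWeights",
  representation(w0 = "numeric", w = "numeric", methods = "character",
                 strategy = "character"),
  validity = function(object) {
    if (length(object@w) != length(object@methods))
      return("one weight per method is required")
    if (any(object@w < 0)) return("weights must be nonnegative")
    TRUE
  })

#' Fitted NLL calibration model
#'
#' @slot weights the fitted [ConsensusWeights-class].
#' @slot floor positive floor applied to the combined variance.
#' @slot nValidation validation-set size used for fitting.
#' @slot optimumLoss NLL loss at the fitted optimum.
#' @export
setClass("CalibrationModel",
  representation(weights = "ConsensusWeights", floor = "numeric",
                 nValidation = "integer", optimumLoss = "numeric"))

## ---------------------------------------------------------------------------
## Splitting
## ---------------------------------------------------------------------------

#' Train/validation/test index sets for one fold
#'
#' @slot regime `"IVIT"`, `"IVOT"` or `"OVOT"`.
#' @slot fold fold index within the fivefold rotation.
#' @slot train,validation,test disjoint, exhaustive 1-based index sets.
#' @export
setClass("SplitPlan",
  representation(regime = "character", fold = "integer", train = "integer",
                 validation = "integer", test = "integer"),
  validity = function(object) {
    idx <- c(object@train, object@validation, object@test)
    if (anyDuplicated(idx)) return("train/validation/test must be disjoint")
    TRUE
  })

## ---------------------------------------------------------------------------
## Evaluation curves
## ---------------------------------------------------------------------------

#' Confidence (error-retention) curve
#'
#' @slot percentiles fraction of most-uncertain samples removed at each step.
#' @slot mae mean absolute error of the retained samples.
#' @slot auc trapezoidal area under the curve over the percentile axis;
#'   smaller is better when curves are compared.
#' @export
setClass("ConfidenceCurve",
  representation(percentiles = "numeric", mae = "numeric", auc = "numeric"),
  validity = function(object) {
    if (length(object@percentiles) != length(object@mae))
      return("percentiles and mae must be aligned")
    TRUE
  })

#' Error-based calibration bins
#'
#' Equal-occupancy bins over uncertainty-sorted samples; the
#' (sqrt(mVAR), sqrt(MSE)) pairs are the scatter data of an error-based
#' calibration plot.
#'
#' @slot mVAR mean predicted variance per bin (non-decreasing).
#' @slot MSE mean squared error per bin.
#' @slot count samples per bin (equal except the last, which absorbs the
#'   remainder).
#' @export
setClass("CalibrationBins",
  representation(mVAR = "numeric", MSE = "numeric", count = "integer"),
  validity = function(object) {
    if (length(object@mVAR) != length(object@MSE) ||
        length(object@mVAR) != length(object@count))
      return("mVAR, MSE and count must be aligned")
    if (is.unsorted(object@mVAR)) return("bins must be ordered by mVAR")
    TRUE
  })

#' Reliability (confidence-based calibration) curve
#'
#' @slot level nominal confidence levels i/100, i = 1..100.
#' @slot accuracy empirical coverage of the corresponding Gaussian intervals.
#' @export
setClass("ReliabilityCurve",
  representation(level = "numeric", accuracy = "numeric"),
  validity = function(object) {
    if (length(object@level) != length(object@accuracy))
      return("level and accuracy must be aligned")
    if (any(object@accuracy < 0 | object@accuracy > 1))
      return("accuracy must lie in [0, 1]")
    if (is.unsorted(object@accuracy)) return("accuracy must be non-decreasing")
    TRUE
  })

## ---------------------------------------------------------------------------
## Conformal prediction
## ---------------------------------------------------------------------------

#' Conformal prediction intervals
#'
#' Vectorised container: one interval per test sample at a common confidence
#' level.  Infinite half-widths flag an unattainable calibration quantile.
#'
#' @slot center predicted means.
#' @slot halfWidth interval half-widths (possibly `Inf`).
#' @slot confidence nominal confidence level.
#' @export
setClass("PredictionIntervals",
  representation(center = "numeric", halfWidth = "numeric",
                 confidence = "numeric"),
  validity = function(object) {
    if (length(object@center) != length(object@halfWidth))
      return("center and halfWidth must be aligned")
    if (object@confidence < 0 || object@confidence > 1)
      return("confidence must lie in [0, 1]")
    if (any(object@halfWidth <= 0)) return("halfWidth must be positive")
    TRUE
  })
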