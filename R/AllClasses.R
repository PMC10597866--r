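#' @import methods
NULL

#' Specification of a synthetic dermoscopy-like lesion image
#'
#' Describes the geometry and photometry of a synthetic grayscale image with
#' zero or more dark, radially perturbed lesion blobs on a lighter skin
#' background, plus additive Gaussian noise. Used by [generateLesionImage()]
#' to produce an image together with its exact ground-truth mask.
#'
#' @slot imageHeight,imageWidth image dimensions in pixels.
#' @slot lesionCount number of lesion blobs (may be 0).
#' @slot radiusRange two-element numeric, min/max base radius in pixels.
#' @slot irregularity dimensionless radial perturbation amplitude (>= 0);
#'   0 gives a circular lesion.
#' @slot lesionIntensity,skinIntensity gray levels in \[0, 255\].
#' @slot noiseSd standard deviation of additive Gaussian noise (gray levels).
#' @slot seed integer seed making generation deterministic.
#' @export
setClass("LesionSpec", representation(
  imageHeight = "numeric", imageWidth = "numeric",
  lesionCount = "numeric", radiusRange = "numeric",
  irregularity = "numeric",
  lesionIntensity = "numeric", skinIntensity = "numeric",
  noiseSd = "numeric", seed = "numeric"
))

setValidity("LesionSpec", function(object) {
  msg <- character()
  if (object@imageHeight < 1 || object@imageWidth < 1)
    msg <- c(msg, "image dimensions must be positive")
  if (object@lesionCount < 0) msg <- c(msg, "lesionCount must be >= 0")
  if (length(object@radiusRange) != 2 || any(object@radiusRange <= 0))
    msg <- c(msg, "radiusRange must be two positive values")
  if (diff(object@radiusRange) < 0)
    msg <- c(msg, "radiusRange must be increasing")
  maxr <- max(object@radiusRange) * (1 + object@irregularity)
  if (object@lesionCount > 0 &&
      2 * maxr > min(object@imageHeight, object@imageWidth))
    msg <- c(msg, "lesion radii exceed image bounds")
  if (object@irregularity < 0) msg <- c(msg, "irregularity must be >= 0")
  ints <- c(object@lesionIntensity, object@skinIntensity)
  if (any(ints < 0 | ints > 255)) msg <- c(msg, "intensities must be in [0,255]")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Specification of a synthetic labeled feature table
#'
#' Describes a two-class feature table in which only a designated subset of
#' features carries class information: informative features differ between
#' classes by exactly `separation` in their means, all others are identically
#' distributed across classes.
#'
#' @slot nPerClass samples per class.
#' @slot nFeatures number of feature columns.
#' @slot informative integer indices (1-based) of class-informative features.
#' @slot separation between-class mean difference on informative features.
#' @slot noiseSd per-feature Gaussian noise standard deviation.
#' @slot seed integer seed.
#' @export
setClass("FeatureTableSpec", representation(
  nPerClass = "numeric", nFeatures = "numeric", informative = "numeric",
  separation = "numeric", noiseSd = "numeric", seed = "numeric"
))

setValidity("FeatureTableSpec", function(object) {
  msg <- character()
  if (object@nPerClass < 1) msg <- c(msg, "nPerClass must be >= 1 (no empty classes)")
  if (object@nFeatures < 1) msg <- c(msg, "nFeatures must be >= 1")
  if (length(object@informative) &&
      (max(object@informative) > object@nFeatures || min(object@informative) < 1))
    msg <- c(msg, "informative indices out of range")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Strategy table of the Q-learning segmenter
#'
#' Maps discretized segmentation states to values of (threshold, morphology
#' radius) actions. States are the four-component vectors of binned area,
#' compactness, object count and tile position; actions index a lattice of
#' threshold levels and opening radii. Values live in an environment so
#' in-place update during training is cheap.
#'
#' @slot values environment mapping state key (string) to a numeric vector of
#'   action values.
#' @slot visits environment mapping state key to per-action visit counts.
#' @slot actions data.frame with columns `tIdx` (threshold index) and `nu`
#'   (opening radius) defining the action lattice.
#' @slot mode state-discretization mode, 1 or 2.
#' @export
setClass("QTable", representation(
  values = "environment", visits = "environment",
  actions = "data.frame", mode = "numeric"
))

setValidity("QTable", function(object) {
  if (!object@mode %in% c(1, 2)) return("mode must be 1 or 2")
  if (!all(c("tIdx", "nu") %in% names(object@actions)))
    return("actions must have columns tIdx and nu")
  TRUE
})

#' Trained reinforcement-learning segmenter
#'
#' Frozen result of [trainSegmenter()]: the strategy table, the sub-image
#' dimensions selected by the competing-agent structure, the post-processing
#' disk radius selected by argmin mean dissimilarity, and the smoothing
#' neighborhood radius.
#'
#' @slot qtable a [QTable-class].
#' @slot dims selected sub-image (height, width) in pixels.
#' @slot lambda selected post-processing opening/closing disk radius.
#' @slot filterRadius neighborhood radius of the pre-processing mean filter.
#' @slot config list of training hyperparameters (learning rate, discount,
#'   epsilon schedule, rewards, lattice sizes).
#' @slot trained logical flag.
#' @export
setClass("SegmenterModel", representation(
  qtable = "QTable", dims = "numeric", lambda = "numeric",
  filterRadius = "numeric", config = "list", trained = "logical"
))

#' Population state of the fish migration optimizer
#'
#' @slot positions n x d matrix of fish positions.
#' @slot previous n x d matrix of previous positions.
#' @slot energy per-fish migration energy (>= 0).
#' @slot energyInit initial energy (2 for every fish at birth).
#' @slot stage integer age stage in 0..4.
#' @slot fitness current objective values.
#' @slot pbest personal best objective values.
#' @slot gbPos position of the global best.
#' @slot gbVal value of the global best (non-increasing across iterations).
#' @slot lower,upper box bounds of the search space.
#' @export
setClass("FishPopulation", representation(
  positions = "matrix", previous = "matrix",
  energy = "numeric", energyInit = "numeric", stage = "numeric",
  fitness = "numeric", pbest = "numeric",
  gbPos = "numeric", gbVal = "numeric",
  lower = "numeric", upper = "numeric"
))

setValidity("FishPopulation", function(object) {
  n <- nrow(object@positions)
  msg <- character()
  if (length(object@energy) != n || length(object@stage) != n)
    msg <- c(msg, "per-fish vectors must match population size")
  if (any(object@energy < 0)) msg <- c(msg, "energies must be >= 0")
  if (any(!object@stage %in% 0:4)) msg <- c(msg, "stages must be in 0..4")
  if (any(object@lower >= object@upper)) msg <- c(msg, "lower must be < upper")
  if (length(msg)) msg else TRUE
})

#' Result of a fish-migration optimization run
#'
#' @slot bestPosition best position found.
#' @slot bestValue best objective value found.
#' @slot history best-so-far value after each iteration (non-increasing).
#' @slot evaluations total number of objective evaluations.
#' @export
setClass("EFMOResult", representation(
  bestPosition = "numeric", bestValue = "numeric",
  history = "numeric", evaluations = "numeric"
))

#' Shifted and rotated benchmark objective
#'
#' One of the four validation objectives: high-conditioned elliptic, bent
#' cigar, discus, or Rosenbrock, each composed with a seeded orthogonal
#' rotation `M` and a shift `o`, plus a constant offset so the global minimum
#' equals 100/200/300/400 respectively.
#'
#' @slot id function id in 1..4.
#' @slot name human-readable name.
#' @slot rotation orthogonal d x d matrix.
#' @slot shift location of the global optimum.
#' @slot offset value at the optimum (F*).
#' @slot lower,upper box bounds.
#' @export
setClass("BenchmarkFunction", representation(
  id = "numeric", name = "character", rotation = "matrix",
  shift = "numeric", offset = "numeric",
  lower = "numeric", upper = "numeric"
))

setValidity("BenchmarkFunction", function(object) {
  M <- object@rotation
  if (max(abs(crossprod(M) - diag(ncol(M)))) > 1e-9)
    return("rotation must be orthogonal")
  if (!object@id %in% 1:4) return("id must be in 1..4")
  TRUE
})

#' Radial-basis-function SVM decision model
#'
#' Stores the decision function of a soft-margin RBF SVM in explicit form:
#' support vectors, dual coefficients, bias, kernel width, together with the
#' training standardization statistics and the feature subset it was fit on.
#' Prediction evaluates sign(sum_i coef_i K(z, z_i) - rho) directly, so the
#' model round-trips through JSON.
#'
#' @slot supportVectors matrix of standardized support vectors.
#' @slot coefs dual coefficients (label-signed alphas).
#' @slot rho negative bias of the decision function.
#' @slot gamma RBF kernel width (> 0).
#' @slot cost soft-margin penalty C (> 0).
#' @slot center,scale training means / standard deviations per feature.
#' @slot features names of the features the model uses, in order.
#' @slot positiveLevel numeric label mapped to positive decision values.
#' @slot negativeLevel the other label.
#' @export
setClass("RBFSVMModel", representation(
  supportVectors = "matrix", coefs = "numeric", rho = "numeric",
  gamma = "numeric", cost = "numeric",
  center = "numeric", scale = "numeric", features = "character",
  positiveLevel = "numeric", negativeLevel = "numeric"
))

setValidity("RBFSVMModel", function(object) {
  msg <- character()
  if (object@gamma <= 0) msg <- c(msg, "gamma must be > 0")
  if (object@cost <= 0) msg <- c(msg, "cost must be > 0")
  if (nrow(object@supportVectors) != length(object@coefs))
    msg <- c(msg, "one dual coefficient per support vector required")
  if (length(msg)) msg else TRUE
})

#' Confusion-matrix derived classification metrics
#'
#' @slot tp,fp,tn,fn confusion counts.
#' @slot sensitivity,specificity,accuracy,ppv,npv fractions in \[0, 1\];
#'   `NaN` marks a ratio with zero denominator.
#' @slot auc area under the ROC curve, `NA` when not computed.
#' @export
setClass("ClassMetrics", representation(
  tp = "numeric", fp = "numeric", tn = "numeric", fn = "numeric",
  sensitivity = "numeric", specificity = "numeric", accuracy = "numeric",
  ppv = "numeric", npv = "numeric", auc = "numeric"
))
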