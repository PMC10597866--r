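#' Pipeline configuration
#'
#' Bundles every stage's settings under one global seed. Defaults reproduce
#' the synthetic study conditions: 64 x 64 images, benign lesions nearly
#' circular (irregularity 0.05), malignant lesions highly irregular
#' (irregularity 0.5) and slightly darker, moderate noise.
#'
#' @param seed global seed; every stochastic stage derives its seed from it.
#' @param nTrainPerClass,nTestPerClass images per class.
#' @param imageSize square image side in pixels.
#' @param benign,malignant lists of [lesionSpec()] overrides per class.
#' @param segmenter [segmenterConfig()] overrides (list).
#' @param selection list of [selectFeatures()] overrides.
#' @param tuning list of [tuneGammaThenC()] overrides.
#' @param outDir directory for stage artifacts (`NULL` = in-memory only).
#' @return a named list.
#' @export
pipelineConfig <- function(seed = 1, nTrainPerClass = 20, nTestPerClass = 15,
                           imageSize = 64,
                           benign = list(irregularity = 0.05, lesionIntensity = 80),
                           malignant = list(irregularity = 0.5, lesionIntensity = 50),
                           segmenter = list(), selection = list(),
                           tuning = list(), outDir = NULL) {
  list(seed = seed, nTrainPerClass = nTrainPerClass, nTestPerClass = nTestPerClass,
       imageSize = imageSize, benign = benign, malignant = malignant,
       segmenter = segmenter, selection = selection, tuning = tuning,
       outDir = outDir)
}

# Build the per-class synthetic image sets of a pipeline run. Class label
# +1 = malignant (melanoma), -1 = benign.
.synthCohort <- function(config, nPerClass, seedOffset) {
  pairs <- list(); labels <- numeric(0)
  mk <- function(over, seed) {
    args <- utils::modifyList(
      list(imageHeight = config$imageSize, imageWidth = config$imageSize,
           radiusRange = c(10, 14), noiseSd = 6, seed = seed), over)
    do.call(lesionSpec, args)
  }
  for (i in seq_len(nPerClass)) {
    s <- config$seed * 1000 + seedOffset + i
    pairs[[length(pairs) + 1]] <- generateLesionImage(mk(config$malignant, s))
    labels <- c(labels, 1)
    pairs[[length(pairs) + 1]] <- generateLesionImage(mk(config$benign, s + 500))
    labels <- c(labels, -1)
  }
  list(pairs = pairs, labels = labels)
}

.featuresOf <- function(pairs, masks) {
  rows <- lapply(seq_along(pairs), function(i) {
    m <- masks[[i]]
    if (!any(m != 0)) m <- pairs[[i]]$mask * 0 + 1  # degenerate: whole image
    as.data.frame(t(extractFeatures(pairs[[i]]$image, m)))
  })
  df <- do.call(rbind, rows)
  # a constant-region correlation is a documented sentinel; neutralize it
  # for selection/classification rather than dropping the row
  df$correlation[!is.finite(df$correlation)] <- 0
  df
}

#' Train the full pipeline on synthetic cohorts
#'
#' Generates the training cohort, trains the Q-learning segmenter on the
#' image/mask pairs, extracts the 19 features from the machine
#' segmentations, selects a feature mask by EFMO, tunes the RBF SVM in two
#' stages, and returns a manifest holding every frozen artifact (and, when
#' `config$outDir` is set, writes them as JSON/CSV/PNG files).
#'
#' @param config a [pipelineConfig()] list.
#' @return manifest list with `segmenter`, `featureTable`, `selection`,
#'   `svm`, `trainMetrics`, `config`, and `paths` (when persisted).
#' @export
runTrain <- function(config = pipelineConfig()) {
  cohort <- .synthCohort(config, config$nTrainPerClass, 0)
  if (!length(cohort$pairs)) stop("empty training set")
  segCfg <- do.call(segmenterConfig,
                    utils::modifyList(list(seed = config$seed), config$segmenter))
  segmenter <- trainSegmenter(cohort$pairs, segCfg)
  masks <- lapply(cohort$pairs, function(p) segmentImage(segmenter, p$image))
  tab <- .featuresOf(cohort$pairs, masks)
  tab$label <- cohort$labels
  if (length(unique(tab$label)) < 2) stop("single-class training labels")
  selArgs <- utils::modifyList(list(table = tab, seed = config$seed),
                               config$selection)
  selection <- do.call(selectFeatures, selArgs)
  tuneArgs <- utils::modifyList(
    list(table = tab, mask = selection$mask, seed = config$seed),
    config$tuning)
  tuned <- do.call(tuneGammaThenC, tuneArgs)
  pred <- predict(tuned$model, tab)
  trainMetrics <- suppressWarnings(
    evaluatePredictions(pred, tab$label,
                        scores = decisionValues(tuned$model, tab)))
  manifest <- list(segmenter = segmenter, featureTable = tab,
                   selection = selection, svm = tuned,
                   trainMetrics = trainMetrics, config = config)
  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      segmenter = file.path(config$outDir, "segmenter.json"),
      features = file.path(config$outDir, "train_features.csv"),
      mask = file.path(config$outDir, "feature_mask.json"),
      svm = file.path(config$outDir, "svm.json"))
    writeSegmenterModel(segmenter, paths$segmenter)
    writeFeatureTable(tab, paths$features)
    writeFeatureMask(selection, paths$mask)
    writeSVMModel(tuned$model, paths$svm)
    manifest$paths <- paths
  }
  manifest
}

#' Apply a trained pipeline to a test cohort
#'
#' Segments unseen images with the frozen segmenter, extracts features,
#' classifies with the frozen SVM, and reports the confusion-derived
#' metrics (percent scale) plus the ROC curve.
#'
#' @param config the [pipelineConfig()] the manifest was trained under.
#' @param manifest result of [runTrain()].
#' @param cohort optional list with `pairs` and `labels`; by default a fresh
#'   held-out cohort of `config$nTestPerClass` images per class is
#'   generated from disjoint seeds.
#' @return list with `metrics` (a [ClassMetrics-class]), `metricsRow`
#'   (percent-scale one-row data.frame), `roc`, `predictions`, `scores`.
#' @export
runTest <- function(config, manifest, cohort = NULL) {
  if (is.null(manifest$segmenter) || is.null(manifest$svm))
    stop("manifest is missing trained artifacts")
  if (is.null(cohort))
    cohort <- .synthCohort(config, config$nTestPerClass, 77000)
  if (!length(cohort$pairs)) stop("empty test set")
  masks <- lapply(cohort$pairs, function(p) segmentImage(manifest$segmenter, p$image))
  tab <- .featuresOf(cohort$pairs, masks)
  scores <- decisionValues(manifest$svm$model, tab)
  pred <- ifelse(scores > 0, manifest$svm$model@positiveLevel,
                 manifest$svm$model@negativeLevel)
  metrics <- suppressWarnings(
    evaluatePredictions(pred, cohort$labels, scores = scores))
  list(metrics = metrics, metricsRow = metricsTable(metrics),
       roc = rocCurve(scores, cohort$labels),
       predictions = pred, scores = scores)
}
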