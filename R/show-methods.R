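setMethod("show", "LesionSpec", function(object) {
  cat(sprintf("LesionSpec: %dx%d px, %d lesion(s), r in [%g, %g], irregularity %g\n",
              object@imageHeight, object@imageWidth, object@lesionCount,
              object@radiusRange[1], object@radiusRange[2], object@irregularity))
  cat(sprintf("  intensities lesion/skin %g/%g, noise sd %g, seed %d\n",
              object@lesionIntensity, object@skinIntensity, object@noiseSd,
              as.integer(object@seed)))
})

setMethod("show", "QTable", function(object) {
  cat(sprintf("QTable (mode %d): %d visited states x %d actions\n",
              object@mode, length(ls(object@values)), nrow(object@actions)))
})

setMethod("show", "SegmenterModel", function(object) {
  cat("Q-learning segmenter",
      if (object@trained) "(trained)" else "(untrained)", "\n")
  cat(sprintf("  sub-image dims %d x %d, post-processing radius %g, filter n = %g\n",
              object@dims[1], object@dims[2], object@lambda, object@filterRadius))
  show(object@qtable)
})

setMethod("show", "FishPopulation", function(object) {
  cat(sprintf("FishPopulation: %d fish in %d-D, stages %s, best value %g\n",
              nrow(object@positions), ncol(object@positions),
              paste(tabulate(object@stage + 1, 5), collapse = "/"),
              object@gbVal))
})

setMethod("show", "EFMOResult", function(object) {
  cat(sprintf("EFMO result: best value %g after %d evaluations (%d iterations)\n",
              object@bestValue, object@evaluations, length(object@history)))
})

setMethod("show", "BenchmarkFunction", function(object) {
  cat(sprintf("F%d %s: d = %d, optimum %g at its shift point\n",
              object@id, object@name, ncol(object@rotation), object@offset))
})

setMethod("show", "RBFSVMModel", function(object) {
  cat(sprintf("RBF SVM: %d support vectors over %d features, gamma = %.4g, C = %.4g\n",
              nrow(object@supportVectors), length(object@features),
              object@gamma, object@cost))
})

setMethod("show", "ClassMetrics", function(object) {
  cat("Classification metrics:\n")
  print(round(metricsTable(object), 2), row.names = FALSE)
})

#' @rdname accessors
#' @export
setMethod("qTable", "SegmenterModel", function(object) object@qtable)

#' @rdname accessors
#' @export
setMethod("subimageDims", "SegmenterModel", function(object) object@dims)

#' @rdname accessors
#' @export
setMethod("postprocRadius", "SegmenterModel", function(object) object@lambda)

#' @rdname accessors
#' @export
setMethod("bestPosition", "EFMOResult", function(object) object@bestPosition)

#' @rdname accessors
#' @export
setMethod("bestValue", "EFMOResult", function(object) object@bestValue)

#' @rdname accessors
#' @export
setMethod("convergenceHistory", "EFMOResult", function(object) object@history)
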