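#' Segment an image with a trained model
#'
#' @param model a trained [SegmenterModel-class].
#' @param image numeric intensity matrix in \[0, 255\].
#' @param ... further arguments passed to methods.
#' @return binary \{0,1\} mask matrix with the dimensions of `image`.
#' @export
setGeneric("segmentImage", function(model, image, ...) standardGeneric("segmentImage"))

#' Evaluate a benchmark objective
#'
#' @param fn a [BenchmarkFunction-class].
#' @param x a numeric vector (one point) or an n x d matrix of points.
#' @return numeric vector of objective values.
#' @export
setGeneric("benchmarkValue", function(fn, x) standardGeneric("benchmarkValue"))

#' @rdname accessors
#' @export
setGeneric("qTable", function(object) standardGeneric("qTable"))

#' @rdname accessors
#' @export
setGeneric("subimageDims", function(object) standardGeneric("subimageDims"))

#' @rdname accessors
#' @export
setGeneric("postprocRadius", function(object) standardGeneric("postprocRadius"))

#' @rdname accessors
#' @export
setGeneric("bestPosition", function(object) standardGeneric("bestPosition"))

#' @rdname accessors
#' @export
setGeneric("bestValue", function(object) standardGeneric("bestValue"))

#' @rdname accessors
#' @export
setGeneric("convergenceHistory", function(object) standardGeneric("convergenceHistory"))

#' Accessors for melanoscan objects
#'
#' `qTable`, `subimageDims` and `postprocRadius` read the components of a
#' trained [SegmenterModel-class]; `bestPosition`, `bestValue` and
#' `convergenceHistory` read an [EFMOResult-class]; `metricsTable` flattens a
#' [ClassMetrics-class] to a one-row data.frame.
#'
#' @param object the object to read from.
#' @name accessors
#' @return the respective component.
NULL

#' @rdname accessors
#' @export
setGeneric("metricsTable", function(object) standardGeneric("metricsTable"))
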