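#' Create a lesion image specification
#'
#' Constructor for [LesionSpec-class] with defaults chosen to emulate the
#' conditions the downstream stages are trained under: a 64 x 64 grayscale
#' field of light skin (intensity 200) carrying one dark lesion blob
#' (intensity 60) whose radius is drawn in 10..16 px, with mild boundary
#' irregularity and additive Gaussian noise.
#'
#' @param imageHeight,imageWidth image size in pixels.
#' @param lesionCount number of lesions (0 allowed).
#' @param radiusRange numeric length-2, base radius range in pixels.
#' @param irregularity radial perturbation amplitude; 0 = circle.
#' @param lesionIntensity,skinIntensity gray levels in \[0, 255\].
#' @param noiseSd additive Gaussian noise SD in gray levels.
#' @param seed integer seed.
#' @return a validated [LesionSpec-class].
#' @examples
#' spec <- lesionSpec(seed = 1)
#' im <- generateLesionImage(spec)
#' dim(im$image)
#' @export
lesionSpec <- function(imageHeight = 64, imageWidth = 64, lesionCount = 1,
                       radiusRange = c(10, 16), irregularity = 0.25,
                       lesionIntensity = 60, skinIntensity = 200,
                       noiseSd = 8, seed = 1) {
  new("LesionSpec", imageHeight = imageHeight, imageWidth = imageWidth,
      lesionCount = lesionCount, radiusRange = as.numeric(radiusRange),
      irregularity = irregularity, lesionIntensity = lesionIntensity,
      skinIntensity = skinIntensity, noiseSd = noiseSd, seed = seed)
}

#' Create a feature table specification
#'
#' Constructor for [FeatureTableSpec-class]. Defaults mirror the pipeline's
#' own feature space: 19 features of which 3 are informative, separated by
#' three noise standard deviations between classes.
#'
#' @param nPerClass samples per class.
#' @param nFeatures number of features.
#' @param informative 1-based indices of informative features.
#' @param separation between-class mean difference on informative features,
#'   in feature units.
#' @param noiseSd per-feature Gaussian SD.
#' @param seed integer seed.
#' @return a validated [FeatureTableSpec-class].
#' @export
featureTableSpec <- function(nPerClass = 50, nFeatures = 19,
                             informative = c(1, 2, 3), separation = 3,
                             noiseSd = 1, seed = 1) {
  new("FeatureTableSpec", nPerClass = nPerClass, nFeatures = nFeatures,
      informative = as.numeric(informative), separation = separation,
      noiseSd = noiseSd, seed = seed)
}

# Smooth periodic radial perturbation in [-1, 1]-ish range: a few random
# harmonics with random phases, normalized by the amplitude sum so the
# perturbed radius stays within r0 * (1 +/- irregularity).
.radialPerturbation <- function(theta, nHarmonics = 4) {
  amp <- stats::runif(nHarmonics)
  amp <- amp / sum(amp)
  phase <- stats::runif(nHarmonics, 0, 2 * pi)
  freq <- sample(2:6, nHarmonics, replace = TRUE)
  out <- numeric(length(theta))
  for (h in seq_len(nHarmonics))
    out <- out + amp[h] * sin(freq[h] * theta + phase[h])
  out
}

#' Generate a synthetic lesion image with its ground-truth mask
#'
#' Draws `lesionCount` radially perturbed disks of `lesionIntensity` on a
#' `skinIntensity` background, adds clipped Gaussian noise, and returns both
#' the image and the exact binary lesion mask. A pixel (row r, col c, 0-based
#' centers at integer coordinates) belongs to a lesion when its distance from
#' the lesion center is at most r(theta) = r0 * (1 + irregularity * g(theta))
#' with g a smooth periodic perturbation. Deterministic given `spec@seed`.
#'
#' @param spec a [LesionSpec-class].
#' @return list with `image` (numeric matrix in \[0,255\]) and `mask`
#'   (\{0,1\} matrix of the same dimensions, 1 = lesion).
#' @export
generateLesionImage <- function(spec) {
  stopifnot(is(spec, "LesionSpec"))
  validObject(spec)
  set.seed(as.integer(spec@seed))
  h <- as.integer(spec@imageHeight); w <- as.integer(spec@imageWidth)
  mask <- matrix(0L, h, w)
  rows <- matrix(seq_len(h) - 1L, h, w)
  cols <- matrix(rep(seq_len(w) - 1L, each = h), h, w)
  maxr <- max(spec@radiusRange) * (1 + spec@irregularity)
  for (k in seq_len(spec@lesionCount)) {
    r0 <- stats::runif(1, spec@radiusRange[1], spec@radiusRange[2])
    # keep the whole perturbed disk inside the image
    cy <- stats::runif(1, maxr, max(maxr, h - 1 - maxr))
    cx <- stats::runif(1, maxr, max(maxr, w - 1 - maxr))
    if (spec@lesionCount == 1) { cy <- (h - 1) / 2; cx <- (w - 1) / 2 }
    dy <- rows - cy; dx <- cols - cx
    dist <- sqrt(dy^2 + dx^2)
    theta <- atan2(dy, dx)
    rtheta <- r0 * (1 + spec@irregularity * .radialPerturbation(theta))
    mask[dist <= rtheta] <- 1L
  }
  img <- matrix(spec@skinIntensity, h, w)
  img[mask == 1L] <- spec@lesionIntensity
  if (spec@noiseSd > 0) {
    img <- img + matrix(stats::rnorm(h * w, 0, spec@noiseSd), h, w)
    img <- pmin(pmax(img, 0), 255)
  }
  list(image = img, mask = mask)
}

#' Generate a two-class labeled feature table
#'
#' Class +1 rows have mean `separation` on the informative features and mean
#' 0 elsewhere; class -1 rows have mean 0 everywhere. Every feature receives
#' i.i.d. Gaussian noise of SD `noiseSd`, so only the informative features
#' carry class signal. Deterministic given `spec@seed`.
#'
#' @param spec a [FeatureTableSpec-class].
#' @return data.frame with `nFeatures` numeric columns `f1..fK` and a final
#'   `label` column in \{+1, -1\}.
#' @export
generateFeatureTable <- function(spec) {
  stopifnot(is(spec, "FeatureTableSpec"))
  validObject(spec)
  set.seed(as.integer(spec@seed))
  n <- as.integer(spec@nPerClass); k <- as.integer(spec@nFeatures)
  X <- matrix(stats::rnorm(2 * n * k, 0, spec@noiseSd), 2 * n, k)
  lab <- rep(c(1, -1), each = n)
  for (j in spec@informative) X[lab == 1, j] <- X[lab == 1, j] + spec@separation
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(k))
  df$label <- lab
  df
}

#' Write / read 8-bit grayscale PNG images
#'
#' Images and masks travel as lossless 8-bit grayscale PNG. `writeGrayPNG`
#' rounds to integer gray levels; `readGrayPNG` returns intensities on the
#' 0..255 scale (an RGB file is converted by channel averaging).
#'
#' @param img numeric matrix in \[0, 255\] (for a mask, \{0, 1\} is scaled to
#'   \{0, 255\}).
#' @param path file path.
#' @return `readGrayPNG` returns a numeric matrix in \[0, 255\].
#' @export
writeGrayPNG <- function(img, path) {
  v <- img
  if (all(v %in% c(0, 1))) v <- v * 255
  png::writePNG(round(v) / 255, target = path)
  invisible(path)
}

#' @rdname writeGrayPNG
#' @export
readGrayPNG <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- apply(a[, , 1:min(3, dim(a)[3]), drop = FALSE], c(1, 2), mean)
  round(a * 255)
}

#' Write / read the labeled feature-table CSV format
#'
#' Header row of feature names, optional `id` column, final column `label`.
#'
#' @param table data.frame as produced by [generateFeatureTable()] or
#'   [extractFeatures()] rows bound together.
#' @param path file path.
#' @return `readFeatureTable` returns the data.frame.
#' @export
writeFeatureTable <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}
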