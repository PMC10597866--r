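#' Names and order of the extracted feature vector
#'
#' The 17 geometric/texture/statistical features plus the three Hu invariant
#' moments, in the fixed order every feature row uses.
#'
#' @return character vector of length 19.
#' @export
featureNames <- function() c(
  "rectangularity", "elongation", "area", "form_factor", "solidity",
  "irregularity_index", "perimeter", "eccentricity",
  "contrast", "energy", "homogeneity", "correlation",
  "mean", "entropy", "variance", "std",
  "hu1", "hu2", "hu3")

.largestComponent <- function(mask) {
  lab <- EBImage::bwlabel((mask != 0) * 1)
  n <- max(lab)
  if (n <= 1) return((mask != 0) * 1)
  sizes <- tabulate(lab[lab > 0], nbins = n)
  (lab == which.max(sizes)) * 1
}

# Major/minor axis lengths: extents of the region along the principal
# directions of its pixel scatter (projection range + 1 pixel width), so an
# axis-aligned L x W rectangle reports exactly a = L, b = W.
.axisLengths <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE) - 1
  if (nrow(idx) == 1) return(c(a = 1, b = 1))
  mu <- colMeans(idx)
  d <- sweep(idx, 2, mu)
  cov <- crossprod(d) / nrow(idx)
  vec <- eigen(cov, symmetric = TRUE)$vectors
  proj <- d %*% vec
  ext <- sort(apply(proj, 2, function(z) diff(range(z)) + 1), decreasing = TRUE)
  c(a = ext[1], b = ext[2])
}

# Pixel count inside the convex hull of the foreground pixel centers,
# counted row by row (the hull is convex, so each row meets it in at most
# one interval). Equals the region's own area for convex raster shapes.
.convexPixelArea <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) <= 2) return(nrow(idx))
  hull <- idx[grDevices::chull(idx[, 1], idx[, 2]), , drop = FALSE]
  if (nrow(hull) <= 2) return(sum(mask != 0))
  nh <- nrow(hull)
  total <- 0
  for (r in seq(min(hull[, 1]), max(hull[, 1]))) {
    xs <- numeric(0)
    for (e in seq_len(nh)) {
      p1 <- hull[e, ]; p2 <- hull[e %% nh + 1, ]
      if ((p1[1] - r) * (p2[1] - r) <= 0) {
        if (p1[1] == p2[1]) xs <- c(xs, p1[2], p2[2])
        else xs <- c(xs, p1[2] + (r - p1[1]) / (p2[1] - p1[1]) * (p2[2] - p1[2]))
      }
    }
    if (length(xs)) {
      lo <- ceiling(min(xs) - 1e-9); hi <- floor(max(xs) + 1e-9)
      if (hi >= lo) total <- total + (hi - lo + 1)
    }
  }
  total
}

#' Geometric shape features of a lesion mask
#'
#' Computes, on the largest connected component: area (foreground pixel
#' count), perimeter (border-walk length: the boundary chain through the
#' border-pixel centers, diagonal steps weighted sqrt(2)), rectangularity
#' Area/(a*b), elongation b/a, form factor Area/a^2, solidity
#' Area/ConvexArea, irregularity index 4*pi*Area/Perimeter^2, and
#' eccentricity sqrt(a^2-b^2)/a, with a >= b the axis lengths of the
#' second-moment ellipse. `printedForms = TRUE` switches elongation and
#' eccentricity to the literal printed forms 2*Area/(a*pi) and
#' 2*a*(a^2-b^2), kept for comparability despite their inconsistent units.
#'
#' @param mask \{0,1\} matrix with at least one foreground pixel.
#' @param printedForms use the literal printed elongation/eccentricity.
#' @return named numeric vector of the 8 geometric features.
#' @export
geometricFeatures <- function(mask, printedForms = FALSE) {
  if (!any(mask != 0)) stop("empty mask")
  m <- .largestComponent(mask)
  A <- sum(m)
  P <- .chainPerimeter(m)
  ax <- .axisLengths(m)
  a <- ax[["a"]]; b <- ax[["b"]]
  conv <- .convexPixelArea(m)
  c(rectangularity = A / (a * b),
    elongation = if (printedForms) 2 * A / (a * pi) else b / a,
    area = A,
    form_factor = A / a^2,
    solidity = A / conv,
    irregularity_index = 4 * pi * A / P^2,
    perimeter = P,
    eccentricity = if (printedForms) 2 * a * (a^2 - b^2) else sqrt(max(a^2 - b^2, 0)) / a)
}

#' Gray-level co-occurrence matrix
#'
#' Counts co-occurrences of quantized gray levels between pixel pairs that
#' are both inside the mask and separated by `offset` (rows, cols),
#' symmetrized and normalized to sum 1. Intensities are quantized into
#' `levels` equal-width bins spanning the masked intensity range.
#'
#' @param img numeric intensity matrix.
#' @param mask \{0,1\} matrix; `NULL` uses the whole image.
#' @param levels number of quantized gray levels (>= 2).
#' @param offset integer (row, col) displacement, default (0, 1).
#' @return list with `p` (levels x levels matrix summing to 1), `levels`,
#'   `offset`, and the marginal statistics `muR`, `muC`, `sdR`, `sdC`.
#' @export
buildGLCM <- function(img, mask = NULL, levels = 8, offset = c(0, 1)) {
  stopifnot(levels >= 2)
  if (is.null(mask)) mask <- matrix(1, nrow(img), ncol(img))
  inMask <- mask != 0
  if (sum(inMask) < 2) stop("mask has fewer than 2 eligible pixel pairs")
  vals <- img[inMask]
  lo <- min(vals); hi <- max(vals)
  qimg <- if (hi > lo) pmin(floor((img - lo) / (hi - lo) * levels) + 1, levels)
          else matrix(1, nrow(img), ncol(img))
  dr <- offset[1]; dc <- offset[2]
  nr <- nrow(img); nc <- ncol(img)
  r1 <- max(1, 1 - dr):min(nr, nr - dr)
  c1 <- max(1, 1 - dc):min(nc, nc - dc)
  i1 <- as.matrix(expand.grid(r = r1, c = c1))
  i2 <- cbind(i1[, 1] + dr, i1[, 2] + dc)
  ok <- inMask[i1] & inMask[i2]
  if (sum(ok) < 1) stop("mask has fewer than 2 eligible pixel pairs")
  li <- qimg[i1][ok]; lj <- qimg[i2][ok]
  p <- matrix(0, levels, levels)
  for (k in seq_along(li)) {
    p[li[k], lj[k]] <- p[li[k], lj[k]] + 1
    p[lj[k], li[k]] <- p[lj[k], li[k]] + 1
  }
  p <- p / sum(p)
  i <- seq_len(levels)
  muR <- sum(i * rowSums(p)); muC <- sum(i * colSums(p))
  sdR <- sqrt(sum((i - muR)^2 * rowSums(p)))
  sdC <- sqrt(sum((i - muC)^2 * colSums(p)))
  list(p = p, levels = levels, offset = offset, muR = muR, muC = muC,
       sdR = sdR, sdC = sdC)
}

#' Texture features of a co-occurrence matrix
#'
#' Energy = sum p^2; homogeneity = sum p/(1+|i-j|); contrast =
#' sum (i-j)^2 p; correlation = sum (i-muR)(j-muC) p / (sdR sdC). The
#' correlation of a constant region (zero marginal deviation) is undefined
#' and reported as `NaN` with a warning.
#'
#' @param g a GLCM from [buildGLCM()].
#' @return named numeric vector (contrast, energy, homogeneity, correlation).
#' @export
textureFeatures <- function(g) {
  p <- g$p
  L <- g$levels
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  energy <- sum(p^2)
  homogeneity <- sum(p / (1 + abs(i - j)))
  contrast <- sum((i - j)^2 * p)
  if (g$sdR * g$sdC == 0) {
    warning("GLCM correlation undefined for a constant region")
    correlation <- NaN
  } else {
    correlation <- sum((i - g$muR) * (j - g$muC) * p) / (g$sdR * g$sdC)
  }
  c(contrast = contrast, energy = energy, homogeneity = homogeneity,
    correlation = correlation)
}

#' Statistical features of the masked intensities
#'
#' Mean, population variance, standard deviation, and base-2 entropy of the
#' normalized histogram of masked pixel intensities (256 integer gray bins;
#' 0 log 0 := 0).
#'
#' @param img numeric intensity matrix in \[0, 255\].
#' @param mask \{0,1\} matrix with at least one foreground pixel.
#' @return named numeric vector (mean, entropy, variance, std).
#' @export
statisticalFeatures <- function(img, mask) {
  if (!any(mask != 0)) stop("empty mask")
  v <- img[mask != 0]
  mu <- mean(v)
  va <- mean((v - mu)^2)
  h <- tabulate(pmin(floor(v), 255) + 1, nbins = 256)
  pr <- h[h > 0] / sum(h)
  ent <- -sum(pr * log2(pr))
  c(mean = mu, entropy = ent, variance = va, std = sqrt(va))
}

#' Hu invariant moments of a binary shape
#'
#' The first three Hu combinations of the normalized central moments
#' eta_pq = mu_pq / mu_00^(1+(p+q)/2):
#' phi1 = eta20 + eta02; phi2 = (eta20 - eta02)^2 + 4 eta11^2;
#' phi3 = (eta30 - 3 eta12)^2 + (3 eta21 - eta03)^2. Invariant to
#' translation exactly and to rotation/scale up to rasterization error.
#'
#' @param mask \{0,1\} matrix with at least one foreground pixel.
#' @return named numeric vector (hu1, hu2, hu3).
#' @export
huMoments <- function(mask) {
  if (!any(mask != 0)) stop("empty mask")
  idx <- which(mask != 0, arr.ind = TRUE)
  x <- idx[, 1]; y <- idx[, 2]
  xb <- mean(x); yb <- mean(y)
  m00 <- nrow(idx)
  mu <- function(p, q) sum((x - xb)^p * (y - yb)^q)
  eta <- function(p, q) mu(p, q) / m00^(1 + (p + q) / 2)
  e20 <- eta(2, 0); e02 <- eta(0, 2); e11 <- eta(1, 1)
  e30 <- eta(3, 0); e03 <- eta(0, 3); e12 <- eta(1, 2); e21 <- eta(2, 1)
  c(hu1 = e20 + e02,
    hu2 = (e20 - e02)^2 + 4 * e11^2,
    hu3 = (e30 - 3 * e12)^2 + (3 * e21 - e03)^2)
}

#' Extract the full 19-value feature vector
#'
#' Assembles geometric, texture, statistical and Hu-moment features in the
#' fixed order of [featureNames()]. Texture features are computed on the
#' GLCM of the masked region; an undefined correlation (constant region) is
#' recorded as `NaN`.
#'
#' @param img numeric intensity matrix in \[0, 255\].
#' @param mask \{0,1\} lesion mask of the same dimensions.
#' @param glcmLevels quantized gray levels for the GLCM.
#' @param glcmOffset (row, col) co-occurrence displacement.
#' @param printedForms passed to [geometricFeatures()].
#' @return named numeric vector of length 19.
#' @export
extractFeatures <- function(img, mask, glcmLevels = 8, glcmOffset = c(0, 1),
                            printedForms = FALSE) {
  stopifnot(all(dim(img) == dim(mask)))
  geo <- geometricFeatures(mask, printedForms)
  tex <- suppressWarnings(
    textureFeatures(buildGLCM(img, mask, glcmLevels, glcmOffset)))
  sta <- statisticalFeatures(img, mask)
  hu <- huMoments(mask)
  out <- c(geo, tex, sta, hu)[featureNames()]
  names(out) <- featureNames()
  out
}
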