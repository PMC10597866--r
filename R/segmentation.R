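#' Neighborhood mean filter
#'
#' Pre-processing smoother: each pixel is replaced by the mean of the
#' neighborhood N_n = \{p* : dist(p, p*) < n\} under Euclidean distance
#' between pixel centers (the pixel itself included, distance 0). `n = 0`
#' returns the input unchanged. Borders use replicated edge pixels, and the
#' output is clipped to \[0, 255\].
#'
#' @param img numeric intensity matrix.
#' @param n neighborhood radius in pixels (>= 0); pixels strictly closer
#'   than `n` are averaged.
#' @return smoothed matrix of the same dimensions.
#' @export
smoothImage <- function(img, n = 1.5) {
  stopifnot(is.matrix(img), n >= 0)
  if (n == 0) return(img)
  r <- ceiling(n - 1e-9)
  off <- seq(-r, r)
  kern <- outer(off, off, function(a, b) as.numeric(sqrt(a^2 + b^2) < n))
  if (sum(kern) == 0) return(img)
  # replicate-pad so the kernel never exceeds the (possibly tiny) image
  ri <- pmin(pmax(seq(1 - r, nrow(img) + r), 1), nrow(img))
  ci <- pmin(pmax(seq(1 - r, ncol(img) + r), 1), ncol(img))
  pad <- img[ri, ci, drop = FALSE]
  out <- EBImage::filter2(pad, kern / sum(kern), boundary = "replicate")
  out <- matrix(as.numeric(out), nrow(pad), ncol(pad))
  out <- out[r + seq_len(nrow(img)), r + seq_len(ncol(img)), drop = FALSE]
  pmin(pmax(out, 0), 255)
}

#' Split an image into a grid of sub-images
#'
#' Row-major tiling with tiles of `dims = c(Li, wi)`; the last row/column of
#' tiles is clipped to the image boundary. Offsets are retained so segmented
#' tiles can be stitched back losslessly with [stitchTiles()].
#'
#' @param img numeric matrix.
#' @param dims integer length-2, tile (height, width).
#' @return list with `tiles` (list of matrices), `offsets` (k x 2 matrix of
#'   0-based top-left corners, row-major order), `dims`, and `imageDim`.
#' @export
splitSubimages <- function(img, dims) {
  stopifnot(is.matrix(img), length(dims) == 2)
  Li <- as.integer(dims[1]); wi <- as.integer(dims[2])
  rI <- nrow(img); cI <- ncol(img)
  if (Li < 1 || wi < 1 || Li > rI || wi > cI)
    stop("tile dims must lie in [1, image dims]")
  r0 <- seq(0L, rI - 1L, by = Li)
  c0 <- seq(0L, cI - 1L, by = wi)
  offsets <- cbind(rep(r0, each = length(c0)), rep(c0, times = length(r0)))
  tiles <- lapply(seq_len(nrow(offsets)), function(k) {
    rr <- (offsets[k, 1] + 1):min(offsets[k, 1] + Li, rI)
    cc <- (offsets[k, 2] + 1):min(offsets[k, 2] + wi, cI)
    img[rr, cc, drop = FALSE]
  })
  list(tiles = tiles, offsets = offsets, dims = c(Li, wi), imageDim = c(rI, cI))
}

#' Reassemble tiles produced by [splitSubimages()]
#'
#' @param grid a grid structure from [splitSubimages()] (its `tiles` may have
#'   been replaced by segmented tiles of identical shapes).
#' @return the stitched matrix.
#' @export
stitchTiles <- function(grid) {
  out <- matrix(0, grid$imageDim[1], grid$imageDim[2])
  for (k in seq_along(grid$tiles)) {
    t <- grid$tiles[[k]]
    rr <- (grid$offsets[k, 1] + 1):(grid$offsets[k, 1] + nrow(t))
    cc <- (grid$offsets[k, 2] + 1):(grid$offsets[k, 2] + ncol(t))
    out[rr, cc] <- t
  }
  out
}

#' Dissimilarity between a machine and a manual segmentation
#'
#' Fraction of pixels on which the two binary masks disagree:
#' sum(XOR) / (rows x cols). 0 for identical masks, 1 for complements.
#'
#' @param machine,manual \{0,1\} matrices of equal dimensions.
#' @return dissimilarity in \[0, 1\].
#' @export
dissimilarity <- function(machine, manual) {
  if (!all(dim(machine) == dim(manual)))
    stop("masks must have equal dimensions")
  mean((machine != 0) != (manual != 0))
}

#' Control-agent elimination rule for competing segmentation agents
#'
#' An agent is killed when its dissimilarity strictly increased over three
#' consecutive sub-images; at the end of a pass, additionally the live agent
#' with the maximal current dissimilarity is killed (ties broken by lowest
#' agent id). The last live agent is never killed.
#'
#' @param agents list of agent records, each with `id`, `history` (numeric),
#'   `alive` (logical).
#' @param endOfPass logical; apply the max-dissimilarity kill too.
#' @return the updated agent list.
#' @export
controlAgentFilter <- function(agents, endOfPass = FALSE) {
  if (!length(agents)) stop("empty agent list")
  nAlive <- function() sum(vapply(agents, function(a) a$alive, logical(1)))
  for (i in seq_along(agents)) {
    a <- agents[[i]]
    if (!a$alive || length(a$history) < 3) next
    h <- utils::tail(a$history, 3)
    if (h[3] > h[2] && h[2] > h[1] && nAlive() > 1) agents[[i]]$alive <- FALSE
  }
  if (endOfPass && nAlive() > 1) {
    cur <- vapply(agents, function(a)
      if (a$alive && length(a$history)) utils::tail(a$history, 1) else -Inf, numeric(1))
    agents[[which.max(cur)]]$alive <- FALSE
  }
  agents
}

# Action lattice: nThresh evenly spaced threshold levels between the
# sub-image's gmin and gmax, crossed with opening radii radii (nu).
.actionLattice <- function(nThresh = 8, radii = 0:3) {
  data.frame(tIdx = rep(seq_len(nThresh), times = length(radii)),
             nu = rep(radii, each = nThresh))
}

.thresholdLevel <- function(tile, tIdx, nThresh) {
  gmin <- min(tile); gmax <- max(tile)
  gmin + (tIdx - 1) / (nThresh - 1) * (gmax - gmin)
}

.discBrush <- function(radius) EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")

#' Apply a (threshold, opening-radius) action to a sub-image
#'
#' Pixels with intensity <= tau are labeled lesion (lesions are darker than
#' the surrounding skin), then the mask is cleaned by morphological opening
#' with a disk structuring element of radius `nu` (`nu = 0` skips opening).
#'
#' @param sub numeric intensity matrix (one sub-image).
#' @param tau threshold gray level.
#' @param nu opening disk radius in pixels (integer >= 0).
#' @return \{0,1\} mask matrix.
#' @export
applyAction <- function(sub, tau, nu = 0) {
  mask <- (sub <= tau) * 1
  if (nu > 0 && min(dim(mask)) > 2 * nu) {
    mask <- EBImage::opening(mask, .discBrush(nu))
    mask <- matrix(as.numeric(mask > 0), nrow(sub), ncol(sub))
  }
  mask
}

# Constant tiles make thresholding ill-posed (tau = gmin selects everything).
# A constant tile is called all-lesion iff its value is below the reference
# mid-intensity of the full image; used by the tile segmentation path only.
.segmentTile <- function(tile, tIdx, nu, nThresh, globalMid) {
  if (max(tile) - min(tile) < 1e-12) {
    return(matrix(as.numeric(tile[1] <= globalMid), nrow(tile), ncol(tile)))
  }
  applyAction(tile, .thresholdLevel(tile, tIdx, nThresh), nu)
}

#' Compactness of a binary mask
#'
#' 4 pi A / P^2 with P the border-walk perimeter; 1 for an ideal circle,
#' smaller for irregular contours, defined as 0 for an empty mask.
#'
#' @param mask \{0,1\} matrix.
#' @return compactness value (clamped to \[0, 1\]).
#' @export
maskCompactness <- function(mask) {
  A <- sum(mask != 0)
  if (A == 0) return(0)
  P <- .chainPerimeter(mask)
  min(4 * pi * A / P^2, 1)
}

# perimeter = length of the border walk around each object: the oriented
# boundary chain through border-pixel centers, orthogonal steps of length 1
# and diagonal steps of sqrt(2). Degenerate 1-2 pixel objects fall back to
# the unit-square circumference so compactness stays finite.
.chainPerimeter <- function(mask) {
  lab <- EBImage::bwlabel((mask != 0) * 1)
  total <- 0
  for (oc in EBImage::ocontour(lab)) {
    if (nrow(oc) <= 2) { total <- total + 4; next }
    d <- rbind(diff(oc), oc[1, ] - oc[nrow(oc), ])
    total <- total + sum(sqrt(rowSums(d^2)))
  }
  total
}

.stateBinCounts <- function(mode) {
  if (mode == 1) c(9L, 5L, 4L, 4L) else c(4L, 4L, 3L, 3L)
}

#' Discretize a sub-image segmentation into a state vector
#'
#' The state is \[X1, X2, X3, X4\]: binned foreground area fraction, binned
#' compactness (4 pi A / P^2), connected-component count (capped at the bin
#' count), and the tile's spatial position. Bin counts follow the mode:
#' mode 1 uses (9, 5, 4, 4) bins, mode 2 uses (4, 4, 3, 3). Area and
#' compactness are binned uniformly on \[0, 1\]; position is the quadrant of
#' the tile center when 4 position bins are available, otherwise a linear
#' position score binned into the available count. All indices are 0-based.
#'
#' @param mask \{0,1\} sub-image mask.
#' @param tileOffset 0-based (row, col) of the tile's top-left corner.
#' @param imageDim full-image (rows, cols).
#' @param mode 1 or 2 (state-discretization category).
#' @return integer vector of length 4.
#' @export
computeState <- function(mask, tileOffset = c(0, 0), imageDim = dim(mask), mode = 1) {
  bins <- .stateBinCounts(mode)
  areaFrac <- mean(mask != 0)
  x1 <- min(floor(areaFrac * bins[1]), bins[1] - 1L)
  x2 <- min(floor(maskCompactness(mask) * bins[2]), bins[2] - 1L)
  ncc <- if (any(mask != 0)) max(EBImage::bwlabel(mask)) else 0
  x3 <- min(ncc, bins[3] - 1L)
  cy <- (tileOffset[1] + nrow(mask) / 2) / max(imageDim[1], 1)
  cx <- (tileOffset[2] + ncol(mask) / 2) / max(imageDim[2], 1)
  if (bins[4] == 4L) {
    x4 <- (cy >= 0.5) * 2L + (cx >= 0.5) * 1L
  } else {
    x4 <- min(floor((cy + cx) / 2 * bins[4]), bins[4] - 1L)
  }
  as.integer(c(x1, x2, x3, x4))
}

#' Reward of a segmentation step
#'
#' `R1` when the dissimilarity strictly improved, `R2` otherwise (ties are
#' "otherwise").
#'
#' @param dAfter,dBefore dissimilarities in \[0, 1\].
#' @param R1,R2 reward constants (defaults +1 / -1).
#' @return the reward value.
#' @export
segmentReward <- function(dAfter, dBefore, R1 = 1, R2 = -1) {
  if (dAfter < dBefore) R1 else R2
}

.stateKey <- function(state) paste(state, collapse = ",")

#' Create an empty strategy table
#'
#' @param nThresh number of threshold levels in the action lattice.
#' @param radii vector of opening radii in the lattice.
#' @param mode state-discretization mode (1 or 2).
#' @return a [QTable-class].
#' @export
newQTable <- function(nThresh = 8, radii = 0:3, mode = 1) {
  new("QTable", values = new.env(parent = emptyenv()),
      visits = new.env(parent = emptyenv()),
      actions = .actionLattice(nThresh, radii), mode = mode)
}

.qRow <- function(q, key) {
  if (is.null(q@values[[key]])) rep(0, nrow(q@actions)) else q@values[[key]]
}

#' One-step Q-learning update
#'
#' Q(s,a) <- Q(s,a) + lr * (r + discount * max_a' Q(s',a') - Q(s,a)).
#' All other entries are unchanged. A `NULL` `sNext` marks a terminal
#' transition (the bootstrap term is 0).
#'
#' @param q a [QTable-class] (updated in place; also returned).
#' @param state,sNext state vectors from [computeState()].
#' @param actionIdx row index into the action lattice.
#' @param reward reward value.
#' @param lr learning rate in \[0, 1\].
#' @param discount discount factor in \[0, 1).
#' @return the updated [QTable-class].
#' @export
qUpdate <- function(q, state, actionIdx, reward, sNext = NULL, lr = 0.1, discount = 0.9) {
  key <- .stateKey(state)
  row <- .qRow(q, key)
  boot <- if (is.null(sNext)) 0 else max(.qRow(q, .stateKey(sNext)))
  row[actionIdx] <- row[actionIdx] + lr * (reward + discount * boot - row[actionIdx])
  q@values[[key]] <- row
  vis <- if (is.null(q@visits[[key]])) rep(0L, nrow(q@actions)) else q@visits[[key]]
  vis[actionIdx] <- vis[actionIdx] + 1L
  q@visits[[key]] <- vis
  q
}

.greedyAction <- function(q, state) {
  row <- .qRow(q, .stateKey(state))
  if (all(row == 0)) return(NA_integer_)  # unvisited state
  which.max(row)
}

#' Opening-then-closing post-processing
#'
#' @param mask \{0,1\} matrix.
#' @param lambda disk radius; 0 returns the mask unchanged.
#' @return cleaned \{0,1\} matrix.
#' @export
postprocessMask <- function(mask, lambda) {
  if (lambda <= 0 || min(dim(mask)) <= 2 * lambda) return((mask != 0) * 1)
  b <- .discBrush(lambda)
  out <- EBImage::closing(EBImage::opening((mask != 0) * 1, b), b)
  matrix(as.numeric(out > 0), nrow(mask), ncol(mask))
}
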