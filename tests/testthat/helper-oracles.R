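# Independent brute-force oracles used across the suite. Each is written as
# plain double loops over pixels/pairs, deliberately sharing no code with the
# package implementations it checks.

# rasterized disk by point-in-circle test on 0-based pixel centers
oracleDiskMask <- function(h, w, cy, cx, radius) {
  m <- matrix(0, h, w)
  for (r in 1:h) for (c in 1:w)
    if (sqrt((r - 1 - cy)^2 + (c - 1 - cx)^2) <= radius) m[r, c] <- 1
  m
}

# border-walk perimeter by naive Moore-neighbor boundary tracing: walk the
# outer boundary clockwise through border-pixel centers, orthogonal steps 1
# and diagonal steps sqrt(2); independent of the package's contour code.
# Assumes a single 8-connected object with >= 3 pixels.
oraclePerimeter <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  P <- matrix(0, h + 2, w + 2)
  P[2:(h + 1), 2:(w + 1)] <- (mask != 0) * 1
  fg <- which(P == 1, arr.ind = TRUE)
  start <- fg[order(fg[, 2], fg[, 1]), , drop = FALSE][1, ]  # leftmost, then topmost
  # clockwise Moore neighborhood starting West
  nbr <- matrix(c(0, -1, -1, -1, -1, 0, -1, 1, 0, 1, 1, 1, 1, 0, 1, -1),
                ncol = 2, byrow = TRUE)
  cur <- start; back <- start + c(0, -1)
  path <- list(start)
  for (step in seq_len(8 * sum(P) + 8)) {
    rel <- back - cur
    k0 <- which(nbr[, 1] == rel[1] & nbr[, 2] == rel[2])
    moved <- FALSE
    for (i in 1:8) {
      k <- ((k0 + i - 1) %% 8) + 1
      cand <- cur + nbr[k, ]
      if (P[cand[1], cand[2]] == 1) {
        back <- cur + nbr[((k - 2) %% 8) + 1, ]
        cur <- cand
        moved <- TRUE
        break
      }
    }
    if (!moved) return(4)  # isolated pixel
    if (all(cur == start)) break
    path[[length(path) + 1]] <- cur
  }
  pts <- do.call(rbind, path)
  d <- rbind(diff(pts), pts[1, ] - pts[nrow(pts), ])
  sum(sqrt(rowSums(d^2)))
}

# pixels inside the convex hull of foreground pixel centers, by a
# point-in-convex-polygon cross-product test (boundary counts as inside)
oracleConvexArea <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) <= 2) return(nrow(idx))
  hull <- idx[grDevices::chull(idx[, 1], idx[, 2]), , drop = FALSE]
  if (nrow(hull) <= 2) return(sum(mask != 0))
  # orient counter-clockwise
  n <- nrow(hull)
  area2 <- sum(hull[, 1] * hull[c(2:n, 1), 2] - hull[c(2:n, 1), 1] * hull[, 2])
  if (area2 < 0) hull <- hull[n:1, , drop = FALSE]
  inside <- function(r, c) {
    for (e in seq_len(n)) {
      p1 <- hull[e, ]; p2 <- hull[e %% n + 1, ]
      cr <- (p2[1] - p1[1]) * (c - p1[2]) - (p2[2] - p1[2]) * (r - p1[1])
      if (cr < -1e-9) return(FALSE)
    }
    TRUE
  }
  cnt <- 0
  for (r in min(hull[, 1]):max(hull[, 1]))
    for (c in min(hull[, 2]):max(hull[, 2]))
      if (inside(r, c)) cnt <- cnt + 1
  cnt
}

# morphological opening with a disk: naive erosion then dilation
oracleOpening <- function(mask, radius) {
  h <- nrow(mask); w <- ncol(mask)
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  b <- EBImage::makeBrush(2 * radius + 1, "disc")
  offs <- offs[b[cbind(offs$dr + radius + 1, offs$dc + radius + 1)] > 0, ]
  ero <- matrix(0, h, w)
  for (r in 1:h) for (c in 1:w) {
    ok <- TRUE
    for (k in seq_len(nrow(offs))) {
      rr <- r + offs$dr[k]; cc <- c + offs$dc[k]
      if (rr < 1 || rr > h || cc < 1 || cc > w || mask[rr, cc] == 0) { ok <- FALSE; break }
    }
    if (ok) ero[r, c] <- 1
  }
  dil <- matrix(0, h, w)
  for (r in 1:h) for (c in 1:w) if (ero[r, c] == 1)
    for (k in seq_len(nrow(offs))) {
      rr <- r + offs$dr[k]; cc <- c + offs$dc[k]
      if (rr >= 1 && rr <= h && cc >= 1 && cc <= w) dil[rr, cc] <- 1
    }
  dil
}

# AUC as concordant pairs + half ties over all positive/negative pairs
oracleAUC <- function(scores, truths) {
  sp <- scores[truths == 1]; sn <- scores[truths == -1]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Fisher score by direct summation of the two-class formula
oracleFisher <- function(vp, vn) {
  m <- mean(c(vp, vn))
  num <- (mean(vp) - m)^2 + (mean(vn) - m)^2
  den <- sum((vp - mean(vp))^2) / (length(vp) - 1) +
    sum((vn - mean(vn))^2) / (length(vn) - 1)
  num / den
}

# smooth single-object mask: union of a few overlapping disks (no thin
# spurs, so boundary tracing is unambiguous)
randomSmoothBlob <- function(h = 28, w = 28) {
  m <- matrix(0, h, w)
  cy <- runif(1, h / 3, 2 * h / 3); cx <- runif(1, w / 3, 2 * w / 3)
  for (k in 1:sample(2:3, 1)) {
    dy <- runif(1, -3, 3); dx <- runif(1, -3, 3)
    m <- pmax(m, oracleDiskMask(h, w, cy + dy, cx + dx, runif(1, 4, min(h, w) / 4)))
  }
  m
}

# random blob mask with at least one foreground pixel
randomBlobMask <- function(h = 24, w = 24) {
  m <- oracleDiskMask(h, w, runif(1, h / 3, 2 * h / 3), runif(1, w / 3, 2 * w / 3),
                      runif(1, 3, min(h, w) / 3))
  extra <- matrix(runif(h * w) < 0.05, h, w)
  m[extra] <- 1
  m
}

# small synthetic training pairs for segmenter tests
makeTrainingPairs <- function(n, seedBase = 1, noiseSd = 0, irregularity = 0,
                              size = 48, radiusRange = c(8, 12)) {
  lapply(seq_len(n), function(i) generateLesionImage(lesionSpec(
    imageHeight = size, imageWidth = size, radiusRange = radiusRange,
    irregularity = irregularity, noiseSd = noiseSd, seed = seedBase + i)))
}
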