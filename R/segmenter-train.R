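#' Default training configuration for the Q-learning segmenter
#'
#' The learning rate, discount, epsilon schedule and reward constants are the
#' package defaults for one-step Q-learning (the strategy-table method names
#' the algorithm but not its hyperparameters). The action lattice uses 8
#' threshold levels spanning each sub-image's intensity range and opening
#' radii 0..3; candidate square sub-image sizes are \{16, 32, 64\} and
#' candidate post-processing radii 1..5.
#'
#' @param ... named overrides of any default.
#' @return a named list.
#' @export
segmenterConfig <- function(...) {
  cfg <- list(
    nThresh = 8L, radii = 0:3, mode = 1,
    lr = 0.1, discount = 0.9,
    epsStart = 0.5, epsEnd = 0.05,
    episodes = 50L, stepsPerTile = 4L,
    candidateDims = c(16L, 32L, 64L),
    candidateLambda = 1:5,
    filterRadius = 1.5,
    R1 = 1, R2 = -1,
    seed = 1L
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

.initialActionIdx <- function(cfg) {
  # mid threshold, no opening: the fixed entry point of every tile episode
  which(.actionLattice(cfg$nThresh, cfg$radii)$tIdx == ceiling(cfg$nThresh / 2) &
          .actionLattice(cfg$nThresh, cfg$radii)$nu == cfg$radii[1])[1]
}

# One episode on a single tile. Starts from the fixed initial action, then
# takes `stepsPerTile` epsilon-greedy transitions, learning when learn=TRUE.
# Returns the final tile mask and its dissimilarity (NA without truth).
.tileEpisode <- function(q, tile, truth, offset, imageDim, cfg, eps,
                         globalMid, learn = TRUE) {
  if (max(tile) - min(tile) < 1e-12) {
    m <- .segmentTile(tile, 1, 0, cfg$nThresh, globalMid)
    d <- if (is.null(truth)) NA_real_ else dissimilarity(m, truth)
    return(list(mask = m, d = d, q = q))
  }
  act <- q@actions
  aIdx <- .initialActionIdx(cfg)
  m <- applyAction(tile, .thresholdLevel(tile, act$tIdx[aIdx], cfg$nThresh), act$nu[aIdx])
  d <- if (is.null(truth)) NA_real_ else dissimilarity(m, truth)
  s <- computeState(m, offset, imageDim, q@mode)
  for (step in seq_len(cfg$stepsPerTile)) {
    if (learn && stats::runif(1) < eps) {
      a <- sample.int(nrow(act), 1)
    } else {
      row <- .qRow(q, .stateKey(s))
      # act only while some action is expected to improve: with the +/-1
      # improvement reward, a state value <= 0 means no action reliably
      # lowers the dissimilarity from here, so the current mask is kept
      if (all(row == 0) || max(row) <= 0) {
        if (!learn) break
        a <- sample.int(nrow(act), 1)
      } else a <- which.max(row)
    }
    m2 <- applyAction(tile, .thresholdLevel(tile, act$tIdx[a], cfg$nThresh), act$nu[a])
    s2 <- computeState(m2, offset, imageDim, q@mode)
    if (learn) {
      d2 <- dissimilarity(m2, truth)
      r <- segmentReward(d2, d, cfg$R1, cfg$R2)
      # transitions are scored terminally: bootstrapping the improvement
      # reward lets action cycles inflate the value of mask-ruining actions
      q <- qUpdate(q, s, a, r, NULL, cfg$lr, cfg$discount)
      d <- d2
    } else {
      d <- if (is.null(truth)) NA_real_ else dissimilarity(m2, truth)
    }
    m <- m2; s <- s2
  }
  list(mask = m, d = d, q = q)
}

# Run one learning pass of an agent over every tile of every training pair;
# returns the per-tile dissimilarities in stream order and the updated QTable.
.agentPass <- function(q, pairs, dims, cfg, eps) {
  ds <- numeric(0)
  for (p in pairs) {
    img <- smoothImage(p$image, cfg$filterRadius)
    gmid <- (min(img) + max(img)) / 2
    gi <- splitSubimages(img, dims)
    gm <- splitSubimages(p$mask, dims)
    for (k in seq_along(gi$tiles)) {
      res <- .tileEpisode(q, gi$tiles[[k]], gm$tiles[[k]], gi$offsets[k, ],
                          gi$imageDim, cfg, eps, gmid, learn = TRUE)
      q <- res$q
      ds <- c(ds, res$d)
    }
  }
  list(q = q, ds = ds)
}

#' Select sub-image dimensions by competing agents
#'
#' One Q-learning agent per candidate dimension segments the stream of
#' training sub-images, reporting its dissimilarity after each one to the
#' control agent, which kills agents per the triple-increase and worst-at-
#' pass-end rules. The dims of the last survivor (or, among survivors, the
#' one with the lowest mean dissimilarity on its final pass) are returned.
#'
#' @param trainingPairs list of `list(image=, mask=)` pairs.
#' @param candidateDims list of length-2 numeric dims (a plain numeric vector
#'   is taken as square sizes).
#' @param config a [segmenterConfig()] list.
#' @return list with `dims` (winner) and `agents` (final agent records).
#' @export
selectSubimageDims <- function(trainingPairs, candidateDims, config = segmenterConfig()) {
  if (!length(trainingPairs)) stop("need at least one training pair")
  if (!length(candidateDims)) stop("need at least one candidate")
  if (!is.list(candidateDims)) candidateDims <- lapply(candidateDims, function(s) c(s, s))
  minDim <- min(vapply(trainingPairs, function(p) min(dim(p$image)), numeric(1)))
  candidateDims <- lapply(candidateDims, function(d) pmin(d, minDim))
  agents <- lapply(seq_along(candidateDims), function(i)
    list(id = i, dims = candidateDims[[i]], history = numeric(0),
         alive = TRUE, q = newQTable(config$nThresh, config$radii, config$mode),
         lastMean = NA_real_))
  if (length(agents) == 1)
    return(list(dims = agents[[1]]$dims, agents = agents))
  maxPasses <- length(agents)  # each pass end kills one: guaranteed termination
  for (pass in seq_len(maxPasses)) {
    eps <- config$epsStart + (config$epsEnd - config$epsStart) * (pass - 1) / maxPasses
    for (i in seq_along(agents)) {
      if (!agents[[i]]$alive) next
      res <- .agentPass(agents[[i]]$q, trainingPairs, agents[[i]]$dims, config, eps)
      agents[[i]]$q <- res$q
      agents[[i]]$lastMean <- mean(res$ds)
      # feed the stream to the control agent one sub-image at a time
      for (d in res$ds) {
        agents[[i]]$history <- c(agents[[i]]$history, d)
        agents <- controlAgentFilter(agents, endOfPass = FALSE)
        if (!agents[[i]]$alive) break
      }
    }
    agents <- controlAgentFilter(agents, endOfPass = TRUE)
    if (sum(vapply(agents, function(a) a$alive, logical(1))) == 1) break
  }
  alive <- Filter(function(a) a$alive, agents)
  means <- vapply(alive, function(a) a$lastMean, numeric(1))
  list(dims = alive[[which.min(means)]]$dims, agents = agents)
}

#' Select the post-processing disk radius
#'
#' Applies opening-then-closing with each candidate radius to the greedy
#' segmentations of the training images and returns the radius minimizing
#' mean dissimilarity (argmin; ties broken by the smallest radius).
#'
#' @param trainingPairs list of `list(image=, mask=)` pairs.
#' @param model a [SegmenterModel-class] (its lambda is ignored here).
#' @param candidateRadii numeric vector of disk radii.
#' @return list with `lambda` (the argmin radius) and `meanD` (named vector
#'   of mean dissimilarities per candidate).
#' @export
selectPostprocRadius <- function(trainingPairs, model, candidateRadii = 1:5) {
  if (!length(candidateRadii)) stop("need at least one candidate radius")
  candidateRadii <- sort(candidateRadii)
  raw <- lapply(trainingPairs, function(p) .greedySegment(model, p$image))
  meanD <- vapply(candidateRadii, function(lam) {
    mean(vapply(seq_along(trainingPairs), function(i)
      dissimilarity(postprocessMask(raw[[i]], lam), trainingPairs[[i]]$mask),
      numeric(1)))
  }, numeric(1))
  names(meanD) <- candidateRadii
  list(lambda = candidateRadii[which.min(meanD)], meanD = meanD)
}

# Greedy (no-learning) segmentation without post-processing.
.greedySegment <- function(model, image) {
  cfg <- model@config
  img <- smoothImage(image, model@filterRadius)
  gmid <- (min(img) + max(img)) / 2
  gi <- splitSubimages(img, model@dims)
  out <- gi
  for (k in seq_along(gi$tiles)) {
    res <- .tileEpisode(model@qtable, gi$tiles[[k]], NULL, gi$offsets[k, ],
                        gi$imageDim, cfg, 0, gmid, learn = FALSE)
    out$tiles[[k]] <- res$mask
  }
  stitchTiles(out)
}

#' Train the reinforcement-learning segmenter
#'
#' Runs the three training stages: sub-image dimension selection by competing
#' agents, episodic epsilon-greedy Q-learning of (threshold, opening-radius)
#' actions against the manual masks, and argmin-dissimilarity selection of
#' the post-processing radius. Deterministic given `config$seed`.
#'
#' @param trainingPairs non-empty list of `list(image=, mask=)` pairs.
#' @param config a [segmenterConfig()] list.
#' @return a trained [SegmenterModel-class].
#' @export
trainSegmenter <- function(trainingPairs, config = segmenterConfig()) {
  if (!length(trainingPairs)) stop("empty training set")
  for (p in trainingPairs)
    if (is.null(p$image) || is.null(p$mask) || !all(dim(p$image) == dim(p$mask)))
      stop("every training pair needs an image and a mask of equal dims")
  set.seed(as.integer(config$seed))
  sel <- selectSubimageDims(trainingPairs, config$candidateDims, config)
  q <- newQTable(config$nThresh, config$radii, config$mode)
  for (ep in seq_len(config$episodes)) {
    eps <- config$epsStart +
      (config$epsEnd - config$epsStart) * (ep - 1) / max(config$episodes - 1, 1)
    res <- .agentPass(q, trainingPairs, sel$dims, config, eps)
    q <- res$q
  }
  model <- new("SegmenterModel", qtable = q, dims = as.numeric(sel$dims),
               lambda = 0, filterRadius = config$filterRadius,
               config = config, trained = TRUE)
  post <- selectPostprocRadius(trainingPairs, model, config$candidateLambda)
  model@lambda <- post$lambda
  model
}

#' @describeIn segmentImage smooth, split at the selected dims, apply the
#'   greedy policy per tile, stitch, and clean with opening+closing at the
#'   selected radius.
#' @export
setMethod("segmentImage", signature("SegmenterModel", "matrix"),
  function(model, image, ...) {
    if (!model@trained) stop("model is not trained")
    postprocessMask(.greedySegment(model, image), model@lambda)
  })

#' Mean greedy-policy dissimilarity on a set of image/mask pairs
#'
#' Evaluates the trained policy tile-by-tile (no post-processing), the
#' quantity the control agent and the fixed-action sweep both score.
#'
#' @param model a trained [SegmenterModel-class].
#' @param pairs list of `list(image=, mask=)`.
#' @return mean per-tile dissimilarity.
#' @export
policyDissimilarity <- function(model, pairs) {
  ds <- numeric(0)
  for (p in pairs) {
    img <- smoothImage(p$image, model@filterRadius)
    gmid <- (min(img) + max(img)) / 2
    gi <- splitSubimages(img, model@dims)
    gm <- splitSubimages(p$mask, model@dims)
    for (k in seq_along(gi$tiles)) {
      res <- .tileEpisode(model@qtable, gi$tiles[[k]], gm$tiles[[k]],
                          gi$offsets[k, ], gi$imageDim, model@config, 0,
                          gmid, learn = FALSE)
      ds <- c(ds, res$d)
    }
  }
  mean(ds)
}

#' Mean dissimilarity of every fixed action (exhaustive sweep)
#'
#' Applies each action of the lattice uniformly to every tile of every pair
#' and scores the mean dissimilarity; the independent yardstick the learned
#' policy is compared against.
#'
#' @param model a [SegmenterModel-class] (supplies dims, lattice, filter).
#' @param pairs list of `list(image=, mask=)`.
#' @return numeric vector of mean dissimilarities, one per lattice action.
#' @export
fixedActionSweep <- function(model, pairs) {
  cfg <- model@config
  act <- model@qtable@actions
  vapply(seq_len(nrow(act)), function(a) {
    ds <- numeric(0)
    for (p in pairs) {
      img <- smoothImage(p$image, model@filterRadius)
      gmid <- (min(img) + max(img)) / 2
      gi <- splitSubimages(img, model@dims)
      gm <- splitSubimages(p$mask, model@dims)
      for (k in seq_along(gi$tiles)) {
        m <- .segmentTile(gi$tiles[[k]], act$tIdx[a], act$nu[a], cfg$nThresh, gmid)
        ds <- c(ds, dissimilarity(m, gm$tiles[[k]]))
      }
    }
    mean(ds)
  }, numeric(1))
}

#' Persist / restore a trained segmenter as JSON
#'
#' The strategy table is written as a state-key to action-value mapping
#' alongside the action lattice, the selected dims and radius, and the
#' training configuration.
#'
#' @param model a [SegmenterModel-class].
#' @param path file path.
#' @return `readSegmenterModel` returns the restored model.
#' @export
writeSegmenterModel <- function(model, path) {
  keys <- ls(model@qtable@values)
  obj <- list(
    dims = model@dims, lambda = model@lambda,
    filterRadius = model@filterRadius, mode = model@qtable@mode,
    actions = model@qtable@actions,
    config = model@config[setdiff(names(model@config), character(0))],
    qvalues = stats::setNames(lapply(keys, function(k) model@qtable@values[[k]]), keys)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSegmenterModel
#' @export
readSegmenterModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- obj$config
  cfg$radii <- as.numeric(cfg$radii)
  cfg$candidateDims <- as.numeric(cfg$candidateDims)
  cfg$candidateLambda <- as.numeric(cfg$candidateLambda)
  q <- newQTable(cfg$nThresh, cfg$radii, obj$mode)
  for (k in names(obj$qvalues)) q@values[[k]] <- as.numeric(obj$qvalues[[k]])
  new("SegmenterModel", qtable = q, dims = as.numeric(obj$dims),
      lambda = as.numeric(obj$lambda), filterRadius = as.numeric(obj$filterRadius),
      config = cfg, trained = TRUE)
}
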