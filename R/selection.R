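#' Fisher score of one feature
#'
#' Two-class form: ((m+ - m)^2 + (m- - m)^2) / (s+^2 + s-^2), with m the
#' grand mean, m+/m- the class means and s^2 the within-class sample
#' variances. A feature with zero within-class variance but distinct class
#' means separates trivially and is reported as `Inf` with a warning.
#'
#' @param values numeric feature values.
#' @param labels class labels in \{+1, -1\} (or any two levels).
#' @return the score (>= 0).
#' @export
fisherScore <- function(values, labels) {
  lev <- sort(unique(labels), decreasing = TRUE)
  if (length(lev) != 2) stop("exactly two classes required")
  vp <- values[labels == lev[1]]; vn <- values[labels == lev[2]]
  if (length(vp) < 2 || length(vn) < 2) stop("need >= 2 samples per class")
  m <- mean(values)
  num <- (mean(vp) - m)^2 + (mean(vn) - m)^2
  den <- stats::var(vp) + stats::var(vn)
  if (den == 0) {
    if (num == 0) return(0)
    warning("zero within-class variance: feature separates trivially")
    return(Inf)
  }
  num / den
}

#' Multiclass Fisher score
#'
#' sum_i (m_ji - m_j)^2 / sum_i s_ji^2 over the l classes, the multiclass
#' generalization of [fisherScore()].
#'
#' @param values numeric feature values.
#' @param labels class labels (any number of levels, >= 2 samples each).
#' @return the score (>= 0).
#' @export
fisherScoreMulti <- function(values, labels) {
  lev <- unique(labels)
  m <- mean(values)
  num <- 0; den <- 0
  for (l in lev) {
    v <- values[labels == l]
    if (length(v) < 2) stop("need >= 2 samples per class")
    num <- num + (mean(v) - m)^2
    den <- den + stats::var(v)
  }
  if (den == 0) return(if (num == 0) 0 else Inf)
  num / den
}

.splitFolds <- function(labels, k) {
  # stratified fold assignment; deterministic given the RNG state
  fold <- integer(length(labels))
  for (l in unique(labels)) {
    idx <- sample(which(labels == l))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated accuracy of a feature mask
#'
#' Fits the inner classifier (a fixed-parameter RBF SVM) on the masked
#' features in stratified k-fold cross-validation and returns the fraction
#' of correctly classified held-out samples. Deterministic given `seed`.
#'
#' @param table data.frame with feature columns and a `label` column.
#' @param mask logical/0-1 vector over the feature columns; must select at
#'   least one feature.
#' @param folds number of CV folds.
#' @param seed integer seed for the fold split.
#' @param gamma,cost inner SVM parameters.
#' @return accuracy in \[0, 1\].
#' @export
maskAccuracy <- function(table, mask, folds = 5, seed = 1,
                         gamma = NULL, cost = 1) {
  feats <- setdiff(names(table), c("label", "id"))
  mask <- as.logical(mask)
  if (!any(mask)) stop("empty feature mask")
  X <- as.matrix(table[, feats[mask], drop = FALSE])
  y <- factor(table$label)
  # seed the fold split without disturbing the caller's RNG stream (the
  # mask search calls this from inside its own seeded optimization)
  oldSeed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv()))
  set.seed(as.integer(seed))
  fold <- .splitFolds(table$label, min(folds, min(table(y))))
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  correct <- 0
  for (f in sort(unique(fold))) {
    tr <- fold != f; te <- !tr
    if (length(unique(y[tr])) < 2) next
    # standardize by training-fold statistics, matching trainSVM's scaling
    ctr <- colMeans(X[tr, , drop = FALSE])
    scl <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    scl[scl == 0] <- 1
    fit <- e1071::svm(scale(X[tr, , drop = FALSE], ctr, scl), y[tr],
                      kernel = "radial", gamma = gamma, cost = cost,
                      scale = FALSE)
    pred <- stats::predict(fit, scale(X[te, , drop = FALSE], ctr, scl))
    correct <- correct + sum(pred == y[te])
  }
  correct / nrow(X)
}

#' Combined selection cost of a feature mask
#'
#' cost = alpha * accuracy + beta * (sum of Fisher scores over selected
#' features / sum over all features), with alpha = 0.65, beta = 0.35 by
#' default (alpha + beta = 1). Larger is better; the selector maximizes
#' this value. Infinite Fisher scores (trivially separating features) are
#' excluded from both sums.
#'
#' @param table data.frame with feature columns and `label`.
#' @param mask 0-1/logical vector over features.
#' @param alpha,beta nonnegative weights summing to 1.
#' @param scores optional precomputed Fisher scores (one per feature).
#' @param ... passed to [maskAccuracy()].
#' @return the cost value.
#' @export
selectionCost <- function(table, mask, alpha = 0.65, beta = 0.35,
                          scores = NULL, ...) {
  stopifnot(abs(alpha + beta - 1) < 1e-9, alpha >= 0, beta >= 0)
  feats <- setdiff(names(table), c("label", "id"))
  if (is.null(scores))
    scores <- vapply(feats, function(f)
      suppressWarnings(fisherScore(table[[f]], table$label)), numeric(1))
  sc <- scores
  sc[!is.finite(sc)] <- 0
  ratio <- if (sum(sc) > 0) sum(sc[as.logical(mask)]) / sum(sc) else 0
  alpha * maskAccuracy(table, mask, ...) + beta * ratio
}

#' Select features by EFMO over the combined cost
#'
#' Runs the enhanced fish migration optimizer over continuous vectors in
#' \[0, 1\]^Nb, thresholded at 0.5 into binary masks; a candidate decoding
#' to the empty mask is repaired by activating the top-Fisher feature.
#' Mask accuracies are cached, so repeated visits to the same mask cost one
#' CV evaluation. Deterministic given `seed`.
#'
#' @param table data.frame with feature columns and two-class `label`.
#' @param alpha,beta cost weights (defaults 0.65 / 0.35).
#' @param folds CV folds of the inner classifier.
#' @param n,maxIter EFMO population and iterations for the mask search.
#' @param seed integer seed.
#' @return list with `mask` (named logical vector), `cost` (best value),
#'   `scores` (per-feature Fisher scores) and `result` (the
#'   [EFMOResult-class] of the search).
#' @export
selectFeatures <- function(table, alpha = 0.65, beta = 0.35, folds = 5,
                           n = 20, maxIter = 30, seed = 1) {
  feats <- setdiff(names(table), c("label", "id"))
  if (length(feats) < 2) stop("need at least two features")
  if (length(unique(table$label)) < 2) stop("need two classes")
  scores <- vapply(feats, function(f)
    suppressWarnings(fisherScore(table[[f]], table$label)), numeric(1))
  topFisher <- which.max(ifelse(is.finite(scores), scores, max(scores[is.finite(scores)], 0) + 1))
  cache <- new.env(parent = emptyenv())
  decode <- function(z) {
    m <- z >= 0.5
    if (!any(m)) m[topFisher] <- TRUE
    m
  }
  objective <- function(z) {
    m <- decode(z)
    key <- paste(as.integer(m), collapse = "")
    if (is.null(cache[[key]]))
      cache[[key]] <- selectionCost(table, m, alpha, beta, scores,
                                    folds = folds, seed = seed)
    -cache[[key]]  # EFMO minimizes
  }
  res <- efmoOptimize(objective, rep(0, length(feats)), rep(1, length(feats)),
                      n = n, maxIter = maxIter, seed = seed)
  mask <- decode(res@bestPosition)
  names(mask) <- feats
  list(mask = mask, cost = -res@bestValue, scores = scores, result = res)
}

#' Exhaustive-enumeration optimum of the selection cost
#'
#' Evaluates the cost of every nonempty mask (feasible for Nb <= ~15); the
#' independent yardstick for the EFMO mask search.
#'
#' @inheritParams selectFeatures
#' @return list with `mask`, `cost`, and `all` (named cost vector).
#' @export
enumerateMasks <- function(table, alpha = 0.65, beta = 0.35, folds = 5, seed = 1) {
  feats <- setdiff(names(table), c("label", "id"))
  nb <- length(feats)
  if (nb > 15) stop("exhaustive enumeration limited to 15 features")
  scores <- vapply(feats, function(f)
    suppressWarnings(fisherScore(table[[f]], table$label)), numeric(1))
  costs <- numeric(2^nb - 1)
  best <- -Inf; bestMask <- NULL
  for (code in seq_len(2^nb - 1)) {
    m <- as.logical(bitwAnd(code, 2^(seq_len(nb) - 1)))
    costs[code] <- selectionCost(table, m, alpha, beta, scores,
                                 folds = folds, seed = seed)
    if (costs[code] > best) { best <- costs[code]; bestMask <- m }
  }
  names(bestMask) <- feats
  list(mask = bestMask, cost = best, all = costs)
}

#' Write a selected feature mask as JSON
#'
#' @param selection result of [selectFeatures()].
#' @param path file path.
#' @return the path, invisibly.
#' @export
writeFeatureMask <- function(selection, path) {
  jsonlite::write_json(
    list(selected = names(selection$mask)[selection$mask],
         mask = as.integer(selection$mask),
         features = names(selection$mask),
         cost = selection$cost),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
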