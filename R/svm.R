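#' Train an RBF-kernel support vector machine
#'
#' Fits a soft-margin SVM with radial basis kernel on the masked feature
#' columns, standardizing each feature by its training mean and SD (stored
#' in the model). The fitted decision function is kept in explicit form
#' (support vectors, dual coefficients, bias), so prediction evaluates
#' y = sgn(sum_i y_i alpha_i K(z, z_i) + b) directly and the model survives
#' a JSON round trip.
#'
#' @param table data.frame with feature columns and a two-class `label`
#'   column in \{+1, -1\}.
#' @param mask logical/0-1 vector over the feature columns (`NULL` = all).
#' @param cost penalty C > 0.
#' @param gamma kernel width > 0 (`NULL` = 1/n_features).
#' @return an [RBFSVMModel-class].
#' @export
trainSVM <- function(table, mask = NULL, cost = 1, gamma = NULL) {
  stopifnot(cost > 0)
  feats <- setdiff(names(table), c("label", "id"))
  if (is.null(mask)) mask <- rep(TRUE, length(feats))
  mask <- as.logical(mask)
  feats <- feats[mask]
  if (!length(feats)) stop("empty feature mask")
  if (length(unique(table$label)) < 2) stop("single-class training set")
  X <- as.matrix(table[, feats, drop = FALSE])
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, ctr, scl)
  if (is.null(gamma)) gamma <- 1 / ncol(Xs)
  stopifnot(gamma > 0)
  y <- factor(table$label, levels = sort(unique(table$label), decreasing = TRUE))
  fit <- e1071::svm(Xs, y, kernel = "radial", gamma = gamma, cost = cost,
                    scale = FALSE)
  # libsvm orients decision values by order of appearance in the training
  # data, not factor levels: read the orientation off the column name
  dv <- attr(stats::predict(fit, Xs, decision.values = TRUE), "decision.values")
  sides <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]]
  new("RBFSVMModel",
      supportVectors = as.matrix(fit$SV), coefs = as.numeric(fit$coefs),
      rho = as.numeric(fit$rho), gamma = gamma, cost = cost,
      center = ctr, scale = scl, features = feats,
      positiveLevel = as.numeric(sides[1]),
      negativeLevel = as.numeric(sides[2]))
}

#' Decision values of an RBF SVM
#'
#' Evaluates sum_i coef_i exp(-gamma ||z - z_i||^2) - rho on standardized
#' inputs; positive values predict the model's positive level.
#'
#' @param model an [RBFSVMModel-class].
#' @param newdata data.frame or matrix containing the model's features.
#' @return numeric vector of decision values.
#' @export
decisionValues <- function(model, newdata) {
  X <- as.matrix(as.data.frame(newdata)[, model@features, drop = FALSE])
  Xs <- scale(X, model@center, model@scale)
  SV <- model@supportVectors
  d2 <- outer(rowSums(Xs^2), rowSums(SV^2), "+") - 2 * Xs %*% t(SV)
  as.numeric(exp(-model@gamma * pmax(d2, 0)) %*% model@coefs - model@rho)
}

#' @describeIn RBFSVMModel-class predict labels in \{+1, -1\} (or decision
#'   scores with `type = "decision"`).
#' @param object an [RBFSVMModel-class].
#' @param newdata data.frame or matrix of features.
#' @param type `"class"` or `"decision"`.
#' @param ... ignored.
#' @export
setMethod("predict", "RBFSVMModel", function(object, newdata, type = "class", ...) {
  dv <- decisionValues(object, newdata)
  if (type == "decision") return(dv)
  ifelse(dv > 0, object@positiveLevel, object@negativeLevel)
})

.cvAccuracyAt <- function(table, mask, gamma, cost, folds, seed) {
  maskAccuracy(table, if (is.null(mask)) rep(TRUE, length(setdiff(names(table), c("label", "id")))) else mask,
               folds = folds, seed = seed, gamma = gamma, cost = cost)
}

#' Two-stage EFMO tuning of gamma then C
#'
#' Stage 1 maximizes cross-validated accuracy over log10(gamma) in \[-4, 2\]
#' at fixed C0; stage 2 freezes gamma at the stage-1 optimum and maximizes
#' over log10(C) in \[-2, 4\]. Returns the tuned parameters and the final
#' model trained on the full table at (gamma*, C*). Optionally the two
#' stages alternate for `rounds` passes. Deterministic given `seed`.
#'
#' @param table data.frame with feature columns and two-class `label`.
#' @param mask feature mask (`NULL` = all features).
#' @param C0 fixed penalty of stage 1.
#' @param logGammaRange,logCRange search boxes in log10 space.
#' @param folds CV folds.
#' @param n,maxIter EFMO population and iterations per stage.
#' @param rounds number of gamma-then-C passes (default 1).
#' @param seed integer seed.
#' @return list with `gamma`, `cost`, `cvAccuracy`, and `model`
#'   (an [RBFSVMModel-class]).
#' @export
tuneGammaThenC <- function(table, mask = NULL, C0 = 1,
                           logGammaRange = c(-4, 2), logCRange = c(-2, 4),
                           folds = 5, n = 10, maxIter = 12, rounds = 1,
                           seed = 1) {
  cache <- new.env(parent = emptyenv())
  acc <- function(g, C) {
    key <- sprintf("%.8g|%.8g", g, C)
    if (is.null(cache[[key]]))
      cache[[key]] <- .cvAccuracyAt(table, mask, g, C, folds, seed)
    cache[[key]]
  }
  gamma <- NA_real_; cost <- C0
  for (rd in seq_len(rounds)) {
    r1 <- efmoOptimize(function(z) -acc(10^z[1], cost),
                       logGammaRange[1], logGammaRange[2],
                       n = n, maxIter = maxIter, seed = seed + 2 * rd - 2)
    gamma <- 10^r1@bestPosition[1]
    r2 <- efmoOptimize(function(z) -acc(gamma, 10^z[1]),
                       logCRange[1], logCRange[2],
                       n = n, maxIter = maxIter, seed = seed + 2 * rd - 1)
    cost <- 10^r2@bestPosition[1]
  }
  list(gamma = gamma, cost = cost, cvAccuracy = acc(gamma, cost),
       model = trainSVM(table, mask, cost = cost, gamma = gamma))
}

#' Confusion-derived classification metrics
#'
#' Counts TP/FP/TN/FN (positive class +1 = melanoma) and derives
#' sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy
#' (TP+TN)/total, PPV TP/(TP+FP) and NPV TN/(TN+FN). A ratio with zero
#' denominator is reported as `NaN` with a warning.
#'
#' @param predictions,truths equal-length label vectors in \{+1, -1\}.
#' @param scores optional decision scores for the AUC.
#' @return a [ClassMetrics-class].
#' @export
evaluatePredictions <- function(predictions, truths, scores = NULL) {
  if (length(predictions) != length(truths)) stop("length mismatch")
  tp <- sum(predictions == 1 & truths == 1)
  fp <- sum(predictions == 1 & truths == -1)
  tn <- sum(predictions == -1 & truths == -1)
  fn <- sum(predictions == -1 & truths == 1)
  ratio <- function(num, den, what) {
    if (den == 0) { warning(what, " undefined (zero denominator)"); return(NaN) }
    num / den
  }
  auc <- if (is.null(scores)) NA_real_ else rocCurve(scores, truths)$auc
  new("ClassMetrics", tp = tp, fp = fp, tn = tn, fn = fn,
      sensitivity = ratio(tp, tp + fn, "sensitivity"),
      specificity = ratio(tn, tn + fp, "specificity"),
      accuracy = ratio(tp + tn, tp + tn + fp + fn, "accuracy"),
      ppv = ratio(tp, tp + fp, "PPV"),
      npv = ratio(tn, tn + fn, "NPV"),
      auc = auc)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the unique scores, collecting
#' (FPR, TPR) points, and integrates the area by the trapezoid rule; ties
#' in the scores are handled so the AUC equals the normalized Mann-Whitney
#' U statistic (concordant pairs + half ties over all pairs).
#'
#' @param scores numeric decision scores (larger = more positive).
#' @param truths labels in \{+1, -1\}.
#' @return list with `points` (data.frame of fpr/tpr, threshold-decreasing)
#'   and `auc`.
#' @export
rocCurve <- function(scores, truths) {
  pos <- truths == 1; neg <- !pos
  nP <- sum(pos); nN <- sum(neg)
  if (nP == 0 || nN == 0) stop("both classes required for a ROC curve")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores[pos] >= t) / nP, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores[neg] >= t) / nN, numeric(1))
  pts <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

#' @describeIn accessors one-row data.frame of the five fractions (and AUC)
#'   on the percent scale used in reporting.
#' @export
setMethod("metricsTable", "ClassMetrics", function(object) {
  data.frame(Accuracy = 100 * object@accuracy,
             Sensitivity = 100 * object@sensitivity,
             Specificity = 100 * object@specificity,
             PPV = 100 * object@ppv,
             NPV = 100 * object@npv,
             AUC = object@auc)
})

#' Persist / restore an RBF SVM model as JSON
#'
#' @param model an [RBFSVMModel-class].
#' @param path file path.
#' @return `readSVMModel` returns the restored model.
#' @export
writeSVMModel <- function(model, path) {
  jsonlite::write_json(list(
    supportVectors = model@supportVectors, coefs = model@coefs,
    rho = model@rho, gamma = model@gamma, cost = model@cost,
    center = model@center, scale = model@scale, features = model@features,
    positiveLevel = model@positiveLevel, negativeLevel = model@negativeLevel),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSVMModel
#' @export
readSVMModel <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("RBFSVMModel",
      supportVectors = as.matrix(o$supportVectors), coefs = as.numeric(o$coefs),
      rho = as.numeric(o$rho), gamma = as.numeric(o$gamma),
      cost = as.numeric(o$cost),
      center = stats::setNames(as.numeric(o$center), names(o$center)),
      scale = stats::setNames(as.numeric(o$scale), names(o$scale)),
      features = o$features,
      positiveLevel = as.numeric(o$positiveLevel),
      negativeLevel = as.numeric(o$negativeLevel))
}
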