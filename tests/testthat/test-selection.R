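test_that("Fisher score matches hand evaluation and direct summation", {
  vals <- c(0.9, 1.1, -0.1, 0.1)
  lab <- c(1, 1, -1, -1)
  expect_equal(fisherScore(vals, lab), 12.5)
  expect_equal(fisherScore(vals, lab), oracleFisher(c(0.9, 1.1), c(-0.1, 0.1)))
  set.seed(6)
  for (i in 1:10) {
    vp <- rnorm(8, 1); vn <- rnorm(12)
    v <- c(vp, vn); l <- rep(c(1, -1), c(8, 12))
    expect_equal(fisherScore(v, l), oracleFisher(vp, vn))
    perm <- sample(20)
    expect_equal(fisherScore(v[perm], l[perm]), fisherScore(v, l))
  }
})

test_that("identically distributed classes score near zero", {
  set.seed(12)
  v <- rnorm(2000)
  l <- rep(c(1, -1), 1000)
  expect_lt(fisherScore(v, l), 0.01)
})

test_that("degenerate within-class variance yields the infinite sentinel", {
  expect_warning(s <- fisherScore(c(1, 1, 0, 0), c(1, 1, -1, -1)), "trivially")
  expect_true(is.infinite(s))
  expect_equal(fisherScore(c(1, 1, 1, 1), c(1, 1, -1, -1)), 0)
})

test_that("the multiclass score reduces to the two-class form", {
  set.seed(3)
  v <- rnorm(30, rep(c(0, 2), 15))
  l <- rep(c(1, -1), 15)
  expect_equal(fisherScoreMulti(v, l), fisherScore(v, l))
  l3 <- rep(1:3, 10)
  expect_gte(fisherScoreMulti(v, l3), 0)
})

test_that("mask accuracy is deterministic, bounded, and exact when separable", {
  tab <- generateFeatureTable(featureTableSpec(nPerClass = 25, nFeatures = 4,
                                               informative = 1, separation = 8,
                                               noiseSd = 0.5, seed = 14))
  m <- c(TRUE, FALSE, FALSE, FALSE)
  a1 <- maskAccuracy(tab, m, folds = 5, seed = 2)
  expect_equal(a1, 1.0)
  expect_identical(a1, maskAccuracy(tab, m, folds = 5, seed = 2))
  expect_error(maskAccuracy(tab, rep(FALSE, 4)), "empty")
})

test_that("the selection cost is the declared weighted combination", {
  tab <- generateFeatureTable(featureTableSpec(nPerClass = 20, nFeatures = 5,
                                               informative = c(1, 2),
                                               separation = 3, seed = 9))
  feats <- paste0("f", 1:5)
  scores <- vapply(feats, function(f) fisherScore(tab[[f]], tab$label), numeric(1))
  mask <- c(TRUE, FALSE, TRUE, FALSE, FALSE)
  acc <- maskAccuracy(tab, mask, folds = 5, seed = 1)
  want <- 0.65 * acc + 0.35 * sum(scores[mask]) / sum(scores)
  expect_equal(selectionCost(tab, mask, folds = 5, seed = 1), want)
  # all features selected -> ratio term is exactly 1
  all5 <- rep(TRUE, 5)
  accAll <- maskAccuracy(tab, all5, folds = 5, seed = 1)
  expect_equal(selectionCost(tab, all5, folds = 5, seed = 1), 0.65 * accAll + 0.35)
  expect_error(selectionCost(tab, mask, alpha = 0.7, beta = 0.5), "alpha")
})

test_that("cost is monotone in accuracy at a fixed score ratio", {
  # same mask, same ratio; sweep hypothetical accuracies through the formula
  ratios <- 0.4
  costs <- 0.65 * seq(0, 1, 0.1) + 0.35 * ratios
  expect_true(all(diff(costs) > 0))
})

test_that("EFMO feature selection matches exhaustive enumeration on small Nb", {
  tab <- generateFeatureTable(featureTableSpec(nPerClass = 20, nFeatures = 2,
                                               informative = 1, separation = 6,
                                               noiseSd = 0.5, seed = 31))
  ex <- enumerateMasks(tab, folds = 4, seed = 3)
  got <- selectFeatures(tab, folds = 4, n = 8, maxIter = 10, seed = 3)
  expect_equal(got$cost, ex$cost, tolerance = 1e-9)
  expect_true(any(got$mask))
  tab8 <- generateFeatureTable(featureTableSpec(nPerClass = 20, nFeatures = 8,
                                                informative = c(2, 5),
                                                separation = 3, seed = 32))
  ex8 <- enumerateMasks(tab8, folds = 4, seed = 3)
  got8 <- selectFeatures(tab8, folds = 4, n = 15, maxIter = 20, seed = 3)
  expect_gte(got8$cost, 0.99 * ex8$cost)
})

test_that("selection recovers planted informative features across seeds", {
  hits <- 0
  for (s in 1:10) {
    tab <- generateFeatureTable(featureTableSpec(nPerClass = 30, nFeatures = 19,
                                                 informative = c(3, 9, 15),
                                                 separation = 3, noiseSd = 1,
                                                 seed = 100 + s))
    sel <- selectFeatures(tab, folds = 4, n = 15, maxIter = 15, seed = s)
    expect_true(any(sel$mask))
    if (all(sel$mask[c(3, 9, 15)])) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("an added pure-noise feature never raises the optimum cost", {
  for (s in 1:3) {
    tab <- generateFeatureTable(featureTableSpec(nPerClass = 15, nFeatures = 6,
                                                 informative = c(1, 2),
                                                 separation = 5, noiseSd = 0.5,
                                                 seed = 200 + s))
    base <- enumerateMasks(tab, folds = 3, seed = 1)$cost
    noisy <- tab
    lab <- noisy$label
    noisy$label <- NULL
    set.seed(300 + s)
    noisy$f7 <- rnorm(nrow(noisy))
    noisy$label <- lab
    withNoise <- enumerateMasks(noisy, folds = 3, seed = 1)$cost
    expect_lte(withNoise, base + 1e-9)
  }
})

test_that("the selected mask serializes to JSON with feature names", {
  tab <- generateFeatureTable(featureTableSpec(nPerClass = 15, nFeatures = 4,
                                               informative = 1, separation = 5,
                                               seed = 41))
  sel <- selectFeatures(tab, folds = 3, n = 8, maxIter = 8, seed = 2)
  f <- tempfile(fileext = ".json")
  writeFeatureMask(sel, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_identical(back$features, paste0("f", 1:4))
  expect_equal(as.logical(back$mask), unname(sel$mask))
  unlink(f)
})
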