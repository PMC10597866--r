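test_that("neighborhood mean filter matches a brute-force oracle", {
  img <- matrix(0, 3, 3); img[2, 2] <- 90
  sm <- smoothImage(img, 1.5)
  # enumerate all pixels within distance < 1.5 of the center
  vals <- c()
  for (r in 1:3) for (c in 1:3)
    if (sqrt((r - 2)^2 + (c - 2)^2) < 1.5) vals <- c(vals, img[r, c])
  expect_equal(sm[2, 2], mean(vals))
  # constant image is a fixed point, n = 0 is the identity
  const <- matrix(77, 5, 7)
  expect_equal(smoothImage(const, 2), const)
  rnd <- matrix(runif(35, 0, 255), 5, 7)
  expect_identical(smoothImage(rnd, 0), rnd)
})

test_that("sub-image splitting tiles, clips, and round-trips", {
  img8 <- matrix(1:64, 8, 8)
  expect_length(splitSubimages(img8, c(4, 4))$tiles, 4)
  img10 <- matrix(runif(100), 10, 10)
  g <- splitSubimages(img10, c(4, 4))
  expect_length(g$tiles, 9)
  expect_identical(stitchTiles(g), img10)
  g2 <- splitSubimages(img8, c(3, 5))
  expect_identical(stitchTiles(g2), matrix(as.numeric(1:64), 8, 8))
  expect_error(splitSubimages(img8, c(9, 4)), "dims")
})

test_that("dissimilarity is the XOR fraction with metric-like behavior", {
  a <- matrix(c(1, 0, 0, 0), 2, 2, byrow = TRUE)
  b <- matrix(c(1, 1, 0, 0), 2, 2, byrow = TRUE)
  expect_equal(dissimilarity(a, a), 0)
  expect_equal(dissimilarity(a, 1 - a), 1)
  expect_equal(dissimilarity(a, b), 0.25)
  expect_equal(dissimilarity(a, b), dissimilarity(b, a))
  set.seed(1)
  for (i in 1:10) {
    x <- matrix(rbinom(36, 1, 0.5), 6, 6)
    y <- matrix(rbinom(36, 1, 0.5), 6, 6)
    expect_equal(dissimilarity(x, y), sum(xor(x == 1, y == 1)) / 36)
    expect_gte(dissimilarity(x, y), 0); expect_lte(dissimilarity(x, y), 1)
  }
  expect_error(dissimilarity(a, matrix(0, 3, 3)), "dimensions")
})

test_that("the control agent kills on triple increase and worst-at-pass-end", {
  ag <- function(id, h) list(id = id, history = h, alive = TRUE)
  agents <- list(ag(1, c(0.3, 0.4, 0.5)), ag(2, c(0.3, 0.3, 0.2)))
  out <- controlAgentFilter(agents)
  expect_false(out[[1]]$alive)
  expect_true(out[[2]]$alive)
  agents <- list(ag(1, 0.1), ag(2, 0.4), ag(3, 0.2))
  out <- controlAgentFilter(agents, endOfPass = TRUE)
  expect_equal(vapply(out, function(a) a$alive, logical(1)), c(TRUE, FALSE, TRUE))
  # the last live agent survives even a triple increase
  solo <- list(ag(1, c(0.1, 0.2, 0.3)))
  expect_true(controlAgentFilter(solo, endOfPass = TRUE)[[1]]$alive)
  expect_error(controlAgentFilter(list()), "empty")
})

test_that("threshold-then-open action matches a reference morphology oracle", {
  expect_true(all(applyAction(matrix(200, 6, 6), tau = 100) == 0))
  solo <- matrix(255, 7, 7); solo[4, 4] <- 0
  expect_true(all(applyAction(solo, tau = 10, nu = 1) == 0))
  img <- matrix(200, 25, 25)
  disk <- oracleDiskMask(25, 25, 12, 12, 8)
  img[disk == 1] <- 50
  got <- applyAction(img, tau = 120, nu = 1)
  want <- oracleOpening((img <= 120) * 1, 1)
  expect_equal(got, want, ignore_attr = TRUE)
})

test_that("state discretization respects the mode bin bounds", {
  m <- matrix(0, 8, 8)
  expect_equal(computeState(m, c(0, 0), c(16, 16), mode = 1)[1:3], c(0L, 0L, 0L))
  expect_equal(computeState(m, c(8, 8), c(16, 16), mode = 1)[4], 3L)
  disk <- oracleDiskMask(16, 16, 7.5, 7.5, 5)
  expect_equal(computeState(disk, c(0, 0), c(16, 16), mode = 1)[3], 1L)
  set.seed(42)
  for (i in 1:200) {
    msk <- matrix(rbinom(64, 1, runif(1)), 8, 8)
    off <- c(sample(0:24, 1), sample(0:24, 1))
    s1 <- computeState(msk, off, c(32, 32), mode = 1)
    s2 <- computeState(msk, off, c(32, 32), mode = 2)
    expect_true(all(s1 >= 0) && all(s1 < c(9, 5, 4, 4)))
    expect_true(all(s2 >= 0) && all(s2 < c(4, 4, 3, 3)))
  }
})

test_that("reward is R1 only on strict improvement", {
  expect_equal(segmentReward(0.2, 0.5), 1)
  expect_equal(segmentReward(0.5, 0.2), -1)
  expect_equal(segmentReward(0.3, 0.3), -1)
  expect_equal(segmentReward(0.2, 0.5, R1 = 7, R2 = -3), 7)
})

test_that("the Q update follows one-step Q-learning arithmetic", {
  q <- newQTable(nThresh = 4, radii = 0:1)
  s <- c(1L, 1L, 1L, 0L); s2 <- c(2L, 1L, 1L, 0L)
  q <- qUpdate(q, s, 3, reward = 1, sNext = NULL, lr = 0.5, discount = 0.9)
  expect_equal(q@values[["1,1,1,0"]][3], 0.5)
  # lr = 0 leaves the table unchanged
  q0 <- qUpdate(q, s, 3, reward = -1, sNext = NULL, lr = 0, discount = 0.9)
  expect_equal(q0@values[["1,1,1,0"]][3], 0.5)
  # bootstrap pulls in discount * max of the next state's row
  q@values[["2,1,1,0"]] <- c(0, 2, 0, 0, 0, 0, 0, 0)
  q <- qUpdate(q, s, 1, reward = 0, sNext = s2, lr = 1, discount = 0.5)
  expect_equal(q@values[["1,1,1,0"]][1], 0 + 1 * (0 + 0.5 * 2 - 0))
  # fixed r = 1 with terminal next state converges monotonically to 1
  q2 <- newQTable(nThresh = 4, radii = 0:1)
  prev <- 0
  for (i in 1:200) {
    q2 <- qUpdate(q2, s, 2, reward = 1, sNext = NULL, lr = 0.1, discount = 0.9)
    now <- q2@values[["1,1,1,0"]][2]
    expect_gte(now, prev)
    prev <- now
  }
  expect_equal(prev, 1, tolerance = 1e-6)
})

test_that("Q values stay within the reward bound |R|/(1-discount)", {
  q <- newQTable(nThresh = 4, radii = 0:1)
  states <- lapply(1:5, function(i) c(i, 1L, 1L, 0L))
  set.seed(3)
  for (i in 1:500) {
    s <- states[[sample(5, 1)]]; s2 <- states[[sample(5, 1)]]
    q <- qUpdate(q, s, sample(8, 1), sample(c(-1, 1), 1), s2,
                 lr = 0.5, discount = 0.9)
  }
  vals <- unlist(mget(ls(q@values), envir = q@values))
  expect_true(all(abs(vals) <= 1 / (1 - 0.9) + 1e-9))
})

test_that("post-processing radius selection is argmin with smallest-radius ties", {
  pairs <- makeTrainingPairs(3, seedBase = 30)
  cfg <- segmenterConfig(episodes = 8, seed = 2, candidateDims = 48,
                         filterRadius = 0)
  model <- trainSegmenter(pairs, cfg)
  sel <- selectPostprocRadius(pairs, model, candidateRadii = c(3, 1, 2))
  expect_equal(sel$lambda, as.numeric(names(sel$meanD)[which.min(sel$meanD)]))
  # perfect segmentations are invariant to small radii: tie -> smallest
  expect_equal(selectPostprocRadius(pairs, model, candidateRadii = c(2, 1))$lambda, 1)
  expect_equal(selectPostprocRadius(pairs, model, candidateRadii = 4)$lambda, 4)
})
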