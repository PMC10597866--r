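test_that("the sine map hits its closed-form values and stays in range", {
  expect_equal(sineMapNext(0.5), 1)
  expect_equal(sineMapNext(0), 0)
  expect_equal(sineMapNext(1 / 6), 0.5)
  expect_equal(sineMapNext(0.25, gamma = 2), 0.5 * sin(pi / 4))
  for (r0 in c(0.1, 0.37, 0.9)) {
    r <- r0
    lo <- 1; hi <- 0
    for (i in 1:1e5) {
      r <- sineMapNext(r)
      if (r < lo) lo <- r
      if (r > hi) hi <- r
    }
    expect_gte(lo, 0); expect_lte(hi, 1)
  }
})

test_that("opposition is an involution fixed at the box midpoint", {
  expect_equal(oblOpposite(3, 0, 10), 7)
  expect_equal(oblOpposite(5, 0, 10), 5)
  set.seed(2)
  for (i in 1:20) {
    lo <- runif(3, -5, 0); hi <- runif(3, 1, 6)
    x <- lo + runif(3) * (hi - lo)
    o <- oblOpposite(x, lo, hi)
    expect_true(all(o >= lo - 1e-12 & o <= hi + 1e-12))
    expect_equal(oblOpposite(o, lo, hi), x)
  }
  expect_error(oblOpposite(11, 0, 10), "bounds")
})

test_that("initialization sets energies, stage ratios, and OBL selection", {
  sphere <- function(X) rowSums(X^2)
  set.seed(4)
  pop <- initPopulation(sphere, rep(-5, 3), rep(5, 3), n = 70)
  expect_true(all(pop@energy == 2))
  counts <- tabulate(pop@stage + 1, 5)
  expect_equal(sum(counts), 70)
  # proportional to 1:1:1:0.66:0.66 up to rounding
  expect_equal(counts / 70, c(1, 1, 1, 0.66, 0.66) / 4.32, tolerance = 0.02)
  # every OBL-kept individual beats or ties its reflected counterpart
  f <- sphere(pop@positions)
  k <- round(0.3 * 70)
  for (i in seq_len(k)) {
    opp <- oblOpposite(pop@positions[i, ], rep(-5, 3), rep(5, 3))
    expect_lte(f[i], sphere(matrix(opp, 1)) + 1e-12)
  }
  expect_error(initPopulation(sphere, rep(-5, 3), rep(5, 3), n = 3))
})

test_that("energy drains by fitness share and recovers on improvement", {
  pop <- new("FishPopulation",
             positions = matrix(0, 2, 2), previous = matrix(0, 2, 2),
             energy = c(2, 2), energyInit = 2, stage = c(2, 3),
             fitness = c(1, 3), pbest = c(1, 3),
             gbPos = c(0, 0), gbVal = 1, lower = c(-5, -5), upper = c(5, 5))
  out <- energyStep(pop, improved = c(FALSE, FALSE), r1 = c(1, 1))
  expect_equal(out@energy, c(2 - 0.25, 2 - 0.75))
  out2 <- energyStep(pop, improved = c(TRUE, FALSE), r1 = c(1, 0.5))
  expect_equal(out2@energy[1], 2 - 0.25 + 1 * 2)
  expect_equal(out2@energy[2], 2 - 0.75)
  # stages 0/1/4 do not drain
  pop@stage <- c(0, 4)
  out3 <- energyStep(pop, improved = c(FALSE, FALSE), r1 = 0)
  expect_equal(out3@energy, c(2, 2))
})

test_that("fecundity preserves size, spares stage 0, and kills per stat", {
  sphere <- function(X) rowSums(X^2)
  mkpop <- function(stage, n = 100) new("FishPopulation",
    positions = matrix(runif(2 * n, -5, 5), n, 2),
    previous = matrix(0, n, 2), energy = rep(2, n), energyInit = 2,
    stage = rep(stage, n), fitness = rep(1, n), pbest = rep(1, n),
    gbPos = c(1, 1), gbVal = 0.5, lower = c(-5, -5), upper = c(5, 5))
  set.seed(11)
  p0 <- fecundityStep(mkpop(0), r2 = 0.5)
  expect_true(all(p0@stage == 0))
  expect_equal(nrow(p0@positions), 100)
  surv <- replicate(300, sum(fecundityStep(mkpop(1), r2 = 0.5)@stage == 1))
  expect_equal(mean(surv), 93, tolerance = 0.03)
  # survivors with r2 = 0 land exactly on the global best location
  p1 <- fecundityStep(mkpop(1), r2 = 0)
  kept <- p1@stage == 1
  expect_true(any(kept))
  expect_true(all(p1@positions[kept, 1] == 1 & p1@positions[kept, 2] == 1))
})

test_that("motion follows the pinned-draw trace oracle", {
  pop <- new("FishPopulation",
             positions = matrix(c(2, 3), 1, 2), previous = matrix(c(1, 1), 1, 2),
             energy = 2, energyInit = 2, stage = 2,
             fitness = 5, pbest = 5, gbPos = c(0, 0), gbVal = 1,
             lower = c(-100, -100), upper = c(100, 100))
  # hand-stepped oracle with every draw pinned to 0.5, three iterations
  Z <- c(2, 3); Zpre <- c(1, 1); gb <- c(0, 0)
  for (it in 1:3) {
    ori <- (Z - Zpre)            # r3 = 0.5 -> first branch
    consumption <- 2 * 0.5       # energy >= init -> Zeng_init * r4
    Znew <- Z + ori * consumption + 2 * 0.5 * (gb - Z)
    Zpre <- Z; Z <- Znew
    pop <- motionStep(pop, 0.5, 0.5, 0.5, 0.5)
    expect_equal(as.numeric(pop@positions), Z)
    expect_equal(as.numeric(pop@previous), Zpre)
  }
  # r3 below 0.5 flips the velocity sign
  pop2 <- new("FishPopulation",
              positions = matrix(c(2, 3), 1, 2), previous = matrix(c(1, 1), 1, 2),
              energy = 2, energyInit = 2, stage = 3,
              fitness = 5, pbest = 5, gbPos = c(0, 0), gbVal = 1,
              lower = c(-100, -100), upper = c(100, 100))
  out <- motionStep(pop2, 0.5, 0.4, 0.5, 0.5)
  expect_equal(as.numeric(out@positions),
               c(2, 3) - c(1, 2) * 1 + 1 * (c(0, 0) - c(2, 3)))
  # a fish sitting on the best with zero velocity does not move
  still <- new("FishPopulation",
               positions = matrix(c(1, 1), 1, 2), previous = matrix(c(1, 1), 1, 2),
               energy = 2, energyInit = 2, stage = 2,
               fitness = 1, pbest = 1, gbPos = c(1, 1), gbVal = 1,
               lower = c(-100, -100), upper = c(100, 100))
  out2 <- motionStep(still, 0.3, 0.9, 0.7, 0.2)
  expect_equal(as.numeric(out2@positions), c(1, 1))
})

test_that("the optimizer solves the sphere and beats random search", {
  sphere <- function(X) rowSums(X^2)
  finals <- histories <- NULL
  hits <- 0
  rsWins <- 0
  for (s in 1:10) {
    r <- efmoOptimize(sphere, rep(-5, 2), rep(5, 2), n = 70, maxIter = 200,
                      seed = s, vectorized = TRUE)
    expect_true(all(diff(convergenceHistory(r)) <= 1e-12))
    if (bestValue(r) <= 1e-2) hits <- hits + 1
    rs <- randomSearch(sphere, rep(-5, 2), rep(5, 2), budget = r@evaluations,
                       seed = s, vectorized = TRUE)
    if (bestValue(r) <= bestValue(rs)) rsWins <- rsWins + 1
    finals <- c(finals, bestValue(r))
  }
  expect_gte(hits, 9)
  expect_gte(rsWins, 9)
})

test_that("optimization is deterministic given the seed", {
  sphere <- function(X) rowSums(X^2)
  a <- efmoOptimize(sphere, rep(-5, 3), rep(5, 3), n = 20, maxIter = 40,
                    seed = 5, vectorized = TRUE)
  b <- efmoOptimize(sphere, rep(-5, 3), rep(5, 3), n = 20, maxIter = 40,
                    seed = 5, vectorized = TRUE)
  expect_identical(bestPosition(a), bestPosition(b))
  expect_identical(convergenceHistory(a), convergenceHistory(b))
})

test_that("benchmark functions equal their offsets at the shift point", {
  for (k in 1:4) {
    for (d in c(2, 10, 30)) {
      fn <- benchmarkFunction(d, k, seed = 17 + d)
      expect_equal(benchmarkValue(fn, fn@shift), 100 * k, tolerance = 1e-9)
      expect_true(max(abs(crossprod(fn@rotation) - diag(d))) < 1e-9)
      # the shift point is the global minimum: random points never beat it
      X <- matrix(runif(50 * d, -100, 100), 50, d)
      expect_true(all(benchmarkValue(fn, X) >= 100 * k - 1e-9))
    }
  }
  expect_error(benchmarkFunction(5, 7), "which")
})

test_that("the comparison harness aggregates per-run statistics faithfully", {
  sphere <- function(X) rowSums(X^2)
  attr(sphere, "lower") <- rep(-5, 2); attr(sphere, "upper") <- rep(5, 2)
  opts <- list(
    rand = function(f, lo, hi, seed)
      bestValue(randomSearch(f, lo, hi, budget = 50, seed = seed, vectorized = TRUE)))
  one <- comparisonHarness(list(sphere = sphere), opts, runs = 1, seed = 3)
  expect_equal(one$table$Max, one$table$Min)
  expect_equal(one$table$Max, one$table$Mean)
  expect_equal(one$table$STD, 0)
  multi <- comparisonHarness(list(sphere = sphere), opts, runs = 8, seed = 3)
  vals <- multi$values[["sphere.rand"]]
  expect_equal(multi$table$Mean, mean(vals))
  expect_equal(multi$table$Max, max(vals))
  expect_equal(multi$table$Min, min(vals))
  expect_equal(multi$table$STD, sd(vals))
})

test_that("population size is conserved through a full optimization", {
  sizes <- integer(0)
  counting <- function(X) { sizes <<- c(sizes, nrow(X)); rowSums(X^2) }
  invisible(efmoOptimize(counting, rep(-5, 2), rep(5, 2), n = 24, maxIter = 30,
                         seed = 2, vectorized = TRUE))
  # after init (n) and one OBL batch, every batch evaluation is exactly n
  expect_true(all(sizes[-2] == 24))
})
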