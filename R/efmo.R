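#' Chaotic sine map
#'
#' One step of the sine map r_{i+1} = (gamma/4) * sin(pi * r_i) on \[0, 1\];
#' with the default gamma = 4 this is sin(pi * r). Iterates stay in \[0, 1\]
#' for any start in \[0, 1\].
#'
#' @param r current value in \[0, 1\].
#' @param gamma map parameter in (0, 6\]; default 4.
#' @return the next value.
#' @export
sineMapNext <- function(r, gamma = 4) {
  stopifnot(r >= 0, r <= 1)
  (gamma / 4) * sin(pi * r)
}

# A bank of per-fish chaotic streams replacing the uniform draws r1..r6 when
# the chaos enhancement is on: one independent sine-map stream per fish, per
# dimension and per coefficient, seeded away from the map's fixed point at 0.
.chaosBank <- function(n, d) array(stats::runif(6 * n * d, 0.01, 0.99), c(n, d, 6))

.advanceChaos <- function(bank) {
  bank <- sineMapNext(bank)
  # re-seed a collapsed stream (sin(pi*1) = 0 sticks at 0)
  dead <- bank < 1e-12
  if (any(dead)) bank[dead] <- stats::runif(sum(dead), 0.01, 0.99)
  bank
}

# coerce a draw (scalar, per-fish vector, or matrix) to an n x d matrix
.asDraw <- function(r, n, d) {
  if (is.matrix(r)) return(r)
  matrix(rep_len(r, n), n, d)
}

#' Opposition-based learning reflection
#'
#' Componentwise opposite lo + hi - x of a point in a box; an involution
#' with the box midpoint as fixed point, bound-preserving by construction.
#'
#' @param x numeric point within the bounds.
#' @param lower,upper box bounds (recycled to `length(x)`).
#' @return the opposite point.
#' @export
oblOpposite <- function(x, lower, upper) {
  lower <- rep_len(lower, length(x)); upper <- rep_len(upper, length(x))
  if (any(x < lower - 1e-12) || any(x > upper + 1e-12))
    stop("point outside bounds")
  lower + upper - x
}

.clampRows <- function(X, lower, upper) {
  X <- pmax(X, matrix(lower, nrow(X), ncol(X), byrow = TRUE))
  pmin(X, matrix(upper, nrow(X), ncol(X), byrow = TRUE))
}

# stage-count ratios (seq) and survival rates (stat) of the grayling
# life cycle, stages 0+ .. 4+
.FMO_SEQ <- c(1, 1, 1, 0.66, 0.66)
.FMO_STAT <- c(1, 0.93, 0.91, 0.37, 0.66)

.stageCounts <- function(n) {
  raw <- .FMO_SEQ / sum(.FMO_SEQ) * n
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    extra <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[extra] <- cnt[extra] + 1
  }
  cnt
}

#' Initialize a fish population
#'
#' Draws `n` uniform random positions; for 30 percent of them the bounds-
#' reflected opposite is also evaluated and the better of the pair kept
#' (opposition-based initialization). Age stages are assigned in proportion
#' 1 : 1 : 1 : 0.66 : 0.66 and every fish starts with energy 2.
#'
#' @param objective vectorized function: n x d matrix -> n values
#'   (minimized).
#' @param lower,upper box bounds (length d).
#' @param n population size (>= 5).
#' @param useOBL apply opposition-based initialization to 30 percent.
#' @param oblFraction fraction of the population opposed at init.
#' @return a [FishPopulation-class] with fitness evaluated.
#' @export
initPopulation <- function(objective, lower, upper, n = 70, useOBL = TRUE,
                           oblFraction = 0.3) {
  stopifnot(n >= 5, length(lower) == length(upper), all(lower < upper))
  d <- length(lower)
  X <- matrix(stats::runif(n * d), n, d)
  X <- sweep(sweep(X, 2, upper - lower, "*"), 2, lower, "+")
  f <- objective(X)
  if (useOBL) {
    k <- max(1, round(oblFraction * n))
    idx <- seq_len(k)
    opp <- t(apply(X[idx, , drop = FALSE], 1, oblOpposite, lower = lower, upper = upper))
    if (d == 1) opp <- matrix(opp, ncol = 1)
    fo <- objective(opp)
    better <- fo < f[idx]
    X[idx[better], ] <- opp[better, , drop = FALSE]
    f[idx][better] <- fo[better]
  }
  cnt <- .stageCounts(n)
  stage <- rep(0:4, times = cnt)
  best <- which.min(f)
  new("FishPopulation",
      positions = X, previous = X,
      energy = rep(2, n), energyInit = 2, stage = stage,
      fitness = f, pbest = f,
      gbPos = as.numeric(X[best, ]), gbVal = f[best],
      lower = as.numeric(lower), upper = as.numeric(upper))
}

#' Energy dynamics of one iteration
#'
#' Migrating fish (stages 2 and 3) spend energy proportional to their share
#' of the population's total cost: Zeng <- Zeng - f_j / sum(f). Fish that
#' improved their personal best regain r1 * Zeng_init. Energies are floored
#' at 0; a degenerate zero total cost skips the drain.
#'
#' @param pop a [FishPopulation-class] with current `fitness` and `pbest`
#'   reflecting the previous iterations.
#' @param improved logical vector marking fish that improved their personal
#'   best this iteration.
#' @param r1 random draws in \[0, 1\] (length n, recycled; a matrix draw
#'   uses its first column).
#' @return the updated population.
#' @export
energyStep <- function(pop, improved, r1) {
  n <- nrow(pop@positions)
  if (is.matrix(r1)) r1 <- r1[, 1]
  r1 <- rep_len(r1, n)
  tot <- sum(pop@fitness)
  migr <- pop@stage %in% c(2, 3)
  if (is.finite(tot) && tot != 0)
    pop@energy[migr] <- pop@energy[migr] - pop@fitness[migr] / tot
  pop@energy[improved] <- pop@energy[improved] + r1[improved] * pop@energyInit
  pop@energy <- pmax(pop@energy, 0)
  pop
}

#' Fecundity: stage-wise survival and repositioning
#'
#' Each fish survives its stage with probability stat = (1, 0.93, 0.91,
#' 0.37, 0.66); deaths are replaced by stage-0 newborns near the global best
#' (exploration scale `alpha` times the box width), keeping the population
#' size constant. Survivors of stages other than 0 reposition toward the
#' global best: Zv <- gbloc + r2 * (Zv - gbpos).
#'
#' @param pop a [FishPopulation-class].
#' @param r2 random draws in \[0, 1\]: a scalar, a per-fish vector, or an
#'   n x d per-dimension matrix.
#' @param alpha exploration-noise scale of newborn placement (default 0.15).
#' @return the updated population (fitness of moved fish is stale until the
#'   caller re-evaluates).
#' @export
fecundityStep <- function(pop, r2, alpha = 0.15) {
  n <- nrow(pop@positions); d <- ncol(pop@positions)
  r2 <- .asDraw(r2, n, d)
  die <- stats::runif(n) > .FMO_STAT[pop@stage + 1]
  surv <- !die & pop@stage > 0
  if (any(surv)) {
    k <- sum(surv)
    Zv <- pop@positions[surv, , drop = FALSE]
    gb <- matrix(pop@gbPos, k, d, byrow = TRUE)
    pop@previous[surv, ] <- pop@positions[surv, , drop = FALSE]
    pop@positions[surv, ] <- .clampRows(gb + r2[surv, , drop = FALSE] * (Zv - gb),
                                        pop@lower, pop@upper)
  }
  if (any(die)) {
    k <- sum(die)
    width <- matrix(pop@upper - pop@lower, k, d, byrow = TRUE)
    gb <- matrix(pop@gbPos, k, d, byrow = TRUE)
    newborn <- gb + alpha * width * matrix(stats::runif(k * d, -1, 1), k, d)
    pop@previous[die, ] <- newborn <- .clampRows(newborn, pop@lower, pop@upper)
    pop@positions[die, ] <- newborn
    pop@stage[die] <- 0L
    pop@energy[die] <- pop@energyInit
    pop@pbest[die] <- Inf
  }
  pop
}

#' Motion: migration of the mature stages
#'
#' Stages 2 and 3 move by
#' Z <- Z + orispeed * consumption + Zeng_init * r4 * (gbpos - Z), where
#' orispeed is (Z - Zpre) when r3 >= 0.5 and its negation otherwise, and
#' consumption is Zeng_init * r4 when the fish's energy is at least its
#' initial energy, else Zeng * r6. Stages 0, 1 and 4 reposition by the
#' fecundity contraction Zv <- gbloc + r2 * (Zv - gbpos). Positions are
#' clamped to the bounds and previous positions updated.
#'
#' @param pop a [FishPopulation-class].
#' @param r2,r3,r4,r6 random draws in \[0, 1\]: scalars, per-fish vectors,
#'   or n x d per-dimension matrices.
#' @return the updated population.
#' @export
motionStep <- function(pop, r2, r3, r4, r6) {
  n <- nrow(pop@positions); d <- ncol(pop@positions)
  r2 <- .asDraw(r2, n, d); r3 <- .asDraw(r3, n, d)
  r4 <- .asDraw(r4, n, d); r6 <- .asDraw(r6, n, d)
  gb <- matrix(pop@gbPos, n, d, byrow = TRUE)
  Z <- pop@positions
  mig <- pop@stage %in% c(2, 3)
  newZ <- Z
  if (any(mig)) {
    ori <- (Z - pop@previous) * ifelse(r3 >= 0.5, 1, -1)
    lowEnergy <- matrix(pop@energy < pop@energyInit, n, d)
    consumption <- ifelse(lowEnergy, pop@energy * r6, pop@energyInit * r4)
    step <- ori * consumption + pop@energyInit * r4 * (gb - Z)
    newZ[mig, ] <- Z[mig, , drop = FALSE] + step[mig, , drop = FALSE]
  }
  oth <- !mig
  if (any(oth))
    newZ[oth, ] <- gb[oth, , drop = FALSE] +
      r2[oth, , drop = FALSE] * (Z[oth, , drop = FALSE] - gb[oth, , drop = FALSE])
  pop@previous <- Z
  pop@positions <- .clampRows(newZ, pop@lower, pop@upper)
  pop
}

#' Enhanced fish migration optimization
#'
#' Iterates the energy, fecundity and motion steps of the grayling life
#' cycle over a box-bounded minimization problem. Enhancements: opposition-
#' based initialization of 30 percent of the population (`useOBL`) and
#' replacement of the uniform draws r1..r6 by per-fish chaotic sine-map
#' streams (`useChaos`). Fish age one stage every ceil(maxIter/5)
#' iterations; stage-4 fish are reborn at stage 0 after fecundity. The
#' global best is elitist, so the convergence history is non-increasing.
#' Deterministic given `seed`.
#'
#' @param objective function of one point (numeric vector) or, when
#'   `vectorized = TRUE`, of an n x d matrix returning n values; minimized.
#' @param lower,upper box bounds (length d).
#' @param n population size (default 70).
#' @param maxIter iterations (default 200).
#' @param seed integer seed (`NULL` leaves the RNG state alone).
#' @param useOBL,useChaos the two enhancements; both on for EFMO, both off
#'   for the plain FMO baseline.
#' @param vectorized whether `objective` accepts a matrix of rows.
#' @param alpha newborn exploration scale (default 0.15).
#' @return an [EFMOResult-class].
#' @export
efmoOptimize <- function(objective, lower, upper, n = 70, maxIter = 200,
                         seed = NULL, useOBL = TRUE, useChaos = TRUE,
                         vectorized = FALSE, alpha = 0.15) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  obj <- if (vectorized) objective else
    function(X) apply(X, 1, function(z) objective(as.numeric(z)))
  evals <- 0
  objCounted <- function(X) { evals <<- evals + nrow(X); obj(X) }
  pop <- initPopulation(objCounted, lower, upper, n, useOBL = useOBL)
  d <- length(lower)
  chaos <- if (useChaos) .chaosBank(n, d) else NULL
  ageEvery <- ceiling(maxIter / 5)
  history <- numeric(maxIter)
  for (it in seq_len(maxIter)) {
    if (useChaos) {
      chaos <- .advanceChaos(chaos)
      r <- lapply(1:6, function(k) chaos[, , k])
    } else {
      r <- lapply(1:6, function(k) matrix(stats::runif(n * d), n, d))
    }
    if (d == 1) r <- lapply(r, function(x) matrix(x, n, 1))
    pop <- motionStep(pop, r[[2]], r[[3]], r[[4]], r[[6]])
    f <- objCounted(pop@positions)
    improved <- f < pop@pbest
    pop@fitness <- f
    pop@pbest <- pmin(pop@pbest, f)
    if (min(f) < pop@gbVal) {
      pop@gbVal <- min(f)
      pop@gbPos <- as.numeric(pop@positions[which.min(f), ])
    }
    pop <- energyStep(pop, improved, r[[1]])
    pop <- fecundityStep(pop, r[[2]], alpha)
    f <- objCounted(pop@positions)
    pop@fitness <- f
    pop@pbest <- pmin(pop@pbest, f)
    if (min(f) < pop@gbVal) {
      pop@gbVal <- min(f)
      pop@gbPos <- as.numeric(pop@positions[which.min(f), ])
    }
    if (it %% ageEvery == 0) pop@stage <- pmin(pop@stage + 1L, 4L)
    history[it] <- pop@gbVal
  }
  new("EFMOResult", bestPosition = pop@gbPos, bestValue = pop@gbVal,
      history = history, evaluations = evals)
}

#' Plain random-search baseline
#'
#' Uniform sampling in the box at an equal evaluation budget; the stand-in
#' comparator for the optimizer ablations.
#'
#' @inheritParams efmoOptimize
#' @param budget total number of objective evaluations.
#' @return an [EFMOResult-class].
#' @export
randomSearch <- function(objective, lower, upper, budget = 1000, seed = NULL,
                         vectorized = FALSE) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  d <- length(lower)
  X <- matrix(stats::runif(budget * d), budget, d)
  X <- sweep(sweep(X, 2, upper - lower, "*"), 2, lower, "+")
  f <- if (vectorized) objective(X) else apply(X, 1, function(z) objective(as.numeric(z)))
  best <- which.min(f)
  new("EFMOResult", bestPosition = as.numeric(X[best, ]),
      bestValue = f[best], history = cummin(f), evaluations = budget)
}

#' Seeded multi-run comparison harness
#'
#' Runs each optimizer on each objective `runs` times with derived seeds and
#' aggregates Max, Min, Mean, STD and wall time per (function, optimizer)
#' cell, the layout of the optimizer-validation experiments.
#'
#' @param objectives named list of [BenchmarkFunction-class] objects or plain
#'   objective closures with attributes `lower`/`upper`.
#' @param optimizers named list of functions `(objective, lower, upper,
#'   seed) -> numeric best value`.
#' @param runs independent repetitions (default 30).
#' @param seed base seed; run r uses seed + r.
#' @return list with `table` (data.frame of aggregates) and `values`
#'   (per-run matrix list).
#' @export
comparisonHarness <- function(objectives, optimizers, runs = 30, seed = 1) {
  stopifnot(runs >= 1)
  rows <- list(); values <- list()
  for (fn in names(objectives)) {
    ob <- objectives[[fn]]
    if (is(ob, "BenchmarkFunction")) {
      f <- (function(b) function(X) benchmarkValue(b, X))(ob)
      lo <- ob@lower; hi <- ob@upper
    } else {
      f <- ob; lo <- attr(ob, "lower"); hi <- attr(ob, "upper")
    }
    for (op in names(optimizers)) {
      vals <- numeric(runs)
      t0 <- proc.time()[["elapsed"]]
      for (r in seq_len(runs))
        vals[r] <- optimizers[[op]](f, lo, hi, seed + r)
      elapsed <- proc.time()[["elapsed"]] - t0
      values[[paste(fn, op, sep = ".")]] <- vals
      rows[[length(rows) + 1]] <- data.frame(
        fn = fn, optimizer = op,
        Max = max(vals), Min = min(vals), Mean = mean(vals),
        STD = if (runs == 1) 0 else stats::sd(vals), Time = elapsed)
    }
  }
  list(table = do.call(rbind, rows), values = values)
}
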