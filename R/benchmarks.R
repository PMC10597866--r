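.BENCH_NAMES <- c("High Conditioned Elliptic", "Bent Cigar", "Discus",
                  "Shifted Rotated Rosenbrock")

# base functions on the rotated/shifted argument z (rows of Z)
.ellipticBase <- function(Z) {
  d <- ncol(Z)
  w <- if (d == 1) 1 else 1e6^((seq_len(d) - 1) / (d - 1))
  as.numeric(Z^2 %*% w)
}

.bentCigarBase <- function(Z) {
  if (ncol(Z) == 1) return(as.numeric(Z^2))
  Z[, 1]^2 + 1e6 * rowSums(Z[, -1, drop = FALSE]^2)
}

.discusBase <- function(Z) {
  if (ncol(Z) == 1) return(as.numeric(1e6 * Z^2))
  1e6 * Z[, 1]^2 + rowSums(Z[, -1, drop = FALSE]^2)
}

.rosenbrockBase <- function(Y) {
  d <- ncol(Y)
  if (d == 1) return((1 - Y[, 1])^2)
  a <- Y[, -d, drop = FALSE]; b <- Y[, -1, drop = FALSE]
  rowSums(100 * (b - a^2)^2 + (1 - a)^2)
}

# seeded random orthogonal matrix: QR of a Gaussian matrix, sign-fixed
.randomRotation <- function(d) {
  qrd <- qr(matrix(stats::rnorm(d * d), d, d))
  Q <- qr.Q(qrd)
  Q %*% diag(sign(diag(qr.R(qrd))), d)
}

#' Build a shifted/rotated benchmark function
#'
#' Constructs one of the four optimizer-validation objectives on the box
#' \[-100, 100\]^d: F_k(x) = f_k(M (x - o_k)) + F_k* for the high-
#' conditioned elliptic (k = 1, F* = 100), bent cigar (k = 2, F* = 200) and
#' discus (k = 3, F* = 300) bases, and
#' F_4(x) = f_4(M (2.048 (x - o_4) / 100) + 1) + 400 for Rosenbrock (the
#' inner transform maps x = o_4 to the all-ones Rosenbrock optimum). `M` is
#' a seeded random orthogonal matrix (QR of a Gaussian matrix) and the shift
#' `o` is drawn uniformly in \[-80, 80\]^d, so each function's value at its
#' own shift point equals its offset exactly.
#'
#' @param dim problem dimension.
#' @param which function id in 1..4.
#' @param seed integer seed for the rotation and shift.
#' @return a [BenchmarkFunction-class].
#' @export
benchmarkFunction <- function(dim, which, seed = 1) {
  if (!which %in% 1:4) stop("which must be in 1..4")
  set.seed(as.integer(seed))
  M <- .randomRotation(dim)
  o <- stats::runif(dim, -80, 80)
  new("BenchmarkFunction", id = which, name = .BENCH_NAMES[which],
      rotation = M, shift = o, offset = 100 * which,
      lower = rep(-100, dim), upper = rep(100, dim))
}

#' @describeIn benchmarkValue evaluate at a vector or a matrix of row-points.
#' @export
setMethod("benchmarkValue", signature("BenchmarkFunction", "numeric"),
  function(fn, x) benchmarkValue(fn, matrix(x, nrow = 1)))

#' @export
setMethod("benchmarkValue", signature("BenchmarkFunction", "matrix"),
  function(fn, x) {
    D <- sweep(x, 2, fn@shift)
    if (fn@id == 4) {
      Y <- (2.048 / 100) * D %*% t(fn@rotation)
      return(.rosenbrockBase(Y + 1) + fn@offset)
    }
    Z <- D %*% t(fn@rotation)
    base <- switch(fn@id, .ellipticBase, .bentCigarBase, .discusBase)
    base(Z) + fn@offset
  })
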