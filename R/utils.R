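# Internal numerical utilities: constants, seeded RNG scoping, and batched
# small-dimension linear algebra used by the steady-state signal solvers.

# Gyromagnetic ratio of 1H: gamma/2pi = 42.577 MHz/T.
# In the unit system used throughout (time ms, B1 uT): rad per (uT * ms).
.GAMMA_RAD_PER_UT_MS <- 2 * pi * 42.577 * 1e-3

#' @noRd
.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library RNG state is untouched.
#' @noRd
.withSeed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic seed derivation. Mixes a base seed with integer tags so each
# stochastic stage (fields, per-volume noise, replicates) has its own stream.
# Kept below 2^31 at every step; multiplier small enough that the product
# stays within double precision (69069 * 2^31 < 2^53).
#' @noRd
.deriveSeed <- function(base, ...) {
  s <- as.numeric(base) %% 2147483647
  for (k in c(...)) {
    s <- (s * 69069 + as.numeric(k) + 1) %% 2147483647
  }
  as.integer(s) + 1L
}

# ---- batched small linear algebra -------------------------------------------
# Matrices of size d x d over N voxels are stored as nested lists M[[i]][[j]]
# of N-vectors; vectors as lists b[[i]]. All operations are elementwise over
# the voxel dimension.

#' @noRd
.batZeroMat <- function(d, n) {
  z <- numeric(n)
  lapply(seq_len(d), function(i) lapply(seq_len(d), function(j) z))
}

#' @noRd
.batMatMul <- function(A, B, d) {
  out <- vector("list", d)
  for (i in seq_len(d)) {
    row <- vector("list", d)
    for (j in seq_len(d)) {
      acc <- A[[i]][[1]] * B[[1]][[j]]
      for (k in seq_len(d)[-1]) acc <- acc + A[[i]][[k]] * B[[k]][[j]]
      row[[j]] <- acc
    }
    out[[i]] <- row
  }
  out
}

#' @noRd
.batMatVec <- function(A, v, d) {
  out <- vector("list", d)
  for (i in seq_len(d)) {
    acc <- A[[i]][[1]] * v[[1]]
    for (k in seq_len(d)[-1]) acc <- acc + A[[i]][[k]] * v[[k]]
    out[[i]] <- acc
  }
  out
}

# Fixed point of the affine recursion x <- A x + b with spectral radius < 1,
# obtained by repeated squaring of the affine map: (A, b) -> (A^2, A b + b).
# After m doublings b accumulates sum_{k<2^m} A^k b -> (I - A)^{-1} b.
# nDoublings = 16 covers 65536 iterations of the per-TR map, enough to drive
# the slowest relaxation mode (T1 up to ~6 s at TR 7 ms) below 1e-14.
#' @noRd
.batAffineFixedPoint <- function(A, b, d, nDoublings = 16L) {
  for (m in seq_len(nDoublings)) {
    b <- {
      Ab <- .batMatVec(A, b, d)
      lapply(seq_len(d), function(i) Ab[[i]] + b[[i]])
    }
    A <- .batMatMul(A, A, d)
  }
  b
}

# Cramer solve of the 3x3 system (I - A) x = b, vectorised over voxels.
#' @noRd
.batSolve3IminusA <- function(A, b) {
  m11 <- 1 - A[[1]][[1]]; m12 <- -A[[1]][[2]]; m13 <- -A[[1]][[3]]
  m21 <- -A[[2]][[1]]; m22 <- 1 - A[[2]][[2]]; m23 <- -A[[2]][[3]]
  m31 <- -A[[3]][[1]]; m32 <- -A[[3]][[2]]; m33 <- 1 - A[[3]][[3]]
  c11 <- m22 * m33 - m23 * m32
  c12 <- m23 * m31 - m21 * m33
  c13 <- m21 * m32 - m22 * m31
  det <- m11 * c11 + m12 * c12 + m13 * c13
  # adjugate columns
  x1 <- (c11 * b[[1]] + (m13 * m32 - m12 * m33) * b[[2]] +
           (m12 * m23 - m13 * m22) * b[[3]]) / det
  x2 <- (c12 * b[[1]] + (m11 * m33 - m13 * m31) * b[[2]] +
           (m13 * m21 - m11 * m23) * b[[3]]) / det
  x3 <- (c13 * b[[1]] + (m12 * m31 - m11 * m32) * b[[2]] +
           (m11 * m22 - m12 * m21) * b[[3]]) / det
  list(x1, x2, x3)
}

# Batched Cholesky solve of the 4x4 symmetric positive definite systems
# H x = g used by the Levenberg-Marquardt engine. H given as the 10 unique
# entries h[[i]][[j]] (i <= j), each an N-vector.
#' @noRd
.batCholSolve4 <- function(h11, h12, h13, h14, h22, h23, h24,
                           h33, h34, h44, g1, g2, g3, g4) {
  l11 <- sqrt(h11)
  l21 <- h12 / l11; l31 <- h13 / l11; l41 <- h14 / l11
  l22 <- sqrt(pmax(h22 - l21 * l21, .Machine$double.xmin))
  l32 <- (h23 - l31 * l21) / l22
  l42 <- (h24 - l41 * l21) / l22
  l33 <- sqrt(pmax(h33 - l31 * l31 - l32 * l32, .Machine$double.xmin))
  l43 <- (h34 - l41 * l31 - l42 * l32) / l33
  l44 <- sqrt(pmax(h44 - l41 * l41 - l42 * l42 - l43 * l43,
                   .Machine$double.xmin))
  # forward substitution L y = g
  y1 <- g1 / l11
  y2 <- (g2 - l21 * y1) / l22
  y3 <- (g3 - l31 * y1 - l32 * y2) / l33
  y4 <- (g4 - l41 * y1 - l42 * y2 - l43 * y3) / l44
  # back substitution L' x = y
  x4 <- y4 / l44
  x3 <- (y3 - l43 * x4) / l33
  x2 <- (y2 - l32 * x3 - l42 * x4) / l22
  x1 <- (y1 - l21 * x2 - l31 * x3 - l41 * x4) / l11
  list(x1, x2, x3, x4)
}
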