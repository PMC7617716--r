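#' @keywords internal
"_PACKAGE"

# Run code with a private RNG stream seeded by `seed`, restoring the caller's
# RNG state afterwards. All generators in the package go through this so that
# fixture construction never perturbs (and is never perturbed by) user code.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# All pairwise Euclidean distances between the rows of two n x 3 matrices.
# Returns an nrow(a) x nrow(b) matrix. Plain vectorized arithmetic; fixtures
# stay small (<= a few thousand atoms) so no neighbor list is needed.
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# Minimum distance between two coordinate sets.
min_dist <- function(a, b) min(cross_dist(a, b))

# Row-wise minima of a matrix (C-level, via max.col on the negated matrix).
row_mins <- function(m) m[cbind(seq_len(nrow(m)), max.col(-m, "first"))]

# Rotation matrix about an arbitrary unit axis (Rodrigues), angle in radians.
rotation_matrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c0 <- cos(angle); s0 <- sin(angle)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
               3, 3, byrow = TRUE)
  diag(3) * c0 + s0 * ux + (1 - c0) * tcrossprod(u)
}

# Uniform random rotation matrix (from a random quaternion).
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# Rotation taking unit(a) onto unit(b) (minimal-angle rotation).
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(v^2)); cth <- sum(a * b)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    # opposite vectors: rotate pi about any perpendicular
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    p <- p - a * sum(p * a); p <- p / sqrt(sum(p^2))
    return(rotation_matrix(p, pi))
  }
  rotation_matrix(v / s, atan2(s, cth))
}

# Kabsch optimal rotation: returns the 3x3 matrix R minimizing ||P R - Q||
# for centered coordinate sets P, Q (rows are atoms).
kabsch_rotation <- function(P, Q) {
  H <- crossprod(P, Q)
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  D <- diag(c(1, 1, d))
  sv$u %*% D %*% t(sv$v)
}

# Least-squares superpose the rows of `mobile` onto `ref` using the subset of
# rows `fit_idx` (same indices in both), applying the transform to all rows.
superpose_onto <- function(mobile, ref, fit_idx) {
  mP <- mobile[fit_idx, , drop = FALSE]
  mQ <- ref[fit_idx, , drop = FALSE]
  cP <- colMeans(mP); cQ <- colMeans(mQ)
  R <- kabsch_rotation(sweep(mP, 2, cP), sweep(mQ, 2, cQ))
  sweep(sweep(mobile, 2, cP) %*% R, 2, cQ, "+")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
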