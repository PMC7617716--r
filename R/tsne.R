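# Exact (dense) t-distributed stochastic neighbor embedding.
#
# O(n^2) implementation suitable for the <= ~1000-conformer ensembles this
# pipeline clusters: per-point bandwidths found by binary search on the
# target perplexity, symmetrized input affinities, 2-D Student-t output
# kernel, gradient descent with momentum and early exaggeration. Seeded and
# deterministic.
tsne_embed <- function(X, perplexity = 30, seed = 1, max_iter = 400,
                       eta = 200, dims = 2) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4) stop("need at least 4 rows to embed")
  max_perp <- (n - 1) / 3
  if (perplexity > max_perp) {
    warning("perplexity ", perplexity, " too large for ", n,
            " points; clamped to ", floor(max_perp))
    perplexity <- floor(max_perp)
  }
  D2 <- as.matrix(stats::dist(X))^2

  # per-point precision by binary search on entropy = log(perplexity)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    beta <- 1; lo <- -Inf; hi <- Inf
    for (it in 1:60) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw < 1e-300) { H <- 0; p <- w }
      else {
        p <- w / sw
        H <- -sum(ifelse(p > 0, p * log(p), 0))
      }
      if (abs(H - target) < 1e-5) break
      if (H > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  with_seed(seed, {
    Y <- matrix(stats::rnorm(n * dims, sd = 1e-4), n, dims)
    inc <- matrix(0, n, dims)
    exaggeration <- 12
    stop_exag <- min(100, max_iter %/% 4)
    for (iter in seq_len(max_iter)) {
      Pe <- if (iter <= stop_exag) P * exaggeration else P
      sumY <- rowSums(Y^2)
      num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      L <- (Pe - Q) * num
      grad <- 4 * (diag(rowSums(L)) - L) %*% Y
      momentum <- if (iter <= 100) 0.5 else 0.8
      inc <- momentum * inc - eta * grad
      Y <- Y + inc
      Y <- sweep(Y, 2, colMeans(Y))
    }
    Y
  })
}
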