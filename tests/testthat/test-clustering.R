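test_that("featurization is the rotation-invariant pairwise C-alpha vector", {
  pep <- fx("pep5")
  feats <- featurize(pep)
  expect_equal(dim(feats), c(5, 53 * 52 / 2))

  rot <- pep
  R <- gqbind:::rotation_matrix(c(0, 1, 1), 0.8)
  rot$coords[1, , ] <- sweep(rot$coords[1, , ] %*% t(R), 2, c(5, 5, 5), "+")
  feats_rot <- featurize(rot)
  expect_equal(feats_rot[1, ], feats[1, ], tolerance = 1e-9)

  two <- make_peptide_conformers("GR", n = 2, seed = 1)
  expect_error(featurize(two), "at least 3")
})

test_that("well-separated archetypes are recovered and medoids are central", {
  set.seed(55)
  base <- make_peptide_conformers(rgg_like_sequence(), n = 5, seed = 41)
  n_per <- 30
  na <- n_atoms(base)
  coords <- array(NA_real_, dim = c(5 * n_per, na, 3))
  truth <- integer(5 * n_per)
  for (a in 1:5) for (i in 1:n_per) {
    f <- (a - 1) * n_per + i
    coords[f, , ] <- base$coords[a, , ] + stats::rnorm(na * 3, 0, 0.3)
    truth[f] <- a
  }
  ens <- ensemble(base$topology, coords)
  feats <- featurize(ens)
  cr <- cluster_conformers(feats, k = 5, perplexity = 15, seed = 2)
  expect_gte(mclust::adjustedRandIndex(cr$labels, truth), 0.95)
  expect_gte(cr$silhouette, 0.5)
  expect_equal(length(unique(cr$labels)), 5)

  # medoid of each cluster is a member minimizing summed feature distance
  for (ci in 1:5) {
    members <- which(cr$labels == ci)
    expect_true(cr$representatives[ci] %in% members)
    dm <- as.matrix(dist(feats[members, ]))
    best <- members[which.min(rowSums(dm))]
    expect_equal(cr$representatives[ci], best)
  }

  reps <- representatives(ens, cr)
  expect_equal(reps$frame_count, 5)

  # determinism under a fixed seed
  cr2 <- cluster_conformers(feats, k = 5, perplexity = 15, seed = 2)
  expect_identical(cr$labels, cr2$labels)
  expect_identical(cr$embedding, cr2$embedding)

  expect_error(cluster_conformers(feats[1:4, ], k = 5), "fewer conformers")
})

test_that("degenerate silhouettes are reported as 0 with a warning", {
  feats <- matrix(rep(1:3, each = 8), nrow = 8)
  expect_warning(cr <- cluster_conformers(feats, k = 1, perplexity = 2,
                                          seed = 1, max_iter = 50),
                 "degenerate")
  expect_equal(cr$silhouette, 0)
  expect_equal(cr$representatives, cr$representatives[1])
})

test_that("singleton and symmetric clusters pick the obvious representative", {
  # 3-point symmetric cluster with an exact center plus a distant singleton
  feats <- rbind(c(0, 1), c(0.5, 0.5), c(0, 0), c(0, -1), c(50, 50))
  feats <- cbind(feats, 0)
  cr <- structure(list(labels = c(1, 1, 1, 1, 2), k = 2,
                       representatives = NA, silhouette = NA,
                       perplexity = NA, embedding = NULL),
                  class = "ClusterResult")
  # medoid logic mirrored from cluster_conformers
  reps <- vapply(1:2, function(ci) {
    members <- which(cr$labels == ci)
    if (length(members) == 1) return(members)
    dm <- as.matrix(dist(feats[members, , drop = FALSE]))
    members[which.min(rowSums(dm))]
  }, integer(1))
  expect_equal(reps[1], 3)  # the central point
  expect_equal(reps[2], 5)  # the singleton is its own representative
})

test_that("perplexity scan reports a silhouette per requested perplexity", {
  set.seed(66)
  feats <- rbind(matrix(stats::rnorm(40, 0), ncol = 4),
                 matrix(stats::rnorm(40, 12), ncol = 4))
  scan <- perplexity_scan(feats, k = 2, perplexities = c(3, 5), seed = 4,
                          max_iter = 120)
  expect_equal(scan$perplexity, c(3, 5))
  expect_true(all(scan$silhouette >= -1 & scan$silhouette <= 1))
})
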