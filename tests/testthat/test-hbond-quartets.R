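# two guanine base fragments with N1 of the first at distance d from O6 of
# the second (other atoms pushed out of range)
two_guanine_probe <- function(d) {
  micro_model(
    atom("N1", "N", "DG", 1, "A", c(0, 0, 0)),
    atom("N2", "N", "DG", 1, "A", c(-8, 0, 0)),
    atom("O6", "O", "DG", 2, "B", c(d, 0, 0)),
    atom("N7", "N", "DG", 2, "B", c(d + 8, 0, 0)))
}

test_that("hydrogen-bond criterion boundary behaviour", {
  hb <- detect_hbonds(two_guanine_probe(2.9))
  expect_equal(nrow(hb), 1)
  expect_equal(hb$kind, "hoogsteen_GG")
  expect_equal(hb$distance, 2.9, tolerance = 1e-12)
  expect_equal(nrow(detect_hbonds(two_guanine_probe(3.8))), 0)
  # protein-only frame with no acceptor in range
  lone <- micro_model(atom("N", "N", "ALA", 1, "A", c(0, 0, 0)),
                      atom("O", "O", "ALA", 2, "A", c(9, 0, 0)))
  expect_equal(nrow(detect_hbonds(lone)), 0)
})

test_that("detector equals the brute-force all-pairs oracle on fixtures", {
  for (frame in list(fx("gq3"), fx("gq_rna"), fx("complex_groove"))) {
    hb <- detect_hbonds(frame)
    orc <- oracle_hbonds(frame)
    expect_equal(nrow(hb), nrow(orc))
    key <- function(df) sort(paste(df$donor_idx, df$acceptor_idx))
    expect_identical(key(hb), key(orc))
  }
})

test_that("quartet detection finds the constructed layers", {
  qa <- detect_quartets(fx("gq3"))
  expect_length(qa$quartets, 3)
  expect_identical(as.integer(table(qa$layer_of)), rep(4L, 3))
  # layers ordered along the axis
  proj <- qa$centroids %*% qa$axis
  expect_true(all(diff(proj) > 0))

  # single ideal quartet: one layer, 8 incident Hoogsteen bonds
  qa1 <- detect_quartets(fx("gq1"))
  expect_length(qa1$quartets, 1)
  hb <- detect_hbonds(fx("gq1"))
  expect_equal(sum(hb$kind == "hoogsteen_GG"), 8)

  # distant collinear guanines: no bonds, empty assignment, no error
  g <- gqbind:::guanine_template()
  rows <- list()
  for (i in 1:4) for (a in rownames(g)[1:11]) {
    rows[[length(rows) + 1]] <- atom(a, substr(gsub("[0-9']", "", a), 1, 1),
                                     "DG", i, "A", g[a, ] + c(20 * i, 0, 0))
  }
  far <- do.call(micro_model, rows)
  expect_length(detect_quartets(far)$quartets, 0)
})

test_that("quartet detection is invariant under rigid motion and atom permutation", {
  qa0 <- detect_quartets(fx("gq3"))
  sig <- function(qa) {
    lapply(qa$quartets, function(q) {
      o <- order(q$chain, q$resid); paste(q$chain[o], q$resid[o])
    })
  }
  set.seed(31)
  for (rep in 1:3) {
    ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
    rot <- rigid_transform_model(fx("gq3"), ax, stats::runif(1, 0, 2 * pi),
                                 stats::runif(3, -30, 30))
    qa <- detect_quartets(rot)
    expect_length(qa$quartets, 3)
    expect_setequal(unlist(sig(qa)), unlist(sig(qa0)))
  }
  perm <- fx("gq3")
  set.seed(32)
  p <- sample(nrow(perm$atoms))
  perm$atoms <- perm$atoms[p, ]
  perm <- structure_model(perm$atoms)
  qa <- detect_quartets(perm)
  expect_length(qa$quartets, 3)
  expect_setequal(unlist(sig(qa)), unlist(sig(qa0)))
})

test_that("per-frame quartet bond series tracks the frame-0 assignment", {
  gq <- fx("gq3")
  qa <- detect_quartets(gq)
  static <- ensemble(gq, array(rep(coord_matrix(gq), each = 4),
                               dim = c(4, n_atoms(gq), 3)))
  s <- quartet_hbond_series(static, qa)
  expect_identical(s$per_frame_quartet_hbonds, rep(24L, 4))
  expect_equal(s$mean_quartet, 24)
  expect_equal(s$label, "stable")

  one <- quartet_hbond_series(ensemble(gq), qa)
  expect_length(one$per_frame_quartet_hbonds, 1)
  expect_equal(one$mean_quartet, one$per_frame_quartet_hbonds[1])

  # unfolding: non-increasing trend after window-5 smoothing
  traj <- make_unfolding_trajectory(gq, n_frames = 30,
                                    strand_displacement_per_frame = 0.5,
                                    noise_sigma = 0.1, seed = 13)
  su <- quartet_hbond_series(traj, qa)
  sm <- stats::filter(su$per_frame_quartet_hbonds, rep(1 / 5, 5))
  sm <- sm[!is.na(sm)]
  # non-increasing trend, allowing single-bond thermal flicker in the window
  expect_true(all(diff(sm) <= 0.4))
  raw <- su$per_frame_quartet_hbonds
  expect_gte(raw[1], 22)          # intact stem at the undisplaced frame
  expect_lte(raw[length(raw)], 13)  # one extruded column severs 12 bonds
  expect_equal(su$label, "unstable")

  expect_error(quartet_hbond_series(ensemble(gq),
                                    structure(list(quartets = list()),
                                              class = "QuartetAssignment")),
               "empty")
})

test_that("stability classification uses 'cutoff or less' semantics and is monotone", {
  mk <- function(vals) {
    structure(list(per_frame_quartet_hbonds = vals,
                   per_frame_intermolecular_hbonds = rep(0L, length(vals)),
                   mean_quartet = mean(vals), mean_intermolecular = 0),
              class = "StabilitySeries")
  }
  expect_equal(classify_stability(mk(c(24, 24))), "stable")
  expect_equal(classify_stability(mk(c(15, 15))), "unstable")
  expect_equal(classify_stability(mk(c(15, 15.4, 15.2))), "stable")
  # raising the cutoff never converts unstable -> stable
  set.seed(77)
  for (rep in 1:20) {
    s <- mk(sample(0:24, 6, replace = TRUE))
    labs <- vapply(10:20, function(ct) classify_stability(s, ct), character(1))
    expect_true(all(diff(labs == "unstable") >= 0))
  }
})

test_that("stability scatter has one row per complex with consistent labels", {
  gq <- fx("gq3")
  qa <- detect_quartets(gq)
  stable_traj <- make_unfolding_trajectory(gq, 5, 0, 0.05, seed = 41)
  unstable_traj <- make_unfolding_trajectory(gq, 12, 1.5, 0.05, seed = 42)
  res <- list(a = quartet_hbond_series(stable_traj, qa),
              b = quartet_hbond_series(stable_traj, qa),
              c = quartet_hbond_series(stable_traj, qa),
              d = quartet_hbond_series(unstable_traj, qa))
  tab <- stability_scatter(res)
  expect_equal(nrow(tab), 4)
  expect_equal(sum(tab$label == "unstable"), 1)
  expect_equal(tab$complex_id[tab$label == "unstable"], "d")
  # apo GQ: no protein, zero intermolecular bonds
  expect_true(all(tab$mean_intermolecular == 0))
})
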