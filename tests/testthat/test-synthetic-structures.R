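test_that("idealized GQ builder meets its geometric contract", {
  gq <- fx("gq3")
  roles <- classify_residues(gq)
  expect_equal(sum(roles$role == "guanine"), 12)   # 3 layers x 4 strands
  expect_equal(sum(gq$atoms$resname == "K"), 2)    # ions between 3 quartets
  expect_equal(length(unique(gq$atoms$chain[
    gq$atoms$chain %in% LETTERS[1:4]])), 4)

  qa <- detect_quartets(gq)
  expect_length(qa$quartets, 3)
  for (q in qa$quartets) expect_equal(nrow(q), 4)

  # single-layer spec: no inter-plane gap, no ions
  expect_equal(sum(fx("gq1")$atoms$resname == "K"), 0)
  expect_length(detect_quartets(fx("gq1"))$quartets, 1)
})

test_that("every molecularity/kind passes quartet detection with 8 bonds per layer", {
  for (nm in c("gq3", "gq_uni", "gq_rna")) {
    gq <- fx(nm)
    qa <- detect_quartets(gq)
    expect_length(qa$quartets, 3)
    hb <- detect_hbonds(gq)
    hb <- hb[hb$kind == "hoogsteen_GG", ]
    dk <- paste(hb$donor_chain, hb$donor_resid, sep = ":")
    ak <- paste(hb$acceptor_chain, hb$acceptor_resid, sep = ":")
    for (l in 1:3) {
      within <- !is.na(qa$layer_of[dk]) & !is.na(qa$layer_of[ak]) &
        qa$layer_of[dk] == l & qa$layer_of[ak] == l
      expect_equal(sum(within), 8)
    }
  }
})

test_that("builders are bit-reproducible under a fixed seed", {
  expect_identical(build_gq(gq_spec(), seed = 9), build_gq(gq_spec(), seed = 9))
  a <- make_peptide_conformers("GRGF", n = 3, seed = 5)
  b <- make_peptide_conformers("GRGF", n = 3, seed = 5)
  expect_identical(a$coords, b$coords)
})

test_that("peptide conformer generator respects its contract", {
  pep <- fx("pep5")
  expect_equal(pep$frame_count, 5)
  expect_equal(sum(pep$topology$atoms$name == "CA"), 53)
  # self-avoidance: non-adjacent C-alpha pairs at least 4 A apart
  ca <- which(pep$topology$atoms$name == "CA")
  for (f in 1:2) {
    d <- as.matrix(dist(pep$coords[f, ca, ]))
    d[abs(row(d) - col(d)) <= 1] <- Inf
    expect_gte(min(d), 4.0)
  }
  expect_equal(make_peptide_conformers("GR", n = 1, seed = 1)$frame_count, 1)
  expect_error(make_peptide_conformers("GR", n = 0, seed = 1), "n must be")
  expect_error(make_peptide_conformers("", n = 1, seed = 1), "non-empty")
  expect_error(make_peptide_conformers("GZB", n = 1, seed = 1), "unknown")
})

test_that("planted poses are mode-pure", {
  gq <- fx("gq3")
  pep <- fx("pep5")
  for (s in 1:4) {
    conf <- get_frame(pep, s)
    for (m in c("end_stack", "groove", "loop")) {
      cpx <- place_peptide(gq, conf, pose_spec(m), seed = 200 + s)
      qa <- detect_quartets(cpx)
      flags <- classify_residue_modes(cpx, qa)
      planted <- attr(cpx, "pose")$peptide_residue_index
      expect_true(flags[[m]][planted],
                  label = paste(m, "flag for planted residue, seed", s))
    }
    cpx <- place_peptide(gq, conf, pose_spec("far"), seed = 200 + s)
    qa <- detect_quartets(cpx)
    flags <- classify_residue_modes(cpx, qa)
    expect_false(any(flags$end_stack | flags$groove | flags$loop))
  }
})

test_that("placement respects the steric floor and errors when impossible", {
  cpx <- fx("complex_groove")
  roles <- gqbind:::atom_roles(cpx)
  xyz <- coord_matrix(cpx)
  d <- gqbind:::cross_dist(xyz[roles == "protein", ],
                           xyz[roles != "protein", ])
  expect_gte(min(d), 2.0)

  # unsatisfiable pose: target distance below the steric floor
  expect_error(
    place_peptide(fx("gq3"), get_frame(fx("pep5"), 1),
                  pose_spec("groove", target_distance = 1.0),
                  seed = 1, max_tries = 25),
    "placement failed")
})

test_that("unfolding generator displaces one strand column progressively", {
  gq <- fx("gq3")
  traj <- make_unfolding_trajectory(gq, n_frames = 10,
                                    strand_displacement_per_frame = 1.0,
                                    noise_sigma = 0, seed = 2)
  # frame 1 is the undisplaced base state
  expect_lt(max(abs(traj$coords[1, , ] - coord_matrix(gq))), 1e-9)
  # displaced atoms move ~ (f-1) * 1.0 A
  moved <- sqrt(rowSums((traj$coords[6, , ] - traj$coords[1, , ])^2))
  expect_equal(sort(unique(round(moved, 1))), c(0, 5))
  expect_error(make_unfolding_trajectory(gq, n_frames = 1), "n_frames")
  expect_error(make_unfolding_trajectory(gq, n_frames = 5, strand = "X"),
               "absent")
})
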