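test_that("loop contacts count any loop-nucleotide atom, others stay off", {
  gq <- fx("gq3")
  at <- gq$atoms
  # a thymine methyl carbon (C7) on a loop residue
  c7 <- which(at$resname == "DT" & at$name == "C7")[1]
  expect_false(is.na(c7))
  pos <- as.numeric(at[c7, c("x", "y", "z")])
  # probe residue placed 3.9 A beyond C7, radially away from everything else
  ctr <- colMeans(coord_matrix(gq))
  dirv <- pos - ctr; dirv <- dirv / sqrt(sum(dirv^2))
  probe <- at[1, ]
  probe$name <- "CB"; probe$element <- "C"; probe$resname <- "ALA"
  probe$resid <- 1; probe$chain <- "P"
  probe[c("x", "y", "z")] <- as.list(pos + 3.9 * dirv)
  cpx <- structure_model(rbind(at, probe))
  qa <- detect_quartets(cpx)
  flags <- classify_residue_modes(cpx, qa)
  expect_equal(nrow(flags), 1)
  expect_true(flags$loop)
  expect_false(flags$end_stack)
  expect_false(flags$groove)
})

test_that("interaction matrix normalizes by amino-acid composition", {
  gq <- fx("gq1")
  at <- gq$atoms
  # pick one quartet guanine and its groove-exposed N3 atom
  g <- which(at$resname == "DG" & at$name == "N3")[1]
  pos <- as.numeric(at[g, c("x", "y", "z")])
  ctr <- colMeans(coord_matrix(gq))
  dirv <- pos - ctr; dirv <- dirv / sqrt(sum(dirv^2))
  mk_res <- function(resname, resid, offset) {
    r <- at[1, ]
    r$name <- "CB"; r$element <- "C"; r$resname <- resname
    r$resid <- resid; r$chain <- "P"
    r[c("x", "y", "z")] <- as.list(pos + offset * dirv)
    r
  }
  # two Arg: one in contact (3 A), one far (30 A)
  cpx <- structure_model(rbind(at, mk_res("ARG", 1, 3.0), mk_res("ARG", 2, 30)))
  ens2 <- ensemble(cpx, array(rep(coord_matrix(cpx), each = 2),
                              dim = c(2, n_atoms(cpx), 3)))
  qa <- detect_quartets(cpx)
  m <- interaction_matrix(ens2, qa, mode = "groove")
  # 2 residue-frame contacts (1 residue x 2 frames) / 2 Arg in sequence = 1
  gcol <- grep("DG", colnames(m))
  expect_equal(sum(m["ARG", ]), 1.0)
  expect_equal(rownames(m), "ARG")  # absent types omitted, no 0/0 rows
  expect_equal(unname(attr(m, "composition")["ARG"]), 2)

  expect_error(interaction_matrix(ens2, qa, mode = "bogus"))
})

test_that("far-pose ensembles give all-zero matrices of every mode", {
  gq <- fx("gq3")
  cpx <- place_peptide(gq, get_frame(fx("pep5"), 2), pose_spec("far"),
                       seed = 5)
  qa <- detect_quartets(cpx)
  ens1 <- ensemble(cpx)
  for (m in c("end_stack", "groove", "loop")) {
    expect_true(all(interaction_matrix(ens1, qa, mode = m) == 0))
  }
})

test_that("matrix entries are monotone in the cutoff and match the per-frame classifier", {
  cpx <- fx("complex_groove")
  qa <- detect_quartets(cpx)
  ens1 <- ensemble(cpx)
  for (m in c("end_stack", "groove", "loop")) {
    m4 <- interaction_matrix(ens1, qa, mode = m, cutoff = 4)
    m5 <- interaction_matrix(ens1, qa, mode = m, cutoff = 5)
    expect_true(all(unclass(m5) - unclass(m4) >= -1e-12))
  }
  # 1-frame consistency: a residue type has nonzero groove row iff some
  # residue of that type carries the groove flag
  flags <- classify_residue_modes(cpx, qa)
  mg <- interaction_matrix(ens1, qa, mode = "groove")
  for (tt in rownames(mg)) {
    has_flag <- any(flags$groove[flags$resname == tt])
    expect_equal(any(mg[tt, ] > 0), has_flag, label = tt)
  }
})

test_that("mode contact rules agree with a brute-force distance oracle", {
  cpx <- fx("complex_groove")
  qa <- detect_quartets(cpx)
  flags <- classify_residue_modes(cpx, qa)
  at <- cpx$atoms
  akey <- paste(at$chain, at$resid, sep = ":")
  xyz <- coord_matrix(cpx)
  o6 <- which(!is.na(qa$layer_of[akey]) & at$name == "O6")
  groove <- which(!is.na(qa$layer_of[akey]) &
                    at$name %in% gqbind:::groove_atom_set())
  roles <- gqbind:::atom_roles(cpx)
  loops <- which(roles == "loop_nucleotide")
  for (i in seq_len(nrow(flags))) {
    ri <- which(at$chain == flags$chain[i] & at$resid == flags$resid[i])
    mind <- function(set) {
      best <- Inf
      for (a in ri) for (b in set) {
        best <- min(best, sqrt(sum((xyz[a, ] - xyz[b, ])^2)))
      }
      best
    }
    expect_equal(flags$end_stack[i], mind(o6) <= 4.0)
    expect_equal(flags$groove[i], mind(groove) <= 4.0)
    expect_equal(flags$loop[i], mind(loops) <= 4.0)
  }
})
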