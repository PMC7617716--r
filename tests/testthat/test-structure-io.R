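test_that("multi-model PDB round-trip preserves metadata and coordinates", {
  traj <- make_unfolding_trajectory(fx("gq3"), n_frames = 3,
                                    strand_displacement_per_frame = 0,
                                    noise_sigma = 0.1, seed = 21)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(traj, f)
  back <- read_structure(f)
  expect_equal(back$frame_count, 3)
  expect_equal(n_atoms(back), n_atoms(traj))
  expect_lte(max(abs(back$coords - traj$coords)), 0.001)
  cols <- c("name", "resname", "resid", "chain")
  expect_identical(back$topology$atoms[cols], traj$topology$atoms[cols])
  lines <- readLines(f)
  expect_equal(sum(startsWith(lines, "MODEL")), 3)
  expect_equal(sum(startsWith(lines, "ENDMDL")), 3)
})

test_that("single-model files read as one frame with atom order preserved", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(ensemble(fx("gq1")), f)
  ens <- read_structure(f)
  expect_equal(ens$frame_count, 1)
  expect_identical(ens$topology$atoms$name, fx("gq1")$atoms$name)
})

test_that("round-trip is identity on random small models (property)", {
  set.seed(404)
  for (rep in 1:5) {
    nres <- sample(2:6, 1)
    rows <- lapply(seq_len(nres * 2), function(i) {
      atom(name = c("CA", "CB")[(i %% 2) + 1], element = "C",
           resname = sample(c("GLY", "ALA", "ARG"), 1),
           resid = (i + 1) %/% 2, chain = "A",
           xyz = round(stats::runif(3, -99, 99), 3))
    })
    rows <- lapply(seq_along(rows), function(i) {
      r <- rows[[i]]; r$name <- paste0(r$name, (i %% 2) + 1); r
    })
    m <- do.call(micro_model, rows)
    f <- withr::local_tempfile(fileext = ".pdb")
    write_structure(ensemble(m), f)
    back <- read_structure(f)
    expect_lte(max(abs(coord_matrix(get_frame(back, 1)) - coord_matrix(m))),
               0.001)
    expect_identical(back$topology$atoms$resname, m$atoms$resname)
  }
})

test_that("malformed and inconsistent PDB input is rejected with diagnostics", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(ensemble(fx("gq1")), f)
  lines <- readLines(f)
  bad <- lines
  i <- which(startsWith(bad, "ATOM"))[3]
  substr(bad[i], 31, 38) <- "  xx.xxx"
  writeLines(bad, f)
  expect_error(read_structure(f), "line")

  # MODEL blocks with differing atom counts
  traj <- make_unfolding_trajectory(fx("gq1"), n_frames = 2,
                                    strand_displacement_per_frame = 0,
                                    noise_sigma = 0, seed = 1)
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(traj, f2)
  lines <- readLines(f2)
  drop <- which(startsWith(lines, "ATOM"))
  writeLines(lines[-drop[length(drop)]], f2)
  expect_error(read_structure(f2), "topology error")
})

test_that("writer rejects empty and unencodable inputs", {
  expect_error(write_structure(list(), tempfile()))
  ens <- ensemble(fx("gq1"))
  ens$topology$atoms$chain[1] <- "AB"
  expect_error(write_structure(ens, tempfile()), "format error")
})

test_that("residue classification is total and follows the synonym table", {
  roles <- classify_residues(fx("gq3"))
  expect_equal(nrow(roles),
               nrow(unique(fx("gq3")$atoms[c("chain", "resid")])))
  expect_setequal(unique(roles$role), c("guanine", "loop_nucleotide", "ion"))
  expect_equal(sum(roles$role == "guanine"), 12)
  expect_equal(sum(roles$role == "ion"), 2)
  expect_equal(roles$role[roles$resname == "DT"][1], "loop_nucleotide")
  expect_equal(roles$role[roles$resname == "K"][1], "ion")

  m <- micro_model(atom("X1", "X", "WAT", 1, "A", c(0, 0, 0)))
  expect_warning(r <- classify_residues(m), "other")
  expect_equal(r$role, "other")

  # synonym edits change classification only for the edited names
  syn <- default_synonyms()
  syn$ion <- c(syn$ion, "WAT")
  r2 <- classify_residues(m, syn)
  expect_equal(r2$role, "ion")
  r3 <- classify_residues(fx("gq3"), syn)
  expect_identical(r3$role, roles$role)
})
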