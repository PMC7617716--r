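test_that("lifetime fractions and the persistence filter behave as specified", {
  cpx <- fx("complex_groove")
  # static 4-frame ensemble: every existing contact lives 100% of frames
  ens4 <- ensemble(cpx, array(rep(coord_matrix(cpx), each = 4),
                              dim = c(4, n_atoms(cpx), 3)))
  cm <- contact_map(ens4)
  expect_true(all(cm$values %in% c(0, 1)))
  expect_gt(sum(cm$values), 0)

  # a contact present in 1 of 200 frames (0.5%) is filtered to 0
  base <- coord_matrix(cpx)
  away <- base
  prot <- gqbind:::atom_roles(cpx) == "protein"
  away[prot, 1] <- away[prot, 1] + 500
  coords <- array(rep(away, each = 200), dim = c(200, nrow(base), 3))
  coords[1, , ] <- base
  cm200 <- contact_map(ensemble(cpx, coords))
  expect_true(all(cm200$values == 0))
  # the raw count still records the single frame
  expect_equal(max(cm200$counts), 1)

  # closed-interval boundary: a pair at exactly the cutoff counts
  m <- micro_model(atom("CB", "C", "ALA", 1, "P", c(0, 0, 0)),
                   atom("N1", "N", "DG", 1, "A", c(4.0, 0, 0)))
  cm1 <- contact_map(ensemble(m), cutoff = 4.0)
  expect_equal(unname(cm1$values[1, 1]), 1)
  m2 <- micro_model(atom("CB", "C", "ALA", 1, "P", c(0, 0, 0)),
                    atom("N1", "N", "DG", 1, "A", c(4.0001, 0, 0)))
  expect_equal(unname(contact_map(ensemble(m2))$values[1, 1]), 0)

  expect_error(contact_map(ensemble(fx("gq3"))), "protein")
})

test_that("map values equal the brute-force per-pair oracle", {
  cpx <- fx("complex_groove")
  traj <- make_unfolding_trajectory(cpx, 3, 0, 0.3, seed = 8)
  cm <- contact_map(traj, min_lifetime = 0)
  roles <- gqbind:::atom_roles(cpx)
  at <- cpx$atoms
  prot_res <- unique(at[roles == "protein", c("chain", "resid")])
  nuc_res <- unique(at[roles %in% c("guanine", "loop_nucleotide"),
                       c("chain", "resid")])
  set.seed(12)
  for (rep in 1:25) {
    i <- sample(nrow(prot_res), 1); j <- sample(nrow(nuc_res), 1)
    n_hit <- sum(vapply(1:3, function(f) {
      oracle_contact(get_frame(traj, f),
                     paste(prot_res$chain[i], prot_res$resid[i], sep = ":"),
                     paste(nuc_res$chain[j], nuc_res$resid[j], sep = ":"),
                     4.0)
    }, logical(1)))
    expect_equal(unname(cm$values[i, j]), n_hit / 3)
  }
})

test_that("merging pools exact frame counts and re-applies the filter", {
  cpx <- fx("complex_groove")
  t1 <- make_unfolding_trajectory(cpx, 4, 0, 0.2, seed = 1)
  t2 <- make_unfolding_trajectory(cpx, 4, 0, 0.2, seed = 2)
  t3 <- make_unfolding_trajectory(cpx, 4, 0, 0.2, seed = 3)
  m1 <- contact_map(t1); m2 <- contact_map(t2); m3 <- contact_map(t3)

  # idempotence on identical inputs
  same <- merge_maps(list(m1, m1))
  expect_equal(same$values, m1$values)
  expect_equal(same$frames, 8)

  # 1.0 + 0.0 at equal frames -> 0.5
  base <- coord_matrix(cpx)
  away <- base
  prot <- gqbind:::atom_roles(cpx) == "protein"
  away[prot, 1] <- away[prot, 1] + 500
  mA <- contact_map(ensemble(cpx, array(rep(base, each = 2),
                                        dim = c(2, nrow(base), 3))))
  mB <- contact_map(ensemble(cpx, array(rep(away, each = 2),
                                        dim = c(2, nrow(base), 3))))
  AB <- merge_maps(list(mA, mB))
  expect_true(all(abs(AB$values[mA$values == 1] - 0.5) < 1e-12))

  # associativity / order-independence (exact integer pooling)
  left <- merge_maps(list(merge_maps(list(m1, m2)), m3))
  right <- merge_maps(list(m1, merge_maps(list(m2, m3))))
  shuffled <- merge_maps(list(m3, m1, m2))
  expect_equal(left$values, right$values)
  expect_equal(left$values, shuffled$values)
  expect_equal(left$frames, 12)

  # pooling divisor: 5 maps x 4 frames
  many <- merge_maps(list(m1, m2, m3, m1, m2))
  expect_equal(many$frames, 20)

  bad <- m2
  rownames(bad$counts)[1] <- "XXX"
  expect_error(merge_maps(list(m1, bad)), "labels")
})
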