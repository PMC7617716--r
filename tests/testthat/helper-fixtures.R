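# Shared fixtures, built once per test run.

fx <- local({
  cache <- new.env(parent = emptyenv())
  function(name) {
    if (!is.null(cache[[name]])) return(cache[[name]])
    cache[[name]] <- switch(name,
      gq3 = build_gq(gq_spec(n_quartets = 3, n_strands = 4), seed = 1),
      gq1 = build_gq(gq_spec(n_quartets = 1, n_strands = 4), seed = 1),
      gq_uni = build_gq(gq_spec(n_strands = 1), seed = 2),
      gq_rna = build_gq(gq_spec(n_strands = 4, nucleic_kind = "RNA"),
                        seed = 3),
      pep5 = make_peptide_conformers(rgg_like_sequence(), n = 5, seed = 7),
      complex_groove = place_peptide(fx("gq3"), get_frame(fx("pep5"), 1),
                                     pose_spec("groove"), seed = 11),
      stop("unknown fixture ", name))
    cache[[name]]
  }
})

# Independent brute-force hydrogen-bond oracle: plain double loop over the
# donor/acceptor tables with no vectorization shared with the implementation.
oracle_hbonds <- function(frame, max_dist = 3.5) {
  at <- frame$atoms
  roles <- gqbind:::atom_roles(frame)
  tab <- gqbind:::donor_acceptor_tables()
  is_donor <- function(i) {
    if (roles[i] == "protein") {
      at$name[i] == "N" ||
        at$name[i] %in% tab$side_don[[at$resname[i]]]
    } else if (roles[i] == "guanine") {
      at$name[i] %in% c("N1", "N2")
    } else if (roles[i] == "loop_nucleotide") {
      at$name[i] %in% tab$nuc_don[[at$resname[i]]]
    } else FALSE
  }
  is_acceptor <- function(i) {
    if (roles[i] == "protein") {
      at$name[i] == "O" ||
        at$name[i] %in% tab$side_acc[[at$resname[i]]]
    } else if (roles[i] == "guanine") {
      at$name[i] %in% c("O6", "N7", "N3") ||
        at$name[i] %in% tab$nuc_acc$backbone
    } else if (roles[i] == "loop_nucleotide") {
      at$name[i] %in% tab$nuc_acc[[at$resname[i]]] ||
        at$name[i] %in% tab$nuc_acc$backbone
    } else FALSE
  }
  xyz <- coord_matrix(frame)
  out <- NULL
  for (i in seq_len(nrow(at))) {
    if (!is_donor(i) || at$element[i] == "H") next
    for (j in seq_len(nrow(at))) {
      if (i == j || !is_acceptor(j) || at$element[j] == "H") next
      if (at$chain[i] == at$chain[j] && at$resid[i] == at$resid[j]) next
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (d <= max_dist) {
        out <- rbind(out, data.frame(donor_idx = i, acceptor_idx = j,
                                     distance = d))
      }
    }
  }
  out
}

# Brute-force residue-residue contact oracle (heavy atoms, closed interval).
oracle_contact <- function(frame, key_a, key_b, cutoff) {
  at <- frame$atoms
  xyz <- coord_matrix(frame)
  ia <- which(paste(at$chain, at$resid, sep = ":") == key_a &
                at$element != "H")
  ib <- which(paste(at$chain, at$resid, sep = ":") == key_b &
                at$element != "H")
  for (i in ia) for (j in ib) {
    if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= cutoff) return(TRUE)
  }
  FALSE
}

# A minimal hand-built model: selected atoms at explicit positions.
micro_model <- function(...) {
  rows <- list(...)
  at <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    data.frame(serial = i, name = r$name, element = r$element,
               resname = r$resname, resid = r$resid, chain = r$chain,
               x = r$xyz[1], y = r$xyz[2], z = r$xyz[3],
               stringsAsFactors = FALSE)
  }))
  structure_model(at)
}

atom <- function(name, element, resname, resid, chain, xyz) {
  list(name = name, element = element, resname = resname, resid = resid,
       chain = chain, xyz = xyz)
}

rigid_transform_model <- function(model, axis, angle, shift) {
  R <- gqbind:::rotation_matrix(axis, angle)
  set_coords(model, sweep(coord_matrix(model) %*% t(R), 2, shift, "+"))
}
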