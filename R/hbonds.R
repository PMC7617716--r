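#' Hydrogen-bond detection criterion
#'
#' Geometric criterion in the MD-analysis convention: donor-acceptor heavy
#' atom distance at most `donor_acceptor_max`, and, when hydrogens are
#' present on the donor, a hydrogen-donor-acceptor angle of at most
#' `h_angle_max`. Fixtures in this package carry no hydrogens, so the
#' heavy-atom distance-only fallback (`heavy_atom_fallback = TRUE`) is the
#' tested default.
#'
#' @param donor_acceptor_max maximum donor-acceptor distance, Angstrom.
#' @param h_angle_max maximum H-donor-acceptor angle, degrees.
#' @param heavy_atom_fallback when a donor has no resolvable hydrogen, accept
#'   the bond on distance alone (`TRUE`) or reject it (`FALSE`).
#' @return an `HBondCriterion` list.
#' @export
hbond_criterion <- function(donor_acceptor_max = 3.5, h_angle_max = 30,
                            heavy_atom_fallback = TRUE) {
  stopifnot(donor_acceptor_max > 0, h_angle_max > 0, h_angle_max <= 90)
  structure(list(donor_acceptor_max = donor_acceptor_max,
                 h_angle_max = h_angle_max,
                 heavy_atom_fallback = isTRUE(heavy_atom_fallback)),
            class = "HBondCriterion")
}

# Fixed per-residue donor/acceptor atom tables. Guanine donates from its
# Watson-Crick edge (N1, N2) and accepts on the Hoogsteen edge (O6, N7) plus
# N3; protein backbone N donates and O accepts; polar sidechains as listed.
donor_acceptor_tables <- function() {
  prot_bb_don <- "N"; prot_bb_acc <- "O"
  side_don <- list(
    ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2", SER = "OG",
    THR = "OG1", TYR = "OH", LYS = "NZ", HIS = c("ND1", "NE2"), TRP = "NE1")
  side_acc <- list(
    ASN = "OD1", GLN = "OE1", SER = "OG", THR = "OG1", TYR = "OH",
    ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), HIS = c("ND1", "NE2"))
  nuc_don <- list(
    guanine = c("N1", "N2"),
    DT = "N3", THY = "N3", U = "N3", URA = "N3", DU = "N3",
    DA = "N6", A = "N6", ADE = "N6", RA = "N6", RU = "N3")
  nuc_acc <- list(
    guanine = c("O6", "N7", "N3"),
    DT = c("O2", "O4"), THY = c("O2", "O4"),
    U = c("O2", "O4"), URA = c("O2", "O4"), DU = c("O2", "O4"),
    DA = c("N1", "N3", "N7"), A = c("N1", "N3", "N7"),
    RA = c("N1", "N3", "N7"), RU = c("O2", "O4"),
    backbone = c("O1P", "O2P", "OP1", "OP2", "O3'", "O5'", "O2'", "O4'"))
  list(prot_bb_don = prot_bb_don, prot_bb_acc = prot_bb_acc,
       side_don = side_don, side_acc = side_acc,
       nuc_don = nuc_don, nuc_acc = nuc_acc)
}

# Index vectors of donor / acceptor heavy atoms for a model.
.donor_acceptor_idx <- function(model, synonyms = default_synonyms()) {
  at <- model$atoms
  roles <- atom_roles(model, synonyms)
  tab <- donor_acceptor_tables()
  don <- logical(nrow(at)); acc <- logical(nrow(at))

  is_prot <- roles == "protein"
  don[is_prot & at$name == tab$prot_bb_don] <- TRUE
  acc[is_prot & at$name == tab$prot_bb_acc] <- TRUE
  for (rn in names(tab$side_don)) {
    don[is_prot & at$resname == rn & at$name %in% tab$side_don[[rn]]] <- TRUE
  }
  for (rn in names(tab$side_acc)) {
    acc[is_prot & at$resname == rn & at$name %in% tab$side_acc[[rn]]] <- TRUE
  }

  is_gua <- roles == "guanine"
  don[is_gua & at$name %in% tab$nuc_don$guanine] <- TRUE
  acc[is_gua & at$name %in% tab$nuc_acc$guanine] <- TRUE
  is_nuc <- roles %in% c("guanine", "loop_nucleotide")
  for (rn in setdiff(names(tab$nuc_don), "guanine")) {
    don[is_nuc & at$resname == rn & at$name %in% tab$nuc_don[[rn]]] <- TRUE
  }
  for (rn in setdiff(names(tab$nuc_acc), c("guanine", "backbone"))) {
    acc[is_nuc & at$resname == rn & at$name %in% tab$nuc_acc[[rn]]] <- TRUE
  }
  acc[is_nuc & at$name %in% tab$nuc_acc$backbone] <- TRUE

  don[at$element == "H"] <- FALSE
  acc[at$element == "H"] <- FALSE
  list(donors = which(don), acceptors = which(acc), roles = roles)
}

#' Detect hydrogen bonds in one frame
#'
#' All donor-acceptor pairs from the fixed per-residue tables (see
#' `donor_acceptor_tables()`) within the distance criterion, excluding pairs
#' within one residue. When the structure carries hydrogens, a candidate is
#' additionally required to have an H-donor-acceptor angle within
#' `criterion$h_angle_max` for at least one hydrogen bound to the donor;
#' without hydrogens the heavy-atom fallback applies. Bond kinds:
#' `hoogsteen_GG` (guanine N1/N2 donor to O6/N7 acceptor of a different
#' guanine), `intermolecular` (protein to nucleic in either direction),
#' `other`.
#'
#' @param frame a `StructureModel`.
#' @param criterion an [hbond_criterion()].
#' @param synonyms residue-name synonym table.
#' @return data.frame with one row per bond: donor/acceptor atom indices,
#'   `donor_chain`, `donor_resid`, `donor_resname`, `donor_name`, the same
#'   for the acceptor, `distance` and `kind`. Zero rows when nothing bonds.
#' @examples
#' q <- build_gq(gq_spec(n_quartets = 1), seed = 1)
#' hb <- detect_hbonds(q)
#' table(hb$kind)  # 8 Hoogsteen bonds in a single quartet
#' @export
detect_hbonds <- function(frame, criterion = hbond_criterion(),
                          synonyms = default_synonyms()) {
  stopifnot(inherits(frame, "StructureModel"))
  da <- .donor_acceptor_idx(frame, synonyms)
  empty <- data.frame(
    donor_idx = integer(0), acceptor_idx = integer(0),
    donor_chain = character(0), donor_resid = integer(0),
    donor_resname = character(0), donor_name = character(0),
    acceptor_chain = character(0), acceptor_resid = integer(0),
    acceptor_resname = character(0), acceptor_name = character(0),
    distance = numeric(0), kind = character(0), stringsAsFactors = FALSE)
  if (!length(da$donors) || !length(da$acceptors)) return(empty)

  at <- frame$atoms
  xyz <- coord_matrix(frame)
  D <- cross_dist(xyz[da$donors, , drop = FALSE],
                  xyz[da$acceptors, , drop = FALSE])
  hit <- which(D <= criterion$donor_acceptor_max, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  di <- da$donors[hit[, 1]]
  ai <- da$acceptors[hit[, 2]]
  same_res <- at$chain[di] == at$chain[ai] & at$resid[di] == at$resid[ai]
  keep <- !same_res
  di <- di[keep]; ai <- ai[keep]
  dist_v <- D[hit][keep]
  if (!length(di)) return(empty)

  # hydrogen-angle filter where hydrogens are resolvable on the donor
  has_h <- any(at$element == "H")
  if (has_h) {
    hpos <- which(at$element == "H")
    keep2 <- vapply(seq_along(di), function(i) {
      d <- di[i]
      hs <- hpos[at$chain[hpos] == at$chain[d] & at$resid[hpos] == at$resid[d]]
      if (length(hs)) {
        hd <- cross_dist(xyz[hs, , drop = FALSE], xyz[d, , drop = FALSE])
        hs <- hs[hd[, 1] <= 1.25]
      }
      if (!length(hs)) return(criterion$heavy_atom_fallback)
      v1 <- sweep(xyz[hs, , drop = FALSE], 2, xyz[d, ])
      v2 <- xyz[ai[i], ] - xyz[d, ]
      ang <- acos(pmin(1, pmax(-1, (v1 %*% v2) /
        (sqrt(rowSums(v1^2)) * sqrt(sum(v2^2)))))) * 180 / pi
      any(ang <= criterion$h_angle_max)
    }, logical(1))
    di <- di[keep2]; ai <- ai[keep2]; dist_v <- dist_v[keep2]
    if (!length(di)) return(empty)
  }

  don_gua <- da$roles[di] == "guanine" & at$name[di] %in% c("N1", "N2")
  acc_gua <- da$roles[ai] == "guanine" & at$name[ai] %in% c("O6", "N7")
  diff_res <- !(at$chain[di] == at$chain[ai] & at$resid[di] == at$resid[ai])
  hoog <- don_gua & acc_gua & diff_res
  prot_d <- da$roles[di] == "protein"
  prot_a <- da$roles[ai] == "protein"
  nuc_d <- da$roles[di] %in% c("guanine", "loop_nucleotide")
  nuc_a <- da$roles[ai] %in% c("guanine", "loop_nucleotide")
  inter <- (prot_d & nuc_a) | (nuc_d & prot_a)
  kind <- ifelse(hoog, "hoogsteen_GG", ifelse(inter, "intermolecular", "other"))

  out <- data.frame(
    donor_idx = di, acceptor_idx = ai,
    donor_chain = at$chain[di], donor_resid = at$resid[di],
    donor_resname = at$resname[di], donor_name = at$name[di],
    acceptor_chain = at$chain[ai], acceptor_resid = at$resid[ai],
    acceptor_resname = at$resname[ai], acceptor_name = at$name[ai],
    distance = dist_v, kind = kind, stringsAsFactors = FALSE)
  out <- out[order(out$donor_idx, out$acceptor_idx), ]
  rownames(out) <- NULL
  out
}
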