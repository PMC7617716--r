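aa3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL")

#' Default RGG-like peptide sequence
#'
#' A synthetic 53-residue low-complexity sequence in the style of an
#' RGG-box: RGG/FGG repeats interspersed with Tyr, Asn and Ser. It is a
#' fixture sequence for exercising the pipeline, not the sequence of any
#' real protein.
#'
#' @return one-letter amino-acid string of length 53.
#' @export
rgg_like_sequence <- function() {
  "GSRGGFGGNRGGRGGYNGGFGGNRGGSRGGFGGYRGGNSGGRGGFGGSRGRGG"
}

#' Generate self-avoiding random-coil peptide conformers
#'
#' Backbone built as a persistent self-avoiding random walk of C-alpha
#' positions (3.8 Angstrom virtual bonds, non-adjacent C-alpha pairs kept
#' at least 4 Angstrom apart), decorated with approximate backbone N, C, O
#' positions and a side-chain centroid pseudo-atom (CB, except glycine).
#' Geometry is a coarse stand-in for a disordered coil ensemble: correct
#' connectivity, realistic compaction, no torsional realism.
#'
#' @param sequence one-letter amino-acid string.
#' @param n number of conformers.
#' @param seed integer seed; the same seed reproduces coordinates bitwise.
#' @param chain chain identifier for the peptide.
#' @return an [ensemble()] with `n` frames.
#' @examples
#' pep <- make_peptide_conformers(rgg_like_sequence(), n = 3, seed = 7)
#' pep$frame_count
#' @export
make_peptide_conformers <- function(sequence, n, seed, chain = "P") {
  if (!nzchar(sequence)) stop("sequence must be non-empty")
  if (n < 1) stop("n must be >= 1")
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  if (!all(letters1 %in% names(aa3))) {
    stop("unknown amino-acid letter(s): ",
         paste(unique(letters1[!letters1 %in% names(aa3)]), collapse = ", "))
  }
  nres <- length(letters1)

  walk_ca <- function() {
    repeat {
      ca <- matrix(NA_real_, nres, 3)
      ca[1, ] <- c(0, 0, 0)
      dir <- c(1, 0, 0)
      ok <- TRUE
      for (i in 2:nres) {
        placed <- FALSE
        for (try in 1:60) {
          nd <- dir + 0.9 * stats::rnorm(3)
          nd <- nd / sqrt(sum(nd^2))
          cand <- ca[i - 1, ] + 3.8 * nd
          prev <- ca[seq_len(max(0, i - 2)), , drop = FALSE]
          if (!nrow(prev) ||
              min(cross_dist(matrix(cand, 1), prev)) >= 4.0) {
            ca[i, ] <- cand; dir <- nd; placed <- TRUE; break
          }
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok) return(ca)
    }
  }

  decorate <- function(ca) {
    rows <- vector("list", nres)
    for (i in seq_len(nres)) {
      d_prev <- if (i > 1) ca[i, ] - ca[i - 1, ] else ca[2, ] - ca[1, ]
      d_next <- if (i < nres) ca[i + 1, ] - ca[i, ] else ca[i, ] - ca[i - 1, ]
      d_prev <- d_prev / sqrt(sum(d_prev^2))
      d_next <- d_next / sqrt(sum(d_next^2))
      perp <- pracma_cross(d_prev, d_next)
      if (sum(perp^2) < 1e-8) perp <- pracma_cross(d_prev, c(0, 0, 1))
      if (sum(perp^2) < 1e-8) perp <- pracma_cross(d_prev, c(0, 1, 0))
      perp <- perp / sqrt(sum(perp^2))
      rn <- aa3[[letters1[i]]]
      pos <- list(
        N = ca[i, ] - 1.25 * d_prev + 0.45 * perp,
        CA = ca[i, ],
        C = ca[i, ] + 1.25 * d_next - 0.45 * perp,
        O = ca[i, ] + 1.25 * d_next - 0.45 * perp + 1.23 * perp_o(d_next, perp))
      if (rn != "GLY") pos$CB <- ca[i, ] + 1.53 * perp
      rows[[i]] <- do.call(rbind, lapply(names(pos), function(a) {
        data.frame(serial = NA_integer_, name = a,
                   element = substr(a, 1, 1), resname = rn, resid = i,
                   chain = chain, x = pos[[a]][1], y = pos[[a]][2],
                   z = pos[[a]][3], stringsAsFactors = FALSE)
      }))
    }
    do.call(rbind, rows)
  }

  with_seed(seed, {
    frames <- vector("list", n)
    topo <- NULL
    for (f in seq_len(n)) {
      at <- decorate(walk_ca())
      if (is.null(topo)) {
        at$serial <- seq_len(nrow(at))
        topo <- structure_model(at)
      }
      frames[[f]] <- as.matrix(at[c("x", "y", "z")])
    }
    coords <- array(NA_real_, dim = c(n, nrow(topo$atoms), 3))
    for (f in seq_len(n)) coords[f, , ] <- frames[[f]]
    ensemble(topo, coords)
  })
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

perp_o <- function(d, perp) {
  v <- pracma_cross(d, perp)
  v / sqrt(sum(v^2))
}

#' Specification of a planted peptide binding pose
#'
#' @param mode `"end_stack"`, `"groove"`, `"loop"` or `"far"`.
#' @param target_distance placement distance, Angstrom. Defaults to 3.5 for
#'   the three binding modes and 8 for `"far"` (beyond every contact
#'   cutoff).
#' @param peptide_residue_index residue of the peptide planted at the site;
#'   `NULL` (default) auto-selects a surface-exposed residue of the
#'   conformer at placement time (a buried residue cannot make rigid
#'   contact without steric clash).
#' @return a `PoseSpec` list.
#' @export
pose_spec <- function(mode = c("end_stack", "groove", "loop", "far"),
                      target_distance = NULL, peptide_residue_index = NULL) {
  mode <- match.arg(mode)
  if (is.null(target_distance)) {
    target_distance <- if (mode == "far") 8.0 else 3.5
  }
  stopifnot(target_distance > 0)
  structure(list(mode = mode, target_distance = target_distance,
                 peptide_residue_index = peptide_residue_index),
            class = "PoseSpec")
}

#' Rigidly place a peptide conformer on a GQ in a planted binding pose
#'
#' Seeded random rigid-body search: the designated peptide residue gets at
#' least one heavy atom within `target_distance` of the mode's anchor atom
#' set (an outer-quartet O6 for `end_stack`; a groove-exposed quartet
#' guanine atom for `groove`; any loop-nucleotide atom for `loop`), while no
#' peptide-GQ atom pair comes closer than 2 Angstrom. For `"far"`, every
#' peptide atom ends at least `target_distance` from every GQ atom.
#'
#' @param gq a `StructureModel` containing at least one detectable quartet.
#' @param peptide a `StructureModel` (one conformer).
#' @param pose a [pose_spec()].
#' @param seed integer seed.
#' @param max_tries rigid-placement attempts before giving up.
#' @param synonyms residue-name synonym table.
#' @return a combined `StructureModel` (GQ chains + peptide chain,
#'   serials renumbered).
#' @export
place_peptide <- function(gq, peptide, pose, seed, max_tries = 400,
                          synonyms = default_synonyms()) {
  stopifnot(inherits(gq, "StructureModel"), inherits(peptide, "StructureModel"),
            inherits(pose, "PoseSpec"))
  if (n_atoms(peptide) == 0) stop("empty peptide")
  assign <- detect_quartets(gq, synonyms = synonyms)
  if (!length(assign$quartets)) stop("gq contains no detectable quartet")

  at <- gq$atoms
  akey <- residue_key(at)
  roles <- atom_roles(gq, synonyms)
  heavy <- at$element != "H"
  xyz_gq <- coord_matrix(gq)
  axis <- assign$axis
  center <- colMeans(assign$centroids)

  anchor_idx <- switch(pose$mode,
    end_stack = {
      outer_layers <- c(1L, length(assign$quartets))
      which(!is.na(assign$layer_of[akey]) &
              assign$layer_of[akey] %in% outer_layers & at$name == "O6")
    },
    groove = which(!is.na(assign$layer_of[akey]) &
                     at$name %in% groove_atom_set() & heavy),
    loop = which(roles == "loop_nucleotide" & heavy),
    far = which(heavy))
  if (!length(anchor_idx)) {
    stop("no anchor atoms for pose mode '", pose$mode, "'")
  }

  pres <- unique(peptide$atoms[c("chain", "resid")])
  ridx <- pose$peptide_residue_index %||% .select_exposed_residue(peptide)
  if (ridx < 1 || ridx > nrow(pres)) stop("peptide_residue_index out of range")
  des_idx <- which(peptide$atoms$chain == pres$chain[ridx] &
                     peptide$atoms$resid == pres$resid[ridx] &
                     peptide$atoms$element != "H")
  pep_xyz0 <- coord_matrix(peptide)
  pep_heavy <- which(peptide$atoms$element != "H")

  combine <- function(pep_xyz) {
    pa <- peptide$atoms
    pa[c("x", "y", "z")] <- pep_xyz
    used <- unique(at$chain)
    if (pa$chain[1] %in% used) {
      pa$chain <- setdiff(c("P", "Q", "R", "S", LETTERS), used)[1]
    }
    all_at <- rbind(at, pa)
    all_at$serial <- seq_len(nrow(all_at))
    out <- structure_model(all_at)
    attr(out, "pose") <- list(mode = pose$mode, peptide_residue_index = ridx,
                              peptide_chain = pa$chain[1])
    out
  }

  if (pose$mode == "far") {
    r_gq <- max(cross_dist(matrix(center, 1), xyz_gq[heavy, , drop = FALSE]))
    return(with_seed(seed, {
      for (try in seq_len(max_tries)) {
        R <- random_rotation()
        pep <- sweep(pep_xyz0, 2, colMeans(pep_xyz0)) %*% R
        r_pep <- max(sqrt(rowSums(pep^2)))
        d <- stats::rnorm(3); d <- d / sqrt(sum(d^2))
        pep <- sweep(pep, 2, center + d * (r_gq + r_pep +
                                             pose$target_distance + 1.0), "+")
        if (min_dist(pep[pep_heavy, , drop = FALSE],
                     xyz_gq[heavy, , drop = FALSE]) >= pose$target_distance) {
          return(combine(pep))
        }
      }
      stop("far placement failed after ", max_tries, " tries")
    }))
  }

  with_seed(seed, {
    ring_d <- NULL
    for (try in seq_len(max_tries)) {
      anchor <- anchor_idx[sample.int(length(anchor_idx), 1)]
      tpos <- xyz_gq[anchor, ]
      if (pose$mode == "end_stack") {
        # approach along the channel axis, above/below the outer layer
        layer <- assign$layer_of[akey[anchor]]
        sgn <- if (layer == 1L) -1 else 1
        d <- sgn * axis
      } else {
        # radially outward from the channel axis through the anchor
        ap <- center + axis * sum((tpos - center) * axis)
        d <- tpos - ap
        nd <- sqrt(sum(d^2))
        d <- if (nd < 1e-6) c(1, 0, 0) else d / nd
      }
      # slide-in docking: orient the coil so the designated residue leads
      # (centroid -> residue along the inward direction), spin randomly
      # about the approach axis, then slide toward the anchor until the
      # residue reaches the target distance or a clash stops the approach
      des_names <- peptide$atoms$name[des_idx]
      ref_pick <- match(c("CB", "CA"), des_names, nomatch = 0)
      ref_atom <- des_idx[ref_pick[ref_pick > 0][1]]
      pep <- sweep(pep_xyz0, 2, colMeans(pep_xyz0[pep_heavy, , drop = FALSE]))
      # local protrusion direction of the designated residue: away from the
      # centroid of its spatial neighborhood, so the residue leads the
      # approach instead of being buried behind the rest of the coil
      nb_d <- cross_dist(pep[pep_heavy, , drop = FALSE],
                         pep[ref_atom, , drop = FALSE])[, 1]
      nb <- pep_heavy[nb_d <= 9 &
                        peptide$atoms$resid[pep_heavy] !=
                          peptide$atoms$resid[ref_atom]]
      u <- if (length(nb) >= 3) {
        pep[ref_atom, ] - colMeans(pep[nb, , drop = FALSE])
      } else pep[ref_atom, ]
      if (try %% 3 == 0) u <- u + 0.6 * sqrt(sum(u^2)) * stats::rnorm(3)
      if (sum(u^2) > 1e-6) pep <- pep %*% t(rotation_between(u, -d))
      pep <- pep %*% t(rotation_matrix(d, 2 * pi * stats::runif(1)))
      # put the reference atom far out along d, then step inward
      pep <- sweep(pep, 2, tpos + d * 18 - pep[ref_atom, ], "+")
      gq_heavy <- xyz_gq[heavy, , drop = FALSE]
      anchor_xyz <- xyz_gq[anchor_idx, , drop = FALSE]
      placed <- NULL
      for (step in seq(0, 17, by = 0.25)) {
        cand <- sweep(pep, 2, d * step)
        d_des <- min_dist(cand[des_idx, , drop = FALSE], anchor_xyz)
        d_all <- min_dist(cand[pep_heavy, , drop = FALSE], gq_heavy)
        if (d_all < 2.0) break
        if (d_des <= pose$target_distance) { placed <- cand; break }
      }
      if (is.null(placed)) {
        # near miss: rigid refinement from the last clash-free-ish pose
        cand <- .refine_rigid(cand, tpos, gq_heavy,
                              des_rows = des_idx, anchor_xyz = anchor_xyz,
                              target = pose$target_distance)
        d_des <- min_dist(cand[des_idx, , drop = FALSE], anchor_xyz)
        d_all <- min_dist(cand[pep_heavy, , drop = FALSE], gq_heavy)
        if (d_des <= pose$target_distance && d_all >= 2.0) placed <- cand
      }
      if (!is.null(placed)) return(combine(placed))
      ring_d <- c(ring_d, d_all)
    }
    stop("placement failed after ", max_tries, " tries (mode ", pose$mode,
         "; closest approach range ",
         paste(sprintf("%.2f", range(ring_d)), collapse = " to "), " A)")
  })
}

# Rank peptide residues by burial and return the index (sequence position)
# of the most exposed one: fewest atoms protruding beyond it (within the
# lateral footprint of a GQ-sized obstacle) along its own local protrusion
# direction.
.select_exposed_residue <- function(peptide) {
  at <- peptide$atoms
  xyz <- coord_matrix(peptide)
  heavy <- which(at$element != "H")
  p <- sweep(xyz, 2, colMeans(xyz[heavy, , drop = FALSE]))
  pres <- unique(at[c("chain", "resid")])
  score <- rep(Inf, nrow(pres))
  for (i in seq_len(nrow(pres))) {
    ref <- which(at$chain == pres$chain[i] & at$resid == pres$resid[i] &
                   at$name %in% c("CB", "CA"))[1]
    if (is.na(ref)) next
    nbd <- cross_dist(p[heavy, , drop = FALSE], p[ref, , drop = FALSE])[, 1]
    nb <- heavy[nbd <= 9 & at$resid[heavy] != at$resid[ref]]
    u <- if (length(nb) >= 3) p[ref, ] - colMeans(p[nb, , drop = FALSE])
         else p[ref, ]
    nu <- sqrt(sum(u^2))
    if (nu < 1e-6) next
    u <- u / nu
    proj <- p[heavy, , drop = FALSE] %*% u
    ahead <- proj - as.numeric(p[ref, ] %*% u)
    lat <- sqrt(rowSums((p[heavy, , drop = FALSE] -
                           outer(as.vector(proj), u))^2))
    score[i] <- sum(ahead > 1 & lat < 12)
  }
  which.min(score)
}

# Rigid-body clash relaxation about a pivot. Minimizes a soft penalty:
# squared penetration below 2.1 A for every peptide-GQ atom pair, plus a
# term keeping the designated residue within the anchor target distance.
.refine_rigid <- function(pep, pivot, gq_xyz, des_rows, anchor_xyz, target) {
  centered <- sweep(pep, 2, pivot)
  energy <- function(p) {
    ang <- sqrt(sum(p[1:3]^2))
    R <- if (ang < 1e-9) diag(3) else rotation_matrix(p[1:3] / ang, ang)
    cand <- sweep(centered %*% t(R), 2, pivot + p[4:6], "+")
    dmin <- row_mins(cross_dist(cand, gq_xyz))
    pen <- sum(pmax(0, 2.1 - dmin)^2)
    ddes <- min(cross_dist(cand[des_rows, , drop = FALSE], anchor_xyz))
    pen + 4 * max(0, ddes - (target - 0.15))^2
  }
  e0 <- energy(rep(0, 6))
  if (e0 < 1e-10) return(pep)
  if (e0 > 25) return(pep)  # hopelessly deep clash: let the caller retry
  fit <- stats::optim(rep(0, 6), energy, method = "Nelder-Mead",
                      control = list(maxit = 250, reltol = 1e-9))
  p <- fit$par
  ang <- sqrt(sum(p[1:3]^2))
  R <- if (ang < 1e-9) diag(3) else rotation_matrix(p[1:3] / ang, ang)
  sweep(centered %*% t(R), 2, pivot + p[4:6], "+")
}

#' Pseudo-trajectory with optional progressive strand displacement
#'
#' Frame `f` (numbered from 0, so the first frame is the undisplaced bound
#' state) = base coordinates + isotropic Gaussian noise (sd `noise_sigma`)
#' everywhere + a rigid translation of one designated strand by
#' `f * strand_displacement_per_frame` along the groove normal (the
#' direction from the channel axis through the strand's centroid,
#' perpendicular to the axis). With zero displacement this is a stable
#' thermal-noise trajectory; with a few tenths of an Angstrom per frame the
#' quartet Hoogsteen network progressively breaks, emulating strand
#' extrusion through the grooves.
#'
#' @param complex a `StructureModel` (GQ alone or GQ + peptide).
#' @param n_frames number of frames (>= 2).
#' @param strand_displacement_per_frame Angstrom per frame.
#' @param noise_sigma Gaussian positional noise sd, Angstrom.
#' @param seed integer seed.
#' @param strand chain identifier of the displaced strand; default the last
#'   guanine-containing chain. The displaced unit is one stem column of
#'   that chain (one guanine per quartet layer), so displacement breaks
#'   Hoogsteen bonds for any molecularity.
#' @param synonyms residue-name synonym table.
#' @return an [ensemble()] with `n_frames` frames.
#' @export
make_unfolding_trajectory <- function(complex, n_frames,
                                      strand_displacement_per_frame = 0.5,
                                      noise_sigma = 0.1, seed = 1,
                                      strand = NULL,
                                      synonyms = default_synonyms()) {
  stopifnot(inherits(complex, "StructureModel"))
  if (n_frames < 2) stop("n_frames must be >= 2")
  at <- complex$atoms
  roles <- atom_roles(complex, synonyms)
  gua_chains <- unique(at$chain[roles == "guanine"])
  if (!length(gua_chains)) stop("no guanine-containing strand in complex")
  strand <- strand %||% gua_chains[length(gua_chains)]
  if (!strand %in% at$chain) stop("designated strand '", strand, "' absent")

  assign <- detect_quartets(complex, synonyms = synonyms)
  if (!length(assign$quartets)) stop("no detectable quartet in complex")

  # displaced unit: one stem column of the designated chain (one guanine per
  # layer, chosen by stacking proximity). For a tetramolecular GQ this is
  # the chain's whole stem; for uni/bimolecular chains, which contribute
  # several columns, displacing the full chain would move the quadruplex
  # rigidly and break nothing.
  akey_all <- residue_key(at)
  xyz_tmp <- coord_matrix(complex)
  res_xy <- function(key) {
    colMeans(xyz_tmp[akey_all == key & at$element != "H", , drop = FALSE])
  }
  nlayer <- length(assign$quartets)
  chain_gua <- names(assign$layer_of)[startsWith(names(assign$layer_of),
                                                 paste0(strand, ":"))]
  if (!length(chain_gua)) stop("designated strand '", strand,
                               "' has no quartet guanines")
  col_keys <- character(0)
  prev <- NULL
  for (l in seq_len(nlayer)) {
    cand <- chain_gua[assign$layer_of[chain_gua] == l]
    if (!length(cand)) next
    pick <- if (is.null(prev)) cand[which.max(as.integer(sub(".*:", "", cand)))]
    else cand[which.min(vapply(cand, function(k)
      sum((res_xy(k) - res_xy(prev))^2), numeric(1)))]
    col_keys <- c(col_keys, pick)
    prev <- pick
  }
  strand_idx <- which(akey_all %in% col_keys)
  axis <- assign$axis
  center <- colMeans(assign$centroids)
  xyz0 <- coord_matrix(complex)
  sc <- colMeans(xyz0[strand_idx, , drop = FALSE])
  v <- (sc - center) - axis * sum((sc - center) * axis)
  nv <- sqrt(sum(v^2))
  if (nv < 1e-8) stop("strand centroid lies on the channel axis")
  v <- v / nv

  na <- nrow(xyz0)
  with_seed(seed, {
    coords <- array(NA_real_, dim = c(n_frames, na, 3))
    for (f in seq_len(n_frames)) {
      xyz <- xyz0 + matrix(stats::rnorm(na * 3, 0, noise_sigma), na, 3)
      xyz[strand_idx, ] <- sweep(xyz[strand_idx, , drop = FALSE], 2,
                                 (f - 1) * strand_displacement_per_frame * v,
                                 "+")
      coords[f, , ] <- xyz
    }
    ensemble(complex, coords)
  })
}
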