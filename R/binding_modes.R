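# Groove-exposed guanine atom set. The literal published list also names
# "N6", an atom guanine does not have; the chemically possible members are
# kept and N7 can be added via `include_N7`.
groove_atom_set <- function(include_N7 = FALSE) {
  c("N2", "C2", "N3", "C4", "C8", "N9", if (include_N7) "N7")
}

#' Classify the GQ-binding mode of each protein residue in one frame
#'
#' Heavy-atom distance rules at `cutoff` (default 4 Angstrom):
#' * `end_stack` — any residue heavy atom within `cutoff` of a quartet
#'   guanine O6 (the carbonyl oxygens lining the central channel). By
#'   default O6 of any layer qualifies; `outer_layers_only` restricts to the
#'   two solvent-exposed terminal quartets.
#' * `groove` — within `cutoff` of a groove-exposed quartet guanine atom
#'   from [groove_atom_set()].
#' * `loop` — within `cutoff` of any atom of a loop/overhang T/U/A
#'   nucleotide, irrespective of backbone, sugar or base.
#'
#' The three modes are not exclusive; a residue can carry several flags.
#'
#' @param frame a `StructureModel` containing protein and GQ.
#' @param assign a non-empty `QuartetAssignment` for the frame's GQ.
#' @param cutoff contact distance, Angstrom.
#' @param include_N7 add N7 to the groove atom set.
#' @param outer_layers_only restrict end-stacking to the outer quartets.
#' @param synonyms residue-name synonym table.
#' @return data.frame, one row per protein residue in sequence order:
#'   `chain`, `resid`, `resname`, `end_stack`, `groove`, `loop`, and
#'   `end_stack_layer` (nearest contacted quartet layer index, `NA` when not
#'   end-stacking).
#' @export
classify_residue_modes <- function(frame, assign, cutoff = 4.0,
                                   include_N7 = FALSE,
                                   outer_layers_only = FALSE,
                                   synonyms = default_synonyms()) {
  if (!length(assign$quartets)) stop("empty quartet assignment")
  at <- frame$atoms
  roles <- atom_roles(frame, synonyms)
  prot <- which(roles == "protein" & at$element != "H")
  if (!length(prot)) stop("no protein chain in frame")

  layers <- if (outer_layers_only && length(assign$quartets) > 1) {
    c(1L, length(assign$quartets))
  } else seq_along(assign$quartets)
  in_layer <- function(keys) !is.na(assign$layer_of[keys]) &
    assign$layer_of[keys] %in% layers
  akey <- residue_key(at)

  quartet_gua <- !is.na(assign$layer_of[akey])
  o6 <- which(quartet_gua & in_layer(akey) & at$name == "O6")
  groove <- which(quartet_gua & at$name %in% groove_atom_set(include_N7) &
                    at$element != "H")
  loop_at <- which(roles == "loop_nucleotide" & at$element != "H")

  xyz <- coord_matrix(frame)
  res <- unique(at[prot, c("chain", "resid", "resname")])
  rownames(res) <- NULL
  n <- nrow(res)
  out <- cbind(res, end_stack = logical(n), groove = logical(n),
               loop = logical(n), end_stack_layer = NA_integer_)
  for (i in seq_len(n)) {
    ai <- prot[at$chain[prot] == res$chain[i] & at$resid[prot] == res$resid[i]]
    p <- xyz[ai, , drop = FALSE]
    if (length(o6)) {
      d <- cross_dist(p, xyz[o6, , drop = FALSE])
      if (min(d) <= cutoff) {
        out$end_stack[i] <- TRUE
        nearest <- o6[which(d == min(d), arr.ind = TRUE)[1, 2]]
        out$end_stack_layer[i] <- assign$layer_of[akey[nearest]]
      }
    }
    if (length(groove) && min_dist(p, xyz[groove, , drop = FALSE]) <= cutoff) {
      out$groove[i] <- TRUE
    }
    if (length(loop_at) && min_dist(p, xyz[loop_at, , drop = FALSE]) <= cutoff) {
      out$loop[i] <- TRUE
    }
  }
  out
}

#' Composition-normalized amino-acid x base interaction matrix
#'
#' For one binding mode, counts residue-base contacts over all frames (a
#' residue-base pair counts once per frame regardless of how many atom pairs
#' are within `cutoff`), then divides each amino-acid-type row by the number
#' of residues of that type in the peptide sequence. Amino-acid types absent
#' from the sequence are omitted (no 0/0 rows). Contact rules per mode
#' mirror [classify_residue_modes()]: `end_stack` counts contacts to a
#' quartet guanine's O6; `groove` to its groove-exposed atoms; `loop` to any
#' atom of a loop nucleotide.
#'
#' @param ens an [ensemble()] containing protein and GQ.
#' @param assign `QuartetAssignment` from frame 1.
#' @param mode `"end_stack"`, `"groove"` or `"loop"`.
#' @param cutoff contact distance, Angstrom.
#' @param include_N7 add N7 to the groove atom set.
#' @param atom_pair_counting count every atom pair within `cutoff` instead
#'   of once per residue-base-frame.
#' @param synonyms residue-name synonym table.
#' @return a `ModeMatrix`: numeric matrix (amino-acid types x GQ bases in
#'   sequence order, dimnames set) with attributes `mode`, `cutoff`,
#'   `composition`.
#' @export
interaction_matrix <- function(ens, assign,
                               mode = c("end_stack", "groove", "loop"),
                               cutoff = 4.0, include_N7 = FALSE,
                               atom_pair_counting = FALSE,
                               synonyms = default_synonyms()) {
  mode <- match.arg(mode)
  stopifnot(inherits(ens, "Ensemble"))
  if (!length(assign$quartets)) stop("empty quartet assignment")
  topo <- ens$topology
  at <- topo$atoms
  roles <- atom_roles(topo, synonyms)
  akey <- residue_key(at)

  prot_res <- unique(at[roles == "protein", c("chain", "resid", "resname")])
  if (!nrow(prot_res)) stop("no protein chain in ensemble")
  nuc_res <- unique(at[roles %in% c("guanine", "loop_nucleotide"),
                       c("chain", "resid", "resname")])
  if (!nrow(nuc_res)) stop("no GQ bases in ensemble")
  rownames(prot_res) <- rownames(nuc_res) <- NULL

  # atom rule per base for this mode
  base_keys <- residue_key(nuc_res)
  base_atoms <- lapply(seq_len(nrow(nuc_res)), function(j) {
    sel <- akey == base_keys[j] & at$element != "H"
    if (mode == "end_stack") {
      which(sel & at$name == "O6" & !is.na(assign$layer_of[akey]))
    } else if (mode == "groove") {
      which(sel & at$name %in% groove_atom_set(include_N7) &
              !is.na(assign$layer_of[akey]))
    } else {
      role_j <- unique(atom_roles(topo, synonyms)[akey == base_keys[j]])
      if (identical(role_j, "loop_nucleotide")) which(sel) else integer(0)
    }
  })
  prot_keys <- residue_key(prot_res)
  prot_atoms <- lapply(prot_keys, function(k) {
    which(akey == k & at$element != "H")
  })

  types <- sort(unique(prot_res$resname))
  composition <- vapply(types, function(tt) sum(prot_res$resname == tt),
                        numeric(1))
  counts <- matrix(0, length(types), nrow(nuc_res),
                   dimnames = list(types, paste0(nuc_res$chain, ":",
                                                 nuc_res$resname,
                                                 nuc_res$resid)))
  for (f in seq_len(ens$frame_count)) {
    xyz <- ens$coords[f, , ]
    for (i in seq_len(nrow(prot_res))) {
      p <- xyz[prot_atoms[[i]], , drop = FALSE]
      for (j in seq_len(nrow(nuc_res))) {
        bj <- base_atoms[[j]]
        if (!length(bj)) next
        d <- cross_dist(p, xyz[bj, , drop = FALSE])
        hit <- if (atom_pair_counting) sum(d <= cutoff) else
          as.numeric(any(d <= cutoff))
        if (hit > 0) {
          counts[prot_res$resname[i], j] <- counts[prot_res$resname[i], j] + hit
        }
      }
    }
  }
  values <- sweep(counts, 1, composition[types], "/")
  structure(values, mode_id = mode, cutoff = cutoff,
            composition = composition, class = c("ModeMatrix", "matrix"))
}
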