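#' Residue-wise contact lifetime map
#'
#' Lifetime of protein-residue x GQ-base contacts over an ensemble: the
#' fraction of frames in which at least one heavy-atom pair of the two
#' residues is within `cutoff` (closed interval, so a pair at exactly the
#' cutoff counts). Lifetimes below `min_lifetime` are reported as 0; the raw
#' integer frame counts are retained internally so maps can be pooled
#' exactly with [merge_maps()].
#'
#' @param ens an [ensemble()] with protein and nucleic chains.
#' @param cutoff heavy-atom contact distance, Angstrom.
#' @param min_lifetime persistence filter, fraction of frames.
#' @param synonyms residue-name synonym table.
#' @param residue_offset added to protein residue numbers in row labels
#'   (set to the construct's first residue number minus one to report
#'   author numbering, e.g. an RGG domain starting at residue 197).
#' @return a `ContactMap`: list with `values` (rows = protein residues in
#'   sequence order, cols = GQ bases), `counts`, `frames`, `cutoff`,
#'   `min_lifetime`.
#' @export
contact_map <- function(ens, cutoff = 4.0, min_lifetime = 0.01,
                        synonyms = default_synonyms(), residue_offset = 0) {
  stopifnot(inherits(ens, "Ensemble"), ens$frame_count >= 1)
  topo <- ens$topology
  at <- topo$atoms
  roles <- atom_roles(topo, synonyms)
  prot_res <- unique(at[roles == "protein", c("chain", "resid", "resname")])
  nuc_res <- unique(at[roles %in% c("guanine", "loop_nucleotide"),
                       c("chain", "resid", "resname")])
  if (!nrow(prot_res)) stop("no protein chain in ensemble")
  if (!nrow(nuc_res)) stop("no nucleic chain in ensemble")
  rownames(prot_res) <- rownames(nuc_res) <- NULL

  akey <- residue_key(at)
  heavy <- at$element != "H"
  p_atoms <- lapply(residue_key(prot_res), function(k) which(akey == k & heavy))
  b_atoms <- lapply(residue_key(nuc_res), function(k) which(akey == k & heavy))

  counts <- matrix(0L, nrow(prot_res), nrow(nuc_res))
  for (f in seq_len(ens$frame_count)) {
    xyz <- ens$coords[f, , ]
    for (i in seq_along(p_atoms)) {
      p <- xyz[p_atoms[[i]], , drop = FALSE]
      for (j in seq_along(b_atoms)) {
        if (min_dist(p, xyz[b_atoms[[j]], , drop = FALSE]) <= cutoff) {
          counts[i, j] <- counts[i, j] + 1L
        }
      }
    }
  }
  dimnames(counts) <- list(
    paste0(prot_res$resname, prot_res$resid + residue_offset),
    paste0(nuc_res$chain, ":", nuc_res$resname, nuc_res$resid))
  new_contact_map(counts, ens$frame_count, cutoff, min_lifetime)
}

new_contact_map <- function(counts, frames, cutoff, min_lifetime) {
  values <- counts / frames
  values[values < min_lifetime] <- 0
  structure(list(values = values, counts = counts, frames = frames,
                 cutoff = cutoff, min_lifetime = min_lifetime),
            class = "ContactMap")
}

#' @export
print.ContactMap <- function(x, ...) {
  cat("ContactMap:", nrow(x$values), "protein residues x", ncol(x$values),
      "bases;", x$frames, "frame(s); cutoff", x$cutoff, "A; min lifetime",
      x$min_lifetime, "\n")
  invisible(x)
}

#' Pool contact maps over complexes
#'
#' Pooled lifetime = total contact frames / total frames across all inputs,
#' exact in integer arithmetic, so merging is associative and
#' order-independent. The persistence filter is re-applied after pooling:
#' a contact sparse in each run but persistent over the pooled period
#' survives.
#'
#' @param maps list of `ContactMap`s with identical row/column labels.
#' @return a pooled `ContactMap`.
#' @export
merge_maps <- function(maps) {
  stopifnot(length(maps) >= 1)
  ref <- maps[[1]]
  for (m in maps[-1]) {
    if (!identical(dimnames(m$counts), dimnames(ref$counts))) {
      stop("contact map labels differ; cannot merge")
    }
    if (m$cutoff != ref$cutoff || m$min_lifetime != ref$min_lifetime) {
      stop("contact map parameters differ; cannot merge")
    }
  }
  counts <- Reduce(`+`, lapply(maps, `[[`, "counts"))
  frames <- sum(vapply(maps, `[[`, numeric(1), "frames"))
  new_contact_map(counts, frames, ref$cutoff, ref$min_lifetime)
}

#' Write a matrix-like result as TSV
#'
#' @param x a `ContactMap`, `ModeMatrix` or plain matrix/data.frame.
#' @param path output path.
#' @param comment optional `# `-prefixed header lines (e.g. a manifest hash).
#' @return invisibly, `path`.
#' @export
write_tsv_matrix <- function(x, path, comment = NULL) {
  m <- if (inherits(x, "ContactMap")) x$values else x
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comment) writeLines(paste0("# ", cm), con)
  if (is.matrix(m)) {
    df <- data.frame(id = rownames(m) %||% seq_len(nrow(m)),
                     as.data.frame(unclass(m)), check.names = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    utils::write.table(m, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
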