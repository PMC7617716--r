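#' Read a (multi-model) PDB file into an Ensemble
#'
#' One frame is produced per `MODEL` record (a single frame if the file has
#' none). Atom order is preserved from the file. When alternate locations are
#' present, the highest-occupancy altloc is kept and the rest dropped (the
#' choice is reported via `message()`). Parsing is delegated to
#' [bio3d::read.pdb()] after a structural pre-scan that reports malformed
#' ATOM/HETATM lines by line number and inconsistent per-MODEL atom counts.
#'
#' @param path path to a PDB file.
#' @param format input format; only `"pdb"` is supported.
#' @return an [ensemble()].
#' @seealso [write_structure()]
#' @export
read_structure <- function(path, format = "pdb") {
  format <- match.arg(format, "pdb")
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  .prescan_pdb(lines, path)

  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  at <- pdb$atom

  # altloc: keep the highest-occupancy record per (chain, resno, insert, elety)
  if (any(!is.na(at$alt) & at$alt != "")) {
    key <- paste(at$chain, at$resno, at$insert, at$elety)
    occ <- ifelse(is.na(at$o), 1, at$o)
    keep <- rep(TRUE, nrow(at))
    for (k in unique(key[duplicated(key)])) {
      idx <- which(key == k)
      best <- idx[which.max(occ[idx])]
      keep[setdiff(idx, best)] <- FALSE
    }
    if (!all(keep)) {
      message("altloc: kept highest-occupancy records, dropped ",
              sum(!keep), " alternate(s)")
      at <- at[keep, , drop = FALSE]
      pdb$xyz <- pdb$xyz[, as.vector(t(cbind((which(keep) - 1) * 3 + 1,
                                             (which(keep) - 1) * 3 + 2,
                                             (which(keep) - 1) * 3 + 3))),
                         drop = FALSE]
    }
  }

  elem <- at$elesy
  bad <- is.na(elem) | elem == ""
  elem[bad] <- guess_element(at$elety[bad])
  chain <- ifelse(is.na(at$chain) | at$chain == "", "A", at$chain)

  atoms <- data.frame(
    serial = at$eleno, name = at$elety, element = elem,
    resname = at$resid, resid = at$resno, chain = chain,
    x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE
  )
  topo <- structure_model(atoms)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  ensemble(topo, coords = unname(as.matrix(xyz)))
}

# Structural pre-scan: fixed-width field sanity for ATOM/HETATM records and
# identical atom counts across MODEL blocks.
.prescan_pdb <- function(lines, path) {
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  for (i in which(is_atom)) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      stop("malformed ATOM/HETATM line ", i, " in ", path,
           ": shorter than coordinate fields")
    }
    coords <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (anyNA(suppressWarnings(as.numeric(coords)))) {
      stop("malformed ATOM/HETATM line ", i, " in ", path,
           ": non-numeric coordinate field")
    }
  }
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts) > 1) {
    ends <- which(startsWith(lines, "ENDMDL"))
    if (length(ends) != length(model_starts)) {
      stop("topology error in ", path, ": unbalanced MODEL/ENDMDL records")
    }
    counts <- mapply(function(s, e) sum(is_atom[s:e]), model_starts, ends)
    if (length(unique(counts)) != 1) {
      stop("topology error in ", path, ": MODEL blocks differ in atom count (",
           paste(unique(counts), collapse = ", "), ")")
    }
  }
  invisible(NULL)
}

# Element symbol from a PDB v3 atom name: strip digits and primes, take the
# leading alphabetic character (two for common monatomic ions).
guess_element <- function(name) {
  vapply(name, function(nm) {
    s <- gsub("[0-9']", "", nm)
    if (toupper(s) %in% c("K", "NA", "CL", "MG", "ZN", "BR")) return(toupper(s))
    substr(s, 1, 1)
  }, character(1), USE.NAMES = FALSE)
}

#' Write an Ensemble as a (multi-model) PDB file
#'
#' Multi-frame ensembles are written as one `MODEL`/`ENDMDL` pair per frame;
#' a single frame is written without MODEL records. Reading the file back
#' with [read_structure()] reproduces all atom metadata and coordinates to
#' the PDB fixed-width precision of 3 decimals.
#'
#' @param ens an [ensemble()] (a `StructureModel` is promoted to one frame).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_structure <- function(ens, path) {
  if (inherits(ens, "StructureModel")) ens <- ensemble(ens)
  stopifnot(inherits(ens, "Ensemble"))
  at <- ens$topology$atoms
  if (nrow(at) == 0) stop("format error: empty ensemble")
  if (any(nchar(at$chain) > 1)) {
    stop("format error: chain identifiers wider than one character")
  }
  if (any(nchar(at$resname) > 4)) {
    stop("format error: residue names wider than four characters")
  }
  if (any(nchar(at$name) > 4)) {
    stop("format error: atom names wider than four characters")
  }
  ion_res <- default_synonyms()$ion
  record <- ifelse(at$resname %in% ion_res, "HETATM", "ATOM  ")
  # PDB v3 alignment: names of <4 chars start in column 14
  name_fmt <- ifelse(nchar(at$name) >= 4, at$name,
                     sprintf(" %-3s", at$name))
  con <- file(path, "w")
  on.exit(close(con))
  nf <- ens$frame_count
  for (f in seq_len(nf)) {
    if (nf > 1) writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- ens$coords[f, , , drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    lines <- sprintf("%s%5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                     record, at$serial %% 100000L, name_fmt, at$resname,
                     at$chain, at$resid %% 10000L,
                     xyz[, 1], xyz[, 2], xyz[, 3], 1, 0,
                     formatC(at$element, width = 2, flag = " "))
    # TER between chains within a frame
    chain_end <- c(at$chain[-1] != at$chain[-nrow(at)], TRUE)
    out <- character(0)
    for (i in seq_along(lines)) {
      out <- c(out, lines[i])
      if (chain_end[i] && record[i] == "ATOM  ") out <- c(out, "TER")
    }
    writeLines(out, con)
    if (nf > 1) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
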