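#' Structure and ensemble containers
#'
#' A `StructureModel` holds one frame of an atomic structure: an atom table
#' (serial, name, element, resname, resid, chain) plus Cartesian coordinates
#' in Angstrom. An `Ensemble` is an ordered set of frames sharing one
#' topology, the in-memory form of a multi-model PDB pseudo-trajectory or a
#' conformer set.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `resid`, `chain`, `x`, `y`, `z`.
#' @param box optional length-3 numeric box vector (Angstrom), or `NULL`.
#' @return `structure_model()` returns a `StructureModel`; `ensemble()`
#'   returns an `Ensemble`.
#' @examples
#' atoms <- data.frame(serial = 1, name = "CA", element = "C",
#'                     resname = "GLY", resid = 1, chain = "A",
#'                     x = 0, y = 0, z = 0)
#' m <- structure_model(atoms)
#' n_atoms(m)
#' @export
structure_model <- function(atoms, box = NULL) {
  req <- c("serial", "name", "element", "resname", "resid", "chain",
           "x", "y", "z")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols)) {
    stop("atom table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  atoms <- as.data.frame(atoms)[req]
  atoms$serial <- as.integer(atoms$serial)
  atoms$resid <- as.integer(atoms$resid)
  for (cc in c("name", "element", "resname", "chain")) {
    atoms[[cc]] <- as.character(atoms[[cc]])
  }
  xyz <- as.matrix(atoms[c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite coordinates in atom table")
  key <- paste(atoms$chain, atoms$resid, atoms$name)
  if (anyDuplicated(key)) {
    stop("duplicate (chain, resid, name) atom records: ",
         paste(utils::head(key[duplicated(key)], 3), collapse = "; "))
  }
  obj <- list(atoms = atoms, box = box)
  class(obj) <- "StructureModel"
  obj
}

#' @rdname structure_model
#' @param topology a `StructureModel` defining atom order (frame 0).
#' @param coords numeric array `frames x atoms x 3`, or a matrix
#'   `frames x (3 * atoms)` in x1,y1,z1,... order, or `NULL` to take the
#'   single frame from `topology`.
#' @export
ensemble <- function(topology, coords = NULL) {
  stopifnot(inherits(topology, "StructureModel"))
  na <- n_atoms(topology)
  if (is.null(coords)) {
    coords <- array(coord_matrix(topology), dim = c(1L, na, 3L))
  } else if (is.matrix(coords)) {
    if (ncol(coords) != 3L * na) {
      stop("coordinate matrix has ", ncol(coords), " columns; expected ", 3L * na)
    }
    coords <- aperm(array(t(coords), dim = c(3L, na, nrow(coords))), c(3, 2, 1))
  }
  d <- dim(coords)
  if (length(d) != 3L || d[2] != na || d[3] != 3L) {
    stop("coords must be a frames x ", na, " x 3 array")
  }
  if (!all(is.finite(coords))) stop("non-finite coordinates in ensemble")
  obj <- list(topology = topology, coords = coords, frame_count = d[1])
  class(obj) <- "Ensemble"
  obj
}

#' @rdname structure_model
#' @param x a `StructureModel` or `Ensemble`.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "Ensemble")) nrow(x$topology$atoms) else nrow(x$atoms)
}

#' Coordinates of a model as an atoms x 3 matrix
#' @param model a `StructureModel`.
#' @return numeric matrix, one row per atom, columns x, y, z (Angstrom).
#' @export
coord_matrix <- function(model) {
  unname(as.matrix(model$atoms[c("x", "y", "z")]))
}

#' Extract one frame of an ensemble as a StructureModel
#' @param ens an `Ensemble`.
#' @param i frame index (1-based).
#' @return a `StructureModel` with the topology's atom table and frame `i`
#'   coordinates.
#' @export
get_frame <- function(ens, i) {
  stopifnot(inherits(ens, "Ensemble"), i >= 1, i <= ens$frame_count)
  m <- ens$topology
  m$atoms[c("x", "y", "z")] <- ens$coords[i, , ]
  m
}

#' Replace a model's coordinates
#' @param model a `StructureModel`.
#' @param xyz atoms x 3 matrix.
#' @return the model with new coordinates.
#' @export
set_coords <- function(model, xyz) {
  stopifnot(nrow(xyz) == n_atoms(model), ncol(xyz) == 3)
  model$atoms[c("x", "y", "z")] <- as.matrix(xyz)
  model
}

#' @export
print.StructureModel <- function(x, ...) {
  cat("StructureModel:", n_atoms(x), "atoms,",
      nrow(unique(x$atoms[c("chain", "resid")])), "residues,",
      length(unique(x$atoms$chain)), "chain(s)\n")
  invisible(x)
}

#' @export
print.Ensemble <- function(x, ...) {
  cat("Ensemble:", x$frame_count, "frame(s) x", n_atoms(x), "atoms\n")
  invisible(x)
}

# ---- residue roles ---------------------------------------------------------

#' Default residue-name synonym table
#'
#' Maps residue names to the roles the pipeline reasons about: `guanine`
#' (quartet-forming bases), `loop_nucleotide` (T/U/A connector or overhang
#' bases — contacts to any of their atoms count as loop binding, irrespective
#' of backbone, sugar or base), `ion` (monovalent channel cations) and
#' `protein`. Edit and pass to [classify_residues()] to extend nomenclature.
#'
#' @return named list of character vectors with elements `guanine`,
#'   `loop_nucleotide`, `ion`, `protein`.
#' @export
default_synonyms <- function() {
  list(
    guanine = c("DG", "G", "GUA", "DG3", "DG5", "RG"),
    loop_nucleotide = c("DT", "DA", "T", "U", "A", "THY", "ADE", "URA",
                        "DU", "DT3", "DT5", "DA3", "DA5", "RU", "RA"),
    ion = c("K", "K+", "NA", "NA+", "POT", "SOD"),
    protein = c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                "THR", "TRP", "TYR", "VAL", "HSD", "HSE", "HSP")
  )
}

#' Classify residues of a structure into pipeline roles
#'
#' Every residue is assigned exactly one role: `protein`, `guanine`,
#' `loop_nucleotide`, `ion` or `other`. Unknown residue names fall through to
#' `other` with a warning, never a hard error.
#'
#' @param model a `StructureModel`.
#' @param synonyms synonym table as from [default_synonyms()].
#' @return data.frame with one row per residue: `chain`, `resid`, `resname`,
#'   `role`, in structure order.
#' @examples
#' gq <- build_gq(gq_spec(n_quartets = 1), seed = 1)
#' table(classify_residues(gq)$role)
#' @export
classify_residues <- function(model, synonyms = default_synonyms()) {
  at <- model$atoms
  res <- unique(at[c("chain", "resid", "resname")])
  rownames(res) <- NULL
  role <- character(nrow(res))
  for (i in seq_len(nrow(res))) {
    rn <- res$resname[i]
    role[i] <- if (rn %in% synonyms$protein) "protein"
    else if (rn %in% synonyms$guanine) "guanine"
    else if (rn %in% synonyms$loop_nucleotide) "loop_nucleotide"
    else if (rn %in% synonyms$ion) "ion"
    else "other"
  }
  unknown <- unique(res$resname[role == "other"])
  if (length(unknown)) {
    warning("unknown residue name(s) classified as 'other': ",
            paste(unknown, collapse = ", "))
  }
  res$role <- role
  res
}

# Residue key strings ("chain:resid") for an atom table or residue table.
residue_key <- function(df) paste(df$chain, df$resid, sep = ":")

# Per-atom role vector for a model, from classify_residues.
atom_roles <- function(model, synonyms = default_synonyms()) {
  res <- suppressWarnings(classify_residues(model, synonyms))
  role_of <- stats::setNames(res$role, residue_key(res))
  unname(role_of[residue_key(model$atoms)])
}

# Heavy-atom (non-hydrogen) row indices of a model's atom table.
heavy_idx <- function(model) {
  which(model$atoms$element != "H")
}
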