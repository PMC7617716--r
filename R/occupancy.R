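#' 3-D occupancy density grid of peptide atoms around the GQ
#'
#' Every frame is first least-squares superposed onto the frame-1 GQ stem
#' heavy atoms (Kabsch), so the density lives in a GQ-fixed reference frame.
#' A voxel's per-frame occupancy is 1 when at least one peptide heavy atom
#' lies in the voxel and that atom is within `cutoff` of any GQ heavy atom,
#' else 0; the grid value is the mean over frames. The grid covers the GQ
#' extent plus `cutoff` plus `margin`.
#'
#' @param ens an [ensemble()] with protein and GQ.
#' @param spacing voxel edge, Angstrom.
#' @param cutoff peptide-to-GQ distance cutoff, Angstrom (the first-shell
#'   6 Angstrom convention by default).
#' @param margin extra padding around the GQ extent, Angstrom.
#' @param synonyms residue-name synonym table.
#' @return an `OccupancyGrid`: list with `origin`, `spacing`, `dims`,
#'   `values` (3-D array, fractions in `[0, 1]`), `cutoff`.
#' @export
occupancy_grid <- function(ens, spacing = 1.0, cutoff = 6.0, margin = 2.0,
                           synonyms = default_synonyms()) {
  stopifnot(inherits(ens, "Ensemble"))
  if (spacing <= 0) stop("spacing must be positive")
  topo <- ens$topology
  at <- topo$atoms
  roles <- atom_roles(topo, synonyms)
  heavy <- at$element != "H"
  gq_idx <- which(roles %in% c("guanine", "loop_nucleotide", "ion") & heavy)
  stem_idx <- which(roles == "guanine" & heavy)
  pep_idx <- which(roles == "protein" & heavy)
  if (!length(pep_idx)) stop("no protein chain in ensemble")
  if (!length(stem_idx)) stop("no guanine stem to superpose onto")

  ref <- ens$coords[1, , ]
  gq_ref <- ref[gq_idx, , drop = FALSE]
  lo <- apply(gq_ref, 2, min) - cutoff - margin
  hi <- apply(gq_ref, 2, max) + cutoff + margin
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / spacing)))

  acc <- array(0L, dim = dims)
  for (f in seq_len(ens$frame_count)) {
    xyz <- ens$coords[f, , ]
    if (f > 1) xyz <- superpose_onto(xyz, ref, stem_idx)
    pep <- xyz[pep_idx, , drop = FALSE]
    gq <- xyz[gq_idx, , drop = FALSE]
    near <- apply(cross_dist(pep, gq), 1, min) <= cutoff
    if (!any(near)) next
    v <- floor(sweep(pep[near, , drop = FALSE], 2, lo) / spacing) + 1
    v <- v[v[, 1] >= 1 & v[, 1] <= dims[1] &
             v[, 2] >= 1 & v[, 2] <= dims[2] &
             v[, 3] >= 1 & v[, 3] <= dims[3], , drop = FALSE]
    if (!nrow(v)) next
    occ <- unique(v)
    acc[occ] <- acc[occ] + 1L
  }
  structure(list(origin = lo, spacing = spacing, dims = dims,
                 values = acc / ens$frame_count, cutoff = cutoff),
            class = "OccupancyGrid")
}

#' @export
print.OccupancyGrid <- function(x, ...) {
  cat("OccupancyGrid:", paste(x$dims, collapse = " x "), "voxels at",
      x$spacing, "A; occupied:", sum(x$values > 0), "\n")
  invisible(x)
}

#' Write an occupancy grid as an OpenDX scalar field
#'
#' Standard molecular-viewer loadable `.dx` (regular positions, z fastest).
#'
#' @param grid an `OccupancyGrid`.
#' @param path output path.
#' @return invisibly, `path`.
#' @seealso [read_dx()]
#' @export
write_dx <- function(grid, path) {
  stopifnot(inherits(grid, "OccupancyGrid"))
  d <- grid$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# occupancy fraction grid",
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.4f %.4f %.4f",
            grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.4f 0 0", grid$spacing),
    sprintf("delta 0 %.4f 0", grid$spacing),
    sprintf("delta 0 0 %.4f", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  # OpenDX order: x slowest, z fastest
  vals <- as.vector(aperm(grid$values, c(3, 2, 1)))
  n <- length(vals)
  idx <- seq(1, n, by = 3)
  lines <- vapply(idx, function(i) {
    paste(formatC(vals[i:min(i + 2, n)], format = "g", digits = 6),
          collapse = " ")
  }, character(1))
  writeLines(lines, con)
  writeLines(c('attribute "dep" string "positions"',
               'object "regular positions regular connections" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}

#' Read an OpenDX scalar field written by [write_dx()]
#'
#' @param path path to a `.dx` file.
#' @return an `OccupancyGrid` (with `cutoff = NA`).
#' @export
read_dx <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  gp <- grep("gridpositions", lines, value = TRUE)[1]
  dims <- as.integer(utils::tail(strsplit(gp, "\\s+")[[1]], 3))
  org <- as.numeric(strsplit(grep("^origin", lines, value = TRUE)[1],
                             "\\s+")[[1]][2:4])
  deltas <- grep("^delta", lines, value = TRUE)
  spacing <- as.numeric(strsplit(deltas[1], "\\s+")[[1]][2])
  start <- grep("data follows", lines)[1]
  end <- grep("^attribute", lines)[1] - 1
  vals <- as.numeric(unlist(strsplit(trimws(lines[(start + 1):end]), "\\s+")))
  stopifnot(length(vals) == prod(dims))
  values <- aperm(array(vals, dim = rev(dims)), c(3, 2, 1))
  structure(list(origin = org, spacing = spacing, dims = dims,
                 values = values, cutoff = NA_real_),
            class = "OccupancyGrid")
}
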