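#' Detect G-quartet layers from the Hoogsteen-bond network
#'
#' Builds a directed graph with an edge G -> G' whenever a `hoogsteen_GG`
#' bond runs from G's donor face (N1/N2) to G''s acceptor face (O6/N7),
#' then extracts directed 4-cycles greedily, largest total incident bond
#' count first (ties broken lexicographically by chain and residue number).
#' Each guanine joins at most one quartet. The channel axis is the principal
#' axis of the quartet centroids (best-fit plane normal when fewer than two
#' layers exist); layers are ordered bottom-to-top along it.
#'
#' @param frame a `StructureModel` with at least 4 guanines.
#' @param criterion an [hbond_criterion()].
#' @param synonyms residue-name synonym table.
#' @return a `QuartetAssignment`: list with `quartets` (list of 4-row
#'   data.frames `chain`, `resid`, in cycle order, layers ordered along the
#'   axis), `axis` (unit 3-vector), `layer_of` (named integer vector keyed
#'   by `"chain:resid"`), and `centroids` (layer x 3 matrix). `quartets` is
#'   empty when no 4-cycle exists (not an error).
#' @examples
#' gq <- build_gq(gq_spec(n_quartets = 3), seed = 1)
#' qa <- detect_quartets(gq)
#' length(qa$quartets)  # 3 layers
#' @export
detect_quartets <- function(frame, criterion = hbond_criterion(),
                            synonyms = default_synonyms()) {
  res <- suppressWarnings(classify_residues(frame, synonyms))
  gua <- res[res$role == "guanine", , drop = FALSE]
  if (nrow(gua) < 4) stop("quartet detection requires at least 4 guanines")
  gkey <- residue_key(gua)

  hb <- detect_hbonds(frame, criterion, synonyms)
  hb <- hb[hb$kind == "hoogsteen_GG", , drop = FALSE]
  empty <- structure(list(quartets = list(), axis = c(0, 0, 1),
                          layer_of = stats::setNames(integer(0), character(0)),
                          centroids = matrix(numeric(0), 0, 3)),
                     class = "QuartetAssignment")
  if (!nrow(hb)) return(empty)

  n <- nrow(gua)
  W <- matrix(0L, n, n, dimnames = list(gkey, gkey))
  dk <- paste(hb$donor_chain, hb$donor_resid, sep = ":")
  ak <- paste(hb$acceptor_chain, hb$acceptor_resid, sep = ":")
  for (i in seq_len(nrow(hb))) W[dk[i], ak[i]] <- W[dk[i], ak[i]] + 1L
  A <- W > 0

  # enumerate unique directed 4-cycles, canonicalized to start at the
  # smallest node index
  cycles <- list()
  seen <- character(0)
  for (a in seq_len(n)) {
    bs <- which(A[a, ])
    for (b in bs[bs != a]) {
      cs <- which(A[b, ])
      for (cc in cs[!cs %in% c(a, b)]) {
        ds <- which(A[cc, ])
        for (d in ds[!ds %in% c(a, b, cc) & A[, a][ds]]) {
          cyc <- c(a, b, cc, d)
          shift <- which.min(cyc)
          canon <- c(cyc[shift:4], cyc[seq_len(shift - 1)])[1:4]
          tag <- paste(canon, collapse = ",")
          if (!tag %in% seen) {
            seen <- c(seen, tag)
            wsum <- W[canon[1], canon[2]] + W[canon[2], canon[3]] +
              W[canon[3], canon[4]] + W[canon[4], canon[1]]
            cycles[[length(cycles) + 1L]] <- list(nodes = canon, w = wsum)
          }
        }
      }
    }
  }
  if (!length(cycles)) return(empty)

  # greedy extraction: most incident bonds first, then lexicographic
  lex <- vapply(cycles, function(cy) paste(sort(gkey[cy$nodes]), collapse = "|"),
                character(1))
  ord <- order(-vapply(cycles, `[[`, numeric(1), "w"), lex)
  used <- logical(n)
  picked <- list()
  for (cy in cycles[ord]) {
    if (!any(used[cy$nodes])) {
      used[cy$nodes] <- TRUE
      picked[[length(picked) + 1L]] <- cy$nodes
    }
  }

  # centroid of each quartet = mean of its guanine base heavy atoms
  at <- frame$atoms
  res_centroid <- function(key) {
    parts <- strsplit(key, ":", fixed = TRUE)[[1]]
    sel <- at$chain == parts[1] & at$resid == as.integer(parts[2]) &
      at$element != "H" & !at$name %in% c("P", "C1'")
    colMeans(as.matrix(at[sel, c("x", "y", "z")]))
  }
  centroids <- t(vapply(picked, function(nodes) {
    colMeans(t(vapply(gkey[nodes], res_centroid, numeric(3))))
  }, numeric(3)))

  if (nrow(centroids) >= 2) {
    cen <- sweep(centroids, 2, colMeans(centroids))
    axis <- svd(cen)$v[, 1]
  } else {
    # single layer: best-fit plane normal of the quartet's atoms
    parts <- gkey[picked[[1]]]
    pts <- do.call(rbind, lapply(parts, function(k) {
      p <- strsplit(k, ":", fixed = TRUE)[[1]]
      sel <- at$chain == p[1] & at$resid == as.integer(p[2]) &
        at$element != "H" & !at$name %in% c("P", "C1'")
      as.matrix(at[sel, c("x", "y", "z")])
    }))
    axis <- svd(sweep(pts, 2, colMeans(pts)))$v[, 3]
  }
  # deterministic sign: largest-magnitude component positive
  axis <- axis / sqrt(sum(axis^2))
  if (axis[which.max(abs(axis))] < 0) axis <- -axis

  proj <- as.vector(centroids %*% axis)
  ord_l <- order(proj)
  picked <- picked[ord_l]
  centroids <- centroids[ord_l, , drop = FALSE]

  quartets <- lapply(picked, function(nodes) {
    data.frame(chain = gua$chain[nodes], resid = gua$resid[nodes],
               stringsAsFactors = FALSE)
  })
  layer_of <- integer(0)
  for (i in seq_along(picked)) {
    layer_of[gkey[picked[[i]]]] <- i
  }
  structure(list(quartets = quartets, axis = axis, layer_of = layer_of,
                 centroids = centroids),
            class = "QuartetAssignment")
}

#' @export
print.QuartetAssignment <- function(x, ...) {
  cat("QuartetAssignment:", length(x$quartets), "layer(s); axis = (",
      paste(sprintf("%.3f", x$axis), collapse = ", "), ")\n")
  invisible(x)
}

# Count hoogsteen_GG bonds within the layers of a (frame-0) assignment for
# one frame.
.count_quartet_hbonds <- function(frame, assign, criterion,
                                  synonyms = default_synonyms()) {
  if (!length(assign$quartets)) stop("empty quartet assignment")
  hb <- detect_hbonds(frame, criterion, synonyms)
  hb <- hb[hb$kind == "hoogsteen_GG", , drop = FALSE]
  if (!nrow(hb)) return(0L)
  dk <- paste(hb$donor_chain, hb$donor_resid, sep = ":")
  ak <- paste(hb$acceptor_chain, hb$acceptor_resid, sep = ":")
  ld <- assign$layer_of[dk]
  la <- assign$layer_of[ak]
  sum(!is.na(ld) & !is.na(la) & ld == la)
}

#' Per-frame quartet hydrogen-bond series
#'
#' Quartet membership is frozen at frame 0 and tracked across frames, so
#' bond loss registers as instability rather than re-assignment. Per frame,
#' Hoogsteen guanine-guanine bonds are counted restricted to within-layer
#' pairs of the assignment; intermolecular (protein-nucleic) bonds are
#' counted alongside when a protein chain is present.
#'
#' @param ens an [ensemble()].
#' @param assign a `QuartetAssignment` computed on frame 1 of `ens`.
#' @param criterion an [hbond_criterion()].
#' @param cutoff instability cutoff passed to [classify_stability()].
#' @param synonyms residue-name synonym table.
#' @return a `StabilitySeries`: list with `per_frame_quartet_hbonds`,
#'   `per_frame_intermolecular_hbonds`, `mean_quartet`,
#'   `mean_intermolecular`, `label`.
#' @export
quartet_hbond_series <- function(ens, assign, criterion = hbond_criterion(),
                                 cutoff = 15, synonyms = default_synonyms()) {
  stopifnot(inherits(ens, "Ensemble"))
  if (!length(assign$quartets)) stop("empty quartet assignment")
  nq <- integer(ens$frame_count)
  ni <- integer(ens$frame_count)
  for (f in seq_len(ens$frame_count)) {
    fr <- get_frame(ens, f)
    hb <- detect_hbonds(fr, criterion, synonyms)
    dk <- paste(hb$donor_chain, hb$donor_resid, sep = ":")
    ak <- paste(hb$acceptor_chain, hb$acceptor_resid, sep = ":")
    hoog <- hb$kind == "hoogsteen_GG"
    ld <- assign$layer_of[dk]; la <- assign$layer_of[ak]
    nq[f] <- sum(hoog & !is.na(ld) & !is.na(la) & ld == la)
    ni[f] <- sum(hb$kind == "intermolecular")
  }
  series <- structure(list(
    per_frame_quartet_hbonds = nq,
    per_frame_intermolecular_hbonds = ni,
    mean_quartet = mean(nq),
    mean_intermolecular = mean(ni),
    label = NA_character_), class = "StabilitySeries")
  series$label <- classify_stability(series, cutoff)
  series
}

#' Classify GQ stability from a quartet hydrogen-bond series
#'
#' A complex is called unstable when the mean within-quartet Hoogsteen bond
#' count over the trajectory is at or below `cutoff` (default 15 of the 24
#' bonds a three-quartet stem carries when intact).
#'
#' @param series a `StabilitySeries` from [quartet_hbond_series()].
#' @param cutoff instability threshold, hydrogen bonds ("or less" semantics:
#'   a mean exactly at the cutoff is unstable).
#' @return `"stable"` or `"unstable"`.
#' @export
classify_stability <- function(series, cutoff = 15) {
  stopifnot(length(series$per_frame_quartet_hbonds) >= 1)
  if (series$mean_quartet <= cutoff) "unstable" else "stable"
}

#' Stability scatter table across complexes
#'
#' One row per complex: mean intermolecular (protein-GQ) hydrogen bonds
#' against mean intra-quartet Hoogsteen bonds, with the stability label —
#' the tabular form of the intermolecular-vs-quartet H-bond scatter.
#'
#' @param complex_results named list of `StabilitySeries`.
#' @param cutoff instability cutoff (bonds).
#' @return data.frame with columns `complex_id`, `mean_intermolecular`,
#'   `mean_quartet`, `label`.
#' @export
stability_scatter <- function(complex_results, cutoff = 15) {
  stopifnot(length(complex_results) >= 1)
  ids <- names(complex_results) %||% as.character(seq_along(complex_results))
  if (is.null(names(complex_results))) names(complex_results) <- ids
  out <- data.frame(
    complex_id = ids,
    mean_intermolecular = vapply(complex_results, function(s)
      s$mean_intermolecular, numeric(1)),
    mean_quartet = vapply(complex_results, function(s)
      s$mean_quartet, numeric(1)),
    stringsAsFactors = FALSE)
  out$label <- vapply(complex_results, classify_stability, character(1),
                      cutoff = cutoff)
  rownames(out) <- NULL
  out
}
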