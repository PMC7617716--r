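# Idealized planar guanine heavy-atom template (standard base reference
# frame, x/y in the base plane, Angstrom). C1' and P are backbone
# pseudo-positions; hydrogens are omitted throughout the fixtures, so the
# heavy-atom hydrogen-bond fallback is the tested default.
guanine_template <- function() {
  m <- rbind(
    N9  = c(-1.289, 4.551),
    C8  = c( 0.023, 4.962),
    N7  = c( 0.870, 3.969),
    C5  = c( 0.071, 2.833),
    C6  = c( 0.424, 1.460),
    O6  = c( 1.554, 0.955),
    N1  = c(-0.700, 0.641),
    C2  = c(-1.999, 1.087),
    N2  = c(-2.949, 0.139),
    N3  = c(-2.342, 2.364),
    C4  = c(-1.265, 3.177),
    `C1'` = c(-2.477, 5.399),
    P   = c(-4.400, 7.100)
  )
  cbind(m, z = 0)
}

#' Specification of an idealized G-quadruplex fixture
#'
#' @param n_quartets number of stacked G-quartet layers (telomeric GQs have 3).
#' @param n_strands molecularity: 4 (tetramolecular), 2 (bimolecular) or
#'   1 (unimolecular).
#' @param nucleic_kind `"DNA"` or `"RNA"` (controls residue naming:
#'   DG/DT/DA vs G/U/A).
#' @param sequence_repeat telomeric repeat; its G-run forms the stem and the
#'   remaining letters become loop/overhang nucleotides. Defaults to
#'   `"TTAGGG"` for DNA and `"UUAGGG"` for RNA.
#' @param rise inter-quartet stacking distance, Angstrom.
#' @param twist helical twist between stacked quartets, degrees.
#' @param hoogsteen_NO_dist target N1(donor)...O6(acceptor) distance within a
#'   quartet, Angstrom.
#' @return a `GQSpec` list.
#' @export
gq_spec <- function(n_quartets = 3, n_strands = 4, nucleic_kind = c("DNA", "RNA"),
                    sequence_repeat = NULL, rise = 3.4, twist = 30,
                    hoogsteen_NO_dist = 2.9) {
  nucleic_kind <- match.arg(nucleic_kind)
  if (is.null(sequence_repeat)) {
    sequence_repeat <- if (nucleic_kind == "DNA") "TTAGGG" else "UUAGGG"
  }
  stopifnot(n_quartets >= 1, n_strands %in% c(1, 2, 4), rise > 0,
            hoogsteen_NO_dist > 0)
  structure(list(n_quartets = as.integer(n_quartets),
                 n_strands = as.integer(n_strands),
                 nucleic_kind = nucleic_kind,
                 sequence_repeat = sequence_repeat,
                 rise = rise, twist = twist,
                 hoogsteen_NO_dist = hoogsteen_NO_dist),
            class = "GQSpec")
}

.placement_cache <- new.env(parent = emptyenv())

# Solve the rigid in-plane placement (rotation theta, translation tx/ty) of
# the guanine template such that four C4-symmetric copies form a quartet with
# N1->O6 and N2->N7 Hoogsteen pairs at the target heavy-atom distance.
# Deterministic; memoized per target distance.
.solve_quartet_placement <- function(target) {
  key <- sprintf("%.6f", target)
  if (!is.null(.placement_cache[[key]])) return(.placement_cache[[key]])
  .placement_cache[[key]] <- .solve_quartet_placement_impl(target)
  .placement_cache[[key]]
}

.solve_quartet_placement_impl <- function(target) {
  tmpl <- guanine_template()
  base_atoms <- rownames(tmpl)[1:11]
  place <- function(p) {
    th <- p[1]
    R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
    xy <- tmpl[, 1:2] %*% t(R)
    cbind(sweep(xy, 2, p[2:3], "+"), 0)
  }
  rot90 <- rotation_matrix(c(0, 0, 1), pi / 2)
  objective <- function(p) {
    g0 <- place(p)
    g1 <- g0 %*% t(rot90)
    d1 <- sqrt(sum((g0["N1", ] - g1["O6", ])^2))
    d2 <- sqrt(sum((g0["N2", ] - g1["N7", ])^2))
    ring0 <- g0[base_atoms, ]; ring1 <- g1[base_atoms, ]
    clash <- max(0, 2.6 - min_dist(ring0, ring1))
    r_o6 <- sqrt(sum(g0["O6", 1:2]^2))
    (d1 - target)^2 + (d2 - target)^2 + 10 * clash^2 + 0.01 * (r_o6 - 3.2)^2
  }
  best <- NULL
  for (th0 in seq(0, 2 * pi, length.out = 9)[-9]) {
    fit <- stats::optim(c(th0, 2.5, 2.5), objective, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  place(best$par)
}

#' Build an idealized G-quadruplex structure
#'
#' Constructs `n_quartets` stacked quartet layers, each four guanines in C4
#' symmetry with donor faces (N1, N2) oriented toward the acceptor face
#' (O6, N7) of the clockwise neighbor at the target Hoogsteen distance;
#' layers are stacked at `rise` with helical `twist`. `n_quartets - 1` K+
#' ions sit on the channel axis midway between adjacent planes (chain
#' `"Z"`). Loop or overhang T/U/A residues from `sequence_repeat` are added
#' with approximate, non-clashing placeholder geometry; the backbone is
#' represented by C1' and P pseudo-positions.
#'
#' The builder self-checks every intra-quartet N1...O6 distance against
#' the window 2.6 to 3.2 Angstrom and errors if construction failed.
#'
#' @param spec a [gq_spec()].
#' @param seed integer seed (construction is deterministic; the seed feeds
#'   only the negligible placeholder jitter of loop residues).
#' @return a [structure_model()] with `n_strands` nucleic chains plus an ion
#'   chain when `n_quartets > 1`.
#' @examples
#' gq <- build_gq(gq_spec(n_quartets = 3, n_strands = 4), seed = 1)
#' sum(classify_residues(gq)$role == "guanine")  # 12 stem guanines
#' @export
build_gq <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "GQSpec"))
  nq <- spec$n_quartets
  g0 <- .solve_quartet_placement(spec$hoogsteen_NO_dist)
  is_dna <- spec$nucleic_kind == "DNA"
  res_g <- if (is_dna) "DG" else "G"
  letter_res <- if (is_dna) c(T = "DT", A = "DA", U = "DU", G = "DG")
                else c(T = "U", A = "A", U = "U", G = "G")

  twist_r <- spec$twist * pi / 180
  top_z <- (nq - 1) * spec$rise
  # column k, layer j: guanine rotated by 90k + twist*j about z, raised j*rise
  col_guanine <- function(k, j) {
    R <- rotation_matrix(c(0, 0, 1), pi / 2 * k + twist_r * j)
    g <- g0 %*% t(R)
    g[, 3] <- g[, 3] + j * spec$rise
    g
  }
  col_angle <- function(k, j) {
    # angular position of column k at layer j (radians); template base
    # centroid defines the reference direction
    ctr <- colMeans(g0[1:11, 1:2])
    atan2(ctr[2], ctr[1]) + pi / 2 * k + twist_r * j
  }

  letters <- strsplit(spec$sequence_repeat, "")[[1]]
  non_g <- letters[letters != "G"]
  g_run_first <- match("G", letters)
  overhang_is_5prime <- !is.null(g_run_first) && !is.na(g_run_first) &&
    g_run_first > 1

  rows <- list()
  add_atom <- function(name, element, resname, resid, chain, xyz) {
    rows[[length(rows) + 1L]] <<- data.frame(
      serial = NA_integer_, name = name, element = element, resname = resname,
      resid = resid, chain = chain, x = xyz[1], y = xyz[2], z = xyz[3],
      stringsAsFactors = FALSE)
  }
  add_guanine <- function(k, j, resid, chain) {
    g <- col_guanine(k, j)
    for (a in rownames(g)) {
      el <- if (a == "P") "P" else substr(gsub("[0-9']", "", a), 1, 1)
      add_atom(a, el, res_g, resid, chain, g[a, ])
    }
  }
  # placeholder nucleotide: a few named atoms at cylindrical (radius, angle, z)
  add_loop_nt <- function(letter, resid, chain, radius, angle, z, jitter) {
    rn <- letter_res[[letter]]
    base_atom <- switch(letter, T = c("N3", "C7"), U = c("N1", "O4"),
                        A = c("N1", "N6"), c("N1"))
    pol <- function(r, a, dz) c(r * cos(a), r * sin(a), z + dz) + jitter
    add_atom("P", "P", rn, resid, chain, pol(radius + 1.6, angle + 0.06, 0.9))
    add_atom("C1'", "C", rn, resid, chain, pol(radius, angle, 0))
    for (i in seq_along(base_atom)) {
      add_atom(base_atom[i], substr(base_atom[i], 1, 1), rn, resid, chain,
               pol(radius - 1.3 - 1.4 * (i - 1), angle - 0.12 * i, -0.4))
    }
  }

  cols_per_strand <- 4L %/% spec$n_strands
  with_seed(seed, {
    for (s in seq_len(spec$n_strands)) {
      chain <- LETTERS[s]
      resid <- 0L
      strand_cols <- ((s - 1L) * cols_per_strand):((s * cols_per_strand) - 1L)
      # 5' overhang (below the bottom quartet) on the first column
      if (overhang_is_5prime && length(non_g)) {
        k <- strand_cols[1]
        for (i in seq_along(non_g)) {
          resid <- resid + 1L
          ang <- col_angle(k, 0) + 0.15 * i
          z <- -1.8 - 2.8 * (length(non_g) - i + 1)
          add_loop_nt(non_g[i], resid, chain, 8.0, ang,
                      z, stats::rnorm(3, 0, 0.01))
        }
      }
      for (ci in seq_along(strand_cols)) {
        k <- strand_cols[ci]
        up <- ci %% 2L == 1L  # alternate 5'->3' direction along columns
        layer_order <- if (up) 0:(nq - 1) else (nq - 1):0
        for (j in layer_order) {
          resid <- resid + 1L
          add_guanine(k, j, resid, chain)
        }
        if (ci < length(strand_cols) && length(non_g)) {
          # connecting loop between this column and the next, arched over
          # whichever face the chain direction ends on
          k2 <- strand_cols[ci + 1]
          at_top <- up
          jz <- if (at_top) top_z else 0
          a1 <- col_angle(k, if (at_top) nq - 1 else 0)
          a2 <- col_angle(k2, if (at_top) nq - 1 else 0)
          for (i in seq_along(non_g)) {
            resid <- resid + 1L
            frac <- i / (length(non_g) + 1)
            ang <- a1 + (a2 - a1 + pi / 2 * 0) * frac
            if (a2 < a1) ang <- a1 + (a2 + 2 * pi - a1) * frac
            z <- jz + (if (at_top) 1 else -1) * (2.6 + 1.6 * sin(pi * frac))
            add_loop_nt(non_g[i], resid, chain, 9.5, ang, z,
                        stats::rnorm(3, 0, 0.01))
          }
        }
      }
      if (!overhang_is_5prime && length(non_g)) {
        # 3' overhang above/below depending on where the last column ended
        k <- strand_cols[length(strand_cols)]
        up <- length(strand_cols) %% 2L == 1L
        jz <- if (up) top_z else 0
        for (i in seq_along(non_g)) {
          resid <- resid + 1L
          ang <- col_angle(k, if (up) nq - 1 else 0) - 0.15 * i
          z <- jz + (if (up) 1 else -1) * (1.8 + 2.8 * i)
          add_loop_nt(non_g[i], resid, chain, 8.0, ang, z,
                      stats::rnorm(3, 0, 0.01))
        }
      }
    }
  })
  # channel K+ ions midway between adjacent quartet planes
  if (nq > 1) {
    for (j in seq_len(nq - 1)) {
      rows[[length(rows) + 1L]] <- data.frame(
        serial = NA_integer_, name = "K", element = "K", resname = "K",
        resid = j, chain = "Z", x = 0, y = 0, z = (j - 0.5) * spec$rise,
        stringsAsFactors = FALSE)
    }
  }
  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  model <- structure_model(atoms)

  # self-check: every intra-quartet N1...O6 adjacent-pair distance in window
  for (j in 0:(nq - 1)) {
    gs <- lapply(0:3, col_guanine, j = j)
    for (k in 1:4) {
      nb <- gs[[k %% 4 + 1]]
      d <- sqrt(sum((gs[[k]]["N1", ] - nb["O6", ])^2))
      if (d < 2.6 || d > 3.2) {
        stop(sprintf(
          "builder self-check failed: N1...O6 = %.3f A outside [2.6, 3.2]", d))
      }
    }
  }
  model
}
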