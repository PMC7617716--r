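#' Featurize a conformer ensemble as pairwise C-alpha distances
#'
#' Each conformer becomes the vector of its `n (n - 1) / 2` pairwise
#' C-alpha distances — a rotation- and translation-invariant shape
#' descriptor for disordered-peptide conformations.
#'
#' @param ens an [ensemble()] whose frames share one residue count (>= 3).
#' @return numeric matrix, one row per conformer, `n (n - 1) / 2` columns
#'   (Angstrom).
#' @export
featurize <- function(ens) {
  stopifnot(inherits(ens, "Ensemble"))
  ca <- which(ens$topology$atoms$name == "CA")
  if (length(ca) < 3) stop("need at least 3 residues (C-alpha atoms)")
  t(vapply(seq_len(ens$frame_count), function(f) {
    as.vector(stats::dist(ens$coords[f, ca, ]))
  }, numeric(length(ca) * (length(ca) - 1) / 2)))
}

#' Cluster conformers by t-SNE embedding + k-means
#'
#' Projects the feature matrix to 2-D by stochastic neighbor embedding at
#' the given perplexity, then partitions the embedding into `k` clusters
#' with k-means. Cluster homogeneity is summarized by the mean silhouette
#' width computed on the embedding (0, with a warning, in degenerate cases:
#' a single cluster or coincident points). Representatives are feature-space
#' medoids.
#'
#' @param features conformer x feature matrix from [featurize()].
#' @param k number of clusters.
#' @param perplexity t-SNE perplexity (the local/global balance; useful
#'   values grow with ensemble size).
#' @param seed integer seed (embedding initialization and k-means starts).
#' @param max_iter t-SNE gradient-descent iterations.
#' @return a `ClusterResult`: list with `labels`, `k`, `silhouette`,
#'   `representatives` (conformer index per cluster), `perplexity`,
#'   `embedding` (n x 2).
#' @export
cluster_conformers <- function(features, k = 50, perplexity = 30, seed = 1,
                               max_iter = 400) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < k) stop("fewer conformers (", n, ") than clusters (", k, ")")
  Y <- tsne_embed(features, perplexity = perplexity, seed = seed,
                  max_iter = max_iter)
  km <- with_seed(seed + 1L, {
    # tight well-separated blobs are prone to k-means local optima: many
    # random restarts are cheap on an n x 2 embedding
    stats::kmeans(Y, centers = k, nstart = 50, iter.max = 200)
  })
  labels <- km$cluster

  sil <- 0
  if (k > 1 && sum(stats::dist(Y)) > 1e-12) {
    sw <- cluster::silhouette(labels, stats::dist(Y))
    sil <- mean(sw[, "sil_width"])
  } else {
    warning("degenerate clustering (single cluster or coincident points); ",
            "silhouette reported as 0")
  }

  reps <- vapply(seq_len(k), function(ci) {
    members <- which(labels == ci)
    if (length(members) == 1) return(members)
    dm <- as.matrix(stats::dist(features[members, , drop = FALSE]))
    members[which.min(rowSums(dm))]
  }, integer(1))

  structure(list(labels = labels, k = k, silhouette = sil,
                 representatives = reps, perplexity = perplexity,
                 embedding = Y),
            class = "ClusterResult")
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat("ClusterResult: k =", x$k, "; mean silhouette =",
      sprintf("%.3f", x$silhouette), "; perplexity =", x$perplexity, "\n")
  invisible(x)
}

#' Extract one representative conformer per cluster
#'
#' The representative of a cluster is its feature-space medoid: the member
#' minimizing the summed distance to all other members (the cluster's most
#' central conformation).
#'
#' @param ens the clustered [ensemble()].
#' @param result a `ClusterResult` for `ens`.
#' @return an [ensemble()] with `k` frames, in cluster order.
#' @export
representatives <- function(ens, result) {
  stopifnot(inherits(ens, "Ensemble"), inherits(result, "ClusterResult"),
            length(result$labels) == ens$frame_count)
  ensemble(ens$topology,
           ens$coords[result$representatives, , , drop = FALSE])
}

#' Silhouette-vs-perplexity scan
#'
#' Re-embeds and re-clusters at each perplexity in `perplexities` and
#' reports the mean silhouette width, the diagnostic used to pick a
#' perplexity that divides the ensemble most discretely.
#'
#' @param features conformer x feature matrix.
#' @param k number of clusters.
#' @param perplexities numeric vector of perplexities to scan.
#' @param seed integer seed.
#' @param max_iter t-SNE iterations per scan point.
#' @return data.frame with columns `perplexity`, `silhouette`.
#' @export
perplexity_scan <- function(features, k, perplexities, seed = 1,
                            max_iter = 300) {
  res <- lapply(perplexities, function(pp) {
    cr <- suppressWarnings(
      cluster_conformers(features, k = k, perplexity = pp, seed = seed,
                         max_iter = max_iter))
    data.frame(perplexity = pp, silhouette = cr$silhouette)
  })
  do.call(rbind, res)
}
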