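#' Yellow-to-black heatmap of a labelled matrix
#'
#' The contact and interaction maps of this pipeline are conventionally
#' drawn on a yellow (low) to black (high) scale.
#'
#' @param m numeric matrix with dimnames (rows plotted on the y axis).
#' @param path output PNG path; `NULL` draws on the current device.
#' @param main plot title.
#' @return invisibly, `path`.
#' @export
plot_heatmap <- function(m, path = NULL, main = "") {
  m <- unclass(as.matrix(m))
  if (!is.null(path)) {
    grDevices::png(path, width = 900, height = 700, res = 110)
    on.exit(grDevices::dev.off())
  }
  pal <- grDevices::colorRampPalette(c("#FFFF00", "#806000", "#000000"))(64)
  old <- graphics::par(mar = c(6, 6, 3, 1))
  on.exit(graphics::par(old), add = TRUE)
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m)[, rev(seq_len(nrow(m))), drop = FALSE],
                  col = pal, axes = FALSE, xlab = "", ylab = "", main = main)
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m), las = 2,
                 cex.axis = 0.6)
  graphics::axis(2, at = seq_len(nrow(m)), labels = rev(rownames(m)), las = 2,
                 cex.axis = 0.6)
  graphics::box()
  invisible(path)
}

#' Scatter plot of intermolecular vs intra-quartet hydrogen bonds
#'
#' One point per complex; the instability cutoff is drawn as a dashed line
#' and unstable complexes are labelled.
#'
#' @param scatter table from [stability_scatter()].
#' @param path output PNG path; `NULL` draws on the current device.
#' @param cutoff instability cutoff to draw.
#' @return invisibly, `path`.
#' @export
plot_stability_scatter <- function(scatter, path = NULL, cutoff = 15) {
  if (!is.null(path)) {
    grDevices::png(path, width = 800, height = 600, res = 110)
    on.exit(grDevices::dev.off())
  }
  cols <- ifelse(scatter$label == "unstable", "#CC3311", "#0077BB")
  graphics::plot(scatter$mean_intermolecular, scatter$mean_quartet,
                 pch = 19, col = cols,
                 xlab = "mean intermolecular H-bonds",
                 ylab = "mean intra-quartet H-bonds",
                 main = "complex stability")
  graphics::abline(h = cutoff, lty = 2)
  bad <- scatter$label == "unstable"
  if (any(bad)) {
    graphics::text(scatter$mean_intermolecular[bad],
                   scatter$mean_quartet[bad],
                   labels = scatter$complex_id[bad], pos = 3, cex = 0.7)
  }
  invisible(path)
}
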