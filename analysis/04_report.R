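#!/usr/bin/env Rscript
# Summarize the complex runs: stability scatter figure, per-GQ contact-map
# and interaction-matrix heatmaps (written by the run itself), and a short
# textual digest of which binding modes dominate each system.

library(gqbind)

out <- "results/complexes"
bundle <- readRDS(file.path(out, "bundle.rds"))

plot_stability_scatter(bundle$scatter, file.path(out, "stability_scatter.png"),
                       cutoff = bundle$manifest$config$thresholds$instability_cutoff)

cat("complexes:", nrow(bundle$scatter), "\n")
cat("unstable:", sum(bundle$scatter$label == "unstable"), "of",
    nrow(bundle$scatter), "\n")
cat("mean intra-quartet H-bonds (stable complexes):",
    round(mean(bundle$scatter$mean_quartet[bundle$scatter$label == "stable"]),
          1), "of 24\n\n")

for (g in names(bundle$mode_matrices)) {
  tot <- vapply(bundle$mode_matrices[[g]], sum, numeric(1))
  cat(sprintf("%-8s dominant mode: %-9s (end_stack %.2f | groove %.2f | loop %.2f)\n",
              g, names(which.max(tot)), tot["end_stack"], tot["groove"],
              tot["loop"]))
  # amino-acid types carrying the most normalized contacts, pooled over modes
  pooled <- Reduce(`+`, lapply(bundle$mode_matrices[[g]], unclass))
  top <- sort(rowSums(pooled), decreasing = TRUE)
  top <- top[top > 0]
  cat("         top residue types:",
      paste(names(utils::head(top, 3)), collapse = ", "), "\n")
}
cat("\nheatmaps and occupancy grids are under", out, "\n")
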