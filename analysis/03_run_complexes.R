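#!/usr/bin/env Rscript
# Enumerate GQ x conformer encounter complexes, simulate a seeded
# pseudo-trajectory per complex, and compute all per-complex and pooled
# analyses (stability series, binding-mode matrices, contact maps,
# occupancy grids). Desk scale: 4 GQ systems x 4 cluster representatives =
# 16 complexes, with two planted-unstable trajectories (the production
# protocol runs 7 x 50 = 350 complexes).

library(gqbind)

out <- "results/complexes"

specs <- list(
  terra6 = gq_spec(n_strands = 4, nucleic_kind = "RNA"),
  terra24 = gq_spec(n_strands = 1, nucleic_kind = "RNA"),
  tel6   = gq_spec(n_strands = 4, nucleic_kind = "DNA"),
  tel22  = gq_spec(n_strands = 1, nucleic_kind = "DNA")
)

cfg <- default_config()
cfg$clustering$perplexity <- 15  # ~ n_raw / 4 at this ensemble size

man <- run_manifest(
  specs,
  n_conformers = 4, n_raw_conformers = 60,
  pose_modes = c("end_stack", "groove", "loop"),
  unstable_jobs = c(6L, 9L),   # one TERRA, one tel complex destabilized
  n_frames = 10, seed = 2024, config = cfg)

jobs <- enumerate_complexes(man)
cat(nrow(jobs), "complex jobs enumerated (", length(specs), "GQs x",
    man$n_conformers, "conformers )\n")

bundle <- run_all(man, out_dir = out, verbose = TRUE)
cat("\nfailures:", nrow(bundle$failures), "\n")
cat("stability scatter:\n")
print(bundle$scatter)
cat("\nunstable complexes:",
    paste(bundle$scatter$complex_id[bundle$scatter$label == "unstable"],
          collapse = ", "), "\n")
saveRDS(bundle, file.path(out, "bundle.rds"))
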