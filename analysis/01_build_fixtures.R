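#!/usr/bin/env Rscript
# Build the GQ fixture library: telomeric DNA and RNA quadruplexes in
# tetramolecular, bimolecular and unimolecular form (7 systems), each a
# three-quartet stem with channel K+ ions and T/U/A loop or overhang bases.
# Writes PDB files plus the pipeline configuration under results/fixtures/.

library(gqbind)

out <- "results/fixtures"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

specs <- list(
  terra6  = gq_spec(n_strands = 4, nucleic_kind = "RNA"),
  terra12 = gq_spec(n_strands = 2, nucleic_kind = "RNA"),
  terra24 = gq_spec(n_strands = 1, nucleic_kind = "RNA"),
  tel6    = gq_spec(n_strands = 4, nucleic_kind = "DNA"),
  tel12   = gq_spec(n_strands = 2, nucleic_kind = "DNA"),
  tel22h1 = gq_spec(n_strands = 1, nucleic_kind = "DNA"),
  tel22h2 = gq_spec(n_strands = 1, nucleic_kind = "DNA", twist = 25)
)

for (i in seq_along(specs)) {
  gq <- build_gq(specs[[i]], seed = 100 + i)
  qa <- detect_quartets(gq)
  hb <- detect_hbonds(gq)
  stopifnot(length(qa$quartets) == 3)
  write_structure(ensemble(gq), file.path(out, paste0(names(specs)[i], ".pdb")))
  cat(sprintf("%-8s %3d atoms, %d quartet layers, %d Hoogsteen bonds\n",
              names(specs)[i], n_atoms(gq), length(qa$quartets),
              sum(hb$kind == "hoogsteen_GG")))
}

write_config(default_config(), file.path(out, "config.yaml"))
cat("fixtures written to", out, "\n")
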