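#!/usr/bin/env Rscript
# Cluster a disordered-peptide conformer ensemble into homogeneous groups
# and keep one central (medoid) conformation per group — the first stage of
# the complex-generation protocol. Desk scale: 150 raw conformers into 10
# clusters (the production protocol groups a much larger ensemble into 50).
# Writes labels, a silhouette-vs-perplexity scan and representative
# conformers under results/clustering/.

library(gqbind)

out <- "results/clustering"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

n_raw <- 150
k <- 10

ens <- make_peptide_conformers(rgg_like_sequence(), n = n_raw, seed = 2024)
feats <- featurize(ens)
cat("featurized", nrow(feats), "conformers x", ncol(feats),
    "pairwise C-alpha distances\n")

scan <- perplexity_scan(feats, k = k, perplexities = c(10, 20, 30, 45),
                        seed = 7)
write_tsv_matrix(scan, file.path(out, "perplexity_scan.tsv"))
best <- scan$perplexity[which.max(scan$silhouette)]
cat("best perplexity:", best, "\n")

cr <- cluster_conformers(feats, k = k, perplexity = best, seed = 7)
print(cr)
write_tsv_matrix(
  data.frame(conformer = seq_along(cr$labels), cluster = cr$labels),
  file.path(out, "labels.tsv"))
reps <- representatives(ens, cr)
write_structure(reps, file.path(out, "representatives.pdb"))
cat("wrote", reps$frame_count, "representative conformers\n")
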