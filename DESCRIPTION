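Package: gqbind
Title: G-Quadruplex Structure Analysis and RGG Peptide Binding Modes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for protein-nucleic-acid complexes of
    telomeric G-quadruplexes (GQ) with disordered arginine-glycine-rich
    (RGG) peptides. Detects hydrogen bonds and G-quartet layers from the
    Hoogsteen-bond network, scores quartet integrity across trajectory
    frames and classifies GQ stability, classifies per-residue binding
    modes (end-stacking, groove, loop), builds composition-normalized
    interaction matrices, residue-wise contact lifetime maps and 3-D
    occupancy density grids, and clusters disordered peptide conformer
    ensembles by stochastic-neighbor embedding followed by k-means.
    Includes generators for idealized GQ fixtures, self-avoiding peptide
    conformers, planted binding poses and unfolding pseudo-trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    cluster,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite
Config/testthat/edition: 3
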