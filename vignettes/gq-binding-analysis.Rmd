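---
title: "Quartet integrity, binding modes and conformer clustering: the methods behind gqbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quartet integrity, binding modes and conformer clustering: the methods behind gqbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gqbind)
```

## The system and the model

A telomeric G-quadruplex (GQ) is a stack of G-quartets: square-planar
cycles of four guanines in which each base donates two Hoogsteen hydrogen
bonds — N1(H)→O6 and N2(H)→N7 — to its clockwise neighbor, 8 bonds per
quartet and 24 for the three-quartet stems formed by d(TTAGGG)n and
r(UUAGGG)n repeats. The quartet carbonyl oxygens (O6) line a central
channel that coordinates K⁺ ions between adjacent planes. Loop and
overhang T/U/A nucleotides connect or flank the guanine columns, and their
arrangement distinguishes tetramolecular, bimolecular and unimolecular
(hybrid) topologies.

Disordered RGG-rich peptide regions recognize GQs in three geometric modes
that are not mutually exclusive: **end-stacking** on a solvent-exposed
terminal quartet, **groove binding** between adjacent strands, and **loop
binding** to the connector/overhang nucleotides. A bound peptide can also
perturb the quartet stack itself; the analyses here quantify both the
recognition geometry and that perturbation from multi-model PDB ensembles
(pseudo-trajectories or conformer sets).

## Hydrogen bonds and quartet detection

The H-bond criterion is the common MD-analysis convention: donor–acceptor
heavy-atom distance ≤ 3.5 Å and, when hydrogens are resolvable on the
donor, an H–donor–acceptor angle ≤ 30°. Structures without hydrogens (all
fixtures here) use the distance-only heavy-atom fallback; this is a
deliberate default, since most deposited GQ structures and many simulation
exports omit hydrogens. Donor/acceptor atoms come from fixed per-residue
tables (guanine donates N1/N2 and accepts O6/N7/N3; protein backbone N
donates and O accepts; polar sidechains as tabulated in
`donor_acceptor_tables()`), which keeps every count auditable.

Quartets are found structurally, not by residue numbering: a directed graph
connects guanine G to G′ when a Hoogsteen bond runs from G's donor face to
G′'s acceptor face, and quartets are directed 4-cycles, extracted greedily
by total incident bond count with lexicographic (chain, residue)
tie-breaking for determinism. The channel axis is the principal axis of
the quartet centroids (best-fit plane normal for a single layer, with the
sign fixed by the largest-magnitude component), and layers are ordered
along it. On the idealized stem the detector also sees ~8 *inter-layer*
Hoogsteen-geometry contacts caused by helical stacking; these are real
geometric contacts but are excluded from integrity scoring, which counts
only within-layer bonds — hence exactly 24 on an intact three-quartet stem.

Quartet membership is frozen at frame 0 and tracked. This is intentional:
when bonds break, re-detection would silently re-assign layers and hide
the loss, whereas tracking registers it as instability. A complex is
labelled **unstable** when its trajectory-mean within-layer count is ≤ 15
of 24 ("or less" semantics: a mean of exactly 15 is unstable; 15.2 is
stable). The classifier is monotone in the cutoff by construction.

## Binding modes, interaction matrices, contact maps

All contact rules use heavy atoms and a closed 4 Å cutoff (a pair at
exactly 4.0 Å counts; the convention is logged, and raising the cutoff can
only add contacts — a property the tests assert). End-stacking is contact
with a quartet guanine O6; the published groove-atom list for guanine
includes an "N6" that guanine does not possess, so the implementation uses
the chemically possible set {N2, C2, N3, C4, C8, N9} with an option to add
N7. Loop binding counts any atom of a loop/overhang nucleotide —
backbone, sugar or base. By default O6 of *any* layer qualifies for
end-stacking (O6 atoms line the channel); an option restricts to the two
outer quartets, and the nearest contacted layer is reported alongside.

Interaction matrices count a residue–base pair once per frame regardless
of how many atom pairs touch (per-residue counting matches
composition-normalized reporting; atom-pair counting is available as a
switch) and divide each amino-acid-type row by that type's count in the
sequence. Types absent from the sequence are omitted rather than reported
as 0/0.

Contact lifetime maps record the fraction of frames in which a protein
residue and a base share a heavy-atom contact; lifetimes under 1 % of
frames are zeroed as noise. Maps keep their integer frame counts
internally, so pooling across complexes is exact, associative and
order-independent, and the persistence filter is re-applied *after*
pooling — a contact sparse in each run but persistent over the pooled
period survives, matching the total-simulation-period reading of the
filter.

## Occupancy grids

Peptide density around the GQ is accumulated on a regular voxel grid
(default 1 Å) after least-squares (Kabsch) superposition of every frame
onto the frame-0 guanine stem, so the density lives in a GQ-fixed frame.
A voxel scores 1 in a frame when at least one peptide heavy atom occupies
it *and* lies within 6 Å of any GQ heavy atom (the first-shell
convention); the value is the mean over frames. Binary per-voxel occupancy
was chosen over Gaussian smearing as the plainest reading of an occupancy
map. The grid origin follows the GQ extent, so uniform translations
reproduce values exactly; uniform rotations preserve total mass up to
voxel-edge reassignment. Output is OpenDX, loadable by standard viewers.

## Conformer clustering

The feature vector is the full set of pairwise Cα distances — rotation-
and translation-invariant and standard for conformational clustering of
disordered chains. A 2-D t-SNE embedding (exact O(n²) implementation:
per-point bandwidths by binary search on the perplexity, early
exaggeration, momentum gradient descent; adequate for the ≤ 10³ conformers
used here) is followed by k-means on the embedding with 50 random
restarts — tight, well-separated embedding blobs are exactly where k-means
local optima occur, and restarts on an n × 2 matrix are nearly free.
Homogeneity is summarized by the mean silhouette width *on the embedding*
(that is the space in which homogeneity is claimed); degenerate cases
(k = 1 or coincident points) report 0 with a warning. Cluster
representatives are feature-space medoids. Perplexity is config-exposed
with a silhouette-vs-perplexity scan; useful values scale with ensemble
size (tens for the desk-scale ensembles here, hundreds to thousands for
production-scale ensembles).

## Synthetic fixtures: what they emulate and what they do not

`build_gq()` constructs quartets from an idealized planar guanine template
(standard base reference frame) by solving the C4-symmetric rigid
placement that puts N1···O6 at the target 2.9 ± 0.05 Å; the builder
self-checks every pair against a 2.6–3.2 Å window. Stems stack at 3.4 Å
rise and 30° twist; K⁺ ions sit on the axis midway between planes (two
ions for three quartets). Loops and overhangs are *geometric
placeholders*: correctly named T/U/A residues (including the thymine C7
methyl) at non-clashing positions, because the analyses test contact and
role logic, not loop conformation. Backbone is reduced to C1′/P
pseudo-atoms, coordinates are treated as pre-imaged (no periodic
boundary), and hydrogens are omitted.

Peptide conformers are persistent self-avoiding random walks of Cα atoms
(3.8 Å virtual bonds, ≥ 4 Å non-adjacent separation) decorated with
approximate backbone N/C/O and a sidechain-centroid CB. The default
53-residue sequence is a synthetic RGG-like composition (RGG/FGG repeats
with interspersed Tyr, Asn, Ser), not the sequence of any real protein.
Planted poses are produced by slide-in rigid docking: the designated
residue (by default an automatically chosen surface-exposed one — a buried
residue of a rigid coil cannot reach a 3.5 Å anchor without steric clash)
leads the approach along its local protrusion direction, with Nelder–Mead
rigid-body relaxation resolving near-miss clashes against a 2 Å steric
floor. Unfolding trajectories displace one stem *column* (one guanine per
layer) along the groove normal — for a tetramolecular GQ this is a
strand's whole stem, while for uni/bimolecular chains displacing the full
chain would move the quadruplex rigidly and break nothing. Each severed
column interface costs 4 bonds per layer (12 of 24 total), so the
trajectory mean crosses the 15-bond cutoff once displacement outruns the
~0.6 Å bond slack; the pipeline's planted-unstable default of 1.5 Å/frame
over 10 frames yields means near 13–14, firmly unstable, while
displacement-free trajectories at 0.08–0.1 Å thermal noise stay at 24.

Consequently, green tests here demonstrate the correctness of the
*operators* — detection, classification, counting, pooling, clustering —
on structures whose ground truth is known by construction. They do not
validate force fields, docking energetics, loop conformations or any
thermodynamic statement about real RGG–GQ systems.

## Numerical and design choices

* Distance comparisons are closed (≤); all thresholds live in one config
  (`default_config()`) and are echoed into run logs, never hard-coded at
  call sites.
* H-bond, quartet and contact detection are brute-force all-pairs at
  fixture scale; tests pin them to independent exhaustive oracles, so any
  later neighbor-list acceleration must reproduce every value exactly.
* Greedy 4-cycle extraction ties break by bond count, then lexicographic
  (chain, resid); detection is invariant under rigid motion and atom-order
  permutation (tested).
* Altloc records keep the highest occupancy; residue numbering is taken
  verbatim from the file; contact-map row labels can carry an author
  numbering offset (default 196, reporting a construct that starts at
  residue 197).
* 5′/3′ overhang bases are classified `loop_nucleotide` (the loop-binding
  rule covers connector *and* overhang bases); a synonym-table edit can
  exclude them.
* Pipeline determinism: every stage seed derives from the manifest seed;
  reruns are byte-identical, cached per-job results make runs resumable,
  and every output carries the manifest MD5 hash.
* Desk-scale problem sizes (chosen for the bundled workflow): 7 GQ
  fixtures of ~206 atoms, 150-conformer ensembles clustered to 10, 16
  complexes of 10 frames; the operators themselves are size-agnostic.

## Known limitations

Placeholder loop geometry cannot support loop-conformation analyses;
intermolecular H-bond counts on fixtures are modest because pseudo-atom
peptides carry only backbone donors/acceptors; the occupancy grid is
world-axis-aligned (rotating *input* data re-voxelizes); and the exact
t-SNE is quadratic in conformer count — beyond ~2000 conformers a
Barnes–Hut implementation would be the right substitute.
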