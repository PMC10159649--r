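---
title: "Geometric contact detection and ensemble analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric contact detection and ensemble analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rinens)
```

# The model

`rinens` treats a conformational ensemble as an ordered list of
*states* — the models of a multi-model PDB/mmCIF file, read in file
order and interpreted as time order for trajectory data. Every state is
reduced to a residue interaction network: nodes are residues
(identified by the canonical key `chain:number[insertion]:name`), edges
are typed non-covalent contacts inferred from atomic geometry alone.
This is the standard geometric-rule approximation: rather than scoring
interaction energies, each interaction class gets a distance gate and,
where physics demands it, an orientation gate. The approximation is
crude per contact but robust in aggregate, and it is cheap enough to
run on hundreds of states.

## Detection rules and their parameters

All thresholds live in `geometric_criteria()` and are exposed to the
user; the defaults below follow common practice for residue interaction
networks. All distances are in Ångström, all angles in degrees, and all
rules operate on heavy atoms so that X-ray structures without hydrogens
work unchanged.

* **Hydrogen bond** (`hbond_max_da = 3.5`, `hbond_min_angle = 90`). A
  donor heavy atom D (amide N, hydroxyls, sidechain N/O donors, base
  amino/imino nitrogens) and an acceptor A with `d(D, A) ≤ 3.5` and
  angle(antecedent–D–A) `≥ 90°`, where the antecedent is D's covalent
  anchor (CA for the backbone amide, CB for a serine OG, …). The
  antecedent angle is a hydrogen-free surrogate for donor
  directionality; when explicit hydrogens are present on D the D–H–A
  angle of the best hydrogen is gated instead. Each donor keeps only
  its closest admissible acceptor — a donor proton is not shared.
* **Ionic bond** (`ionic_max_dist = 4.0`). Centroid of a cationic group
  (Lys NZ, Arg guanidinium, chain N-terminus; His imidazolium only on
  request, since its protonation is unknowable without hydrogens)
  within 4 Å of the centroid of an anionic group (Asp/Glu carboxylate,
  C-terminal carboxylate when OXT is present, nucleotide phosphate).
  Group centroids, not closest atoms, so a bidentate carboxylate counts
  once.
* **π–π stack** (`pipi_max_centroid = 6.5`, `pipi_max_planar_angle =
  30`). Two aromatic ring systems (Phe/Tyr/His rings, both Trp rings,
  purine and pyrimidine rings) with centroid distance ≤ 6.5 Å whose
  planes are either near-parallel (folded angle ≤ 30°) or near-
  perpendicular (≥ 60°, the T-shaped stack).
* **π–cation** (`pication_max_dist = 5.0`, `pication_max_angle = 45`).
  A cationic-group centroid within 5 Å of a ring centroid and within
  45° of the ring normal: the cation must face the π cloud, not the
  ring edge.
* **van der Waals** (`vdw_slack = 0.5`). Heavy-atom pairs within the
  sum of element vdW radii (internal Bondi-style table) plus slack.
  Pairs already explained by a hydrogen or ionic bond are not repeated
  as packing contacts.
* **Disulphide** (`ssbond_max_ss = 2.5`). Cys SG–SG.

Residue pairs closer in author numbering than `min_seq_separation = 2`
within one chain are suppressed (they are covalently constrained, not
interacting); disulphides are exempt because adjacent cysteines can
genuinely bond. Per residue pair and type only the geometrically best
(closest) instance is reported unless `multi_edge` is requested.
Residues outside the chemistry tables — ligands, modified residues —
participate in van der Waals contacts only, and a warning can list
them.

## Ensemble statistics

With per-state networks `N_1 … N_T`:

* **Edge frequency** of a typed contact = (states containing it) / T,
  exact by construction. `frequency_filter()` is inclusive at both band
  ends, so `max_freq` slightly below 1 drops contacts that never break.
* **Probabilistic contact map**: `P[i, j]` = fraction of states in
  which residues i and j share at least one edge of the requested
  scope; symmetric, zero diagonal, indexed by all residues in ensemble
  order, so maps from different scopes are directly comparable.
* **Contact-count matrix** `C`: rows are sequence positions, columns
  states, entries the number of incident edges; each edge increments
  both endpoints, so a column sums to twice the state's edge count.
* **Contact correlation**: Pearson r across states for every pair of
  position rows of `C`. Counts (not binary presence) are the default
  substrate — a literal reading of "number of contacts per position" —
  and an edge-level binary mode is available through
  `edge_presence_matrix()`, with `contact_count_matrix(..., binary =
  TRUE)` as the position-level binary variant. Rows with zero variance
  are reported as `defined = FALSE` with `r = NA` rather than 0: a
  contact that never changes carries no correlation information, and a
  silent zero would mislead exactly the stable contacts users care
  about. Fewer than three states leaves everything undefined. No
  multiple-testing machinery is attached; r is a descriptive screen,
  not a test.

## Clustering

The RMSD matrix is built over a named-atom selection, by default CA
plus C1' — coarse backbone anchors that exist in almost every protein
and nucleotide residue. Every pair of states is superposed
*independently* with the Kabsch algorithm (closed-form SVD solution,
proper rotation enforced), giving the pairwise-optimal, reference-free
distance; this is the stricter reading of "all-versus-all RMSD after
superposition", and a reference-based mode (`reference = k`) is
available for users who want deviations measured in one common frame —
its entries are never smaller than the pairwise-optimal ones.

Agglomerative clustering runs on that matrix through `stats::hclust`
(average linkage by default — robust middle ground for RMSD matrices;
complete and single exposed). The dendrogram is cut at a height in Å
with fixed, documented semantics: merges strictly below the cutoff
join, merges at or above it split. Any inclusive/exclusive convention
would do, but only a fixed one is reproducible. Cluster ids are
numbered by first occurrence in time order, so cluster 1 always
contains state 0. Representatives are *medoids* (the member minimizing
summed RMSD to its cluster, ties to the lowest state index), never
centroids: a representative must be an actual conformation that can be
written out as a structure file.

# Structure input

Parsing is delegated to `bio3d` (PDB per MODEL block; mmCIF through
`read.cif` with models split on `pdbx_PDB_model_num`), then normalized:
author chain/residue numbering is kept (labels must match what users
see in a viewer), waters are dropped by default, hydrogens kept when
present, HETATM residues kept with polymer class `other`, and
alternate locations collapsed to the highest-occupancy conformer (ties
to the alphabetically first altloc) so each state is one consistent
conformer. All states of a multi-model file must carry the same
residue sequence; the first differing residue key is reported
otherwise. Trajectories are expected as multi-model coordinate files —
binary trajectory formats are out of scope, and subsampling arithmetic
(`trajectory_frame_count()`) maps a duration and sampling interval to
a state count.

# Synthetic generators and what they show

All tests run on generated structures with built-in ground truth:

* `make_ideal_helix()` builds a backbone-only polyalanine helix by
  natural-extension-reference-frame chain construction at
  (φ, ψ) = (−57°, −47°) with ideal bond lengths and angles. The
  parametrization puts every N(i+4)…O(i) pair at 3.09 Å — inside the
  hydrogen-bond rule — and, at the N-terminus, N(3)…O(1) at 3.37 Å and
  N(4)…O(1) at 3.21 Å with admissible donor angles. Those two boundary
  contacts are genuine consequences of the written rule (interior
  donors prefer their closer (i, i+4) partner; donors 3 and 4 have no
  closer option), so they are part of the fixture's ground truth
  rather than an error to be suppressed.
* `make_salt_bridge()`, `make_stacked_rings()`, `make_pication_pair()`
  place interacting pairs at 0.85× the active cutoff when "on" and 2×
  when "off" — relative to whatever criteria object is passed, so the
  suite remains valid if defaults change.
* `make_scripted_contact_ensemble()` drives three spatially isolated
  interaction modules (salt bridge, π stack, sidechain hydrogen bond)
  on and off per state from a logical script. Scripted truth covers the
  directional typed interactions; incidental van der Waals packing
  around an "on" module is deliberately not scripted and is excluded
  from truth comparisons (it is covered by the detector–oracle
  equivalence tests instead).
* `make_two_basin_ensemble()` displaces alternating CA positions of a
  reference trace by ±`basin_shift` — an internal deformation rigid
  superposition cannot remove, so the cross-basin RMSD stays near the
  shift — and adds iid Gaussian coordinate noise per state. It emulates
  a two-minimum free-energy landscape with harmonic thermal noise.
* `make_decoy_state()` scatters residues with full typed chemistry at
  realistic local geometry but random global arrangement in a box:
  dense enough that every detector fires, unstructured enough that the
  exhaustive rule-scan oracle is the only ground truth.

What these fixtures do *not* emulate: real sidechain rotamers, chain
connectivity constraints, solvent, or physically continuous dynamics.
Passing tests therefore demonstrate that the rules are implemented
exactly and that the ensemble statistics recover designed signals; they
do not validate the biological accuracy of the default thresholds on
experimental structures, which users should treat as tunable starting
points.

# Numerical choices

* Ring planes are total-least-squares fits (SVD); the normal's sign is
  fixed (positive dot with +z, then +y, then +x) and collinear inputs
  are rejected. All π angles are folded to [0°, 90°], so the sign
  convention cannot affect results.
* Neighbor search uses a cell list with cell edge equal to the cutoff
  (27-cell scan, expected linear time), with a dense-scan fallback for
  small inputs; both are exactly equivalent to the quadratic scan, and
  property tests enforce this up to n = 1000.
* The cutoff comparison is `d ≤ cutoff` with a 1e-12 slack on squared
  distances to keep boundary fixtures deterministic.
* Kabsch superposition enforces a proper rotation (no reflection) by
  sign-correcting the smallest singular vector.
* Edges are oriented canonically (source before target under the
  (chain, number, insertion, name) order), deduplicated per
  (pair, type) by minimum distance with deterministic tie-breaks on
  atom names, so detection is invariant to atom input order.
* `stats::hclust` supplies the merge order; its tie handling is
  deterministic, and the offered linkages are monotone so dendrogram
  heights never decrease.
* Ensembles whose states share one atom topology are detected once at
  the chemistry level and re-evaluated per state only numerically
  (`network_for_ensemble` fast path) — identical results, measured, to
  the state-by-state path.

# Problem sizes in the test suite

The suite checks detector–oracle equivalence on 50 random 200-residue
decoys, scripted-ensemble statistics at 100 states across 100 seeded
replicates, and two-basin recovery across 100 seeded replicates at a
shift-to-noise ratio of 12; these sizes were chosen to make the
statistical claims (≥ 95% decorrelation, 100/100 recovery) meaningful
while keeping a full run in minutes on one CPU. The acceptance script
reports the same quantities at 25 replicates.

# Known limitations

* Thresholds are heuristics; no claim of equivalence to any particular
  published rule set is made, and no energies are computed.
* Protonation states are not predicted: His is aromatic but not
  cationic by default, and hydrogen-bond directionality without
  hydrogens is approximated by the antecedent angle.
* Halogen bonds, metal coordination and water-mediated contacts are
  out of scope.
* mmCIF support covers the `atom_site` coordinate loop (through
  bio3d's reader); chemical-component dictionaries and assembly
  expansion are not interpreted.
* Sequence separation uses author numbering differences; insertion
  codes do not count toward separation.
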