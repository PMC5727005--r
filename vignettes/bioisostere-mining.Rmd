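---
title: "Mining bioisosteric fragment replacements from protein-ligand complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining bioisosteric fragment replacements from protein-ligand complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoswap)
```

## The method

Two chemically different fragments that occupy the same region of two
similar binding pockets, in two independently determined crystal
structures, are good candidates for a bioisosteric exchange: whatever
interactions the pocket supplies, both fragments evidently satisfy them.
`isoswap` turns that observation into a pipeline:

1. **Binding sites** are the protein residues with any heavy atom within a
   cutoff (default 5.0 Å, closed interval) of a ligand heavy atom.
2. **Site description.** Each residue contributes one labeled point — its
   side-chain functional group centroid, labeled `hydrophobic`, `aromatic`,
   `donor`, `acceptor` or `donor_acceptor` from a fixed residue table
   (e.g. Phe ring centroid → aromatic, Ser OG → donor_acceptor).
3. **Superposition.** Two sites are matched through the product graph of
   same-label point pairs, with an edge between two pairs when their
   intra-site distances agree within `eps` (default 2.0 Å). An exact
   maximum clique (igraph's complete search) gives the largest
   distance-consistent correspondence; the matched points are superposed
   with the Kabsch algorithm (proper rotations only). The clique size is
   the alignment score.
4. **Z-filter.** Within a batch of alignments, scores are standardized
   against the batch mean and population standard deviation; alignments
   with Z ≥ 2 are kept. This mirrors normalizing against a large
   all-against-all background. At desk scale the batch is whatever was
   mined together, so two special cases arise (see *Small batches* below).
5. **Transposition and fragmentation.** The second ligand is mapped into
   the first site's frame with the alignment transform. Both ligands are
   cut at every rotatable bond — single, non-aromatic, non-ring bonds
   whose endpoints both have ≥ 2 heavy neighbours. Each broken bond leaves
   a *join atom* (a copy of the cross-bond partner, with its original
   coordinates and Sybyl type) on each side; all other atoms are *core*
   atoms.
6. **Overlap scoring.** Fragment spatial overlap is the Hausdorff distance
   between van der Waals surfaces,
   `HD(A,B) = max{ oHD(A,B), oHD(B,A) }`, where `oHD(A,B)` is the maximum
   over points of A of the distance to the nearest point of B. Three
   variants are stored per pair: *Overall* (all heavy atoms), *Core*
   (core atoms only) and *H-bonding* (donor/acceptor atoms only; absent
   when either fragment has none). Pairs with Overall HD ≤ 1.50 Å (the
   default cutoff) enter the database, in both orientations, together
   with greedily matched corresponding join atoms and the SCOP family
   relation of the two proteins.
7. **Queries.** A replacement search takes a query fragment and applies
   the join/core rules: *specific structure* mode requires an exact match
   including join atoms, where join types are compared strictly or by
   element + hybridization geometry class (so an N.2 join can stand in
   for N.pl3) when interchangeable join types are enabled; *common core*
   mode strips join atoms, matches cores up to labeled-graph isomorphism,
   and remaps the selected join atom onto the replacement by nearest
   matched core position. The *loose* preset is (both families, common
   core); *rigorous* is (intra-family, strict join types, specific
   structure). Join-to-core conversion of non-selected join atoms is
   deliberately not offered; join atoms outside the selected
   reconnection pair are ignored.
8. **Reconnection.** A chosen replacement is grafted back: its selected
   join atom is superposed onto the molecule-side attachment atom, the
   join-to-core bond vector aligned with the original attachment
   direction, one explicit bond formed there, and every further severed
   attachment reconnected by the closest (replacement atom, molecule
   atom) pair in ascending distance order in which both partners still
   have free valence — heavy-atom valence maxima of C 4, N 3, O 2,
   S 2/4/6 by type, halogens 1, with bonds to hydrogens ignored.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| binding-site cutoff | 5.0 | Å | residues defining a site (closed interval) |
| `eps` | 2.0 | Å | distance-consistency tolerance of the product graph |
| `min_score` | 4 | points | smallest clique accepted as an alignment |
| Z threshold | 2 | SD | alignment batch filter |
| HD cutoff | 1.50 | Å | maximal Overall HD for a stored/queried pair |
| surface density | 64 | points/atom | Fibonacci samples per atom sphere (32 in tests) |
| join tolerance | 1.5 | Å | maximal distance for corresponding join atoms |
| page size | 10 | rows | result pagination |

The HD cutoff default of 1.50 Å is the point up to which two fragments
are still loosely superimposable given typical atom radii; it is also the
default for join-atom correspondence. Surface density 64 keeps HD
discretization error well below 0.1 Å for fragment-sized molecules; the
test suite uses 32 to halve the work, which is still far below the 1.50 Å
decision threshold for planted pairs displaced by 0 vs 6 Å.

## Small batches and the Z-filter

The Z-score is meaningful against a population. With three or more
alignments the filter is applied as defined — including the degenerate
zero-spread case, where all Z-scores are 0 and nothing passes a positive
threshold. With only one or two alignments (e.g. mining a single complex
pair) a standard score cannot be formed at all, and the miner falls back
to the absolute clique-size criterion `min_score`, with a message. This
keeps two-complex runs useful while preserving the batch semantics
whenever a batch exists.

## What the synthetic fixtures emulate — and what they do not

`make_complex_pair()` builds two complexes sharing a congruent 6-residue
pocket (Phe, Ser, Leu, Lys, Asp, His side-chain groups on a ~5 Å sphere),
the second rigidly moved by a seeded random transform, with ligands placed
so a designated benzene-core fragment pair coincides up to a chosen
displacement after correct re-alignment. Every output is a pure function
of the seed, and the generator emits the ground-truth transform, the
planted pair's core keys and a recommended site cutoff (5 Å plus the
planted displacement, so that the displaced ligand still defines a site).

This emulates exactly what the mining pipeline consumes: congruent
pockets, a recoverable rigid motion, and fragments in controlled overlap.
It does **not** emulate real structural variability — side-chain rotamers,
backbone plasticity, partial pocket conservation, crystallographic noise,
protonation states or realistic ligand conformations. Passing the planted
tests therefore demonstrates the correctness of the geometry, mining and
query machinery, not the biological recall of the approach on deposited
structures.

Ligand templates are idealized (planar rings, standard bond lengths).
The worked-example inhibitor shipped as
`inst/extdata/murf_inhibitor_synthetic.mol` is a *synthetic
reconstruction* — a sulfonamide wired as
benzothiophene-2-sulfonyl → NH → dichlorophenyl → morpholine — built to
contain the three rings and the linker of the reference worked example and to
fragment into exactly five pieces under the rotatable-bond rule. It is
not the deposited coordinates of the original compound.

## Numerical and design choices

* **Van der Waals radii** are Bondi values; unsupported elements are
  rejected, never defaulted. All surface geometry uses heavy atoms only
  (deposited ligands usually lack hydrogens); donor perception uses
  explicit hydrogens when any are present, otherwise standard-valence
  inference on N and O.
* **Sphere sampling** is a deterministic Fibonacci lattice, so HDs are
  bit-reproducible; buried points are culled with a 1e-6 Å tolerance
  (points exactly on a neighbouring sphere survive).
* **Hausdorff distances** are computed with the same row-wise
  direct-difference arithmetic as a textbook double loop, so they agree
  with an exhaustive oracle exactly, not merely to rounding.
* **Ties.** The maximum clique is made deterministic by choosing the
  lexicographically smallest sorted node-index set among all maximum
  cliques; result rows with equal HD sort by source complex ids and the
  replacement's core key.
* **Kabsch degeneracies** (collinear or coincident points) raise an
  error; mirror solutions are excluded by the determinant correction. One
  property worth stating precisely: removing a matched pair and refitting
  can only lower the residual *sum of squares*, but the per-point RMSD can
  rise when the removed pair had a small residual — the tests check the
  sum-of-squares form.
* **Bond orders from coordinate files.** PDB ligands carry no orders;
  bonds come from CONECT records or, failing that, a distance rule
  (≤ 1.25 × covalent-radius sum, single). Planar 5/6-rings of C/N/O/S
  with aromatic-range bond lengths are then marked aromatic, and
  Kekulé-form connection tables are normalized to aromatic rings on
  reading, so fragments mined from coordinates compare equal to fragments
  drawn as SMILES.
* **Rotatable bonds** include amide C–N bonds by default (a configurable
  exemption exists): the five-fragment worked example calibrates this
  rule.
* **The pair database** is a single versioned JSON file with an in-memory
  index keyed by an order-invariant core fingerprint (exact isomorphism
  confirms within a bucket), plus a JSON-Lines export. A relational
  single-file store would serve equally; the JSON form keeps the artifact
  dependency-free and diffable.
* **Aligner scope.** The site aligner is a contract-compatible surrogate
  for a full local surface-alignment engine: same inputs (two sites),
  same outputs (transform, score, Z-filter). Mining can also consume
  externally computed transforms (12 numbers per line, row-major rotation
  then translation), which is how results from a production aligner would
  be reproduced; the reference two-structure benchmark pairs require
  those deposited entries and are therefore exercised only when the user
  supplies them.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run entirely on generated
inputs: 1000 (tests) / 200 (script) random point-set pairs of up to 200
points for the Hausdorff oracle, 500/200 planted Kabsch recoveries, 50/25
seeded complex pairs for planted-pair mining at density 32, and ~1000/12
randomized or identity fragment replacements. These sizes keep a full run
in the low minutes on one core while leaving each property's decision
margin (e.g. 0 Å vs 6 Å displacement against a 1.5 Å cutoff) orders of
magnitude above the discretization error.

## Known limitations

* The surrogate aligner matches labeled points, not molecular surfaces;
  its scores are clique sizes and are not calibrated to any external
  alignment score beyond the thresholding behaviour.
* Aromaticity from geometry is a heuristic (planarity + bond lengths) and
  will misclassify distorted or unusual rings.
* No protonation-state or tautomer handling; donors/acceptors follow
  simplified rules.
* Reconnection places fragments rigidly and does not relax the product
  geometry.
* Mining is all-pairs within the supplied batch; there is no incremental
  update or prefiltering, which is adequate at desk scale only.
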