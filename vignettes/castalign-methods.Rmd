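---
title: "Three-stage C-alpha structure alignment: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-stage C-alpha structure alignment: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(castalign)
```

## The problem and the model

Structural similarity between two proteins is usually summarized by a rigid
superposition of their backbones and a residue-level correspondence.
`castalign` reduces each chain to its ordered Cα trace and aligns two traces
in three stages:

1. **Seeding.** The intra-molecular Cα–Cα distance matrix is invariant under
   rigid motion, so two rigidly similar fragments have near-identical
   distance sub-matrices.  The seeder scans every diagonal of the
   (position-1, position-2) grid and reports every maximal gapless segment
   pair `(i, j, l)` on which the two distance matrices agree entry-wise
   within `epsilon` over a band of width `d1` (each position is compared
   against the `d1` positions preceding it).  The band makes the scan
   O(`d1·m1·m2`) rather than O(`l²`) per seed.
2. **Superposition.** Each seed's pair set is fed to a least-squares
   rigid-body fit (Kabsch, with a determinant-sign correction so that only
   proper rotations are returned).  The fit and a candidate set are then
   iterated: superimpose, collect *every* residue pair closer than `delta`
   — deliberately ignoring conflicts where a residue appears in several
   pairs — refit, and repeat until the candidate set stops growing.
   Tolerating conflicts during fitting keeps this stage simple and fast:
   no assignment problem is solved per iteration, and ambiguous
   correspondences simply contribute both options to the fit.
3. **Finishing.** The conflict-tolerant candidate set is turned into a
   conflict-free alignment.  Candidate pairs are first grouped into diagonal
   runs; runs shorter than `min_run` (default 4) are discarded as isolated,
   biologically meaningless pairs.  The *sequential* finisher (SPSA) selects
   a non-crossing subset of (possibly truncated) runs by dynamic
   programming, maximizing the number of matched pairs; the *non-sequential*
   finisher (NPSA) drops the order constraint and computes a
   maximum-cardinality bipartite matching, breaking ties toward the smaller
   total pair distance.  Over all seeds the largest alignment wins; its
   transform is refit on the final conflict-free pairs and the reported RMSD
   refers to those pairs.

Alignments are scored with the Q-score,

$$Q = \frac{N_{mat}^2}{\bigl(1 + (\mathrm{RMSD}/r_0)^2\bigr)\, N_1 N_2},
\qquad r_0 = 3\ \text{Å},$$

which is 1 exactly for a full-length, zero-RMSD superposition of
equal-length chains, and with the SAS family

$$\mathrm{SAS}_k = \mathrm{RMSD} \cdot (100 / N_{mat})^k, \qquad k \in \{1,2,3\},$$

whose `k` tunes the length/accuracy trade-off (lower is better; `SAS_1` is
the classical `100·RMSD/N_mat`).  Both formulas follow the published
conventions these scores are known by; the exponent placement in `SAS_k` is
one of two defensible readings and is therefore isolated in the single
function `sas_k()`, so swapping the convention cannot touch any caller.

## Tunable parameters

All distances are in Ångström; defaults live in `align_params()`.

| parameter | default | role and rationale |
|---|---|---|
| `epsilon` | 1.5 | max distance-matrix discrepancy inside a seed; tolerates thermal-scale deformation, rejects topology changes |
| `d1` | 8 | band width of the matrix comparison; the seed condition checks roughly two helical turns of context |
| `l_min_seed` | 8 | minimum seed length; matches the helix-filter scale |
| `helix_min_keep` | 8 | helical runs shorter than this are masked before seeding — short helices are ubiquitous and would flood the seed list; long helices are informative and kept |
| `delta` | 4.0 | candidate-pair cutoff during refinement; about one Cα step, consistent with the ~2 Å RMSD regime of good alignments |
| `max_iter` | 30 | safety cap on refinement; the loop normally stops much earlier, when the candidate set stops growing strictly |
| `r_skip` | 2.0 | a seed already explained to ≤ 2 Å RMSD by a previously fitted transform is skipped as redundant |
| `min_run` | 4 | minimum surviving run in stage 3, for both finishers |
| `r0` | 3.0 | Q-score distance scale |
| `q_threshold` | 0.5 | grouping threshold of the search index |
| `expand_groups` | 10 | groups fully aligned in the second query phase |

`epsilon`, `d1` and `l_min_seed` are not published for this algorithm
family; the values above were fixed once from the geometric arguments given
and are deliberately conservative.  They are all exposed as configuration.

## The search engine

For library search, an offline pass partitions the library into groups in
which **every** pair of members has Q ≥ `q_threshold` (greedy
complete-linkage in input order — the clique-partition constraint itself is
NP-hard, so a deterministic greedy is used and documented).  Each group's
representative is the member with the highest intra-group Q-score sum.  A
query then aligns against one representative per group (phase 1), expands
the `expand_groups` best groups to their full membership (phase 2), and
ranks hits by Q-score with `n_mat`, then id, as tie-breaks.  Phase-1 work is
split into contiguous index ranges whose sizes differ by at most one and
merged in representative order, so results are byte-identical for any
worker count — the single-host contract for distributing representative
alignments over machines.

## What the synthetic generators emulate

The package tests itself on generated backbones, not downloaded structures:

* `make_helix(n)` — ideal α-helix (radius 2.3 Å, rise 1.5 Å/residue,
  100°/residue).  Its closed-form geometry pins the Cα step (~3.83 Å) and
  the `d(i, i+3)` ≈ 5 Å signature the helix mask keys on.
* `make_coil(n, seed)` — self-avoiding random walk with exact 3.8 Å steps
  and ≥ 4 Å non-consecutive separation.  Two independent coils are reliably
  dissimilar, which makes decoys and singleton groups constructible.
* `perturb_copy(chain, sigma, transform, seed)` — rigid copy plus isotropic
  Gaussian coordinate noise.  The true correspondence and transform are
  known, and the expected RMSD under the true correspondence is
  analytically `sigma·sqrt(3)`, so parameter recovery is checkable.
* `make_chimera(parts, seed)` — independently re-oriented parts joined by
  3.8 Å virtual bonds; models partial homology, the case plain geometric
  filters tend to miss.

These generators exercise every code path, but they are not proteins: no
Ramachandran statistics, no side chains, no secondary-structure content
beyond the ideal helices, and noise is isotropic rather than
structure-correlated.  Passing tests therefore demonstrate algorithmic
correctness (optimality, invariance, recovery, determinism), not biological
benchmark performance; evaluations against curated fold classifications
require real structure databases and are out of scope here.

## Numerical and design choices

* **1-based indexing** throughout, as native to R; report files carry the
  original PDB residue numbers (with insertion codes), so internal indices
  never leak.
* **Reflection handling**: the Kabsch fit corrects the sign of the smallest
  singular direction, so every returned rotation satisfies `RᵀR = I`,
  `det R = +1` to 1e-9, including near-planar inputs.
* **Degenerate fits** (fewer than 3 pairs, collinear points) raise typed
  errors; the pipeline skips such seeds rather than aborting.
* **Refinement stopping** is "no strict growth" of the candidate set, with
  the set rebuilt from scratch each iteration; `max_iter` only guards
  floating-point oscillation.  The largest set seen is returned.
* **Chain breaks** (consecutive Cα–Cα distance > 4.5 Å) are treated as hard
  seed boundaries: a gapless seed across a physical break would be
  geometrically meaningless.
* **Helix mask overlap rule**: a seed is dropped only when *both* matched
  segments are ≥ 90% masked, so a short helix packed against informative
  context still seeds.
* **Seed post-processing**: maximal seeds only; overlapping seeds on the
  same diagonal are merged (their union is still non-extendable), avoiding
  redundant refinement of near-identical starts.
* **DP truncation model**: stage-3 selections are built from contiguous
  sub-runs of at least `min_run` pairs, so crossings can be resolved by
  trimming run ends without ever leaving a fragment shorter than the
  stage-3 minimum.  The DP enumerates every sub-run end exactly, with the
  distance sum, then lexicographic order, as tie-breaks; its cardinality is
  tested against an exhaustive memoized oracle on 500 small instances.
* **Weighted matching**: the non-sequential finisher solves a linear
  assignment with a large penalty on non-edges, which yields a
  maximum-cardinality matching of minimum total distance; cardinality is
  cross-checked against exhaustive enumeration and igraph.
* **Tie-break chain** for the winning seed: matched pairs, then RMSD, then
  Q-score; chosen once so that repeated runs are byte-identical.

## Problem sizes used by the test suite

The packaged checks run at desk scale, chosen so the full suite stays fast
while every property is still exercised meaningfully: 200 random pair sets
(4–200 points) against 1,000 random rigid transforms each for fit
optimality; 20 noisy-copy recoveries at n = 150; 500 random small instances
(≤ 12 residues/side) for finisher-oracle equivalence; 50 pairs for mode
dominance; a 100-chain library with 5 planted homologs for retrieval; and
100 alignments of 150-residue pairs for throughput.  `scripts/acceptance.R`
re-runs the same computations from scratch under a caller-supplied seed and
writes the resulting numbers as JSON.

## Known limitations

* PDB input only (no mmCIF); first model only; one chain at a time.
* No flexible or hinge alignment, no gap-penalty scoring, no sequence term.
* The greedy grouping depends on library input order (documented, and
  deterministic for a fixed order); incremental index updates are not
  implemented.
* Helix detection is the Cα-geometric rule above, not a DSSP-style
  assignment.
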