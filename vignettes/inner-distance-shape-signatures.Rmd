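---
title: "Inner distance shape signatures: methods and design notes"
author: "idssr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inner distance shape signatures: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idssr)
```

## The problem

Many macromolecules are flexible: a single protein can adopt conformations
whose rigid-body superposition is poor even though, intuitively, the two
shapes are "the same molecule, bent". Rigid shape descriptors (chord
histograms, spherical harmonics, local curvature statistics) treat a bent
conformer as a different shape, so a retrieval system built on them will
scatter the conformers of one flexible molecule across the database.

The inner distance repairs this. For two points on the molecular surface it
is the length of the shortest path connecting them *through the molecular
volume*. When a shape articulates at a hinge, the Euclidean chord between
points on opposite arms collapses, but the shortest internal path -- which
has to travel along the arms and around the hinge -- barely changes. A
histogram of inner distances over many surface point pairs is therefore
almost invariant under articulation while remaining sensitive to genuine
differences of global shape. That histogram, normalised to a probability
density over 128 bins, is the Inner Distance Shape Signature (IDSS).

## The pipeline

1. **Volume model.** A chain's atoms (van der Waals radii from the Bondi
   table: H 1.20, C 1.70, N 1.55, O 1.52, S 1.80, P 1.80, default
   1.70 Å) are rasterised onto a uniform lattice. A voxel is marked when
   its center lies within `radius + probe` of an atom, and the marked set
   is then eroded by the probe radius. The dilation/erosion pair is a
   morphological closing of the van der Waals union and approximates the
   solvent-excluded (Connolly) volume, exactly so as the lattice step
   shrinks. The erosion uses a digital ball (all integer offsets with
   `|o|*h <= probe`), which is identical to thresholding the Euclidean
   distance transform of the complement at the probe radius. Only the
   largest 26-connected component is kept: inner distances are undefined
   across disconnected pieces.
2. **Landmarks.** `n` surface voxels (occupied voxels with an unoccupied
   6-neighbor) are spread by Lloyd relaxation: assign every surface voxel
   to its nearest site in ambient Euclidean distance, move each site to
   the member voxel nearest its cluster centroid, repeat. The relaxed
   sites are approximately uniform ("blue noise"), which keeps the
   histogram stable across seeds; initialisation is a seeded draw, so the
   whole pipeline is reproducible.
3. **Inner distances.** The occupied voxels (interior included -- paths may
   cut through the volume) form a graph with 26-neighbor edges weighted
   `h`, `h√2`, `h√3`. One Dijkstra sweep per landmark yields all
   `n(n-1)/2` pairwise shortest-path lengths.
4. **Signature.** The lengths are binned over `[0, d_max]` into `B = 128`
   bins and divided by the pair count, giving a PDF.
5. **Similarity.** Two signatures are compared by the Minkowski L1 norm,
   which for PDFs lies in `[0, 2]`; the reported score is `s = 1 - L1/2`,
   1 for identical signatures, 0 for disjoint ones.
6. **Retrieval and maps.** An index of signatures supports ranked queries,
   the group-averaged precision-recall protocol with trapezoidal AUC, and
   classical multidimensional scaling of the `1 - s` distance matrix into
   2D/3D navigation maps with one color per conformational group.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| lattice step `h` | 1.0 Å | ~1 voxel per heavy atom; keeps protein-chain graphs at a desk scale (≤ 96³ cap, `h` auto-rescales above it) |
| probe radius | 1.4 Å | conventional water probe for the solvent-excluded surface |
| landmarks `n` | 128 | 8128 pairs; enough for a stable 128-bin histogram, cheap enough for interactive use |
| bins `B` | 128 | the customary IDSS resolution |
| normalisation | `per_shape_max` | `d_max` = largest observed distance makes the signature scale-invariant; `fixed_range` is available when absolute size matters |
| Lloyd iterations | 20 | relaxation has converged or nearly so on all shapes we generate |
| SD pairs | `n(n-1)/2` | matches the landmark pair count, so SD and D2 histograms have equal sampling depth |
| SHD | 32 shells, `L` = 16, 64×128 sphere grid | standard shell decomposition at desk scale; see quadrature note below |
| SAH ball radius | 4 voxels | large enough that the ball occupancy fraction reads local concavity rather than lattice jitter |

The histogram normalisation question is genuinely open -- nothing in the
method forces one choice -- so both modes are exposed. `per_shape_max` is
the default because flexible-shape retrieval should not separate a molecule
from its uniformly scaled copy, and because it needs no database-wide
calibration pass.

## The synthetic generator

`makeSyntheticShape()` rasterises capsules (rods), articulated capsules
(bent rods), balls and dumbbells directly onto the lattice.
`makeSyntheticBenchmark()` assembles the retrieval testbed: four articulated
tube families, each bent at 0/22.5/45/67.5/90 degrees, plus five balls and
five dumbbells as rigid distractors, all in seeded random orientations. Two
design points matter:

* Families are distinguished by *aspect ratio* while tube radii are shared
  pairwise across families. A local-curvature descriptor (SAH) reads tube
  radius directly, so giving every family its own radius would hand the
  baseline the answer for a reason unrelated to deformation invariance.
  Sharing radii forces every method to read global shape.
* Conformers of one family differ *only* by articulation angle, the
  transformation the signature claims invariance to.

What the generator does **not** emulate: real surface texture (pockets,
clefts, side-chain bumps), density variation, disconnected hetero groups,
or the mild volume changes of real conformational transitions. Passing the
benchmark therefore demonstrates the geometric claims -- articulation
invariance, global-shape sensitivity -- not retrieval quality on any real
protein database.

## Numerical choices

* **Metrication.** Shortest paths on a 26-connected lattice overestimate
  Euclidean length by up to ~8% in direction-dependent fashion, and paths
  between surface landmarks additionally detour around the jagged
  discretized boundary; on convex solids we observe path/chord ratios up
  to ~1.13. This smears fine histograms slightly and is the main reason
  worked similarity scores reproduce only approximately across
  implementations with different lattice settings.
* **SHD quadrature.** Shell functions are sampled on Gauss-Legendre
  latitudes × equispaced longitudes. With 64 Gauss nodes the quadrature is
  exact for integrands of degree ≤ 127, so a shell of constant occupancy
  has *exactly* zero energy at `l ≥ 1`; midpoint latitudes would leak
  a spurious percent-level signal into high degrees.
* **Determinism.** Every stochastic stage (Lloyd initialisation, SD pair
  draw, benchmark orientations) consumes an explicit seed and restores the
  caller's RNG state. Ranked retrieval breaks score ties by lexicographic
  id. MDS axis signs are fixed by making each axis's largest-magnitude
  coordinate positive. Re-running a pipeline with the same configuration
  is byte-identical, and every output embeds the configuration hash.
* **Degenerate inputs.** An all-equal distance multiset puts all mass in
  the top bin; an all-zero one (impossible from distinct landmarks) in the
  first. A distance matrix with fewer than `d` positive eigenvalues is
  zero-padded with a warning. Singleton conformational groups are excluded
  from evaluation (warned) but stay in the database as distractors.
* **Evaluation protocol.** Precision is recorded at each relevant
  retrieval, linearly interpolated onto a 20-level recall grid
  (0.05...1.0), averaged within groups, then across groups; AUC is the
  trapezoidal integral with the first precision value extended to recall
  0. Self-matches are excluded. These conventions are stated here because
  AUC values are only comparable under a fixed protocol.

## Design decisions

* **Paths through the volume, not along the surface.** The inner distance
  is defined inside the shape; the surface-restricted variant is exposed
  separately as the GD baseline, which also serves shapes whose surface
  graph disconnects (e.g. internal cavities raise an error there).
* **D2 vs SD.** Both are Euclidean chord histograms; D2 uses the Lloyd
  landmarks, SD uses seeded uniform random surface pairs. Keeping both
  separates the effect of landmark quality from the effect of the distance
  definition.
* **Classical (Torgerson) MDS** rather than iterative stress majorisation:
  deterministic, dependency-light, and exact for exactly-embeddable
  inputs, which makes the navigation map reproducible run to run. The map
  embeds the pairwise `1 - similarity` matrix -- descriptors enter only
  through their L1 geometry.
* **Similarity map `s = 1 - L1/2`.** The simplest affine map taking the L1
  range `[0, 2]` of PDFs onto scores in `[0, 1]`. For the L2-normalised
  SHD vector the same map is applied and clamped at 0; SHD scores are
  comparable within the method only.

## Problem sizes

The shipped tests and the acceptance script run entirely on generated
shapes: tubes of 30-60 voxel length (1500-5000 occupied voxels, graphs of
20k-70k edges), 128 landmarks, a 30-molecule benchmark. A protein chain at
`h = 1 Å` is one to two orders of magnitude larger in voxel count and takes
a few minutes per structure, dominated by the Dijkstra sweeps.

## Known limitations

* The solvent-excluded volume is a lattice closing, not the analytic
  Connolly surface; thin channels narrower than the probe and sub-voxel
  features are lost.
* Scores depend mildly on `h`, `n` and the normalisation mode, so absolute
  similarity values should only be compared between runs with identical
  configuration (the embedded config hash makes this checkable).
* One chain, first model only; no mmCIF.
* The signature is intentionally blind to articulation; molecules whose
  *function* depends on conformation will look identical to it.
* A volume-matched ball is a surprisingly hard distractor for chord
  histograms: per-shape-max normalisation absorbs much of the chord
  shrinkage under bending, so the chord histogram of a bent tube stays
  closer to the straight tube's than to the ball's even at 90 degrees.
  The articulation advantage of the inner distance shows up reliably in
  the retrieval AUC contrast rather than in every pairwise ordering.
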