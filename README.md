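# idssr — deformation-invariant molecular shape comparison

Flexible molecules bend. A kinase in its open and closed conformations is
one molecule twice, yet most 3D shape descriptors — chord-length
histograms, spherical harmonics, local curvature statistics — see two
different shapes, because all of them change when a shape articulates.
`idssr` implements shape retrieval built on the **inner distance**: the
length of the shortest path between two surface points *through the
molecular volume*. When a shape bends at a hinge, chords across the hinge
collapse but internal paths, forced to travel along the material, barely
change.

The core object is the **Inner Distance Shape Signature (IDSS)**: for a
molecule voxelized into its solvent-excluded volume on a uniform lattice,
sample *n* surface landmarks with Lloyd relaxation, compute all
*n(n−1)/2* pairwise inner distances by Dijkstra sweeps over the
26-connected voxel graph, and bin them into a 128-bin probability density

&nbsp;&nbsp;&nbsp;&nbsp;IDSS = hist(d_inner(p_i, p_j)) / (n(n−1)/2),

compared between molecules by the Minkowski L1 norm of the two PDFs,
reported as a similarity s = 1 − L1/2 ∈ [0, 1]. Around this core the
package provides:

* PDB chain ingestion (`readStructure`), solvent-excluded voxelization
  (`voxelize`), surface extraction, and a synthetic generator of rigid and
  articulated solids (`makeSyntheticShape`, `makeSyntheticBenchmark`);
* five baseline descriptors for benchmarking — D2 (landmark chords), GD
  (surface-restricted geodesics), SD (random-pair shape distribution), SHD
  (rotation-invariant spherical-harmonic shell energies), SAH (solid-angle
  concavity histogram);
* ranked retrieval over a descriptor index, the group-averaged
  precision–recall protocol with trapezoidal AUC, and classical-MDS 2D/3D
  navigation maps with per-group coloring;
* an end-to-end pipeline (`runPipeline`) and a command-line front-end
  (`exec/idssr`) with `synth`, `voxelize`, `describe`, `compare`,
  `pipeline`, `evaluate`, `embed`, `search` subcommands.

## Worked example

Two conformers of one articulated tube against a volume-matched ball:

```r
library(idssr)

rodA <- makeSyntheticShape("bent_rod", length = 40, radius = 3,
                           angle = 20, sourceId = "confA")
rodB <- makeSyntheticShape("bent_rod", length = 40, radius = 3,
                           angle = 70, sourceId = "confB")
ball <- makeSyntheticShape("sphere", radius = 7.5, sourceId = "ball")

rodA
#> VoxelGrid 'confA': 49 x 17 x 10 @ h = 1 A, 1336 occupied voxels

s <- lloydSample(extractSurface(rodA), 128, seed = 1)
allPairsInnerDistances(buildVoxelGraph(rodA), s)
#> InnerDistanceSet 'confA': 8128 pairs from 128 points, range [1.00, 47.54] A

dA <- describeGrid(rodA, "IDSS", seed = 1)$IDSS
dB <- describeGrid(rodB, "IDSS", seed = 1)$IDSS
dS <- describeGrid(ball, "IDSS", seed = 1)$IDSS

similarity(dA, dB)$value   # same molecule, bent 50 degrees further
#> [1] 0.8997
similarity(dA, dS)$value   # different shape, equal volume
#> [1] 0.5449
```

The conformer pair scores ~0.90 although one copy is bent 50° relative to
the other; the unrelated equal-volume pair scores ~0.54. A chord histogram
(`describeGrid(..., "D2")`) separates the two conformers roughly twice as
far as the IDSS does — that contrast is what makes the signature suitable
for flexible-molecule retrieval, and the precision–recall benchmark
(`precisionRecall` over `makeSyntheticBenchmark`) quantifies it as a
consistently higher retrieval AUC for IDSS than for the rigid baselines.

For real structures: `readStructure("1lwm.pdb", "A") |> voxelize()` drops
into the same pipeline, and `Rscript exec/idssr compare --a x.pdb --b
y.pdb` prints the pairwise report.

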