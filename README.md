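# actring

Brownian dynamics and image quantification of actin ring formation in
spherical confinement.

Cell-sized lipid vesicles (GUVs) with encapsulated actin and bundling
proteins are a leading chassis for building a minimal cell-division
machine: under the right conditions the actin condenses into a single
membrane-anchored ring, the precursor of a contractile divisome.
`actring` implements the computational side of that story end to end:

* **Simulation** (`sim_params()`, `run_simulation()`): overdamped
  bead–spring dynamics of polymerizing semiflexible filaments
  (persistence length `Lp`, worm-like-chain bending energy
  `(Lp·kT/l0)(1−cos θ)`) inside a sphere of radius `R`, with
  cross-linking modeled as a short-range inter-filament attraction of
  spring constant `k_atr` and membrane anchoring as a short-range radial
  attraction to the confining boundary. Filament number realizes the
  actin concentration `c` through actin's 370 subunits/µm.
* **Ring scoring** (`build_bundle_graph()`, `classify_ring()`,
  `ring_probability()`): snapshots collapse to a spatial bundle graph;
  a structure is a *ring* when a single unbranched cycle carries ≥ 80%
  of the contour, *ring-like* when the cycle has side branches or the
  path has a gap < 10% of its circumference; sweeps report
  P(ring ∪ ring-like) per condition with exact binomial intervals.
* **Image analysis** (`detect_vesicle()`, `extract_skeleton()`,
  `segment_curvature()`, `membrane_proximity()`,
  `classify_ring_image()`): sphere fit, 3D thinning skeletonization with
  sub-voxel centerline refinement, per-segment Menger curvature
  normalized to membrane curvature (`κ_rel = κ·R_ves`, 1.0 = follows the
  membrane), and a membrane-proximity index
  `P = 2⟨(r/R)³⟩_I − 1 ∈ [−1, +1]` (−1 = all actin at the centre,
  +1 = all on the membrane).
* **Synthetic confocal stacks** (`scene_spec()`, `render_stack()`,
  `fixture_suite()`): parametric rings, arcs, chords and radial control
  distributions rendered with anisotropic PSF, log-normal per-vesicle
  brightness and Poisson + read noise — every quantification stage is
  validated against known ground truth.

## Worked example

```r
library(actring)

## simulate 2 µM actin in a 2.5 µm sphere with membrane anchoring
p <- sim_params(R = 2.5, L = 1.2, c = 2, boundary_mode = "confine_attract",
                total_time = 0.05, snapshot_interval = 0.025)
traj <- run_simulation(p)
final_snapshot(traj)
#> filament_system: 584 beads in 178 filaments, pool 57222 subunits, t = 0.05 s

g <- build_bundle_graph(final_snapshot(traj), bundling_distance = p$r_c)
classify_ring(g)
#> ring_report: none (cycle 0.01 of contour, gap 0.000, 0 side branches)

## synthetic vesicle with a membrane-hugging actin ring, then quantify it
st  <- render_stack(scene_spec("ring", R_ves = 8, seed = 5),
                    render_spec(gain = 0, read_noise_sd = 0,
                                lognormal_sd = 0), seed = 5)
geo <- detect_vesicle(st)
geo
#> vesicle_geometry: R = 8.00 um, centre (9.50, 9.50, 9.50) um, rms residual 0.112 um [membrane]
sk  <- extract_skeleton(st, geo)
sk
#> skeleton: 1 polylines (1 closed), total 50.2 um
segment_curvature(sk, geo, seg_len = 1)
#> curvature_result: 50 segments of 1 um, mean kappa_rel = 1.003 +/- 0.007 (SEM), 0 skipped
classify_ring_image(sk, geo)
#> ring_report: ring (cycle 1.00 of contour, gap 0.000, 0 side branches)
```

The curvature output reads: the traced bundle follows the membrane
(relative curvature 1.0), as membrane-bound bundles do; straight,
unattached bundles measure near 0.

A command-line front end wrapping the same functions lives in
`inst/cli/actring` (`simulate`, `sweep`, `quantify`, `synth`), each
writing a replay manifest next to its outputs.

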