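---
title: "Models and methods: actin ring formation in spherical confinement"
author: "actring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: actin ring formation in spherical confinement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`actring` studies one question: does anchoring actin filaments to the inner
surface of a cell-sized spherical compartment promote their condensation into
a single contractile ring? The package provides (i) a coarse-grained
Brownian-dynamics model of polymerizing, cross-linking semiflexible filaments
in a sphere with optional surface attraction, (ii) the quantification used to
score the outcome -- bundle-graph construction, ring/ring-like topology
classification, ring-formation probability sweeps, simulated
maximum-intensity projections -- and (iii) an image-analysis branch (sphere
fitting, 3D skeletonization, membrane-normalized curvature, a
membrane-proximity index) together with a synthetic confocal generator that
makes every image stage testable against known ground truth.

## The mechanical model

Filaments are bead--spring chains in the overdamped (Brownian dynamics)
regime, updated by Euler--Maruyama:

x <- x + (F/gamma) dt + sqrt(2 kT dt / gamma) xi.

The deterministic force field has four parts, each the exact negative
gradient of a declared potential (the test suite verifies this to 1e-6
against central finite differences):

* **Backbone springs.** Hookean bonds of rest length `l0` (default 0.1 um)
  and stiffness `k_spring` (100 pN/um).
* **Bending.** Discrete worm-like chain, energy `(Lp kT / l0)(1 - cos
  theta)` per interior joint. `Lp = 17` um is the accepted persistence
  length of bare actin; a configuration switch multiplies it to emulate
  cross-linking-induced bundle stiffening.
* **Cross-linking.** Bundling proteins are not explicit; their effect is a
  short-range pairwise attraction between beads on different filaments -- a
  harmonic spring anchored at the contact distance `sigma_c` (0.1 um),
  active out to the capture range `r_c` (0.15 um), with slope `k_atr`
  (default 2 pN/um, the value used for bundle formation without sliding
  compaction). Below contact the same form turns into excluded-volume
  repulsion of stiffness `k_rep`.
* **Boundary.** A stiff radial wall spring (`k_b`) confines beads to radius
  `R`; in `confine_attract` mode an additional harmonic well of stiffness
  `k_ba` (10 pN/um) spans the shell `(R - d_b, R]` (`d_b` = 0.15 um). Its
  depth, about 27 kT per bead, makes anchoring effectively irreversible --
  the model proxy for biotin--neutravidin membrane linkage. A hard radial
  cap at `R + 0.04 l0` backs up the wall spring so the confinement
  invariant holds pathwise, i.e. the wall acts as a stiff spring plus a
  reflecting barrier.

Polymerization adds beads at one filament end only (the barbed end) at rate
`polymerization_rate * dt` per step, along the terminal tangent plus angular
noise, debiting a finite monomer pool. The pool realizes the actin
concentration: with 370 subunits per um of filament, a concentration `c` in
a sphere of radius `R` yields `c N_A V` subunits, and the seed count
`round(c N_A V / (370 L))` makes filaments converge to the target length
`L`. For the printed study conditions (c = 2 uM, R = 2.5 um, L = 1.2 um)
this gives 178 seeds; (c = 2, R = 5, L = 6) gives 284.

The timestep defaults to `0.05 gamma / k_max`, with `k_max` the largest
force constant in play including the effective bending stiffness
`kappa / l0^2`; construction rejects any dt with
`dt * max(k_spring, k_atr, k_b) / gamma >= 0.1`. The drag `gamma` is the
Stokes value for an `l0`-sized segment in water-like viscosity. The
integrator owns a counter-based RNG stream (xoshiro256++ with a Ziggurat
normal sampler), so a run is bit-reproducible from `(params, seed)`
regardless of R's global RNG state.

Numerical validation (all in the test suite, fixed seeds): free-bead
diffusion and trap equipartition to 5%; mean bond length to 5%; two-filament
zipping against the reduced two-particle ODE to 1%; preservation of the
worm-like-chain tangent correlation, started from the exact discrete-WLC
Boltzmann distribution, recovering Lp in {1, 10, 17} um within 15%. The WLC
check runs at 0.4x the default timestep: at `dt k/gamma = 0.05` the
Euler--Maruyama variance inflation visibly broadens the bend distribution of
the floppiest chains (a known first-order-integrator artifact, documented
rather than hidden).

## Scoring ring formation in simulations

A final snapshot is collapsed to a **bundle graph**: beads on different
filaments closer than the bundling distance (default `r_c`), with their
separation transverse to both local tangents, merge by single linkage into
spine points; spine points inherit bond connectivity. The transversality
window (half a bond length) prevents chains of staggered beads from
collapsing a whole bundle into one node.

`classify_ring()` then applies the topology rules: **ring** -- a single
closed cycle carrying at least `f_min = 0.8` of the total contour with no
side branches; **ring-like** -- an open path carrying at least `f_min` of
the contour whose endpoint gap is below `g_max = 0.1` of its would-be
circumference, or a dominant closed cycle with side branches; **none**
otherwise. Side branches shorter than twice the bundling distance are
treated as reconstruction noise. The largest cycle is found exactly:
degree-2 chains of the graph's 2-core are contracted to a junction
multigraph and simple cycles are enumerated by depth-first search; the
test suite pins this against brute-force edge-subset enumeration.
"Small gap" and "at least 80% of contour" are not quantified in the source
material; both thresholds are exposed as arguments and echoed in every
report.

`ring_probability()` runs independently seeded replicates per condition and
reports the ring + ring-like fraction with a Clopper--Pearson 95% interval;
`compare_boundary_modes()` performs the one-sided exact test that surface
attraction increases that fraction.

### What the scaled-down sweep can and cannot show

The acceptance-grade sweep runs the printed grid point (R = 2.5 um, L = 1.2
um, c = 2 uM, k_atr = 2 pN/um), 20 replicates per arm, at a coarser
discretization chosen for throughput (`l0` = 0.2 um, softened springs
`k_spring = k_b = 12` pN/um with the correspondingly larger stable timestep,
capture range scaled with the bead size) and a reduced duration of 0.45
simulated seconds. Under these conditions the two arms separate clearly in
*where* the actin ends up -- with surface attraction the filaments collect
at the membrane (mean radial position near 0.9 R versus 0.6--0.7 R with
confinement alone) -- but neither arm reaches single-ring topology: closure
requires surface patches to coarsen into one band, a process our
explorations place at hundreds of simulated seconds (patch diffusion
coefficients of order kT/(150 gamma), micron-scale spacings, several merge
generations). At the stability-limited timestep that is of order 1e8 steps
per replicate, far beyond any interactive budget, so the topological
ordering test in `test-acceptance.R` is expected to fail at short durations
and is retained as an honest negative: the assertion documents the claim the
model makes at full duration, and the failure documents how far a
desk-scale run gets. Parameter regimes that force faster condensation were
explored and rejected for cause: raising the capture range beyond ~2 kT of
binding energy per bead triggers longitudinal sliding and collapse into
compact three-dimensional aggregates (the compaction regime the k_atr = 2
choice deliberately avoids), while weaker binding leaves the cortex
dispersed.

## The image-quantification pipeline

`detect_vesicle()` fits the algebraic least-squares sphere to
membrane-channel voxels above a robust threshold (Otsu anchored to the
bright tail, followed by two trimmed refits); without a membrane channel it
falls back to the outer hull of the actin signal.

`extract_skeleton()` mirrors a filament-tracing pipeline with deterministic
parts only: median background subtraction; resampling the anisotropic stack
(0.5 um slices) to isotropic voxels; an extra 0.3 um isotropic smoothing
*for binarization only*, which rounds the elongated axial PSF tube so that
3D thinning produces a clean one-voxel centerline; Otsu threshold;
topology-preserving 3D thinning (sequential deletion of simple points, six
directional subiterations); conversion of the voxel skeleton to polylines
between junctions with spur pruning (default 1 um); and sub-voxel refinement
of every polyline point to the Gaussian-window intensity centroid of the
unsmoothed volume. The refinement is computed from four blurred volumes
(`G*I`, `G*(I x)`, `G*(I y)`, `G*(I z)`), which turns each iteration into
trilinear lookups; the window sigma (0.35 um) balances convergence along the
elongated axial PSF against bleeding intensity from neighbouring structures
at crossings. On noise-free renders this centers the ring polyline to ~0.03
um, which is what makes the curvature measurement quantitative.

`segment_curvature()` resamples each polyline at uniform arc length,
smooths lightly (moving average over 1.5 um, circular for closed curves),
cuts consecutive 1 um segments and assigns each the Menger curvature of its
three spanning points. Curvature is reported relative to the membrane,
`kappa_rel = kappa * R_ves`: 1.0 means the bundle follows the membrane,
0 a straight chord. Segments within 1.5 um of an open polyline's end are
excluded -- curvature next to junctions and free ends is reconstruction
artifact. Histogram bins are 0.125 wide over [0, 2.5]; segments count
equally (length weighting would differ only for strongly fragmented
skeletons). The rendered validation: great-circle rings at R_ves 7.5--10 um
give mean kappa_rel = 1.00 +/- 0.01 and straight chords ~0.1.

`membrane_proximity()` maps the actin intensity distribution to one number
P in [-1, +1]: the intensity-weighted mean of the *cubed* normalized radius,
rescaled, `P = 2 <(r/R)^3>_I - 1`. The cube makes all three anchors exact:
signal at the centre gives -1, at the membrane +1, and -- because the volume
element grows as r^2 -- signal uniform over the vesicle volume gives exactly
0. A linear variant (`2 <r/R>_I - 1`, uniform maps to +0.5) is one switch
away. Voxels beyond `R(1 + margin)` are excluded; included radii are clamped
to R so membrane signal spread outward by the PSF still counts as membranal.
The background pedestal is estimated from outside the vesicle (median plus a
4-MAD floor): integrated over the ~1e5 voxels of the lumen, even faint read
noise would otherwise outweigh the actin signal.

## The synthetic microscope

`make_geometry()` builds parametric scenes with exact ground truth:
membrane-hugging great-circle rings, gapped rings, rings with a side branch,
disjoint cortex arcs, straight chords, and the three volumetric proximity
controls (membrane shell, central blob, uniform fill). Arcs and chords are
rejection-sampled to stay 2--2.5 um apart: bundles closer than the PSF
width image as one structure, which would invalidate the fixtures' own
labels. `render_stack()` deposits line integrals by trilinear interpolation
(this preserves intensity centroids exactly, which the proximity anchors
rely on), applies an anisotropic Gaussian PSF (0.15 um lateral, 0.45 um
axial -- plausible for a 40x/1.2 water objective; the source names the
objective but no PSF), scales by a per-vesicle log-normal brightness
(sigma 0.4; encapsulated protein content varies log-normally across a
vesicle population), and adds Poisson shot noise plus Gaussian read noise.
Defaults: 0.2 um lateral voxels and the 0.5 um slice interval of the
experimental stacks; vesicle radii default to the analyzed 7.5--10 um
population.

The three proximity anchor fixtures are rendered *without* PSF or noise:
they probe the index normalization with ideal distributions ("all actin on
the membrane" spread by a 0.45 um PSF is genuinely not all on the membrane,
and measures ~0.93 rather than ~0.96). The structural fixtures keep the PSF
and drop only the noise. What passing on these fixtures does not show:
robustness to deconvolution artifacts, depth-dependent aberrations,
vesicle-shape deviations from sphericity, or densely entangled networks in
which distinct bundles run closer than the PSF width.

## Degenerate inputs and tie-breaks

Zero-length bonds produce a capped (zero) force rather than NaN; blank
channels yield empty skeletons, which classify as `none`; a zero-signal
channel is a fitting error naming the channel tried; non-finite coordinates
abort a run with the partial trajectory preserved. Thinning deletes voxels
sequentially in raster order within six fixed directional subiterations, so
skeletons are deterministic; redundant diagonal adjacencies are dropped
longest-first. Replicate seeds are drawn from one master seed, and every
CLI command writes its manifest before computing.

## Problem sizes

The default test and acceptance runs use desk-scale sizes chosen as such:
stacks of ~40 x 95 x 95 voxels (one vesicle at full calibration), sweeps of
2 x 20 replicates at the coarse discretization above, and physics checks on
hundreds of beads over 1e4--5e4 steps. All were selected so the full suite
exercises every claim end-to-end on one core.
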