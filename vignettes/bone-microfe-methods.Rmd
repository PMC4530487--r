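---
title: "Methods: voxel micro-FE bending analysis and its verification"
author: "bonefe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxel micro-FE bending analysis and its verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bonefe)
```

This vignette explains the models and numerical choices behind the
package: what is computed, under which assumptions, which parameters
matter, what the synthetic phantoms do and do not emulate, and where the
known limitations are.

## The measurement model

A destructive three-point bending test loads a femur supported on two
bottom rollers until failure at a constant crosshead speed (0.1 mm/min).
Three whole-bone properties are read off the load-displacement record:

* **elastic stiffness** — the slope of the linear elastic range (N/mm);
* **yield load** — the force at the changing point between the elastic
  and plastic ranges (N);
* **ultimate load** — the maximum force (N).

The companion micro-FE model answers a different question: given the
bone's imaged geometry and a *reference* tissue modulus, what bending
stiffness would linear elasticity predict?  Because the model is linear
in the tissue modulus, the ratio of measured to predicted stiffness
rescales the reference into the *actual* tissue modulus:

$$E_\text{tissue} = \frac{k_\text{exp}}{k_\text{FE}}\,E_\text{ref},
  \qquad E_\text{ref} = 10\ \text{GPa}.$$

This separates whole-bone (geometry-driven) effects from tissue-level
(material) effects: an intervention can leave $k$ unchanged while
degrading the tissue, or vice versa.

## Image processing chain

The order is fixed: reorient → reduce resolution → threshold → crop →
component cleanup.

* **Reorientation** brings the scan into the test frame (axis 1 = roller
  span, axis 3 = load direction).  Axis permutations/flips are lossless;
  arbitrary rotations use trilinear resampling.  No automatic alignment
  is attempted: the physical mounting cannot be inferred from the image,
  so the rotation is user input.
* **Resolution reduction** from the 25 um scan voxel to 50 um uses the
  block mean — the standard anti-aliasing reduction; it conserves
  integrated intensity exactly, which the tests assert.
* **Segmentation** applies a single threshold at 500 per mille of the
  *maximum possible* intensity of the storage range (default 32767).
  Reading "maximum possible value" as the storage range rather than the
  observed maximum keeps the cut independent of image noise; a
  `reference = "observed"` switch covers the other reading.
* **Cropping** keeps the span between the bottom rollers plus 0.5 mm per
  side.  All coordinate arithmetic is 0-based with half-open intervals
  and voxel centers at $(i + 0.5)h$: rollers at 1 and 11 mm with a
  0.5 mm margin at 50 um give exactly the index range [10, 230).
* **Component cleanup** (not part of the published chain) removes
  floating islands by 6-connected labeling, because disconnected
  fragments make the stiffness matrix singular.  Size ties go to the
  component containing the smallest linear voxel index.

## The voxel micro-FE model

Every bone voxel becomes a cubic 8-node trilinear element (full 2×2×2
Gauss integration); all elements share one 24×24 matrix, scaled linearly
by the tissue modulus and the edge length.  Units are mm / N / MPa, so
stiffness comes out in N/mm.

**Boundary conditions.**  The rollers are idealized as rolling pins: at
each bottom roller the bottom-most bone-surface nodes within one voxel of
the roller plane (across the full width) have only their vertical freedom
fixed.  Rigid-body motions are removed by minimal stabilizers (axis-1
freedom fixed on one support band, axis-2 freedom on a single node).  The
load is a prescribed vertical displacement (default −0.01 mm) on the
analogous top-surface band at the load position.  Full clamping of the
supports would overstiffen the model, so it is deliberately avoided.
The measured sensitivity of the stiffness to the contact-band half-width
(1 → 2 voxels changes $k_\text{FE}$ by ≈7% at 50 um on the validation
cylinder) quantifies the leading boundary-condition uncertainty; the
corresponding physical unknown — how the real rollers distribute contact
— is also the main reason FE and experimental stiffness differ in
practice.

**Solver.**  Prescribed displacements are eliminated exactly (no penalty
terms), so reactions are exact resultants of $K u$.  The constrained
system is solved matrix-free by element-by-element Jacobi-preconditioned
conjugate gradients; the per-element products are batched into a single
BLAS `dgemm` per iteration, which makes ~10⁶-element models tractable on
one core.  An assembled sparse direct route (through the Matrix package)
serves small models and acts as the independent cross-check in the test
suite.  The default stopping rule is a relative residual of 1e-6.  The
stiffness functional converges much earlier than the pointwise residual
(at 1e-4 the stiffness of the 50 um beam is already within 0.03% of its
converged value), so the largest verification meshes are run at 1e-5 —
an order of magnitude of safety margin on a quantity that is itself only
compared at the percent level.

## Verification against beam theory

Timoshenko theory gives the midspan stiffness of a simply supported beam
including shear deformation,
$k = [L^3/(48EI) + L/(4\kappa GA)]^{-1}$, with $\kappa = 5/6$ for a
rectangle and Cowper's expression for a hollow circle.  Two voxelized
geometries anchor the solver to this closed form:

* **Square beam**, 1.2 mm edge, 9.6 mm span.  The FE stiffness is
  +27.9% / +7.3% / +1.2% relative to the closed form at 100 / 50 / 25 um.
  The coarse-mesh excess is the shear locking of fully integrated
  trilinear hexahedra — a stiffness overestimate that vanishes
  quadratically with refinement — so the monotone approach to the beam
  value is itself a verification of the element.
* **Hollow cylinder**, outer radius 1.0 mm, wall 0.5 mm, 7 mm span,
  built through the full phantom → threshold → crop → mesh chain; FE is
  within ~6% of the annulus closed form at 50 um.

The validation geometry is chosen where the *oracle* is valid: beam
theory needs slenderness, and the voxel mesh needs ≈10 elements across
the wall to keep locking small.  Outside that window the discrepancy is
real physics or real numerics, not a solver defect — a stubby
femur-scale cylinder (outer radius 1.5–2 mm on a 7 mm span) sits ~13%
*below* beam theory because of cross-section ovalization and local
contact deformation that Timoshenko theory does not model, while a 0.3 mm
wall (6 voxels) sits ~13% *above* it because of locking.  These two
competing error sources are worth remembering when interpreting absolute
FE stiffness values at 50 um: whole-bone comparisons (treated vs
control, or FE vs FE) are far more accurate than any single absolute
value.

## Load-displacement curve analysis

The published definition of the elastic slope ("slope of the linear
elastic range") does not specify how the range is found.  The package's
rule: among contiguous sample windows that lie in the 10–60% band of the
ultimate force (before the force maximum) and cover at least 15% of all
samples, take the one maximizing R²; break ties by length, then by
earliness.  A best R² below 0.9 flags the fit instead of failing
silently.  Yield is detected as the first sample beyond the fit window
where the measured force drops more than 5% (relative) below the
extrapolated elastic line — a deviation rule rather than a 0.2%-offset
rule, because whole-bone tests have no gauge strain.  Both the band and
the deviation threshold are configurable; machine toe-region trimming is
available but off by default.

On noiseless bilinear curves the analyzer recovers the generator's
stiffness exactly and yield/ultimate to one sample spacing — generator
and analyzer are mutual oracles, and that property is asserted in the
tests.

## Statistics

All paired treated-versus-control comparisons use the Wilcoxon
signed-rank test with zero differences dropped, average ranks for ties,
and the normal approximation *without* continuity correction — the
convention under which three pairs give two-sided p = 0.109, 0.285 and
0.593 for T = 0, 1 and 2.  These three values are the package's anchor
to the statistical engine that produced the published p-values (they
round to 0.11, 0.29, 0.59), and the test suite asserts them to three
decimals.  Because the asymptotic p at n = 3 is an approximation, an
exact mode enumerates all 2ⁿ sign patterns (at n = 3 the smallest
attainable two-sided p is 2/8 = 0.25 — no three-pair comparison can ever
reach significance at α = 0.05, which the tests demonstrate on null
cohorts).  Across-timepoint comparisons of the treated/control ratios
use the two-sided pooled-variance t test (Welch optional).  No
multiplicity correction is applied.

## Synthetic phantoms

No real scans or curves ship with the package; generators replace them.

* **Femur phantom**: a hollow cortical cylinder (defaults: 12 mm shaft,
  2.0 mm outer radius, 0.6 mm wall — typical literature values for a rat
  femur mid-shaft, *not* measured study geometry) rendered at 25 um with
  bone at 75% and background at 5% of the data range, Gaussian
  partial-volume blur (default one voxel), and additive Gaussian noise
  (default 2% of range) clipped to the range.  Treated bones add an
  endosteal "woven bone" shell and periosteal thickening — purely
  geometric mimics of post-ablation bone modeling.  Voxel membership is
  by voxel-center-inside-surface, so the noiseless phantom thresholded
  at 500‰ reproduces the analytic annulus voxel-for-voxel.
* **Load curves**: bilinear elastic/plastic response with a terminal
  failure drop, sampled at the step implied by 0.1 mm/min and the
  sampling interval (default 10 s ⇒ 1/60 mm), plus Gaussian force noise.
* **Paired cohorts**: lognormal control values, multiplicative treatment
  effect, lognormal pair noise; defaults follow the study scale (3 pairs
  per timepoint).

What the phantoms do *not* emulate: trabecular architecture, cortical
porosity, density gradients (the model is binary bone/background),
beam-hardening or ring artifacts, anisotropic tissue properties, and any
real post-ablation biology.  Passing tests therefore demonstrate the
*computational chain* — geometry in, stiffness and statistics out — not
the biological variability of real bones.

## Problem sizes and determinism

The verification suite runs the square beam at 100/50/25 um (up to ~0.9M
elements, ~2.9M unknowns), the validation cylinder at 50 um (~140k
elements), and the end-to-end demo on reduced-size phantoms (8 mm shaft,
1.2 mm radius, processed at 100 um; ~20k elements per bone, two or three
pairs per timepoint) — sizes chosen so the full chain, including two
complete demo reruns, verifies in minutes on a single core.  Every
generator is a pure function of its spec including the seed, the solver
is deterministic, and report files contain no timestamps, so a pipeline
rerun with the same seed is bit-identical — asserted by the tests.

## Known limitations

* Linear elasticity only: yield and ultimate load are *measured* from
  curves, never predicted by the FE model.
* Homogeneous tissue modulus; no density-derived heterogeneity.
* The support idealization (which nodes, which freedoms) is the dominant
  modeling uncertainty for absolute FE stiffness.
* The asymptotic Wilcoxon p at n = 3 is an approximation used for
  comparability; the exact mode is the honest small-sample inference.
* Absolute FE-vs-beam-theory agreement at 50 um is limited by element
  locking (few-percent level); ratios of FE stiffnesses are much more
  accurate.
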