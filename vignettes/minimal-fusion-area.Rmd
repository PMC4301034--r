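---
title: "Finding the minimal mechanically relevant fusion area of a plated nonunion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding the minimal mechanically relevant fusion area of a plated nonunion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nonunionFE)
```

## The model

`nonunionFE` asks a mechanical question about an unhealed fracture held by a
locking plate: which subset of the nonunion cross-section actually has to
fuse for the bone–implant system to carry physiological axial load without
overloading the implant? The package answers it with image-based voxel
finite elements: every non-background voxel of a segmented CT-like volume
becomes one trilinear hexahedral element with isotropic linear-elastic
constants derived from its grayscale, the system is loaded axially by body
weight, and an iterative algorithm strips mechanically idle material out of
the nonunion region.

The modeling assumptions, in order of consequence:

* **Linear elasticity, single static load.** Cyclic weight bearing is
  represented by one static solve per optimization step; in a linear model
  the stress field scales with load amplitude, so a cycle adds no
  information. Gait kinematics, torsion and shear are not represented, and
  bone remodeling over time (load-adaptive maturation) is outside the model.
* **Voxel geometry.** Elements are axis-aligned boxes; surfaces are jagged
  at the voxel scale. This is standard for image-based micro-FE and is the
  reason stress is read at element centroids rather than surfaces.
* **Isotropic material per voxel.** Bone anisotropy and strain-rate effects
  are ignored; the density–modulus power law is a population-level scalar
  relation.

## The control quantity and the two scenarios

All decisions run on a single scalar field: the per-element von Mises
equivalent stress. Two bracketing scenarios anchor the scale:

* **Worst case** — every nonunion cell set to soft tissue (no fusion at
  all). The load has to bypass the gap through the plate; the global maximum
  von Mises stress of this solve (an implant stress concentration) defines
  the reference, mapped to **100** on the scaled axis.
* **Full fusion** — every nonunion cell set to cortical bone; the
  optimization's starting state, and mechanically the other extreme: the
  fused column carries the load and the implant is nearly idle.

On the package's phantoms the fully fused system sits near 8–12 on the
scaled axis, and the worst case at 100 with near-zero stress in the gap —
the implant absorbs the load exactly when the nonunion cannot.

## The optimization loop

From full fusion, each sweep solves the system and simultaneously demotes to
soft tissue every still-active nonunion cell whose von Mises stress is below
`threshold` (default 0.2) times a maximum stress. Demotions are permanent.
The loop ends when (a) a sweep would push the scaled global maximum above
`stopCap` (default 84 on the 0–100 scale) — that sweep is rolled back and
the pre-sweep state reported, (b) no cell qualifies, or (c) `maxSteps`
(default 10) is reached.

Two design points deserve explanation because the problem statement admits
more than one reading:

* **Which maximum anchors the per-cell test.** The package defaults to the
  *current step's* global maximum (`perStepMax = TRUE`). The alternative —
  the fixed worst-case reference — is available as a switch but degenerates
  on idealized geometry: the worst-case maximum is an implant stress
  concentration that sits far above every stress in a well-fused gap, so the
  very first sweep would demote *all* cells, trip the stop cap, roll back,
  and terminate at 0% reduction. With the per-step anchor the threshold
  grows as material is removed and stress concentrates, producing the
  expected progressive cascade (on the toy phantom, the first sweep demotes
  54–58% of the gap). The stop cap is always evaluated on the worst-case
  scale, since it expresses "how close to the no-fusion implant load are we
  willing to go".
* **Simultaneous demotion with look-ahead.** All qualifying cells of a sweep
  are demoted together, then the post-demotion solve is checked against the
  cap; ties at exactly `threshold × max` are retained. Rolling back an
  overshooting sweep guarantees the reported state never violates the cap.

The result object records, per sweep, the removed-cell count, the reduction
as a percent of the initial nonunion cells, the running total, and the
scaled maximum; the surviving-cell mask is the minimal fusion set. The
scaled maximum is non-decreasing across sweeps and the active set strictly
shrinks, which also guarantees termination.

## What the phantom emulates — and what it does not

The generator produces a 12-bit grayscale stack of a hollow cortical
cylinder (cancellous core), a transverse gap filled with soft-tissue gray, a
lateral plate slab and cylindrical locking screws crossing both cortices
above and below the gap, plus additive Gaussian noise clipped to the valid
range. Defaults (desk scale): 48×48×120 voxels at 0.5×0.5×1.0 mm, shaft
outer radius 6 mm, cortical wall 2.5 mm, gap half-width 2.5 mm, plate
3×8 mm spanning z 20–100 mm, four screws of radius 1.5 mm at z = 40, 50,
70, 80 mm, noise SD 50 gray levels. Gray levels (background 0, soft 300,
cancellous 1300, cortical 2600, implant 4000) are spread so the five classes
are separable by thresholds (150, 800, 1950, 3300) with a misclassification
probability around 0.1% at noise SD 50 (3σ separations).

What it deliberately does not emulate: anatomical tibia geometry, the
commercial 14-hole plate, comminuted fracture patterns, CT physics beyond
additive noise (beam hardening, partial-volume blur, metal artifacts).
Consequences for interpretation: passing tests show the *pipeline and
algorithm* behave correctly and that the qualitative conclusion (far less
than full circumferential fusion suffices) reproduces on idealized geometry;
the exact surviving fraction is geometry-specific and transfers to no
clinical case. On an idealized transverse gap the demotion cascade is also
shorter than on an irregular fracture: the fused gap restores an almost
intact load path, stress in it is comparatively homogeneous, and the loop
converges in one or two sweeps rather than six.

## Materials

The grayscale→modulus chain is affine → affine → power law:
HU = g − 1024; ρ = 0.001·HU + 0.224 g/cm³ (a two-point calibration placing
the phantom's cancellous and cortical gray levels at 0.5 and 1.8 g/cm³, in
lieu of a physical calibration phantom); E = 6850·ρ^1.49 MPa, clamped to
[0.1 MPa, 16.7 GPa]. Class constants: soft tissue E = 1 MPa, ν = 0.45;
titanium E = 105 GPa, ν = 0.34; bone ν = 0.3. These are standard literature
ranges, configurable in `calibrationModel()`; the analysis is qualitative
and none of its conclusions hinge on the exact constants. The distinction
between apparent and real density is collapsed into the single calibration
line, as no separate relation is specified anywhere in the problem.

## Numerical choices

* **Element integration** — 2×2×2 Gauss quadrature of the standard trilinear
  hexahedron; the element matrix is assembled as λ·K_λ + μ·K_μ from two
  material-independent parts, so per-element stiffness costs one fused
  multiply over precomputed 24×24 blocks.
* **Solver** — the global system is reduced by eliminating fixed DOFs. The
  `"auto"` policy uses a sparse Cholesky factorization (CHOLMOD via the
  Matrix package) up to 200,000 DOF and Jacobi-preconditioned conjugate
  gradients (tolerance 1e-8, cap 20,000 iterations) beyond. The direct
  branch is preferred wherever it fits in memory because the soft/titanium
  stiffness contrast of 10^5 makes Jacobi-CG converge slowly; every solve is
  residual-checked and the reactions at the fixed nodes are verified to
  balance the applied load.
* **Boundary conditions** — distal fixation clamps all bottom-face nodes of
  the lowest occupied slice; the proximal load (m·g, default 80 kg → 784.8 N
  along −z) is distributed over the top-face nodes of non-implant elements,
  either equally (default) or by tributary area (exact for a uniform
  traction — the closed-form validation tests use this mode).
* **Stress evaluation** — at the element centroid; single-point evaluation
  of a trilinear element is exact for constant-strain states and the
  conventional choice for voxel meshes.
* **Coarsening** — arithmetic window mean, then re-classification with the
  *same* thresholds used for segmentation (one consistent rule, since no
  separate post-averaging threshold is specified); remainder pixels drop
  from the high-index edge, giving `floor(N/level)` widths (512 → 256, 170,
  128, 102, 85, 73, 64 for levels 1–8). Coarsening is 2-D in-plane (slices
  are typically already thicker than pixels); z-binning exists behind a
  flag. The nonunion mask survives a window when it covered at least half
  of it and the re-classified label is tissue.
* **Diffusion** — explicit forward-Euler Perona–Malik, 6-neighborhood,
  zero-flux boundaries, conductance exp(−(|∇I|/κ)²), dt ≤ 1/6 (3-D
  stability bound). The scheme conserves the gray-value sum to rounding.
* **Degenerate inputs** — zero-iteration diffusion, level-1 coarsening and
  zero crop fractions are exact identities; a zero-thickness nonunion slab
  yields an empty mask with a typed warning; geometry that cannot fit the
  grid, non-monotone thresholds, disconnected load paths and non-positive
  scaling references raise typed errors.

## Problem sizes

The package's own test and reproduction runs use: toy phantoms of 16×16×40
to 24×24×60 voxels (2,000–6,000 elements) for algorithmic properties, and
the desk-scale 48×48×120 phantom coarsened at level 2 (≈12,000 elements,
≈44,000 DOF) for the worst-case and optimization runs — mirroring the
workflow of coarsening before simulation rather than solving the raw grid.
A full worst-case solve at that size takes tens of seconds on one CPU; the
optimization run a couple of minutes.

## Known limitations

Axial loading only; no contact, thread or interface mechanics at the screws
(voxel connectivity welds them to bone); isotropic materials; stress read at
centroids underestimates surface concentrations; the phantom's idealized
geometry makes the absolute surviving fraction optimistic relative to real
comminuted nonunions; and the optimization is greedy — demotions are never
revisited, so the surviving set is minimal with respect to the sweep order,
not globally optimal.
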