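---
title: "Methods: modulator design, the dose engine, and the misalignment study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modulator design, the dose engine, and the misalignment study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rm3d)
```

This vignette is the package's account of its science: the models it
implements, the assumptions behind them, the tunable parameters and their
defaults, and the numerical choices that were genuinely open.  Nothing here
states an empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## 1. The problem

A 3D range-modulator (3D RM) is a passive, 3D-printed array of pin-like
structures placed in a single-energy scanned proton beam.  The local
material thickness under each lateral position modulates the beam's
residual range, so an entire spread-out Bragg peak (SOBP) — conformal both
proximally and distally when the pins are target-specific — is delivered in
one fast lateral scan.  The price is a new geometric degree of freedom: the
modulator can be mounted slightly shifted or tilted relative to the beam
axis.  The package designs such modulators and quantifies the dosimetric
effect of misalignment with the field's standard comparison metric, the
local gamma index.

## 2. Beam model

**Depth dose.** The pristine curve is the Bortfeld-style analytic
parametrization: stopping power `∝ u^(1/p−1)` in the residual range
`u = R₀ − z`, a term linear in `u` for fluence loss plus locally deposited
nuclear dose (slope `β = 0.012 cm⁻¹`, local fraction `γ = 0.6`), convolved
with Gaussian range straggling `σ = 0.012 cm · (R₀/cm)^0.935`.  The range
is calibrated to the Bragg–Kleeman power law `R₀ = α E^p` in water with
`α = 0.0022 cm·MeV⁻ᵖ`, `p = 1.77`; at 250 MeV this gives
`range_80 ≈ 386 mm` and a straggling width of 3.65 mm.  The u-singularity
at the end of range is integrated analytically per 0.02 mm cell before the
convolution, so the sampled curve is exact in the cell-average sense.  The
mean excitation energy of water (78 eV) is carried as metadata only — the
range calibration subsumes it.  The beamline is operated with zero momentum
spread; `bragg_curve(straggling_sigma=)` exposes the straggling width for
sensitivity studies.

**Geometry.** Coordinates are right-handed, the beam travels towards +z,
the isocenter is z = 0, and every internal unit is mm.  Scan spots are
deflected at two points (Y magnet at −2560 mm, X magnet at −2000 mm); the
kick angles are the unique two-point solution through the spot position at
the isocenter plane.  The source spot is 3 mm FWHM with a 1 mrad Gaussian
angular divergence.

**Scattering.** Lateral beam sigma combines, in quadrature: source size,
divergence drift, and Highland multiple Coulomb scattering
`θ₀ = 14.1/pv · sqrt(x/X₀) · (1 + log₁₀(x/X₀)/9)` with the full lever-arm
integral for scattering distributed along a slab
(`σ² = θ₀²(x²/3 + xL + L²)`).  `pv` is evaluated at the residual energy at
the middle of the slab.  Radiation lengths come from a small built-in table
(water 360.8 mm, PMMA 340.7 mm, printable polymer 337 mm).  Only the
magnitude and ordering of the blur matters for the study conclusions, which
is what this level of modelling preserves.

**Materials.** The printable polymer has a published density of
1.2 g/cm³ but no published stopping-power ratio; the default RSP of 1.165
is a PMMA-like assumption and is configurable — results that depend on it
(pin heights) scale trivially.

## 3. SOBP weights and pin contours

`optimize_sobp_weights()` solves non-negative least squares on a 0.5 mm
depth grid for layer weights on a uniform WET ladder (default step: the
3 mm pin period in water-equivalent mm).  Two conventions matter:

* **`distal` is the depth of the distal-80% falloff** of the SOBP, i.e. the
  deepest layer is pulled back so its own `range_80` lands exactly at
  `distal`.  The *flat* region therefore ends where the deepest pristine
  peak culminates, `plateau_distal = distal − (range_80 − peak_depth)`
  (≈ 3.3 mm at 250 MeV); fitting a flat target into the falloff region
  would force oscillating weights and plateau ripple.  With this window the
  34-layer, 10 cm design meets the package's 1% flatness contract.
* **No explicit regularization.** The NNLS solution has sparse support
  (some layers are exactly zero).  Smoothness-promoting variants
  (second-difference penalties, monotone-cone fits) were evaluated and
  rejected because every variant that visibly smoothed the weights violated
  the 1% flatness contract.  The sparse support has one physical
  consequence discussed in §7.

A **step contour** assigns each layer a partial area of the 3 mm square
cell exactly proportional to its weight, arranged as concentric square
rings with the tallest level at the cell center (square rings tessellate
the square cell exactly; the ring order is a convention, since only the
area-per-WET distribution enters the physics).  Heights are
`WET / RSP(material)`.

A **stepless contour** interpolates the cumulative area-vs-WET staircase:
within the WET bin of every layer `k ≥ 2` the cumulative area rises
linearly by exactly `w_k`, so re-binning at the design step reproduces the
weights exactly and each interior layer keeps its mean pullback.  The
deepest layer cannot ramp below zero removable material; it remains a flat
valley floor (an atom at WET 0), exactly as in the step contour and as in
printed stepless modulators.  This choice keeps the distal edge of the
SOBP identical between the two pin kinds, which is what makes them
dosimetrically interchangeable.

## 4. The rotated-cube modulator

The study target is a 6 cm cube rotated 45° about x and then y, one corner
towards the nozzle: in beam's-eye view it presents every SOBP length from
zero to the 85 mm central chord, with sharp dose gradients — a deliberate
worst case.  `target_depth_interval()` intersects axial rays with the cube
analytically in the cube's own frame.

Per 3 mm pin cell whose center falls inside the silhouette (+ one period of
margin), the builder solves the layer weights for that pin's chord and adds
a uniform **compensator offset** so the pin's deepest Bragg peak lands on
its own distal edge.  Pin intervals are quantized to 1 mm to cache weight
solves.  The cube's depth defaults to the deepest reachable placement (the
distal corner needs zero offset); the phantom, pre-absorber (170 mm PMMA),
air gaps (5 mm modulator–absorber, 50 mm absorber–phantom) and scoring grid
(2.5 mm lateral, 1 mm depth, depths counted from the phantom surface)
follow the reference setup; a baseline variant (200 mm PMMA, isocenter
90 mm inside the phantom, no modulator) is a second preset.

Since clinical spot-weight optimization is proprietary, the raster plan
uses a documented heuristic: per-spot MU is the cell average of the
per-pin unnormalized weight totals (zero outside the pin field).  This
delivers an approximately flat lateral plateau; none of the robustness
comparisons depend on the exact MU pattern, because reference and
misaligned scenarios share it.

## 5. Mesh geometry and the WET class field

Modulators tessellate to a union of closed, outward-oriented solids (base
slab, four wall boxes, one concentric-ring "wedding cake" per pin), so
every edge is shared by exactly two triangles and the enclosed volume
equals the analytic volume.  Misalignments are applied to the mesh
(`v → R(v − pivot) + pivot + t`), mirroring an STL-transform workflow, and
the transformed mesh is re-rasterized.  STL I/O supports the binary and
ASCII dialects (mm units, binary default).

The engine does **not** point-sample modulator heights.  Small layer
weights map to concentric rings down to a few *hundredths* of a millimetre
wide; any practical sampling lattice aliases them, which measurably
distorts the SOBP.  Instead the modulator is reduced to a **WET class
field**: per 0.5 mm lateral cell, the area fraction occupied by each
quantized total-WET class (0.25 mm default quantization).  For the nominal
device the fractions are closed-form (the Chebyshev ball of a square pin
intersects an axis-aligned cell in a product of interval overlaps).  For a
transformed mesh they come from scanline rasterization onto a dense
sub-ray lattice — `cell_size/subsamples` pitch, with a deterministic
golden-ratio jitter of each row's y position and x origin.  The jitter
converts what would be a systematic aliasing bias (every pin repeats at the
same lattice phase) into unbiased stratified noise that averages out across
rows and pins; it is seed-free and reproducible.  The identity-transformed
mesh path agrees with the analytic path within the 0.5% contract that the
suite enforces.

## 6. Dose engine and fluence scoring

For each scan spot the class-field cells inside ±3σ of the spot at the
modulator plane are weighted with the cell-integrated Gaussian fluence,
carried to the phantom entrance along the spot axis, and accumulated into
(lateral voxel × WET class) fluence matrices.  The dose is then one matrix
product with the per-class pulled-back Bragg curves, followed by a
depth-dependent separable Gaussian lateral blur (absorber and in-water
scattering with full lever arms, plus residual divergence).  Everything is
deterministic and exactly linear in MU.

Approximations, stated explicitly:

* **Thin-modulator projection**: the pin WET is assigned at the modulator
  plane; rays travel parallel to their spot axis inside the phantom
  (in-phantom divergence ≤ ~2 mm at the field edge is neglected, and it is
  common to reference and scenario runs).
* **In-pin scattering is neglected for dose** (the absorber dominates the
  blur); it *is* modelled for fluence scoring, where it is the effect under
  study: each sub-ray spreads with the Highland angle of its own pin path
  and the corresponding lever arm, which produces the strong 3 mm-periodic
  fluence texture directly behind the modulator and its complete washout
  behind the absorber (the suite checks CoV > 0.1 at the modulator exit and
  a ≥ 5× drop at the phantom surface).
* **Nuclear interactions** reduce to an optional linear fluence attenuation
  per mm WET (off by default): SOBP flatness and tilt sensitivity are
  WET-distribution effects.

For a *single pencil* the flat quantity is the laterally **integrated**
depth dose (the central-axis dose of a pencil falls with depth simply
because scattering dilutes it); the tilt sweep therefore compares IDDs.
For the scanned cube field the center-line profile is itself the SOBP.

**Problem sizes.** The default "desk" profile uses 0.5 mm class-field
cells with 15×15 sub-rays per cell for mesh rasterization and 0.25 mm WET
quantization; the tilt sweep uses 25×25 sub-rays and 0.1 mm quantization on
a 30 mm half-extent, 1 mm-lateral grid.  A "full" profile doubles the mesh
sub-sampling.  These sizes keep a complete five-scenario study in the
minutes range on a single core while the sampling noise stays well below
the 2% gamma criterion; they are engine resolutions, not physics.

## 7. Gamma analysis and the scenario runner

The gamma index follows the standard Low formulation with local
normalization: `γ²(r) = min_e |e−r|²/dta² + (D_e(e)−D_r(r))²/(dc·D_r(r))²`,
evaluated only for reference voxels above 20% of the maximum (which also
guards the local denominator).  The evaluated distribution is interpolated
multilinearly on a search lattice of `dta/10` within a radius of `3·dta`;
an independent brute-force dense-search implementation exists solely as the
oracle in tests (the two must agree within 0.01 in γ; for such comparisons
the two search lattices must be commensurate with the voxel spacing).
Slice gamma is evaluated strictly within the extracted 2D plane, matching
a 2D-array measurement.  Passing rates are kept at full precision and only
rounded to integer percent in the report renderer.

Scenario conventions: rotations are right-handed about the named axis; the
mounting-point pivot sits at (−200, 0, −180) mm relative to the modulator
isocenter, which this package defines as the footprint center at the
pin-base plane (a convention — the device has no canonical origin).  The
reference dose is computed through the *same* mesh path with an identity
transform, so rasterization effects cancel in every comparison.  The
distal-surface displacement is the median over well-sloped columns of the
local shift implied by the distal-80% depth map; the center-line SOBP
plateau for deviation metrics ends where the reference rolls below 95% of
its plateau level, because lateral mixing with shallower neighboring pins
rounds the distal shoulder of the widest SOBP.

## 8. What the synthetic study does and does not show

All inputs are generated internally under the study conditions: the
rotated-cube target, the reference beamline and phantom geometry, the
single-energy plan, and the 10 cm-SOBP 2D modulators.  Passing tests
demonstrate that the *mechanisms* of misalignment sensitivity — distal
surface translation under device shifts, proximal/distal asymmetry, strong
degradation beyond ~1° of tilt, step/stepless equivalence — are reproduced
by a transport model whose fidelity is deliberately limited.  They do not
demonstrate agreement with measurements, which requires a physical beam,
nor absolute dose.

Known limitations:

* Without in-pin transport, multiple scattering inside the ~90 mm pins —
  which in reality mixes WET laterally by ~0.5 mm even at perfect alignment
  — is absent at 0°.  A 0.5° tilt (0.76 mm shear over the pin height) is
  therefore the *first* sub-millimetre mixing the engine sees, and the
  computed SOBP deviation at 0.5° (≈ 1%, concentrated at the distal plateau
  edge) overestimates what full transport shows for the same geometry.  The
  effect is second-order at 1–2° tilt, where the engine's degradation is
  dominated by genuine WET redistribution.
* The NNLS weight vector's sparse support produces a few step walls
  spanning several WET layers, which makes the small-angle response
  somewhat dependent on the optimizer's degenerate solution choice; real
  designs with proprietary optimizers may distribute weights differently.
* No CT heterogeneity, apertures, LET/RBE, secondary-particle spectra, or
  dose-rate time structure; water phantom only.
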