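---
title: "Modelling spring-assisted cranioplasty: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling spring-assisted cranioplasty: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its science: the forward
model and its assumptions, the parameters that matter, the numerical
choices, and what the synthetic skull does and does not capture about
real patients.

## The forward model

Spring-assisted cranioplasty widens a scaphocephalic head by removing a
midline bone strip and letting pre-compressed springs push the parietal
bones apart. The package models the immediate (elastic) response of the
skull to spring insertion as one linear boundary-value problem per
parameter configuration:

1. **Geometry.** The calvarium is idealised as an ellipsoid-like shell
   of uniform thickness *t*, truncated by the basal plane *z* = 0. The
   outer surface is an ellipsoid with anterior–posterior length 165 mm,
   breadth 116 mm and height 87 mm by default (cranial index ≈ 0.70, a
   scaphocephalic five-month-old). The ellipsoid's equator sits
   `base_offset_mm` = 15 mm above the basal cut, so the widest and
   longest points of the skull lie above the fixed base, as on a real
   head — this matters because the cranial dimensions are measured on
   the deforming surface, and extremal landmarks pinned to the fixed
   boundary could not move at all.
2. **Regions.** Transverse coronal and lambdoid fibrous bands (2 mm
   wide, one element column each) separate frontal, parietal and
   occipital plates; a fibrous anterior fontanelle patch (radius 10 mm)
   sits at bregma, confined to the coronal band so that no fibrous
   tissue bridges the future osteotomy strip; the sagittal midline is
   bone — the synostotic fusion itself. Bone is isotropic linear
   elastic (default E = 421 MPa, ν = 0.22), fibrous tissue much softer
   and nearly incompressible (16 MPa, 0.49).
3. **Surgery.** The osteotomy removes the parietal elements inside the
   strip |y| ≤ OS/2 strictly between the suture bands. Springs attach
   to the two cut edges: the anterior spring at arc distance SP
   posterior to the coronal band, the posterior spring at arc distance
   SP anterior to the lambdoid band, and an optional third spring
   midway between them.
4. **Mechanics.** Small-strain linear elasticity with the basal rim
   fully fixed. Each spring is linearised about its inserted state: it
   contributes a rank-one axial stiffness *k* along its initial axis
   and an equal-and-opposite force pair of magnitude *k*(L₀ − d₀),
   where L₀ is the free length and d₀ the attachment separation at
   insertion. One sparse direct solve gives equilibrium; the outcome is
   ΔCI = 100 × (CI_deformed − CI_intact) in CI points.

### Assumptions

The model is deliberately the *simplest* faithful one: linear
kinematics (openings of a few millimetres against a 165 mm skull),
elastic bone (no viscoelastic creep, so this is the immediate
post-insertion response, not the weeks-long time course of spring
opening), no skull growth, no contact, uniform bone thickness, and
spring axes frozen at their insertion orientation (the follower-force
correction is second order in the opening). Within a linear model the
spring free length only scales the load, so L₀ is a configuration
constant (default 60 mm) recorded with every result rather than a
studied parameter.

## Mesh generation

The shell is meshed with structured 8-node hexahedra: rings around the
anterior–posterior axis at a set of stations, one element layer through
the thickness by default (configurable via `layers`), and degenerate
wedge hexahedra closing the frontal and occipital poles. Two features
of the discretisation are load-bearing for the sweeps:

* **Conforming seams.** Station spacing puts each suture band in
  exactly one element column (so any resolution "resolves" a 2 mm
  band), and the ring node distribution places nodes exactly on the
  planned cut lines y = ±OS/2. The osteotomy therefore removes the same
  structured block of elements for every OS, and the cut geometry
  varies *smoothly* with OS instead of jumping whenever an element
  centroid crosses the strip boundary.
* **Embedded spring attachments.** Attachment points are located by arc
  length along the cut edge and expressed as convex combinations of the
  two bracketing nodes, with force and stiffness distributed by the
  interpolation weights. Nearest-node snapping would quantise SP to the
  edge node spacing (~6 mm at the sweep resolution, coarser than the
  3 mm SP grid step) and flatten consecutive sweep points; the embedded
  attachment keeps ΔCI(SP) smooth and strictly monotone.

Similarly, the fixed boundary is the *structural* basal rim (the node
rows on the basal cut boundary) rather than a coordinate threshold such
as z < 2 mm: a height threshold lets the constrained node set flicker
discretely as node distributions shift during OS and t sweeps, which
shows up as spurious jumps in otherwise smooth sweep curves.

## Finite elements

Trilinear hexahedra lock badly in thin, nearly incompressible regions,
so the element uses the mean-dilatation B-bar formulation (selective
reduced integration of the volumetric strain): full 2×2×2 Gauss
quadrature with the dilatational part of the strain–displacement matrix
replaced by its volume average. This controls volumetric locking in the
ν = 0.49 sutures — which carry most of the deformation, acting as soft
hinges for the parietal flaps — while passing the linear patch test
exactly (asserted to 1e-8 in the tests, along with the six-mode
rigid-body null space, a closed-form bar stiffness, a two-block spring
oracle, zero-load/zero-displacement and vanishing net base reaction).
Degenerate (collapsed-edge) wedge hexahedra at the poles are standard
and keep positive Jacobians at the interior Gauss points; truly
inverted elements abort assembly. The sparse symmetric system is
factorised directly, so results are deterministic — the package has no
randomness anywhere in the geometry or mechanics path.

## Parameters

| symbol | meaning | default (control) | range swept |
|---|---|---|---|
| E | calvarial bone elastic modulus | 421 MPa | 100–3000 MPa, step 100 |
| ν | bone Poisson ratio | 0.22 | fixed |
| t | shell thickness | 2 mm | 2–4 mm, step 0.2 |
| SP | spring arc distance from suture | 34 mm | 10–40 mm, step 3 |
| OS | osteotomy strip width | 20 mm | 10–20 mm, step 2 |
| k | spring stiffness | 0.39 N/mm | {0.17, 0.39, 0.69} N/mm |
| n | number of springs | 2 | {2, 3} |
| L₀ | spring free length | 60 mm | fixed, recorded |
| — | fibrous modulus / Poisson | 16 MPa / 0.49 | fixed |

Wire diameters 1.0 / 1.2 / 1.4 mm map to the three catalogue
stiffnesses. Values with no published basis are package choices:
suture band width (2 mm), fontanelle radius (10 mm), base offset
(15 mm), suture centrelines at +42 % / −60 % of the semi-length (placed
so the cut-edge arc, ~86 mm at the default geometry, accommodates
SP = 40 mm from both ends), and the 60 mm free length.

## The sensitivity layer

Each fitted surrogate — ΔCI = A·X^B + C for E, t, SP and
ΔCI = P₁·X + P₂ for OS — is sampled at 30 equally spaced points over
its study range, so every normalized step is 1/29 ≈ 3.45 % of the
range. Per-step indices Sᵢ divide consecutive differences by that
normalized step; their mean telescopes exactly to
ΔCI(X_max) − ΔCI(X₁), and the implementation asserts both computations
agree to 1e-10. Pairwise absolute-difference curves compare two
parameters' sampled curves at a shared index. The package bundles the
reference surrogate coefficient table so this whole layer runs in
milliseconds without the FE stage (`reproduce_analysis()`); one known
quirk is that the reference table's own rounding makes the
spring-position three-spring average come out at 0.399 where the
published summary prints 0.41, and the tests carry a slightly widened
tolerance for that single cell.

## Numerical choices

* **Power fits.** Three-parameter power laws are sensitive to the
  starting exponent, so `fit_power` multi-starts over
  B ∈ {−2, −1, −0.5, −0.25}; at each start the model is linear in
  (A, C) and solved in closed form before full Levenberg–Marquardt
  refinement (tolerances 1e-14, 200 iterations); the smallest residual
  wins. R² is 1 − SSres/SStot with the centred total sum of squares.
  Constant data are a degenerate input handled as A = 0, R² = 0 with a
  flag rather than an error.
* **Confidence bands.** Delta-method: ± z √(gᵀΣg) with g the
  coefficient gradient of the prediction. Zero-residual fits give
  zero-width bands.
* **Ties and tie-breaks.** Spring-site interpolation picks the segment
  whose arc interval contains the target (left-closed); mirrored
  attachments reuse the same weights on the mirrored node pair, so the
  pair is exactly symmetric in exact arithmetic.
* **Parameter-recovery design.** The recovery study adds σ = 0.01
  Gaussian noise to a known law and refits. On the modulus law, which
  spans 1.5 decades, all three coefficients are identifiable and a
  300-point sampling gives the 5 % recovery criterion ~98 % power
  across seeds; on the narrow thickness range [2, 4] mm the three
  coefficients are nearly collinear (the intercept C is smaller than
  its own sampling error at any practical sample size), so there the
  meaningful recoverable quantity is the fitted *curve*, tested as an
  RMS error, not each raw coefficient.

## What the sweeps show, and the osteotomy subtlety

On the simulator's output the tests assert: ΔCI > 0 everywhere in
range; strictly decreasing in E and t; strictly increasing in SP and
k; three springs above two springs pointwise; the modulus response
flattening above ~900 MPa; and anterior/posterior wire-diameter swaps
changing ΔCI by < 10 %.

The osteotomy width is the interesting exception. Two mechanisms
compete: a wider strip reduces the insertion pre-compression
k(L₀ − OS) (less force), but also removes more bone (more compliance).
Their near-cancellation makes ΔCI(OS) almost flat with a shallow
interior maximum near OS ≈ 12 mm at the default free length —
consistent across mesh resolutions 16/20/24, i.e. genuine model
physics, not discretisation noise. The package therefore checks the
osteotomy relationship as an *overall decline* (negative fitted slope
and lower endpoint), which is also the only reading its famously poor
linear fit supports: on this simulator the OS fit's R² (~0.87–0.90) is
far below the ≥ 0.99 of the three power fits, mirroring the published
contrast between the osteotomy fit (R² 0.56–0.86) and the others.

## Problem sizes

The default generated skull (resolution 24) has ~700 hexahedra and
~1400 nodes; sweeps run at resolution 16 (~350 elements, ~2100 dofs,
about 0.3 s per case), which mesh-refinement checks show changes
measured dimensions by well under 1 % relative to doubled resolution.
The full 2- and 3-spring sweep battery is ~120 independent solves.

## Limitations

The skull is one idealised geometry: no patient-specific shape, no
regional thickness variation, no metopic/coronal variants. The model is
elastic and instantaneous: no viscoelastic relaxation, spring-opening
time course, growth, helmet therapy or bone remodelling. Absolute ΔCI
magnitudes depend on the shell idealisation and the assumed free
length and are smaller than clinically reported changes; the package's
claims are about *relative* effects — orderings, trends and sensitivity
rankings — which is precisely what the test suite pins down. Passing
tests on the synthetic skull therefore demonstrate internal
consistency and the direction and ranking of parameter effects, not
patient-level predictive accuracy.
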