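---
title: "Hybrid particle-flow modeling in truncated hepatic arterial trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid particle-flow modeling in truncated hepatic arterial trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepatrunc)
```

## The problem

Transarterial radioembolization (TARE) treats unresectable liver cancer by
injecting radioactive microspheres (typically 20-60 µm resin or glass
spheres) through a catheter placed in the hepatic arteries. Where those
spheres end up — tumor-feeding branches versus healthy parenchyma — depends
on the arterial geometry, the flow split over the outlets, and the exact
injection location and timing. Computational models that track every
particle through a full patient-specific tree are expensive; the approach
implemented here reduces that cost in two ways:

1. **Truncation.** The arterial tree is pruned by tumor-perfusion rules, so
   that explicit particle modeling is only needed in the proximal
   generations of the tree.
2. **Hybrid redistribution.** Beyond a truncated outlet, particles are
   assumed to distribute proportionally to the imposed blood-flow split; a
   particle fraction computed on the truncated tree is mapped back to the
   full outlet set by multiplying with per-member flow fractions.

The package implements the full chain — perfusion territories, truncation,
outlet boundary conditions, a desk-scale Lagrangian transport surrogate,
release-grid classification, and a Monte Carlo tumor-dose distribution —
with synthetic data generators standing in for patient imaging.

## Perfusion territories and TPP

The tumor perfusion percentage (TPP) of an outlet is the share of tumor
volume that the outlet feeds. It is computed on a cubic voxel grid
(default $100^3$, edge length fitted to the bounding box of vessels and
tumor; a patient-scale box yields roughly 1.2 mm voxels):

* the centerline of each terminal vessel segment (strictly between the
  final bifurcation and the outlet) seeds that outlet's wavefront;
* all wavefronts advance **simultaneously**, one 6-connected voxel layer
  per iteration, through the whole grid (the seeds generally lie outside
  the tumor mask);
* growth stops when every tumor voxel is claimed; TPP is the claimed tumor
  voxel count over the total tumor voxel count.

Two conventions are deliberate choices, configurable and tested:

* **Tie rule.** A voxel reached by several wavefronts in the same iteration
  goes to the lowest outlet id. This is deterministic and independent of
  iteration order, but it breaks permutation equivariance exactly on tie
  voxels — the property tests compare labelings away from ties.
* **Growth domain.** Wavefronts propagate through non-tumor voxels, because
  terminal vessel segments usually sit outside the mask; only tumor voxels
  count toward TPP.

## Truncation

Truncation runs in two steps with hard safety rails: the two most proximal
junction levels are never cut (`protected_levels = 2`), and a junction whose
feeding branch is shorter than `min_cut_space` (default 2 mm — the
underlying criterion is only verbal, so this number is a package default,
not a literature value) is preserved.

* **Step 1** repeatedly collapses terminal junctions that contain an outlet
  with TPP at or below 1%. The resulting outlet inherits the summed TPP of
  the group, the lowest member id, and the label *tumor* if the group TPP
  exceeds the threshold, *healthy* otherwise. Iterating the collapse lets a
  group swallow several consecutive junction generations, since a merge can
  turn the parent junction into a new terminal junction that itself
  qualifies; the grouping is order-independent because only sibling leaves
  ever merge.
* **Step 2** additionally collapses terminal junctions whose outlets all
  carry the same tissue label; mixed junctions are never simplified.
  Outlets that end the sweep with TPP at or below the threshold and no
  label are resolved by the **tumor-flow majority rule**: tumor if and only
  if the tumoral share of their flow exceeds 50%.

After each step, resulting outlets shorter than 5 mm on the centerline are
extruded along their terminal tangent to a total length of 20 mm so a
developed velocity profile can form.

## Outlet boundary conditions

Flows are built from two perfusion rate constants: healthy tissue receives
$Q_s = V_s k_h$ per Couinaud segment ($k_h = 0.100\ \mathrm{min}^{-1}$),
split symmetrically along the intrasegmental junctions (1/2 per
bifurcation, 1/3 per trifurcation); tumor tissue receives
$Q_t = V_t k_c$ ($k_c = 0.415\ \mathrm{min}^{-1}$), split by TPP. Each
outlet's outflow is the sum of its healthy and tumoral contributions, and
the inlet inflow follows by mass conservation. With a 1,357 ml liver and a
310 ml tumor this gives 135.7 + 128.65 = 264.35 ml/min, reported as
136/129/264 (rounding is always applied last, to unrounded sums).

The segmental volume fractions themselves are not universal constants; the
package ships a literature-typical default table (segments I-VIII: 2, 6,
10, 16, 14, 16, 20, 16% of liver volume) that callers should override with
patient-specific values when available.

The inflow waveform is tabulated input. The synthetic generator produces a
half-sine systolic pulse over a diastolic baseline with period 0.8 s and
min/mean/max velocity 0.041/0.121/0.260 m/s; the systolic duration is
solved numerically so the sampled trapezoidal mean is exact, and
`scale_waveform()` rescales velocities so the time-averaged volumetric
inflow matches the boundary-condition total within 0.1%.

## The transport surrogate

The package does not solve the 3-D Navier-Stokes equations. Each branch is
treated as a straight tube (axis from first to last centerline point,
length equal to the arc length) carrying an analytic pulsatile Poiseuille
profile whose amplitude tracks the branch's imposed flow times the
normalized waveform shape. Because every branch follows the same shape,
flow is conserved at every junction at all times. On this field the full
microsphere force balance is integrated: buoyancy-corrected gravity, drag,
pressure-gradient force, and virtual mass. Numerical choices:

* **Rheology.** Simplified Quemada viscosity
  $\mu(\dot\gamma) = \max\{\mu_0, (\sqrt{\mu_\infty} +
  \sqrt{\tau_0}/(\sqrt{\lambda}+\sqrt{\dot\gamma}))^2\}$ with
  $\mu_0 = 3.09\times10^{-3}$, $\mu_\infty = 2.65\times10^{-3}$ kg/(m s),
  $\tau_0 = 4.36\times10^{-3}$ Pa, $\lambda = 2.18\times10^{-2}$ 1/s;
  the clamp takes over near $\dot\gamma \approx 253$ 1/s. The viscosity
  enters the particle force closure only; the profile shape stays
  parabolic — a documented simplification relative to a shear-thinning 3-D
  solver. A dimensionally inconsistent "literal" variant of the formula is
  retained behind a flag purely for auditability, and a Newtonian option
  supports closed-form verification.
* **Drag closure.** The spherical-particle correction
  $C_D Re_p/24 = 1 + 0.15\,Re_p^{0.687}$ (Schiller-Naumann); the virtual
  mass coefficient is the standard sphere value $C_V = 0.5$. Neither
  closure is prescribed by the methodology this package follows; both are
  configurable.
* **Integrator.** Semi-implicit Euler with the drag term implicit and the
  $-du_p/dt$ part of the virtual-mass force folded into an added-mass
  factor. This matters: the drag relaxation time of a 40 µm, 1600 kg/m³
  sphere in blood is about $5\times10^{-5}$ s, far below the time step
  (0.5 ms in accelerating/decelerating waveform phases, 1 ms in flat
  phases, switched on the waveform slope), so an explicit update would be
  unstable while the implicit one relaxes exactly onto the local fluid
  velocity. The scheme reproduces the Stokes terminal velocity
  $(\rho_p-\rho) g d_p^2/(18\mu_0) = 1.524\times10^{-4}$ m/s to 0.25%
  (the residual is the drag-law correction, not integration error).
* **Walls.** Specular reflection with unit tangential and normal
  restitution.
* **Junctions.** The parent exit disk is split into contiguous angular
  sectors ordered by daughter azimuth, each sector's angle equal to the
  daughter's flow share; a particle is assigned by azimuth, its azimuth is
  rescaled within the sector and its radius rescaled to preserve the
  normalized Poiseuille streamfunction. This map is *defined* by its
  flow-split property — uniformly seeded tracers reproduce the imposed
  outlet flow fractions — and makes no claim about 3-D junction
  hydrodynamics.
* **Injection.** Planar mode seeds a uniform grid (default pitch
  $10^{-4}$ m, matching the release-grid spacing) across the inlet lumen,
  released at the local fluid velocity in bursts every 0.01 s throughout
  the third flow cycle; catheter mode seeds the 0.7 mm tip disk at
  0.12 m/s (a 2.77 ml/min catheter flow). The run continues in whole
  cycles until fewer than 1.5% of all injected particles exited in the
  latest cycle, with a configurable cycle cap; remaining particles are
  recorded as no-exit.

## Release grids and the hybrid estimators

Per burst timing, the injection plane is rasterized on a fixed reference
grid ($10^{-4}$ m cells anchored at the lumen centroid, half-open, 0-based)
into a Particle Release Grid: a cell is *tumor* if all its particles exited
tumor-perfusing outlets, *healthy* if all exited healthy ones, *no exit* if
all remained stuck, *spatially uncertain* for any mixture, *no value* if
empty. Composite PRGs combine (by default eight) timings with strict
thresholds evaluated in order: >75% for the constant states, >50% for the
mostly states, then >37.5% for no-value before spatially-uncertain (so the
4/8 + 4/8 tie resolves to no-value), else temporally uncertain.

Cell fractions (CF) count cell-timing pairs whose particles unanimously
exited one outlet, over all associated pairs including no-exit; uncertain
and empty cells enter neither numerator nor denominator (the source
methodology leaves this case open; exclusion is this package's documented
choice). Counting cell-timing pairs rather than pooling particles first
keeps spatial and temporal uncertainty separate. Exit fractions (EF) count
particles directly. The hybrid estimators extend either to the full outlet
set: $TCF_x = CF_{x^*} FF_x$ with $FF_x = Q_x/Q_{x^*}$, so member values
sum exactly to the parent value.

## Tumor dose

For a catheter-sized $7\times7$-cell section of the plane, the tumor dose
is $TD = \sum_x CF_x\, Q_{t,x}/(Q_{t,x}+Q_{h,x})$, in percent. Shifting
the section uniformly at random over all admissible centers (cells whose
full square contains no empty cell) yields the Monte Carlo TD
distribution; 50 locations are sampled without replacement by default
(both choices configurable — the source methodology states neither the
replacement convention nor an explicit admissibility formula; "the square
fits inside the valued region" is this package's reading). Section CFs are
pooled over all burst PRGs.

## Synthetic data: what it does and does not emulate

No patient data ships with the package. `generate_synthetic_tree()` grows
rooted trees (2-48 outlets, bifurcations with occasional trifurcations,
Murray-law diameters by default — the generation-to-generation diameter
relationship is a free, configurable choice) and `build_scenario()` wraps
them with voxel tumors and the parameter set above:

* `paper_like` — 48 outlets, a 310 ml spherical tumor over part of the
  outlet fan, a 1,357 ml liver, the default $100^3$ grid; the full voxel
  pipeline reproduces the 136/129/264 ml/min flow report.
* `well_mixed` — 8 outlets behind a long straight inlet; used for the
  tracer-limit and hybrid self-consistency checks.
* `degenerate` — a small tumor entirely inside one outlet's territory
  (TPP = 100% for that outlet, 0 elsewhere).

Scenario generation is deterministic per seed; a random tree draw whose
terminal segments fold through a shared seed voxel (a physically
implausible layout) is rejected and regenerated from a derived seed, so
every input seed still yields exactly one scenario. Tumor masks are unions
of ellipsoids, which supports peripherally as well as internally
vascularized shapes but does not emulate CT noise or real hepatic
branching statistics. Consequently, passing tests demonstrate the internal
consistency of the method — flow-split fidelity, conservation laws,
threshold rules — on idealized geometry; they do not validate the
surrogate against 3-D hemodynamics or patient outcomes, and the published
patient-specific comparison numbers are out of reach without the imaging
data and a 3-D solver.

## Problem sizes and tolerances

The shipped tests and the acceptance script run at desk scale, chosen so
each transport run finishes in seconds on one CPU: 5-12 outlet trees,
seeding pitches of 1.5-4×10⁻⁴ m (hundreds to a few thousand particles),
2-8 bursts, and voxel grids of $48^3$ or smaller for randomized-mask
properties ($100^3$ for the paper-like preset, whose region growing is
vectorized and fast). Key numeric tolerances: TPP and flow-fraction sums
are exact to $10^{-9}$; tracer exit fractions match imposed flow splits
within 2 percentage points absolute; the settling velocity matches the
Stokes closed form within 0.5%; CPRG threshold strictness is verified by
exhaustive enumeration of all 8-timing state combinations.

## Known limitations

* The flow field is an analytic network surrogate: no secondary flows, no
  recirculation, no junction hydrodynamics beyond the flow-split map.
* Outflow fractions are constant in time; progressive embolization is not
  modeled.
* The catheter is a point-velocity seed disk (thin-walled, carrier fluid
  treated as blood); catheter wall thickness and saline are not modeled.
* No particle-particle interaction and no Basset history force.
* Anisotropic voxels and 26-connectivity are unsupported; healthy-tissue
  territories are not grown (only the tumor mask is partitioned).
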