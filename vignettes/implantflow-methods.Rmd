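---
title: "Methods: a reduced-order model of blood and fibrinogen infiltration around screw implants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a reduced-order model of blood and fibrinogen infiltration around screw implants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

When a screw-shaped implant is placed in bone, a blood-filled gap forms
between the implant surface and the osteotomy wall. The proteins that this
blood carries — fibrinogen above all — condition the implant surface for the
cells that later build bone on it, so *where* protein accumulates and *how
fast* the blood moves past each part of the surface are early determinants
of osseointegration. Neither quantity can be measured in vivo at this scale,
which makes a computational model the only practical instrument.

`implantflow` is a deliberately reduced-order simulator of this situation:
a two-dimensional, planar longitudinal half-section of an implant seated in
a bone gap, with blood entering from the apical gap below the implant and
through the lateral bone wall, air escaping through the top of the gap, and
fibrinogen carried passively by the advancing blood. The model resolves the
thread-scale geometry (millimetre pitch and depth) explicitly; the
micrometre-scale surface texture that distinguishes "microrough" from
"smooth" implants is handled by a sub-grid wetting/drag model described
below. All reported quantities are zone statistics with natural 2-D
analogues (masses and volumes per unit depth), so the dimensional reduction
changes scale, not structure.

## Geometry and zones

The implant profile is a polyline: a flat apex face and symmetric
triangular threads of pitch 0.8 mm and depth 0.4 mm over an 8 mm threaded
length; the outer gap from thread tip to bone wall is 0.8 mm and the apical
clearance below the implant 0.8 mm. These dimensions are the package's own
choice, set so that the thread-envelope recess area is one quarter of the
outer-channel area — the area ratio that anchors the zone statistics. The
domain is rasterized to a uniform cell-centered grid (origin lower-left,
0-based indexing); cells are classified as fluid, implant, bone, apical
inlet, bone inlet, or outlet, and a flood fill verifies that all fluid is
reachable from the inlets.

Three concentric analysis zones partition the peri-implant gap:

* **interface** — fluid cells within `interface_band_delta` of the implant
  surface,
* **thread** — the remaining recess fluid inside the thread-tip envelope,
* **outer** — the gap from the tip envelope to the bone wall.

`interface_band_delta` defaults to two cell widths. For scenario runs the
band is set to one cell width, the thinnest band the grid can express: the
interface zone is conceptually a thin boundary layer, and the 1:4
thread-to-outer area anchor presupposes that the band does not consume the
recess. Geometry-only statistics (the area-ratio check) are evaluated on a
fine geometry grid (10 µm cells) where the default band is thin.

## Surface microtopography

Acid-etched implant surfaces carry random peaks and valleys of 0.5–3 µm
height and width. Two representations are provided:

* **Explicit roughness** — a seeded random sawtooth superimposed normal to
  the profile, with peak-to-valley amplitudes drawn uniformly from the
  physical range times a `coarsening_factor` and feature widths treated the
  same way. Offset polylines self-intersect in small loops at concave
  thread corners; loops shorter than a few feature widths are clipped,
  while folds on the thread scale are rejected as a parameter error. This
  mode is geometrically faithful but requires the coarsened feature width
  to span at least two grid cells, which desk-scale grids cannot honour at
  physical amplitudes.
* **Wenzel-effective mode** (scenario default for microrough surfaces) —
  the roughness acts through its two mechanisms without being meshed:
  (1) the intrinsic contact angle is replaced by the Wenzel-corrected value
  `cos(theta_eff) = r cos(theta)`, with the roughness ratio `r` measured on
  a realization of the texture at physical scale (arc length over projected
  length, typically `r ≈ 1.4`, giving `theta_eff ≈ 61°` for `theta = 70°`);
  (2) a momentum sink in the first fluid cell layer along the implant
  represents the drag of the unresolved texture. The sink coefficient is a
  porous-layer estimate: the texture acts as a Darcy layer of permeability
  `(a/2)²` (with `a` the mean peak-to-valley height) and thickness `a`,
  rescaled to the cell size `h`, giving `lambda = 4 mu / (rho a h)` — about
  `10^5 s^-1` at desk resolution. The same damping factor
  `1/(1 + lambda dt)` enters the predictor and the face mobility of the
  pressure projection, so the drag acts on the full (pressure-corrected)
  velocity. This is an order-of-magnitude closure set once from the
  roughness scale; the interface-zone speed is the quantity most sensitive
  to it, and with this value the first fluid layer is strongly retarded —
  stronger than the few-fold interface slowdowns the full-scale study
  reports, which is visible in the speed-ratio statistics (see
  limitations).

## Flow, interface, and species transport

Blood is one Newtonian phase (density 1060 kg/m³, viscosity 3.5 mPa·s —
effective whole-blood values; the 45% hematocrit is carried as a
composition constant, not a separate phase). The displaced air is a passive
light phase. The solver is a classical staggered-grid projection method:
explicit upwind advection and diffusion of momentum with density and
viscosity mixed by the volume fraction, a continuum-surface-force (CSF)
surface-tension term, and a variable-coefficient pressure Poisson equation
solved by incomplete-Cholesky preconditioned conjugate gradients with warm
starts. At the study's Reynolds number (about 0.24, four orders below the
turbulence transition at 2800) this scheme is more than adequate, and a
laminar check is asserted before every run.

The blood–air interface is captured by a volume-of-fluid field advected
geometrically: Youngs' piecewise-linear reconstruction, directionally split
sweeps, and the dilatation marker that keeps split advection conservative
and bounded at CFL ≤ 0.5. A compressive algebraic (donor–acceptor) scheme
is retained as an independent cross-check kernel. Wall wetting is imposed
by re-orienting interface normals in wall-adjacent cells to the prescribed
contact angle (0° superhydrophilic, 70° hydrophobic at the implant; the
bone wall is wet tissue and fully wetting). Curvature comes from smoothed
volume-fraction normals (four Laplacian passes by default; droplet fixtures
use six).

Fibrinogen is transported as the conserved load `C = alpha Y` riding the
same reconstructed phase fluxes — protein moves only with blood — plus an
explicit in-phase diffusion term (`D = 2 × 10^-11 m²/s`, a macromolecular
scale; the choice is recorded with all results and has negligible influence
at these Péclet numbers). The inlet composition is the physiological value
`Y0 = 3 kg/m³ / 1024 kg/m³ = 0.29%`.

## Time stepping and stabilization

The reference time step is `1e-4 s` and runs last 3 s (30 000 steps). The
actual step is the minimum of the reference step, the advective CFL limit
(cap 0.4), the capillary limit `sqrt(rho_blood h³ / (2 pi sigma))`, and the
explicit-diffusion limit. Two stabilization choices keep desk-scale runs in
this regime and are recorded in every run manifest:

* `sigma_scale = 0.02`: the surface tension used in scenarios is 2% of the
  plasma-like 0.058 N/m, the largest value whose capillary time-step limit
  does not undercut the reference step at desk resolution. Capillary
  pressure still exceeds the viscous and inertial pressure scales by more
  than two orders of magnitude, so wetting-driven redistribution — the
  mechanism under study — is preserved; only the (irrelevant) speed of
  interfacial ringing is reduced.
* `rho_air = 10 kg/m³` in scenario presets: a regularized passive-gas
  density that improves the conditioning of the variable-density pressure
  equation. Air dynamics are irrelevant here; the air phase only needs to
  vacate.

## Scenarios, statistics, and the study

The study crosses surface topography (smooth / microrough) with wettability
(0° / 70°). Resolution presets are `test` (100 µm cells), `desk` (64 µm;
25 cells across the domain width, the default analysis resolution), and
`fine` (32 µm). A desk scenario takes a few minutes on one CPU; the full
four-scenario study runs in roughly ten.

Each output interval reduces the fields to a tidy zone table: fibrinogen
mass `M_z = sum(alpha rho Y h²)`, blood volume, and mean blood speed (the
arithmetic mean of cell speeds over cells with `alpha > 0.5`; a
volume-weighted variant is available). Derived statistics follow the
study's definitions: the infiltration ratio `100 M_z / M_outer` and the
recruitment/retention index `I_z = M_z / max(V_z, epsilon_v)` — the mass of
protein present per unit speed of the blood carrying it, large where much
protein sits in slow blood. Because the pairing of mass and speed for the
index is a convention, both an instantaneous variant (at 2 s) and a
time-averaged variant (means over 1–3 s) are computed; the time-averaged
variant is the default because it is insensitive to output cadence. Report
times follow the 1, 2, 3 s convention of the study design.

The four-scenario comparison emits every cross-scenario and cross-zone
ratio (mass, speed, index) with numerator and denominator provenance, and a
set of ordering assertions is evaluated mechanically: outer > thread >
interface speeds in every scenario; wetting increases and microroughness
decreases zone masses; the superhydrophilic microrough interface index is
the global maximum.

## What the synthetic fixtures do and do not show

All validation inputs are generated in code; there is no external data.

* **Plane Poiseuille flow** validates the momentum/pressure core against
  the exact 3/2 centerline-to-mean ratio (2% tolerance, with a grid
  refinement check of the observed order).
* **Static and sessile droplets** validate the CSF term: the Young–Laplace
  jump `sigma / R` to 10%, and the relaxed contact angle of a sessile
  droplet to 5°.
* **Capillary infiltration** validates wetting-driven transport against
  the channel Lucas–Washburn law `L(t) = sqrt(sigma R cos(theta) / (2 mu))
  sqrt(t)` to 20%. The fit uses a ten-fold viscosity so the inertial
  transient (`rho R² / mu`, about 2 ms) is short relative to the window and
  the capillary number stays low; the fit window starts after the
  transient. Front growth must also be diffusive (`L²` linear in `t`).
* **Synthetic zone snapshots** with piecewise-constant fields tie the
  statistics module to direct arithmetic, independently of the solver.

Passing these fixtures certifies the kernels on the same grid/type stack
the scenarios use — there is no separate fixture code path. What they do
*not* show: that a 2-D half-section with coarsened sub-grid roughness
reproduces a 3-D screw quantitatively. The scenario statistics are
reduced-order analogues, expected to land in the reported regime (the
acceptance bands are factors of two), not to replicate a production CFD
solution.

## Numerical choices and degenerate inputs

* Pressure solves iterate to a scaled-divergence target (default `1e-6`
  relative to the velocity scale); the warm-started solver typically needs
  tens of iterations per step. A failed solve aborts with its residual.
* VOF boundedness is enforced by the geometric scheme itself; violations
  beyond `1e-6` abort as scheme defects, tiny excursions are clipped at
  machine-noise level.
* Zones with no blood cells report zero speed and an explicit flag; the
  index uses a velocity floor `epsilon_v = 1e-9 m/s` and flags floored
  values; an empty outer zone makes the infiltration ratio `NA` rather
  than infinite.
* A vanishing interface band assigns its cells to the thread zone; an
  interface band wide enough to swallow the thread zone warns.
* Roughness that folds the profile on the thread scale, or whose coarsened
  features a grid cannot resolve, is rejected with a diagnostic.
* All randomness flows through explicit integer seeds; identical seeds give
  bit-identical grids, profiles, and trajectories.

## Known limitations

* Two-dimensional planar geometry: no helical thread path, no
  circumferential flow.
* One effective blood phase: no separate plasma/red-cell dynamics, no
  non-Newtonian rheology.
* Passive fibrinogen: no adsorption to the wall (an optional first-order
  wall-uptake term exists but is off by default and excluded from all
  reported runs), no coagulation.
* The microrough scenarios rest on the Wenzel-effective closure; its sink
  coefficient is an order-of-magnitude wall-friction estimate, and the
  interface-zone speeds are the quantities most sensitive to it.
* Air is displaced or trapped as resolved by the VOF field; there is no
  dissolution of trapped bubbles, so recess air pockets persist to the end
  of a run.
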