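# implantflow

A reduced-order, two-dimensional multiphase flow model of early blood and
fibrinogen infiltration into the peri-implant gap around screw-shaped bone
implants. It is written for implant-surface researchers who want a fast,
fully scripted way to ask: *how do surface microtopography (smooth vs
microrough) and wettability (superhydrophilic θ = 0° vs hydrophobic
θ = 70°) change how much protein reaches the implant surface, and how fast
the blood carrying it moves?*

## The model

Blood enters the implant–bone gap from the apical clearance and through the
lateral bone wall at capillary speed (U = 0.001 m/s, Re ≈ 0.24 ≪ 2800, so
the flow is laminar). The solver couples:

* incompressible Navier–Stokes on a staggered grid (Chorin projection,
  IC(0)-preconditioned conjugate-gradient pressure solves),
* volume-of-fluid interface capturing (Youngs PLIC reconstruction) with
  continuum-surface-force surface tension and an imposed wall contact
  angle θ,
* passive advection–diffusion of the fibrinogen mass fraction Y, carried
  only by blood-phase fluxes, with the physiological inlet composition
  Y₀ = 3 kg m⁻³ / 1024 kg m⁻³ = 0.29 %.

Microroughness (0.5–3 µm random peaks and valleys) acts either as an
explicit seeded perturbation of the implant profile or — the scenario
default — through a Wenzel-effective mode: cos θ_eff = r·cos θ with the
roughness ratio r measured on the generated texture, plus a near-wall
momentum sink representing sub-grid drag.

Fields are reduced to three analysis zones around the implant (interface
band, thread recesses, outer channel). Per zone and output time the package
reports the fibrinogen mass M_z = Σ α ρ Y h², blood volume, and mean blood
speed V_z, and derives the infiltration ratio 100·M_z/M_outer and the
fibrinogen recruitment/retention index

    I_z = M_z / max(V_z, ε_v)   [kg·s/m]

— the mass of protein present per unit speed of the blood moving past, the
study's headline statistic.

## Worked example

One hydrophobic smooth scenario at the default analysis ("desk")
resolution — a few minutes on one CPU:

```r
library(implantflow)

cfg <- scenario_config(surface = "smooth", theta = 70, resolution = "desk")
res <- run_scenario(cfg)

dplyr::filter(tidy(res), time == 3)
#    scenario time      zone         mass blood_volume  mean_speed blood_cells
#  smooth_70     3 interface 1.158746e-06 3.731307e-07 0.002251685         103
#  smooth_70     3    thread 3.422740e-06 1.102165e-06 0.004695050         289
#  smooth_70     3     outer 1.675948e-05 5.396763e-06 0.008651562        1323

zone_window_stats(res$series, 1, 3)
#        zone         mass  mean_speed        index
#   interface 1.048588e-06 0.001957509 0.0005356746
#       outer 1.643991e-05 0.007805406 0.0021062215
#      thread 2.954944e-06 0.004168586 0.0007088599
```

Reading the output: at t = 3 s the thread recesses hold
3.42×10⁻⁶ kg (per metre of depth) of fibrinogen against 1.68×10⁻⁵ kg in
the outer channel — an infiltration ratio of 20 %, i.e. the screw recesses
capture less protein than their area share (25 %) would suggest. Blood
moves fastest in the outer channel and 2–4× slower in the thread and
interface zones; dividing mass by speed gives the recruitment/retention
index per zone. `run_study()` runs the full 2×2 surface matrix
(smooth/microrough × 0°/70°), emits the fold-change table between all
scenarios and zones, and checks the qualitative orderings (zone speed
ordering, wettability and topography effects, the superhydrophilic
microrough interface index as global maximum).

Plots: `autoplot(res, "density")` (fibrinogen color map),
`autoplot(res, "vectors")` (blood velocity vectors),
`plot_zone_series()` (zone statistics over time).

A thin command-line front-end wraps the same functions:

```sh
Rscript scripts/implantflow-cli.R bench --out out/     # analytic fixtures
Rscript scripts/implantflow-cli.R run   --surface smooth --theta 70 --out out/
Rscript scripts/implantflow-cli.R study --resolution desk --out out/
```

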