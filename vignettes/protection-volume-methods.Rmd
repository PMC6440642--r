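---
title: "Modelling spatial protection volumes for controlled-release repellent devices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling spatial protection volumes for controlled-release repellent devices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srvolume)
```

## The problem

A controlled-release device (CRD) emits a volatile insecticide —
metofluthrin, a pyrethroid — through a calibrated porous membrane, creating
an airborne concentration field around it. The efficacy question is
spatial: over what volume of air is the time-averaged concentration high
enough to achieve a target effect (here, mortality of caged *Anopheles*
mosquitoes)? `srvolume` chains four models to answer it:

1. **Evaporation kinetics** turn gravimetric mass-loss measurements of
   AI/solvent formulations into device-level emission rates (mg/s).
2. **Scalar transport** disperses those emissions through a scene — a tent
   with door fans and ambient wind, or an open field — on a structured
   finite-volume grid, giving a 3-D concentration field.
3. **Dose–response regression** links simulated concentrations at caged
   "pouch" positions to observed (or synthetic) mortality with an ordinary
   linear fit, inverted to the concentration achieving a target mortality
   (C100 for 100%).
4. **The protection bubble** is the superlevel set of the time-averaged
   field at that threshold: its iso-surface and enclosed volume are the
   headline deliverable.

## Evaporation model

The formulation is a three-component liquid (AI, solvent, hygroscopic
water) with masses $m_{ai}, m_s, m_w$ and instantaneous mass fractions
$x_i = m_i / \sum_j m_j$. With $A$ the open surface area (cm²):

$$\frac{dm_s}{dt} = -k_s A x_s, \qquad
  \frac{dm_{ai}}{dt} = -k_{ai}\,(1 + \alpha x_s)\, A x_{ai}, \qquad
  \frac{dm_w}{dt} = +k_w A \;(\text{capped at a ceiling})$$

No mechanistic equations accompany the published mass curves, so this is
the package's own minimal model, built to reproduce the two robust
qualitative observations: AI evaporates faster the more volatile solvent
(isopropanol) is present, and all formulations converge to the same
pure-AI rate once the solvent is gone. The enhancement coefficient
$\alpha \ge 0$ makes solvent-carried AI loss explicit; $\alpha = 0$
decouples the components exactly (a tested limit). The model deliberately
omits vapour–liquid equilibrium thermodynamics (activity coefficients,
Antoine equations) and temperature-dependent kinetics — the exothermic
activation phase enters only as a multiplicative boost factor on the
release schedule, mirroring how the device behaves operationally (a hotter
first 8 h, then passive release).

Integration is a fixed-step classical Runge–Kutta (RK4) with step
$\le 0.01$ h: the system is non-stiff, and a fixed step makes every run
bit-reproducible. Agreement with an adaptive stiff integrator (`deSolve`)
is verified to $10^{-6}$ relative in the tests.

Rates are *estimated* from (possibly noisy) mass series by central finite
differences (one-sided at the ends), floored at zero with a warning —
gravimetric noise must never become a negative emission source. Vessel
rates scale to the device by the open-area ratio; the device's open area
follows from its membrane (1000 pores × 200 µm ⇒ 0.314 cm²). Units are
mg/s at every interface and g/h only inside the kinetics, with the
conversions centralized.

## Scene and flow model

Scenes are explicit data: a domain box (origin at the minimum corner,
z up, meters), an optional wall enclosure with door openings, fans, ambient
wind, point-source devices with release schedules, and pouch sites. The
on-disk format is YAML with units in the key names; unknown keys are
rejected and `read_scene(write_scene(s))` is an exact identity (numbers
are serialized with 22 significant digits because the YAML emitter's
`precision` argument under-delivers by one digit).

The flow is *prescribed*, not solved from momentum equations: ambient wind
everywhere, fan faces overwritten with the fan speed (a "speed jump" held
fixed), zero velocity on wall faces, then a pressure-Poisson projection of
all unconstrained faces so every fluid cell is discretely divergence-free
(typically to ~1e-13 of $|u|_{max}/dx$). Open domain boundaries use a
zero-potential ghost cell, so air enters and leaves freely; the domain
floor is solid ground by default so a tent can stand on it. This replaces
a RANS turbulence solution and is the package's principal fidelity gap:
turbulent structure enters only through a single uniform eddy diffusivity
(default 0.05 m²/s, a mid-range indoor-air value; configurable). Two
consequences worth knowing:

* An isolated fan in open air projects to a potential (dipole-like) flow:
  its face flux splits between upstream suction and the downstream jet, so
  no full cross-section plane carries the face flux. Mounted in a doorway
  — the semi-field configuration — continuity does force every interior
  cross-section to carry exactly the fan flux, and the tests verify that
  to 1%.
* Fan normals must be axis-aligned; this is a restriction of the staggered
  discretization, not of the scene format.

Buoyancy is omitted on the stated grounds that the trace AI concentrations
cannot drive it.

## Scalar transport

First-order upwind advective fluxes plus central diffusive fluxes on a
uniform staggered grid; point sources deposit into their containing cell.
Open boundaries advect mass out with upwind fluxes and admit clean
(zero-concentration) air; there is no diffusive exchange across domain
boundaries. Upwind advection is monotone and positivity-preserving —
important because concentrations feed a regression and a threshold — at
the cost of streamwise numerical diffusion $u\,dx/2$. That cost is mild
here: in a plume aligned with the flow, centerline concentration is
controlled by *cross-stream* diffusion, which upwinding does not touch, and
the verification suite holds the solver to the analytic Gaussian plume
(within 15% on the coarsest 0.5 m grid, ~2% at 0.125 m, converging under
refinement) and to the transient diffusion kernel (within 10%).

Two time schemes share the same fluxes: explicit Euler with an enforced
advective + diffusive CFL bound, and backward-Euler implicit whose sparse
operator is factorized once (the flow is steady) and reused every step.
Both conserve mass to solver precision; the global balance
(injected = in-domain + outflow) is tracked every step and reported on the
field object, with the closed-box test holding it below $10^{-9}$
relative. The implicit scheme is the default for production runs; the
projection solve uses a sparse Cholesky factorization (the system is
symmetric positive definite), which stays tractable at the finest grids
used here (~150k cells).

Concentrations are mg/m³ internally. "ppm" means parts-per-million *by
volume* via the ideal-gas conversion at the scene's air state (default
298.15 K, 101325 Pa — the midpoint of the reported room range) and
metofluthrin's molar mass 360.45 g/mol; the published thresholds never
state their basis, so this choice is explicit and configurable.

## Dose–response

Mortality fraction is regressed on concentration (ppm) by unweighted OLS,
per pouch, exactly as the source analysis does — a deliberate fidelity
choice even though a bounded response argues for a binomial GLM. The
logistic alternative (`fit_logistic()`) exists for sensitivity analysis
only and cannot produce a finite 100%-mortality threshold, which is the
analysis's headline quantity. Inversion is
$c^* = (p^\dagger - b)/a$; results beyond the observed concentration range
are returned with an extrapolation warning (the published C100 values are
themselves extrapolations). Abbott's control correction
$(p - p_c)/(1 - p_c)$ is available but off by default: it is ambiguous
whether the published per-pouch mortalities were control-adjusted, so the
correction is opt-in and the controls never enter the regression. The
time-averaging statistic correlated with mortality is the average over the
exposure window, since the mosquitoes are exposed throughout; stratified
fits (by pouch level and/or period) are descriptive, with no
multiple-testing correction.

## Protection bubble

The primary statistic is the voxel superlevel volume: the summed volume of
fluid cells whose time-averaged concentration is $\ge$ the threshold (ties
inside; 6-connectivity when restricting to the component containing the
sources). It is exactly monotone in the threshold, which the tests
exercise. The iso-surface mesh — marching tetrahedra on the lattice of
cell centers with linear edge interpolation, triangles oriented outward by
the local inside-direction — is for reporting and export (ASCII STL,
VTK); its divergence-theorem volume agrees with the voxel count to within
one surface layer and with analytic spheres to ~5%. "Convex" in the
source's description of these surfaces is treated as descriptive:
superlevel sets of concentration fields need not be convex and are not
forced to be.

## Synthetic data: what it does and does not emulate

The generators reproduce the *designs*: the 7×5×3 m tent with 27 pouches
of 20 mosquitoes (3×3 plan grid at quarter points × heights 0.5/1.5/2.5 m
— the study reports counts and levels, not coordinates, so those heights
are package defaults), two 1 m/s door fans, 5 km/h axial wind, six center
devices at the reported window-averaged rates (0.224/0.042 mg/s for 24 h,
0.116/0.024 mg/s for 48 h); and the outdoor rings (radii 0.5/1.25/2.5 m,
heights 1.0/1.5 m, five pouches per ring, controls 25 m out and excluded
from simulation). Mortality is binomial around a clipped linear
dose–response — matched to the fitted model's assumptions so that recovery
tests measure estimation error, not model mismatch; a logistic generator
supports mismatch experiments. Everything is seed-deterministic.

What passing tests therefore show: the chain recovers known truth under
its own assumptions (C100 bias ~1% over 120 replicates of the tent
design), and the numerics meet their analytic oracles. What they do not
show: that real mosquito mortality is linear in concentration, that a
single eddy diffusivity captures real tent turbulence, or that the
published thresholds (0.234 ppm / 0.097 ppm) are reproducible — those
derive from per-pouch data published only as bar plots, and the package
treats them as reference configuration values, never as targets.

## Numerical and design choices, collected

* Problem sizes: production tent runs use dx = 0.25 m with a 1800 s
  quasi-steady exposure window averaged over its second half — the tent
  air-exchange time is a few hundred seconds, so the window is several
  exchange times deep; verification sweeps use dx ∈ {0.5, 0.25, 0.125} m.
* Half-open cell membership `[x, x + dx)` resolves source and pouch
  placement unambiguously; points exactly on a fluid–wall face are sampled
  from the fluid side.
* Trilinear sampling drops solid stencil corners and renormalizes; a point
  strictly inside a wall is an error, not a zero.
* Negative estimated rates are floored with a warning, never silently
  erased; pipeline warnings are collected into the run manifest.
* The outdoor wind is a required user input — the trial did not record it,
  and defaulting it would manufacture data.
* Fan faces default to 0.5 × 0.5 m at 1 m/s in the tent preset; door
  openings default to 1 × 2 m. Discrete fan footprints (and hence
  ventilation rates) vary with dx; at fixed dx they are deterministic.
* Exothermic boost default: factor 2 for 8 h when building schedules from
  measured curves; the tent preset instead uses the reported
  window-averaged rates directly, which already integrate the boost.

## Known limitations

Prescribed flow with uniform eddy diffusivity (no RANS/LES, no buoyancy);
first-order spatial accuracy near sources; pouches are points (the real
15 cm mesh pyramids integrate over a small volume); no surface deposition
or photodegradation of the AI; the linear dose–response saturates
unphysically above C100 and below the baseline; isomer-resolved kinetics
are out of scope.
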