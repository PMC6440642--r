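# srvolume

Spatial protection volumes for controlled-release mosquito repellent
devices.

Passive controlled-release devices (CRDs) emit a volatile pyrethroid
(metofluthrin) through a calibrated porous membrane, building an airborne
concentration field that kills or repels mosquitoes over a region of
space. For vector-control researchers and device designers the operative
question is not "does it work at one point" but "how large is the
protected volume, for how long, under which ventilation conditions".
`srvolume` is an analysis pipeline that answers this by combining
bioassay-style data with desk-scale simulation:

1. **Release rates** — evaporation kinetics of AI/solvent formulations
   (`simulate_evaporation()`, `estimate_rate_curve()`), scaled to the
   device membrane by open-area ratio and turned into piecewise-constant
   release schedules with an exothermic boost phase.
2. **Transport** — transient advection–diffusion of the AI scalar on a
   structured finite-volume grid (first-order upwind + central diffusion,
   explicit or backward-Euler), under a prescribed divergence-free flow
   composed from ambient wind, door fans and enclosure walls
   (`build_grid()`, `compose_velocity_field()`, `solve_transport()`).
3. **Dose–response** — per-pouch mortality regressed on simulated
   concentration, `mortality = b + a·c` (OLS), inverted to the
   concentration achieving a target mortality,
   `C100 = (1 − b)/a` (`fit_linear()`, `concentration_for_mortality()`),
   with optional Abbott control correction.
4. **Protection bubble** — the superlevel set `{x : c̄(x) ≥ C100}` of the
   time-averaged field: voxel volume, iso-surface mesh (marching
   tetrahedra) and report (`superlevel_volume()`, `extract_isosurface()`,
   `bubble_report()`).

A synthetic-data module (`make_tent_scene()`, `make_outdoor_scene()`,
`generate_pouch_mortality()`, `generate_evaporation_series()`) reproduces
the semi-field tent (7×5×3 m, 27 pouches × 20 mosquitoes, two 1 m/s door
fans, 5 km/h wind) and outdoor ring layouts, so the entire chain runs and
is testable without field data. See the methods vignette
(`vignettes/protection-volume-methods.Rmd`) for the models, assumptions
and numerical choices.

## Worked example: the 24-hour tent trial

```r
library(srvolume)

sc <- make_tent_scene(24)
sc
#> <sr_scene> domain 9 x 7 x 4 m, duration 24 h
#>   enclosure 7 x 5 x 3 m, 2 opening(s)
#>   wind (1.39, 0, 0) m/s; 2 fan(s), 6 device(s), 27 pouch(es)

g <- build_grid(sc, dx = 0.25)
v <- compose_velocity_field(sc, g)
v
#> <sr_velocity> max |u| = 5.02 m/s, max |div| = 7.603e-13 1/s

params <- transport_params(eddy_diffusivity = 0.05, dt_s = 1)
f <- solve_transport(g, v, params, sc$devices, duration_h = 0.5,
                     avg_window_s = c(900, 1800))
f
#> <sr_conc_field> 36 x 28 x 16 cells; 1 snapshot(s); avg window [900, 1800] s
#>   injected 1436 mg, outflow 1432 mg, max balance error 2.70e-14

conc <- pouch_concentration_table(f, sc)   # 27 pouches, mg/m^3 and ppmv

# synthetic mortality from a known linear dose-response, then the fit
gen <- generator_config(seed = 1, true_slope = 9, true_intercept = 0.1)
obs <- generate_pouch_mortality(conc$c_ppmv, gen, site_id = conc$site_id)
fit <- concentration_for_mortality(fit_linear(obs), target = 1.0)
fit
#> <sr_dose_fit linear> stratum all: mortality = 0.1062 + 8.918 * c_ppm (r2 = 0.858, n = 27)
#>   c(target mortality 100%) = 0.1002 ppm

bubble_report(f, fit, sc)
#> <sr_bubble> threshold 0.1002 ppm (target mortality 100%)
#>   voxel volume 0.2031 m^3, mesh volume 0.1754 m^3
#>   all pouches inside: FALSE
```

Reading the output: after a 1800 s quasi-steady window the six center
devices (0.224 mg/s × 3 and 0.042 mg/s × 3) maintain pouch concentrations
up to ~0.09 ppm; the fitted line recovers the generating slope/intercept
(9 and 0.1) within sampling noise; inverting it puts 100% predicted
mortality at ~0.10 ppm (flagged as an extrapolation beyond the largest
observed concentration, as such thresholds typically are); and the air
volume held at or above that threshold is ~0.2 m³ around the devices.
Mass is conserved to 3e-14 relative.

`run_pipeline()` wires these stages together from a single YAML/list
config, writes all artifacts (scene, sampled concentrations, fit table,
bubble JSON + STL, VTK field) plus a seeded run manifest. The numbered
scripts under `analysis/` are narrative drivers: release-rate estimation
(`01`), the 24/48 h tent pipeline (`02`), stratified and Abbott-corrected
fits (`03`), the outdoor rings (`04`); each writes its tables under
`results/`.

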