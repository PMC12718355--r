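---
title: "Methods: storm-driven air-sea CO2 diagnostics in stormflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: storm-driven air-sea CO2 diagnostics in stormflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

stormflux diagnoses how tropical cyclones (TCs) perturb the surface-ocean
carbon system: the instantaneous wind-driven burst of air-sea CO2 exchange,
the weeks-long suppression of surface pCO2 by the cold wake, the nutrient
entrainment that fuels a post-storm phytoplankton bloom, and the bookkeeping
needed to attribute each effect. This vignette documents the models,
parameterizations, numerical choices and deliberate limitations behind the
package. Everything stated here about model behaviour is computed by the
test suite or by `scripts/acceptance.R`; nothing is quoted from elsewhere.

## Air-sea CO2 flux and the carbonate system

The flux is

$$F = k_w \, S_{CO_2}\,\left(pCO_2^{ocean} - pCO_2^{atm}\right),$$

positive upward (ocean to atmosphere), so positive values are outgassing and
negative values ocean uptake. The pieces:

* **Gas transfer velocity** `gas_transfer_velocity()`:
  $k_w = a\,u_{10}^2 \sqrt{660/Sc(T)}$ with $a = 0.251$ cm h$^{-1}$
  (m s$^{-1}$)$^{-2}$ (Wanninkhof 2014). The quadratic wind dependence is
  what makes hurricane-force winds amplify gas exchange by factors of tens.
* **Schmidt number** `schmidt_number()`: the Wanninkhof (2014) fourth-order
  polynomial for CO2 in seawater, valid for $-2$ to $40\,^\circ$C
  ($Sc(20\,^\circ\mathrm{C}) = 668$).
* **Solubility** `co2_solubility()`: Weiss (1974), converted to
  mol m$^{-3}$ µatm$^{-1}$ with the reference density 1025 kg m$^{-3}$.
* **Ocean pCO2** `solve_carbonate()`: solved from DIC and total alkalinity.
  The total-alkalinity balance includes carbonate, bicarbonate, borate and
  water terms on the total pH scale, with the OMIP-recommended constants:
  K1/K2 from Lueker et al. (2000), KB from Dickson (1990), KW from Millero
  (1995), total boron from salinity after Uppström (1974). Global
  ocean-biogeochemistry models commonly defer to the same protocol family;
  the exact constant set used here is documented rather than asserted to
  be identical to any one model.
  The solver is a vectorized, safeguarded Newton iteration on the
  hydrogen-ion concentration, bracketed in pH 3–12, tolerance $10^{-3}$
  µmol kg$^{-1}$ in alkalinity, at most 100 iterations, warm-started from
  the previous time step when run inside the scenario model. An
  independent route (pH-grid root finding on the DIC-speciation form)
  agrees to well under 1 µatm across the tested (DIC, Alk, T, S) ranges.
* **Atmospheric pCO2** `pco2_atmosphere()`: dry-air mole fraction times
  (sea-level pressure minus saturation water-vapor pressure), vapor
  pressure from Weiss and Price (1980). The default mole fraction, 414
  ppm, represents year-2020 conditions.

## Decomposing surface-pCO2 changes

`decompose_pco2()` splits a pCO2 change between a pre-storm reference
("ref", by convention 24 h before the local passage) and a later state into
SST, SSS, DIC and alkalinity contributions:

$$\delta pCO_2^{SST} = \gamma_{SST}\, pCO_2^{ref}\,\delta SST,\qquad
  \delta pCO_2^{X} = \gamma_{X}\, pCO_2^{ref}\,\delta X / X^{ref}
  \;\; (X \in \{SSS, DIC, Alk\}),$$

with $\gamma_{SST} = 0.0423\,^\circ$C$^{-1}$ (a 1 °C warming raises pCO2 by
4.23 %), $\gamma_{SSS} = 1$, and

$$\gamma_{DIC} = \frac{3\,Alk\,DIC - 2\,DIC^2}{(2\,DIC - Alk)(Alk - DIC)},
  \qquad
  \gamma_{Alk} = \frac{-Alk^2}{(2\,DIC - Alk)(Alk - DIC)},$$

the Revelle-factor approximation and its alkalinity counterpart, which
satisfy $\gamma_{DIC} + \gamma_{Alk} = 1$ identically. The SST term is
absolute while the other three are normalized — that asymmetry is part of
the method, not an oversight. Two open choices were decided as follows:

* **Where to evaluate the gammas.** At the reference state (default), with
  a midpoint option (`gamma_at = "midpoint"`). The difference is second
  order in the perturbation.
* **Accuracy against full chemistry.** $\gamma_{DIC}$ matches
  finite-difference sensitivities of the full solver to within about 10 %
  for 1 % perturbations. $\gamma_{Alk}$ is derived from the carbonate-only
  system; borate buffering in the full solver damps the true alkalinity
  sensitivity, so agreement there is ~15–20 %, while against a borate-free
  solver both gammas agree within 15 %. The reconstruction residual is
  always reported (`decompose_along_track()`), and on the packaged
  scenario the RMS residual is under 10 % of the RMS signal.

## TC detection and tracking

`track_cyclones()` implements a two-stage tracker on MSLP and 10-m wind
snapshots:

1. **Candidates** (`detect_candidates()`): iteratively take the global MSLP
   minimum; if below 1,010 hPa (strict), store it and mask all cells within
   800 km; repeat until no cell is below the threshold. The candidate's
   wind is the maximum within 200 km of the pressure minimum, because wind
   maxima sit at the radius of maximum wind rather than at the centre.
2. **Stitching** (`stitch_tracks()`): starting from the earliest unused
   candidate with wind ≥ 17 m s$^{-1}$ inside the genesis band (absolute
   latitude 0–35°, hemisphere restriction available), extend with
   candidates within 100 km and the next 24 h, preferring points closer in
   time; simultaneous qualifiers are resolved by lowest MSLP and the losers
   are removed. Retained tracks must exceed 24 h lifetime and 33 m
   s$^{-1}$ lifetime-maximum intensity, both strictly.

Distances are haversine great circles on a 6,371-km sphere; the 100-km/24-h
bounds are inclusive. One practical constraint the implementation makes
explicit: the grid must resolve the 100-km link radius. On a 1° mesh the
meridional cell spacing (111 km) exceeds the link radius and every track
fragments; the packaged scenarios therefore use 0.5° or finer.

## Along-track diagnostics

All composites use a moving 200-km-radius circle: cells whose centres fall
inside the circle, area-weighted (uniform weights available). The "passage
time" at any location is the time of closest approach of the storm centre.
The main operations:

* `wake_delta()` — after-minus-before circle averages (default 24 h each
  side): the cold-wake composite.
* `along_track_diagram()` — a full-period time series per track point,
  optionally as an anomaly against 12 h before passage.
* `fold_increase()` — |circle-mean flux at passage| over the time-mean
  |circle-mean flux| in a calm baseline window; absolute values in the
  baseline keep the ratio positive where baseline fluxes change sign.
* `integrate_track_region()` — $\sum_t \sum_{cells} F\,A\,\Delta t$
  converted with 12.011 g mol$^{-1}$ to TgC ($10^{12}$ g); the footprint is
  the union of circles.
* `cumulative_flux()` — running integral from 24 h before passage.
* `mixed_layer_depth()` (density thresholds 0.03 / 0.125 kg m$^{-3}$ over
  the surface value, linear interpolation), `brunt_vaisala()`
  ($N^2 = (g/\rho_{ref})\,d\rho/dz$), `inertial_period()`
  ($2\pi / (2\Omega \sin|\phi|)$, 21.3 h near 34.2° latitude). Closed-form
  tests use the linear equation of state `linear_density()`
  ($\sigma = \sigma_0 - \alpha(T - T_0) + \beta(S - S_0)$).

## Tracer budgets and the remineralization counterfactual

The budget contract is the standard tendency decomposition

$$\frac{\partial C}{\partial t} = -\,\mathbf{U}\cdot\nabla C
  + \frac{\partial}{\partial z}\Big(k_v \frac{\partial C}{\partial z}\Big)
  + \text{surface fluxes} + \text{biogeochemical sources/sinks},$$

with horizontal and vertical advection carried separately.
`budget_residual()` checks closure (tendency minus the term sum) and
reports the max-normalized residual; the scenario model emits terms that
close to round-off by construction, and any externally supplied term set is
validated the same way.

Remineralization is first order in the substrate with a Q10 temperature
factor, $r = r_0\,Q_{10}^{(T - T_{ref})/10}\,C$ (defaults $r_0 = 0.08$
day$^{-1}$ at 10 °C, $Q_{10} = 2$) — the functional form is an emulation
choice, stated as such. `temperature_counterfactual()` recomputes the rate
with temperatures frozen at a pre-storm profile (default 24 h before
passage, consistent with the decomposition reference) and integrates the
difference to 100 m and 1,000 m by the trapezoid rule. Because storm wakes
cool the surface and warm the subsurface, the two contributions largely
cancel in the vertical integral; the antisymmetric closed-form case in the
tests makes that cancellation exact to within discretization.
`export_ratio()` computes lagged export-to-NPP ratios (default lag 9 days).

## The synthetic TC-ocean scenario generator

The generator is first-class, tested code: it defines the study conditions
under which every scenario-dependent property is evaluated.

**Atmosphere.** Each storm is a Holland (1980) parametric vortex:

$$P(r) = P_c + \Delta P\, e^{-(R_{mw}/r)^B}, \qquad
  V(r) = V_{max}\left[(R_{mw}/r)^B e^{1 - (R_{mw}/r)^B}\right]^{1/2},$$

with $B = V_{max}^2 \rho_a e / \Delta P$ clamped to [1, 2.5], translated
along a constant-velocity track with a piecewise-linear intensity ramp
(spin-up over the first 30 % of the life, peak plateau, decay over the last
20 %). Additive Gaussian noise (0.3 hPa, 0.4 m s$^{-1}$) under a single
integer seed; all randomness in the package flows from that seed and reruns
are bit-identical.

**Ocean.** A per-cell slab mixed layer of depth $h$ over prescribed
sub-mixed-layer gradients, with bulk entrainment
$w_e = c_e\,u_*^3 / (h\,\Delta b)$ capped at $10^{-3}$ m s$^{-1}$, where
$u_*$ is the water-side friction velocity from a capped drag law and
$\Delta b$ the buoyancy jump at the base (plus a background jump of
$5\times10^{-4}$ m s$^{-2}$ that keeps calm-weather entrainment
negligible). Entrained water carries the sub-ML properties; the mixed layer
shoals back toward its initial depth with a 10-day e-folding when stirring
is weak. Rightward wake asymmetry — in nature a consequence of inertial
resonance with the turning wind vector — is emulated parametrically by a
cross-track multiplier $1 + a\,w_{right}$ (default $a = 0.5$) on the
stirring power; the package does not resolve inertial currents. Surface
heat exchange is bulk aerodynamic (latent plus sensible, fixed exchange
coefficients, air 1.2 °C cooler at 82 % relative humidity), a diurnal
shortwave cycle with a 190 W m$^{-2}$ mean, and a constant 75 W m$^{-2}$
non-solar loss; category-4 winds over warm water yield peak latent heat
fluxes around 1,200 W m$^{-2}$, inside the observed 400–2,000 W m$^{-2}$
envelope for major hurricanes. Biology is NPZ-style: one nutrient, one
phytoplankton, one detritus pool, Monod uptake with Q10 growth, linear
mortality, temperature-dependent remineralization and a 2 m day$^{-1}$
detritus sinking export out of the mixed layer, Redfield-coupled to DIC
and nutrient.

**Default scenario.** Two category-4 storms (peak 62 m s$^{-1}$, $R_{mw}$
40 km, translation ≈ 5.8 m s$^{-1}$) crossing a 0.5°, 62–38° W / 16–44° N
domain over 18 hourly-sampled days, the second storm's track converging
onto the first one's wake in the extratropics, after a calm 2.4-day
baseline. The background state (28.5 °C, S 36.5, DIC 1998, Alk 2310
µmol kg$^{-1}$) is supersaturated in pCO2 against a 414-ppm atmosphere, so
storm passage causes instantaneous outgassing while the cold wake drives
pCO2 below saturation afterwards. The sub-ML gradients (−0.12 K m$^{-1}$,
+0.25 µmol kg$^{-1}$ m$^{-1}$ DIC, +0.12 µmol kg$^{-1}$ m$^{-1}$ nutrient
over 150 m) were chosen once so that the default run exhibits the canonical
storm-wake regime: cat-4 wake cooling between 1.0 and 2.5 °C with a
rightward shift, mixed-layer deepening of several tens of meters,
temperature-dominated pCO2 drawdown of 10–40 µatm, a 20–40× flux
amplification over the calm baseline, and a nutrient-fueled bloom peaking
days to two weeks after passage. The two-storm overlap matters: only where
the second storm's winds act on already-undersaturated wake water do
cumulative along-track fluxes invert from net outgassing to net uptake —
with a single storm the instantaneous burst always wins.

**What the generator does not emulate.** No three-dimensional dynamics: no
horizontal advection (so no boundary-current spreading of blooms or warm
advection into wakes — those terms are identically zero in the emitted
budgets), no near-inertial wave propagation (asymmetry is parametric), no
subsurface warming below the slab (the counterfactual's compensation
structure is therefore demonstrated on constructed profiles), no sea ice,
no land. Passing tests on this scenario demonstrate that the diagnostics
measure what they claim on fields with the right statistical structure;
they are not evidence about any particular real ocean state.

## Numerical choices

* Slab integration: explicit Euler at the forcing step (1 h), written
  in-package rather than with an ODE library precisely so that each process
  term is recorded at each step and the budget closes to round-off. Rates
  at these defaults keep per-step relative changes of order $10^{-2}$; a
  negative tracer concentration aborts the run as an integration failure
  rather than being clipped.
* Carbonate solver: bracketed Newton with log-space bisection fallback;
  non-convergence after 100 iterations is an error with diagnostics, never
  a silent value.
* Grid: regular latitude-longitude, spherical cell areas, longitudes
  normalized to [−180, 180); cell-in-circle means cell centre inside the
  great-circle radius.
* Problem sizes in the tests: the default 0.5° scenario (2,688 cells × 433
  hours), a 10-day three-storm recovery scenario at 0.5° over a wider
  basin, and a 90-day small-domain run for export-ratio stability — sizes
  chosen to exercise every code path in well under an hour on one CPU.
* Tie-breaks: tracker ties at equal time go to lowest MSLP, making the
  result invariant to candidate storage order.

## Known limitations

The slab model's single-layer carbon response understates vertical DIC
redistribution compared to depth-resolved models; the export pathway is a
single sinking detritus pool, not an aggregate-resolving scheme; the
decomposition is first-order (no second-order Taylor terms); circle
averages assume ocean everywhere (no land masking); and the carbonate
solver covers the borate/carbonate/water alkalinity terms only — nutrient
and ligand alkalinity are out of scope.
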