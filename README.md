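# stormflux

Diagnostics of tropical-cyclone (TC) impacts on the ocean carbon cycle from
gridded surface fields.

Intense hurricanes perturb air–sea CO₂ exchange twice over: during passage,
winds drive an instantaneous burst of gas exchange (the transfer velocity is
quadratic in wind speed), and for weeks afterwards the cold wake left by
storm-driven mixing suppresses surface pCO₂ — cooling lowers pCO₂ by about
4 % per °C — which can flip a supersaturated outgassing region into a CO₂
sink. The same mixing entrains nutrients that fuel a post-storm
phytoplankton bloom. stormflux packages the computations needed to detect
storms in gridded model output and to quantify these effects, together with
a seeded synthetic TC–ocean scenario generator used to validate every
diagnostic against planted ground truth.

For ocean-carbon and storm–ocean interaction researchers working with
gridded surface output (CF netCDF) from eddy/storm-resolving simulations,
reanalyses, or idealized models.

## What is inside

* **TC tracker** (`track_cyclones()`): masked-minimum candidate detection on
  MSLP (< 1,010 hPa, 800-km masking), greedy stitching (wind ≥ 17 m/s,
  100 km / 24 h link rules, lowest-MSLP tie-break), strict retention
  (lifetime > 24 h, lifetime-maximum intensity > 33 m/s).
* **Carbonate system and flux** (`solve_carbonate()`,
  `air_sea_co2_flux()`): pCO₂ from DIC and total alkalinity (total pH
  scale, OMIP-style constants), Schmidt number and Weiss solubility, and

  `F = k_w · S_CO2 · (pCO2_ocean − pCO2_atm)`, positive upward,
  with `k_w = 0.251 u₁₀² (Sc/660)^(−1/2)` cm/h.
* **Along-track diagnostics**: 200-km moving-circle averages, cold-wake
  deltas (24 h after − 24 h before), along-track time diagrams, flux
  fold-increase over a calm baseline, track-region carbon integrals in TgC,
  cumulative fluxes, mixed-layer depth (0.03 / 0.125 kg/m³ thresholds),
  Brunt–Väisälä frequency, inertial period.
* **pCO₂ decomposition** (`decompose_pco2()`): Takahashi-style split of a
  pCO₂ change into SST, SSS, DIC and alkalinity terms with
  γ_SST = 0.0423 °C⁻¹, γ_SSS = 1, and the Revelle-factor pair
  γ_DIC = (3·Alk·DIC − 2·DIC²)/((2·DIC − Alk)(Alk − DIC)),
  γ_Alk = −Alk²/((2·DIC − Alk)(Alk − DIC)), which satisfy
  γ_DIC + γ_Alk = 1; reconstruction residuals are always reported.
* **Budgets and remineralization** (`budget_residual()`,
  `temperature_counterfactual()`, `export_ratio()`): tendency-closure
  checks for the standard advection/diffusion/surface/biology
  decomposition, a Q10 remineralization model with a fixed-temperature
  counterfactual and 0–100 m / 0–1,000 m integrals, and lagged
  export-to-NPP ratios.
* **Synthetic scenarios** (`default_scenario()`, `run_slab_ocean()`):
  Holland-vortex forcing over a slab mixed layer with wind-stirring
  entrainment, rightward wake asymmetry, bulk heat fluxes, full carbonate
  chemistry and NPZ-style biology, with planted tracks attached as ground
  truth and per-term budget bookkeeping that closes to round-off.

See `vignettes/stormflux-methods.Rmd` for the full model description,
parameter defaults and limitations.

## Worked example

```r
library(stormflux)

res <- run_pipeline(read_config(), verbose = FALSE)   # seeded end to end
tr  <- res$tracks[[1]]                                # most intense track

length(res$tracks)                                    # 2
track_lmi_ms(tr)                                      # 62.9  (cat4)
min(res$wake$delta, na.rm = TRUE)                     # -1.19 degC
max(res$fold$fold, na.rm = TRUE)                      # 22.5
res$integral$total_tgc                                # 0.244 TgC
res$decomposition$summary$residual_fraction           # 0.088
res$budget$normalized                                 # 0
```

The pipeline synthesizes the packaged two-storm category-4 scenario,
recovers both storms from the MSLP/wind fields alone, and then diagnoses
them. Reading the numbers: the tracker's best storm peaks at 62.9 m/s
(category 4); its strongest 200-km-circle wake cooling is −1.19 °C (this is
the second storm, which runs over the first one's wake — the fresh-water
storm cools by up to −1.6 °C); storm-time CO₂ fluxes are 22.5× the calm
baseline; the instantaneous passage integral over the track region is a net
outgassing of 0.244 TgC; the four-term pCO₂ decomposition reconstructs the
simulated change to within 8.8 % RMS, with the SST term dominant; and the
emitted DIC budget closes exactly.

At one point of strongest drawdown the decomposition reads (µatm):

```
dpco2_sst  dpco2_sss  dpco2_dic  dpco2_alk  dpco2_total  dpco2_sim
   -21.35       0.48      -0.27      -0.84       -21.98      -20.12
```

cooling does almost all the work, slightly offset by salinity, with a small
residual left to the linearization.

A thin CLI wrapping the same functions is installed at
`inst/scripts/stormflux` (subcommands `run`, `synthesize`, `track`,
`diagnose`, `decompose`).

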