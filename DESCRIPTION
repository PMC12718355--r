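Package: stormflux
Title: Tropical-Cyclone Impacts on the Ocean Carbon Cycle from Gridded Surface Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Diagnostics of tropical-cyclone (TC) impacts on air-sea CO2
    exchange and upper-ocean biogeochemistry from gridded surface fields.
    Provides a pressure-minimum TC tracker with track stitching and
    hurricane-strength filtering; a carbonate-system solver (pCO2 from DIC
    and total alkalinity) with Schmidt-number, solubility and quadratic
    wind-speed gas-transfer parameterizations for the air-sea CO2 flux;
    along-track composite diagnostics (200-km circle averages, cold-wake
    deltas, flux fold-increase, track-region carbon integrals, cumulative
    fluxes); a Takahashi-style decomposition of surface-pCO2 changes into
    temperature, salinity, DIC and alkalinity contributions with Revelle
    factors; tracer-budget closure and a fixed-temperature remineralization
    counterfactual; and a seeded synthetic TC-ocean scenario generator
    (parametric translating vortex over a slab mixed layer with entrainment
    and NPZ-style biology) for testing and method studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    ncdf4,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
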