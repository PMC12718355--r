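#' Schmidt number of CO2 in seawater
#'
#' Fourth-order polynomial fit of Wanninkhof (2014) for CO2 in seawater,
#' valid for -2 to 40 degC (Sc = 668 at 20 degC).
#'
#' @param temp_c temperature in degC.
#' @return dimensionless Schmidt number, strictly decreasing in temperature.
#' @export
schmidt_number <- function(temp_c) {
  check_range(temp_c, -2, 40, "temperature (degC)")
  2116.8 - 136.25 * temp_c + 4.7353 * temp_c^2 -
    0.092307 * temp_c^3 + 0.0007555 * temp_c^4
}

#' Gas transfer velocity, quadratic in 10-m wind
#'
#' k_w = a * u10^2 * (Sc/660)^(-1/2) with a = 0.251 cm h^-1 (m s^-1)^-2
#' (Wanninkhof 2014), returned in m/s. The quadratic wind dependence makes
#' storm-force winds dominate air-sea exchange.
#'
#' @param u10 10-m wind speed (m/s), >= 0.
#' @param temp_c temperature (degC) entering via the Schmidt number.
#' @param a transfer coefficient, cm h^-1 (m s^-1)^-2.
#' @return k_w in m/s; 0 at zero wind.
#' @export
gas_transfer_velocity <- function(u10, temp_c, a = 0.251) {
  if (any(u10 < 0, na.rm = TRUE)) stop("u10 must be >= 0")
  sc <- schmidt_number(temp_c)
  kw_cm_h <- a * u10^2 * sqrt(660 / sc)
  kw_cm_h / 100 / 3600
}

#' CO2 solubility in seawater (Weiss 1974)
#'
#' K0 from the Weiss (1974) fit (gravimetric form, mol kg^-1 atm^-1),
#' converted to volumetric mol m^-3 uatm^-1 with the reference density.
#'
#' @param temp_c temperature (degC), -2..40.
#' @param sal practical salinity, 0..45.
#' @param rho0 seawater density used for the kg -> m^3 conversion (kg/m^3).
#' @return solubility in mol m^-3 uatm^-1, strictly decreasing in temperature.
#' @export
co2_solubility <- function(temp_c, sal, rho0 = 1025) {
  co2_k0(temp_c, sal) * rho0 * 1e-6
}

# Weiss (1974) K0 in mol kg^-1 atm^-1
co2_k0 <- function(temp_c, sal) {
  check_range(temp_c, -2, 40, "temperature (degC)")
  check_range(sal, 0, 45, "salinity")
  tk100 <- (temp_c + 273.15) / 100
  exp(-60.2409 + 93.4517 / tk100 + 23.3585 * log(tk100) +
        sal * (0.023517 - 0.023656 * tk100 + 0.0047036 * tk100^2))
}

check_range <- function(x, lo, hi, what) {
  bad <- !is.na(x) & (x < lo | x > hi)
  if (any(bad))
    stop(sprintf("%s outside validity range [%g, %g] (got %g)",
                 what, lo, hi, x[bad][1]))
  invisible(x)
}

#' Carbonate-system equilibrium constants (total pH scale)
#'
#' The OMIP-recommended set: K1/K2 from Lueker et al. (2000), KB from
#' Dickson (1990), KW from Millero (1995), total boron from salinity after
#' Uppstrom (1974), K0 from Weiss (1974). All on the total hydrogen-ion
#' scale, surface pressure, concentrations in mol/kg-solution.
#'
#' @param temp_c temperature (degC).
#' @param sal practical salinity.
#' @return list of vectors `k0`, `k1`, `k2`, `kb`, `kw`, `bt` recycled to a
#'   common length.
#' @export
carbonate_constants <- function(temp_c, sal) {
  check_range(temp_c, -2, 40, "temperature (degC)")
  check_range(sal, 0, 45, "salinity")
  tk <- temp_c + 273.15
  lntk <- log(tk)
  s <- sal
  # Lueker et al. (2000): pK on total scale
  pk1 <- 3633.86 / tk - 61.2172 + 9.6777 * lntk - 0.011555 * s + 0.0001152 * s^2
  pk2 <- 471.78 / tk + 25.929 - 3.16967 * lntk - 0.01781 * s + 0.0001122 * s^2
  # Dickson (1990) boric acid
  lnkb <- (-8966.90 - 2890.53 * sqrt(s) - 77.942 * s +
             1.728 * s^1.5 - 0.0996 * s^2) / tk +
    148.0248 + 137.1942 * sqrt(s) + 1.62142 * s -
    (24.4344 + 25.085 * sqrt(s) + 0.2474 * s) * lntk +
    0.053105 * sqrt(s) * tk
  # Millero (1995) water dissociation, total scale
  lnkw <- 148.9652 - 13847.26 / tk - 23.6521 * lntk +
    (118.67 / tk - 5.977 + 1.0495 * lntk) * sqrt(s) - 0.01615 * s
  list(k0 = co2_k0(temp_c, sal),
       k1 = 10^(-pk1), k2 = 10^(-pk2),
       kb = exp(lnkb), kw = exp(lnkw),
       bt = 0.0004157 * s / 35)
}

#' Solve the carbonate system: pCO2 from DIC and total alkalinity
#'
#' Solves the total-alkalinity balance (carbonate, bicarbonate, borate and
#' water terms) for the hydrogen-ion concentration with a safeguarded,
#' vectorized Newton iteration bracketed in pH 3..12, then derives aqueous
#' CO2 and pCO2 = [CO2*]/K0. This is the pCO2 "calculated from DIC and
#' alkalinity" that drives the air-sea flux.
#'
#' @param dic dissolved inorganic carbon (umol/kg).
#' @param alk total alkalinity (umol/kg). Requires DIC < Alk < 2*DIC.
#' @param temp_c temperature (degC), -2..40.
#' @param sal practical salinity, 0..45.
#' @param h_init optional initial hydrogen-ion concentration (mol/kg) to
#'   warm-start the iteration (e.g. the previous time step's solution).
#' @param tol convergence tolerance on the alkalinity balance (umol/kg).
#' @param maxit maximum Newton/bisection iterations.
#' @return list of vectors: `pco2` (uatm), `h` (mol/kg, total scale),
#'   `co2star` (umol/kg), `ph` (total scale).
#' @examples
#' solve_carbonate(2000, 2300, 25, 36)$pco2
#' @export
solve_carbonate <- function(dic, alk, temp_c, sal, h_init = NULL,
                            tol = 1e-3, maxit = 100) {
  n <- max(length(dic), length(alk), length(temp_c), length(sal))
  dic <- rep_len(dic, n); alk <- rep_len(alk, n)
  temp_c <- rep_len(temp_c, n); sal <- rep_len(sal, n)
  bad <- !is.na(dic) & !is.na(alk) & !(dic > 0 & alk > dic & alk < 2 * dic)
  if (any(bad))
    stop(sprintf(
      "invalid DIC/Alk ordering: need 0 < DIC < Alk < 2*DIC (got DIC=%g, Alk=%g)",
      dic[bad][1], alk[bad][1]))
  k <- carbonate_constants(temp_c, sal)
  dic_m <- dic * 1e-6; alk_m <- alk * 1e-6
  tol_m <- tol * 1e-6

  # alkalinity balance and its dH derivative at hydrogen-ion conc h
  balance <- function(h) {
    den <- h^2 + k$k1 * h + k$k1 * k$k2
    ac <- dic_m * (k$k1 * h + 2 * k$k1 * k$k2) / den
    ab <- k$bt * k$kb / (k$kb + h)
    ac + ab + k$kw / h - h - alk_m
  }
  dbalance <- function(h) {
    den <- h^2 + k$k1 * h + k$k1 * k$k2
    num <- k$k1 * h + 2 * k$k1 * k$k2
    dac <- dic_m * (k$k1 * den - num * (2 * h + k$k1)) / den^2
    dab <- -k$bt * k$kb / (k$kb + h)^2
    dac + dab - k$kw / h^2 - 1
  }

  lo <- rep(10^-12, n); hi <- rep(10^-3, n)
  flo <- balance(lo); fhi <- balance(hi)
  if (any(flo * fhi > 0, na.rm = TRUE))
    stop("carbonate solver: root not bracketed in pH 3..12")
  h <- if (is.null(h_init)) rep(1e-8, n) else pmin(pmax(rep_len(h_init, n), lo), hi)
  f <- balance(h)
  converged <- abs(f) < tol_m
  it <- 0
  while (!all(converged | is.na(f)) && it < maxit) {
    it <- it + 1
    # maintain bracket
    pos <- !is.na(f) & f > 0   # f>0 means h too small (alk overshoot)
    lo[pos & !converged] <- h[pos & !converged]
    hi[!pos & !converged] <- h[!pos & !converged]
    step <- f / dbalance(h)
    hn <- h - step
    # safeguard: fall back to bisection where Newton leaves the bracket
    out <- is.na(hn) | hn <= lo | hn >= hi
    hn[out] <- sqrt(lo[out] * hi[out])  # geometric midpoint (log-bisection)
    h[!converged] <- hn[!converged]
    f <- balance(h)
    converged <- converged | abs(f) < tol_m
  }
  if (!all(converged, na.rm = TRUE))
    stop(sprintf(
      "carbonate solver failed to converge in %d iterations (max |residual| = %.3g umol/kg)",
      maxit, max(abs(f[!converged]), na.rm = TRUE) * 1e6))
  den <- h^2 + k$k1 * h + k$k1 * k$k2
  co2star <- dic_m * h^2 / den
  pco2 <- co2star / k$k0 * 1e6  # atm -> uatm given co2star in mol/kg
  list(pco2 = pco2, h = h, co2star = co2star * 1e6, ph = -log10(h))
}

#' DIC from pCO2 and alkalinity (solver inversion)
#'
#' Inverts the carbonate system: given surface pCO2 and total alkalinity,
#' recovers DIC. Used for round-trip validation of [solve_carbonate()].
#'
#' @param pco2 uatm.
#' @param alk total alkalinity (umol/kg).
#' @param temp_c,sal as in [solve_carbonate()].
#' @return DIC in umol/kg.
#' @export
dic_from_pco2 <- function(pco2, alk, temp_c, sal) {
  n <- max(length(pco2), length(alk), length(temp_c), length(sal))
  pco2 <- rep_len(pco2, n); alk <- rep_len(alk, n)
  temp_c <- rep_len(temp_c, n); sal <- rep_len(sal, n)
  k <- carbonate_constants(temp_c, sal)
  alk_m <- alk * 1e-6
  vapply(seq_len(n), function(i) {
    co2 <- k$k0[i] * pco2[i] * 1e-6
    f <- function(h) {
      ac <- co2 * (k$k1[i] / h + 2 * k$k1[i] * k$k2[i] / h^2)
      ab <- k$bt[i] * k$kb[i] / (k$kb[i] + h)
      ac + ab + k$kw[i] / h - h - alk_m[i]
    }
    h <- stats::uniroot(f, c(1e-12, 1e-3), tol = 1e-18)$root
    co2 * (1 + k$k1[i] / h + k$k1[i] * k$k2[i] / h^2) * 1e6
  }, numeric(1))
}

#' Atmospheric pCO2 from dry-air mole fraction and pressure
#'
#' pCO2_atm = xCO2 * (SLP - pH2O_sat), with the saturation water-vapor
#' pressure over seawater from the Weiss and Price (1980) fit. This is the
#' total-pressure correction applied to the uniformly prescribed
#' atmospheric CO2 mole fraction.
#'
#' @param xco2_ppm dry-air CO2 mole fraction (ppm); default 414 ppm
#'   (year-2020 global surface mean).
#' @param slp_hpa sea-level pressure (hPa), 870..1085.
#' @param temp_c,sal surface temperature and salinity for the vapor pressure.
#' @return pCO2_atm in uatm.
#' @export
pco2_atmosphere <- function(xco2_ppm, slp_hpa = 1013.25, temp_c = 25, sal = 35) {
  if (any(xco2_ppm <= 0, na.rm = TRUE)) stop("xco2_ppm must be > 0")
  check_range(slp_hpa, 870, 1085, "sea-level pressure (hPa)")
  tk100 <- (temp_c + 273.15) / 100
  ph2o_atm <- exp(24.4543 - 67.4509 / tk100 - 4.8489 * log(tk100) - 0.000544 * sal)
  xco2_ppm * (slp_hpa / 1013.25 - ph2o_atm)
}

#' Air-sea CO2 flux
#'
#' F = k_w * S_CO2 * (pCO2_ocean - pCO2_atm), positive upward (ocean to
#' atmosphere): positive = outgassing, negative = ocean uptake.
#'
#' @param kw gas transfer velocity (m/s), >= 0.
#' @param s_co2 solubility (mol m^-3 uatm^-1), > 0.
#' @param pco2_ocean,pco2_atm partial pressures (uatm).
#' @param units `"mmol_m2_day"` (display unit) or `"mol_m2_s"` (internal SI).
#' @return flux in the requested unit, positive upward.
#' @export
air_sea_co2_flux <- function(kw, s_co2, pco2_ocean, pco2_atm,
                             units = c("mmol_m2_day", "mol_m2_s")) {
  units <- match.arg(units)
  if (any(kw < 0, na.rm = TRUE)) stop("kw must be >= 0")
  if (any(s_co2 <= 0, na.rm = TRUE)) stop("s_co2 must be > 0")
  f <- kw * s_co2 * (pco2_ocean - pco2_atm)  # mol m^-2 s^-1
  if (units == "mmol_m2_day") f * 1000 * 86400 else f
}
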