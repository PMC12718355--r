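#' Specification of one translating parametric vortex
#'
#' Describes a storm by genesis position, constant translation velocity (or
#' waypoints via successive specs), maximum wind, radius of maximum wind,
#' and a piecewise-linear intensity ramp over its life. The radial
#' structure follows the Holland (1980) parametric model (see
#' [make_vortex_snapshot()]).
#'
#' @param genesis_lon,genesis_lat genesis position (deg).
#' @param translation_ms constant translation velocity, length-2 (east,
#'   north) in m/s.
#' @param vmax_ms lifetime-maximum 10-m wind (m/s), >= 0.
#' @param rmw_km radius of maximum wind (km), > 0.
#' @param penv_hpa environmental sea-level pressure (hPa).
#' @param pmin_hpa central pressure at peak intensity (hPa); must be below
#'   `penv_hpa` whenever `vmax_ms` > 17 m/s.
#' @param t_start,t_end POSIXct life span of the vortex.
#' @param ramp piecewise-linear intensity ramp: data.frame with `frac`
#'   (0..1, fraction of the life span) and `scale` (0..1 multiplier on the
#'   peak intensity). Default: linear spin-up over the first 30%, peak
#'   plateau, decay over the final 20%.
#' @return object of class `vortex_spec`.
#' @export
vortex_spec <- function(genesis_lon, genesis_lat, translation_ms,
                        vmax_ms, rmw_km = 40, penv_hpa = 1012,
                        pmin_hpa = 940, t_start, t_end,
                        ramp = data.frame(frac = c(0, 0.3, 0.8, 1),
                                          scale = c(0.25, 1, 1, 0.5))) {
  stopifnot(vmax_ms >= 0, rmw_km > 0, length(translation_ms) == 2,
            inherits(t_start, "POSIXct"), inherits(t_end, "POSIXct"),
            t_end > t_start)
  if (vmax_ms > 17 && pmin_hpa >= penv_hpa)
    stop("central pressure must be below environmental pressure for storm-force vortices")
  structure(list(genesis_lon = normalize_lon(genesis_lon),
                 genesis_lat = genesis_lat,
                 translation_ms = translation_ms, vmax_ms = vmax_ms,
                 rmw_km = rmw_km, penv_hpa = penv_hpa, pmin_hpa = pmin_hpa,
                 t_start = t_start, t_end = t_end, ramp = ramp),
            class = "vortex_spec")
}

# position of the vortex centre at POSIXct time(s); NA outside its life
vortex_position <- function(spec, time) {
  el_s <- as.numeric(difftime(time, spec$t_start, units = "secs"))
  life_s <- as.numeric(difftime(spec$t_end, spec$t_start, units = "secs"))
  lat <- spec$genesis_lat + spec$translation_ms[2] * el_s /
    (EARTH_RADIUS_M * pi / 180)
  # integrate zonal motion at the mean latitude of the displacement
  lat_mid <- (spec$genesis_lat + lat) / 2
  lon <- normalize_lon(spec$genesis_lon + spec$translation_ms[1] * el_s /
                         (EARTH_RADIUS_M * cos(lat_mid * pi / 180) * pi / 180))
  alive <- el_s >= 0 & el_s <= life_s
  data.frame(lon = ifelse(alive, lon, NA_real_),
             lat = ifelse(alive, lat, NA_real_),
             frac = ifelse(alive, el_s / life_s, NA_real_))
}

# intensity multiplier (0..1) from the piecewise-linear ramp
vortex_intensity_scale <- function(spec, frac) {
  stats::approx(spec$ramp$frac, spec$ramp$scale, xout = frac, rule = 2)$y
}

#' Instantaneous MSLP/wind fields of one or more parametric vortices
#'
#' Evaluates the Holland (1980) radial profile on the grid:
#' \deqn{P(r) = P_c + (P_{env} - P_c)\,e^{-(R_{mw}/r)^B}}
#' \deqn{V(r) = V_{max} \left[(R_{mw}/r)^B e^{1-(R_{mw}/r)^B}\right]^{1/2}}
#' with the shape parameter B fixed by the spec's peak wind and pressure
#' deficit, \eqn{B = V_{max}^2 \rho_a e / (P_{env} - P_c)}, clamped to
#' [1, 2.5]. The wind maximum sits at the radius of maximum wind and both
#' fields decay to environmental values far from the centre. A vortex
#' outside its life span contributes nothing (environmental field).
#'
#' @param specs a `vortex_spec` or list of them.
#' @param time POSIXct, one time.
#' @param grid an [sf_grid()].
#' @param background_wind_ms ambient wind added in quadrature (m/s).
#' @return list with vectors `mslp` (hPa) and `wind10` (m/s) over grid
#'   cells, plus `centers` (data.frame of active vortex centres).
#' @export
make_vortex_snapshot <- function(specs, time, grid, background_wind_ms = 0) {
  if (inherits(specs, "vortex_spec")) specs <- list(specs)
  ncell <- length(grid$cell_lon)
  penv <- if (length(specs)) specs[[1]]$penv_hpa else 1012
  mslp <- rep(penv, ncell)
  wind2 <- rep(background_wind_ms^2, ncell)
  centers <- list()
  for (spec in specs) {
    pos <- vortex_position(spec, time)
    if (is.na(pos$lon)) next
    sc <- vortex_intensity_scale(spec, pos$frac)
    vmax <- spec$vmax_ms * sc
    dp <- (spec$penv_hpa - spec$pmin_hpa) * sc^2  # deficit ~ vmax^2
    if (vmax <= 0 || dp <= 0) next
    b <- min(max(vmax^2 * 1.15 * exp(1) / (dp * 100), 1), 2.5)
    r <- gc_dist_km(grid$cell_lon, grid$cell_lat, pos$lon, pos$lat)
    x <- (spec$rmw_km / pmax(r, 1e-6))^b
    mslp <- mslp - dp * (1 - exp(-x))  # Penv - P(r) = dp (1 - e^-x)
    v <- vmax * sqrt(x * exp(1 - x))
    wind2 <- wind2 + v^2
    centers[[length(centers) + 1]] <-
      data.frame(lon = pos$lon, lat = pos$lat, vmax_ms = vmax,
                 pmin_hpa = spec$penv_hpa - dp)
  }
  list(mslp = mslp, wind10 = sqrt(wind2),
       centers = if (length(centers)) do.call(rbind, centers)
       else data.frame(lon = numeric(), lat = numeric(),
                       vmax_ms = numeric(), pmin_hpa = numeric()))
}
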