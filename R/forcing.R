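#' Ground truth of a synthetic scenario
#'
#' Carries the planted storm tracks (as `cyclone_track` objects on the
#' forcing's time axis), the originating vortex specs, and the seed, for
#' tracker-recovery and timing tests.
#'
#' @param specs list of [vortex_spec()]s.
#' @param tracks list of `cyclone_track`s sampled from the specs.
#' @param seed integer seed used for the forcing noise.
#' @return object of class `scenario_truth`.
#' @export
scenario_truth <- function(specs, tracks, seed) {
  for (tr in tracks) {
    if (nrow(tr) < 2) stop("every planted track needs >= 2 points")
    if (any(diff(as.numeric(tr$time)) <= 0))
      stop("planted track times must be strictly increasing")
  }
  structure(list(specs = specs, tracks = tracks, seed = seed),
            class = "scenario_truth")
}

#' Generate gridded atmospheric forcing for translating parametric vortices
#'
#' Evaluates [make_vortex_snapshot()] at every time, adds seeded Gaussian
#' observation noise, and attaches the planted ground truth. Fields carry
#' CF-style units.
#'
#' @param specs a [vortex_spec()] or list of them (may be empty for a calm
#'   scenario).
#' @param grid an [sf_grid()].
#' @param times POSIXct vector, uniform spacing.
#' @param background_wind_ms ambient wind speed (m/s).
#' @param noise_sd_mslp_hpa,noise_sd_wind_ms additive noise standard
#'   deviations (0 disables noise).
#' @param seed integer seed controlling all noise.
#' @return `field_series` with `mslp` (hPa) and `wind10` (m/s, >= 0) and a
#'   `scenario_truth` in `attr(, "truth")`.
#' @export
make_forcing <- function(specs, grid, times, background_wind_ms = 6,
                         noise_sd_mslp_hpa = 0.3, noise_sd_wind_ms = 0.4,
                         seed = 1L) {
  if (inherits(specs, "vortex_spec")) specs <- list(specs)
  nt <- length(times); ncell <- length(grid$cell_lon)
  mslp <- matrix(NA_real_, nt, ncell)
  wind <- matrix(NA_real_, nt, ncell)
  for (ti in seq_len(nt)) {
    snap <- make_vortex_snapshot(specs, times[ti], grid, background_wind_ms)
    mslp[ti, ] <- snap$mslp
    wind[ti, ] <- snap$wind10
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  if (noise_sd_mslp_hpa > 0)
    mslp <- mslp + matrix(stats::rnorm(nt * ncell, 0, noise_sd_mslp_hpa), nt, ncell)
  if (noise_sd_wind_ms > 0)
    wind <- pmax(wind + matrix(stats::rnorm(nt * ncell, 0, noise_sd_wind_ms),
                               nt, ncell), 0)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  fs <- field_series(grid, times, list(mslp = mslp, wind10 = wind),
                     units = c(mslp = "hPa", wind10 = "m s-1"))
  attr(fs, "truth") <- scenario_truth(specs, planted_tracks(specs, times), seed)
  fs
}

# sample the planted specs on the forcing time axis as cyclone_tracks
planted_tracks <- function(specs, times) {
  out <- list()
  for (spec in specs) {
    pos <- vortex_position(spec, times)
    alive <- !is.na(pos$lon)
    if (sum(alive) < 2) next
    sc <- vortex_intensity_scale(spec, pos$frac[alive])
    df <- data.frame(time = times[alive], lat = pos$lat[alive],
                     lon = pos$lon[alive],
                     mslp_hpa = spec$penv_hpa -
                       (spec$penv_hpa - spec$pmin_hpa) * sc^2,
                     vmax_ms = spec$vmax_ms * sc)
    out[[length(out) + 1]] <- as_cyclone_track(df)
  }
  out
}

#' The packaged default synthetic scenario
#'
#' Two successive category-4 vortices translating northward across a
#' subtropical western-boundary domain, their tracks converging in the
#' extratropics so that the second storm crosses the first one's cold
#' wake (the configuration in which storm winds act on already-cooled,
#' pCO2-undersaturated water and instantaneous fluxes invert to uptake):
#' a 0.5-degree grid over 62-38 W, 16-44 N, hourly times over 18 days
#' starting 1 September; storm lives days 2.5-8 and 8.5-14, peak winds
#' 62 m/s, radius of maximum wind 40 km, translation ~5.8 m/s. The calm
#' first two days serve as the flux baseline window.
#'
#' @param seed integer seed for the forcing noise.
#' @param res grid spacing in degrees.
#' @param days scenario length in days.
#' @return list with `forcing` (`field_series` + truth), `grid`, `specs`,
#'   `baseline_window` (POSIXct length-2) and `times`.
#' @export
default_scenario <- function(seed = 1L, res = 0.5, days = 18) {
  grid <- sf_grid(c(-62, -38), c(16, 44), res = res)
  t0 <- as.POSIXct("2020-09-01 00:00:00", tz = "UTC")
  times <- seq(t0, by = 3600, length.out = days * 24 + 1)
  tc1 <- vortex_spec(
    genesis_lon = -50, genesis_lat = 20,
    translation_ms = c(-1.2, 5.3), vmax_ms = 62, rmw_km = 40,
    penv_hpa = 1012, pmin_hpa = 938,
    t_start = t0 + 2.5 * 86400, t_end = t0 + 8 * 86400)
  tc2 <- vortex_spec(
    genesis_lon = -45, genesis_lat = 19,
    translation_ms = c(-2.3, 5.3), vmax_ms = 62, rmw_km = 40,
    penv_hpa = 1012, pmin_hpa = 938,
    t_start = t0 + 8.5 * 86400, t_end = t0 + 14 * 86400)
  forcing <- make_forcing(list(tc1, tc2), grid, times, seed = seed)
  list(forcing = forcing, grid = grid, specs = list(tc1, tc2),
       baseline_window = c(t0, t0 + 2.4 * 86400), times = times)
}
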