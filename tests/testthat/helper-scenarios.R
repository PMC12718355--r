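# Shared scenario fixtures, computed once per test run and cached.
.sf_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, .sf_cache)) assign(name, builder(), .sf_cache)
  get(name, .sf_cache)
}

# the packaged two-storm default scenario with slab run and tracks
default_run <- function() {
  cached("default_run", function() {
    scen <- default_scenario(seed = 7)
    run <- run_slab_ocean(scen$forcing, keep_terms = c("sst", "dic"))
    tracks <- track_cyclones(run$fields)
    tracks <- tracks[order(vapply(tracks, function(t) as.numeric(t$time[1]), 1))]
    list(scen = scen, run = run, tracks = tracks)
  })
}

# three staggered hurricane-strength storms, 10 days hourly, for
# tracker-recovery tests (forcing only; no ocean integration needed)
recovery_forcing <- function() {
  cached("recovery_forcing", function() {
    grid <- sf_grid(c(-80, -28), c(5, 45), res = 0.5)
    t0 <- as.POSIXct("2020-09-01 00:00:00", tz = "UTC")
    times <- seq(t0, by = 3600, length.out = 10 * 24 + 1)
    specs <- list(
      vortex_spec(-72, 10, c(-1.0, 4.5), vmax_ms = 62, rmw_km = 40,
                  pmin_hpa = 938, t_start = t0 + 0.2 * 86400,
                  t_end = t0 + 6 * 86400),
      vortex_spec(-52, 12, c(-1.0, 4.8), vmax_ms = 58, rmw_km = 45,
                  pmin_hpa = 944, t_start = t0 + 1 * 86400,
                  t_end = t0 + 8 * 86400),
      vortex_spec(-34, 15, c(-1.5, 4.2), vmax_ms = 55, rmw_km = 35,
                  pmin_hpa = 948, t_start = t0 + 2 * 86400,
                  t_end = t0 + 9 * 86400))
    make_forcing(specs, grid, times, seed = 11)
  })
}

# a small single-storm scenario for controlled slab experiments
small_scenario <- function(translation = c(0, 5.3), days = 9, seed = 3,
                           vmax = 62) {
  grid <- sf_grid(c(-58, -46), c(18, 42), res = 0.5)
  t0 <- as.POSIXct("2020-09-01 00:00:00", tz = "UTC")
  times <- seq(t0, by = 3600, length.out = days * 24 + 1)
  spec <- vortex_spec(-52, 20, translation, vmax_ms = vmax, rmw_km = 40,
                      pmin_hpa = 938, t_start = t0 + 1 * 86400,
                      t_end = t0 + 6 * 86400)
  list(forcing = make_forcing(spec, grid, times, seed = seed),
       grid = grid, times = times, spec = spec)
}

# calm forcing on a tiny grid (no storms, no noise, no background wind)
calm_forcing <- function(hours = 48, background = 0) {
  grid <- sf_grid(c(-52, -50), c(24, 26), res = 0.5)
  t0 <- as.POSIXct("2020-09-01 00:00:00", tz = "UTC")
  times <- seq(t0, by = 3600, length.out = hours + 1)
  make_forcing(list(), grid, times, background_wind_ms = background,
               noise_sd_mslp_hpa = 0, noise_sd_wind_ms = 0, seed = 1)
}

# slab params with every surface exchange and the biology switched off
inert_params <- function(...) {
  slab_params(sw_mean_wm2 = 0, lw_up_wm2 = 0, ce_lhf = 0, ch_shf = 0,
              rain_storm_m_s = 0, biology = FALSE, ...)
}

# fraction of planted track points matched by a recovered track within
# tol_km and one time step
track_match_fraction <- function(planted, recovered, tol_km) {
  hits <- 0
  for (i in seq_len(nrow(planted))) {
    dt_h <- abs(as.numeric(difftime(recovered$time, planted$time[i],
                                    units = "hours")))
    near_t <- which(dt_h <= 1)
    if (!length(near_t)) next
    d <- gc_dist_km(recovered$lon[near_t], recovered$lat[near_t],
                    planted$lon[i], planted$lat[i])
    if (min(d) <= tol_km) hits <- hits + 1
  }
  hits / nrow(planted)
}

# synthetic single-time field series on a given grid from a function of
# (lon, lat) or a constant
make_test_fields <- function(grid, times, fields, units = NULL) {
  vars <- lapply(fields, function(f) {
    if (is.function(f)) {
      row <- f(grid$cell_lon, grid$cell_lat)
      matrix(rep(row, each = length(times)), length(times))
    } else if (is.matrix(f)) f
    else matrix(f, length(times), length(grid$cell_lon))
  })
  field_series(grid, times, vars, units = units)
}
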