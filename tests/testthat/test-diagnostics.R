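t0 <- as.POSIXct("2020-09-01 00:00:00", tz = "UTC")

test_that("translation speed from great-circle spacing over native time steps", {
  # two points 100 km apart, 3 h apart -> 9.26 m/s
  lat2 <- 20 + 100 / 111.195
  tr <- stormflux:::as_cyclone_track(data.frame(
    time = t0 + c(0, 3) * 3600, lat = c(20, lat2), lon = -60,
    mslp_hpa = 990, vmax_ms = 40))
  expect_equal(translation_speed(tr), rep(1e5 / 10800, 2), tolerance = 1e-3)
  # stationary track
  tr0 <- stormflux:::as_cyclone_track(data.frame(
    time = t0 + c(0, 3, 6) * 3600, lat = 20, lon = -60,
    mslp_hpa = 990, vmax_ms = 40))
  expect_equal(translation_speed(tr0), c(0, 0, 0))
  expect_error(translation_speed(tr0[1, ]), ">= 2")
  # planted constant-velocity storm: all points at the spec speed
  f <- recovery_forcing()
  pl <- attr(f, "truth")$tracks[[1]]
  sp <- translation_speed(pl)
  expect_true(all(abs(sp - sqrt(1.0^2 + 4.5^2)) < 0.1))
})

test_that("circle averages: uniform field, planted disc, and brute-force equivalence", {
  g <- sf_grid(c(-65, -55), c(20, 30), res = 0.5)
  fs <- make_test_fields(g, t0, list(c = 7.5), units = c(c = "1"))
  expect_equal(circle_average(fs, "c", -60, 25, t0), 7.5)
  # indicator of the 200-km disc averages to ~1 (discretization < 5%)
  fs2 <- make_test_fields(g, t0, list(ind = function(lon, lat)
    as.numeric(gc_dist_km(lon, lat, -60, 25) <= 200)), units = c(ind = "1"))
  expect_equal(circle_average(fs2, "ind", -60, 25, t0), 1, tolerance = 0.05)
  # oracle equivalence on 20 random circles vs explicit cell enumeration
  set.seed(9)
  fs3 <- make_test_fields(g, t0, list(
    x = matrix(rnorm(length(g$cell_lon)), 1)), units = c(x = "1"))
  for (k in 1:20) {
    lon <- runif(1, -64, -56); lat <- runif(1, 21, 29)
    r <- runif(1, 80, 400)
    idx <- which(gc_dist_km(g$cell_lon, g$cell_lat, lon, lat) <= r)
    want <- sum(fs3$vars$x[1, idx] * g$area_m2[idx]) / sum(g$area_m2[idx])
    expect_identical(circle_average(fs3, "x", lon, lat, t0, radius_km = r),
                     want)
  }
  expect_warning(circle_average(fs, "c", 100, -60, t0), "no grid cells")
})

test_that("wake deltas: constant field, planted step, and linearity", {
  g <- sf_grid(c(-65, -55), c(18, 34), res = 0.5)
  times <- seq(t0, by = 3600, length.out = 97)
  tr <- stormflux:::as_cyclone_track(data.frame(
    time = t0 + (40:52) * 3600, lat = seq(24, 26, length.out = 13),
    lon = -60, mslp_hpa = 980, vmax_ms = 55))
  fs_const <- make_test_fields(g, times, list(sst = 28), units = c(sst = "degC"))
  w0 <- wake_delta(fs_const, "sst", tr)
  expect_true(all(w0$delta == 0))
  # -2 degC step at each cell's passage time
  pass <- passage_time(tr, g$cell_lon, g$cell_lat)
  step <- sapply(seq_along(g$cell_lon), function(i)
    ifelse(times > pass[i], 26, 28))
  fs_step <- field_series(g, times, list(sst = step), units = c(sst = "degC"))
  ws <- wake_delta(fs_step, "sst", tr)
  expect_equal(ws$delta, rep(-2, nrow(tr)), tolerance = 1e-10)
  # linearity: wake_delta(a*X + b) = a * wake_delta(X)
  fs_lin <- field_series(g, times, list(sst = 3 * step + 11),
                         units = c(sst = "degC"))
  wl <- wake_delta(fs_lin, "sst", tr)
  expect_equal(wl$delta, 3 * ws$delta, tolerance = 1e-10)
  # insufficient coverage yields NA for that point
  tr_edge <- stormflux:::as_cyclone_track(data.frame(
    time = t0 + c(4, 8) * 3600, lat = 25, lon = -60,
    mslp_hpa = 980, vmax_ms = 55))
  we <- wake_delta(fs_const, "sst", tr_edge)
  expect_true(is.na(we$delta[1]))
})

test_that("along-track diagrams reference anomalies to before the passage", {
  g <- sf_grid(c(-65, -55), c(18, 34), res = 0.5)
  times <- seq(t0, by = 3600, length.out = 97)
  tr <- stormflux:::as_cyclone_track(data.frame(
    time = t0 + (40:52) * 3600, lat = seq(24, 26, length.out = 13),
    lon = -60, mslp_hpa = 980, vmax_ms = 55))
  fs_const <- make_test_fields(g, times, list(sst = 28), units = c(sst = "degC"))
  a0 <- along_track_diagram(fs_const, "sst", tr, anomaly = "ref")
  expect_lt(max(abs(a0$values)), 1e-9)
  pass <- passage_time(tr, g$cell_lon, g$cell_lat)
  step <- sapply(seq_along(g$cell_lon), function(i)
    ifelse(times > pass[i], 26, 28))
  fs_step <- field_series(g, times, list(sst = step), units = c(sst = "degC"))
  as_ <- along_track_diagram(fs_step, "sst", tr, anomaly = "ref")
  expect_equal(as_$values[, ncol(as_$values)], rep(-2, nrow(tr)),
               tolerance = 1e-10)
  expect_identical(as_$point_lat, tr$lat)
})

test_that("fold-increase arithmetic against a constructed flux series", {
  g <- sf_grid(c(-62, -58), c(23, 27), res = 0.5)
  times <- seq(t0, by = 3600, length.out = 73)
  flux <- matrix(1, length(times), length(g$cell_lon))
  flux[times >= t0 + 48 * 3600, ] <- 30
  fs <- field_series(g, times, list(fco2 = flux),
                     units = c(fco2 = "mmolC m-2 day-1"),
                     positive = c(fco2 = "up"))
  tr <- stormflux:::as_cyclone_track(data.frame(
    time = t0 + c(50, 53) * 3600, lat = c(24.7, 25.3), lon = -60,
    mslp_hpa = 980, vmax_ms = 55))
  out <- fold_increase(fs, "fco2", tr, c(t0, t0 + 24 * 3600))
  expect_equal(out$fold, c(30, 30))
  # passage equal to baseline -> 1
  fs1 <- field_series(g, times, list(fco2 = matrix(2, length(times),
                                                   length(g$cell_lon))),
                      units = c(fco2 = "mmolC m-2 day-1"))
  expect_equal(fold_increase(fs1, "fco2", tr, c(t0, t0 + 24 * 3600))$fold,
               c(1, 1))
  expect_error(fold_increase(fs, "fco2", tr,
                             c(t0 + 49 * 3600, t0 + 60 * 3600)), "disjoint")
})

test_that("fold-increase under a quadratic transfer law equals the wind ratio squared", {
  # flux scaled by k_w(u) with fixed disequilibrium: analytic (u1/u0)^2
  g <- sf_grid(c(-62, -58), c(23, 27), res = 0.5)
  times <- seq(t0, by = 3600, length.out = 49)
  u <- ifelse(times >= t0 + 24 * 3600, 24, 6)
  kw <- gas_transfer_velocity(u, 25)
  flux <- matrix(kw * co2_solubility(25, 35) * 20 * 1000 * 86400,
                 length(times), length(g$cell_lon))
  fs <- field_series(g, times, list(fco2 = flux),
                     units = c(fco2 = "mmolC m-2 day-1"))
  tr <- stormflux:::as_cyclone_track(data.frame(
    time = t0 + c(30, 33) * 3600, lat = c(24.7, 25.3), lon = -60,
    mslp_hpa = 980, vmax_ms = 55))
  out <- fold_increase(fs, "fco2", tr, c(t0, t0 + 23 * 3600))
  expect_equal(out$fold, rep((24 / 6)^2, 2), tolerance = 1e-10)
})

test_that("track-region carbon integrals: hand arithmetic, sign, and additivity", {
  # uniform 10 mmolC m-2 day-1 over ~1e11 m2 for 10 days -> ~0.12 TgC
  g <- sf_grid(c(-62, -58), c(23, 27), res = 0.5)
  times <- seq(t0, by = 3600 * 6, length.out = 41)  # 10 days
  fs <- make_test_fields(g, times, list(fco2 = 10),
                         units = c(fco2 = "mmolC m-2 day-1"))
  tr <- stormflux:::as_cyclone_track(data.frame(
    time = times, lat = 25, lon = -60, mslp_hpa = 980, vmax_ms = 55))
  out <- integrate_track_region(fs, "fco2", tr, radius_km = 200,
                                window = c(times[1], times[40]))
  hand <- 10 * out$footprint_area_m2 * 10 * 12.011e-3  # g
  expect_equal(out$total_g, hand, tolerance = 1e-9)
  expect_gt(out$footprint_area_m2, 5e10)
  # zero flux integrates to zero; negative flux keeps its sign
  fs0 <- make_test_fields(g, times, list(fco2 = 0),
                          units = c(fco2 = "mmolC m-2 day-1"))
  expect_equal(integrate_track_region(fs0, "fco2", tr)$total_tgc, 0)
  fsn <- make_test_fields(g, times, list(fco2 = -4),
                          units = c(fco2 = "mmolC m-2 day-1"))
  expect_lt(integrate_track_region(fsn, "fco2", tr)$total_tgc, 0)
  # disjoint windows sum exactly to the full-window integral
  mid <- times[21]
  full <- integrate_track_region(fs, "fco2", tr)
  a <- integrate_track_region(fs, "fco2", tr, window = c(times[1], mid))
  b <- integrate_track_region(fs, "fco2", tr,
                              window = c(mid + 1, times[length(times)]))
  expect_equal(a$total_g + b$total_g, full$total_g, tolerance = 1e-12)
  # unitless flux input is rejected
  fsu <- make_test_fields(g, times, list(fco2 = 10))
  expect_error(integrate_track_region(fsu, "fco2", tr), "units")
})

test_that("carbon integral ratios reproduce printed-number arithmetic", {
  expect_equal(carbon_integral_ratio(1.25, 4.8), 26.0417, tolerance = 1e-4)
  expect_lt(carbon_integral_ratio(1.25, -63.8), 2)
  expect_error(carbon_integral_ratio(1, 0), "denominator")
})

test_that("cumulative fluxes ramp linearly for constant flux and stay zero for none", {
  g <- sf_grid(c(-62, -58), c(23, 27), res = 0.5)
  times <- seq(t0, by = 3600, length.out = 97)
  tr <- stormflux:::as_cyclone_track(data.frame(
    time = t0 + c(48, 51) * 3600, lat = c(24.7, 25.3), lon = -60,
    mslp_hpa = 980, vmax_ms = 55))
  fs <- make_test_fields(g, times, list(fco2 = 12),
                         units = c(fco2 = "mmolC m-2 day-1"))
  cum <- cumulative_flux(along_track_diagram(fs, "fco2", tr))
  # slope 12 mmol/m2 per day after the start offset
  i_live <- which(times >= tr$time[1] - 24 * 3600)
  expect_equal(cum[1, i_live[25]] - cum[1, i_live[1]], 12, tolerance = 1e-9)
  expect_true(all(cum[1, times < tr$time[1] - 24 * 3600] == 0))
  fs0 <- make_test_fields(g, times, list(fco2 = 0),
                          units = c(fco2 = "mmolC m-2 day-1"))
  expect_true(all(cumulative_flux(along_track_diagram(fs0, "fco2", tr)) == 0))
})

test_that("mixed-layer depth closed forms on a linear density profile", {
  z <- seq(0, 50, by = 0.5)
  pr <- column_profile(z, density = 1025 + 0.01 * z)
  expect_equal(mixed_layer_depth(pr, 0.03), 3, tolerance = 1e-9)
  expect_equal(mixed_layer_depth(pr, 0.125), 12.5, tolerance = 1e-9)
  # homogeneous column: bottom depth
  prh <- column_profile(z, density = rep(1025, length(z)))
  expect_equal(mixed_layer_depth(prh, 0.03), 50)
  # monotone thresholds
  expect_gte(mixed_layer_depth(pr, 0.125), mixed_layer_depth(pr, 0.03))
  expect_error(column_profile(c(10, 5), density = c(1025, 1026)),
               "increasing")
})

test_that("Brunt-Vaisala frequency from density gradients, with sign", {
  z <- seq(0, 100, by = 2)
  pr <- column_profile(z, density = 1025 + 0.01 * z)
  n2 <- brunt_vaisala(pr, rho_ref = 1025)
  expect_equal(n2, rep(9.81 * 0.01 / 1025, length(z)), tolerance = 1e-9)
  expect_equal(max(abs(brunt_vaisala(
    column_profile(z, density = rep(1026, length(z)))))), 0)
  inv <- brunt_vaisala(column_profile(z, density = 1026 - 0.01 * z))
  expect_true(all(inv < 0))
})

test_that("inertial period matches rotation-rate arithmetic", {
  expect_equal(inertial_period(90), 11.97, tolerance = 0.01)
  expect_equal(inertial_period(30), 23.93, tolerance = 0.01)
  expect_equal(inertial_period(-30), 23.93, tolerance = 0.01)
  expect_equal(inertial_period(34.2), 21.3, tolerance = 0.15)
  expect_identical(inertial_period(0), Inf)
})

test_that("slab column profiles feed the mixed-layer and stratification diagnostics", {
  d <- default_run()
  tr <- d$tracks[[1]]
  i <- which.max(tr$vmax_ms)
  cell <- stormflux:::circle_cells(d$run$fields$grid, tr$lon[i], tr$lat[i], 60)[1]
  pr_before <- slab_column_profile(d$run, cell, tr$time[i] - 48 * 3600)
  pr_after <- slab_column_profile(d$run, cell, tr$time[i] + 24 * 3600)
  expect_gt(mixed_layer_depth(pr_after, 0.125),
            mixed_layer_depth(pr_before, 0.125))
  expect_true(all(brunt_vaisala(pr_after)[-1] >= 0))
})
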