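test_that("no forcing and no exchange leaves every state variable constant", {
  run <- run_slab_ocean(calm_forcing(24), inert_params(),
                        keep_terms = c("sst", "dic"))
  for (v in c("sst", "sss", "dic", "alk", "nutrient", "phyto", "detritus",
              "mld")) {
    m <- fs_var(run$fields, v)
    expect_equal(max(abs(sweep(m, 2, m[1, ]))), 0,
                 info = v, tolerance = 1e-12)
  }
  for (tr in c("sst", "dic")) {
    bt <- emit_budget_terms(run, tr)
    expect_true(all(unlist(bt[c("tendency", "vdiff", "surface", "bio")]) == 0))
  }
})

test_that("identical seed and configuration give bit-identical runs", {
  s1 <- small_scenario(seed = 5)
  s2 <- small_scenario(seed = 5)
  expect_identical(s1$forcing$vars, s2$forcing$vars)
  r1 <- run_slab_ocean(s1$forcing, keep_terms = NULL)
  r2 <- run_slab_ocean(s2$forcing, keep_terms = NULL)
  expect_identical(r1$fields$vars, r2$fields$vars)
  s3 <- small_scenario(seed = 6)
  expect_false(identical(s1$forcing$vars$mslp, s3$forcing$vars$mslp))
})

test_that("emitted budget terms close the tendency to integrator tolerance", {
  d <- default_run()
  for (tr in c("sst", "dic")) {
    bt <- emit_budget_terms(d$run, tr)
    res <- budget_residual(bt)
    expect_lt(res$normalized, 1e-6)
  }
  expect_error(emit_budget_terms(d$run, "alk"), "unavailable")
})

test_that("with gas exchange only, the DIC surface term equals -F/h and others vanish", {
  # suppress entrainment with a huge buoyancy jump and tiny efficiency
  p <- inert_params(entrain_eff = 1e-12, delta_b0 = 10)
  run <- run_slab_ocean(calm_forcing(24, background = 8), p,
                        keep_terms = c("dic"))
  bt <- emit_budget_terms(run, "dic")
  f_mol <- fs_var(run$fields, "fco2") / (1000 * 86400)  # back to mol m-2 s-1
  h <- fs_var(run$fields, "mld")
  nt <- nrow(f_mol)
  expected <- -f_mol[-nt, , drop = FALSE] * 1e6 / (1025 * h[-nt, , drop = FALSE])
  expect_equal(bt$surface, expected, tolerance = 1e-12)
  expect_lt(max(abs(bt$vdiff)), 1e-15)
  expect_true(all(bt$bio == 0))
})

test_that("category-4 forcing cools the wake 1.0-2.5 degC, shifted to the right", {
  d <- default_run()
  run <- d$run
  for (k in seq_along(d$tracks)) {
    tr <- d$tracks[[k]]
    w <- wake_delta(run$fields, "sst", tr)
    intense <- which(tr$vmax_ms >= 58)
    if (k == 1) {
      # fresh pre-storm background: the canonical 1.0-2.5 degC cold wake
      expect_true(all(w$delta[intense] <= -1.0 & w$delta[intense] >= -2.5))
    } else {
      # the second storm runs over the first one's wake; its own
      # after-minus-before signal is weakened but still a clear cooling
      expect_true(all(w$delta[intense] <= -0.5))
      expect_gte(min(w$delta[intense]), -2.5)
    }
    # rightward shift: per-storm right-minus-left 200-km semicircle dSST
    # composite < 0 (more cooling on the right of the track)
    rml <- c()
    for (i in which(tr$vmax_ms >= 50)) {
      j1 <- max(1, i - 3); j2 <- min(nrow(tr), i + 3)
      head_vec <- c((tr$lon[j2] - tr$lon[j1]) * cos(tr$lat[i] * pi / 180),
                    tr$lat[j2] - tr$lat[j1])
      if (sum(head_vec^2) == 0) next
      rhat <- c(head_vec[2], -head_vec[1]) / sqrt(sum(head_vec^2))
      off <- stormflux:::local_offsets_km(run$fields$grid$cell_lon,
                                          run$fields$grid$cell_lat,
                                          tr$lon[i], tr$lat[i])
      r <- sqrt(off[, 1]^2 + off[, 2]^2)
      side <- off[, 1] * rhat[1] + off[, 2] * rhat[2]
      ti_b <- fs_time_index(run$fields, tr$time[i] - 24 * 3600)
      ti_a <- fs_time_index(run$fields, tr$time[i] + 24 * 3600)
      if (is.na(ti_b) || is.na(ti_a)) next
      dsst <- fs_var(run$fields, "sst")[ti_a, ] - fs_var(run$fields, "sst")[ti_b, ]
      right <- r <= 200 & side > 0; left <- r <= 200 & side < 0
      if (any(right) && any(left))
        rml <- c(rml, mean(dsst[right]) - mean(dsst[left]))
    }
    expect_lt(mean(rml), 0)
    expect_gt(mean(rml < 0), 0.5)
  }
})

test_that("halving the translation speed does not decrease wake cooling", {
  sf <- small_scenario(translation = c(0, 5.2), days = 9)
  ss <- small_scenario(translation = c(0, 2.6), days = 9)
  rf <- run_slab_ocean(sf$forcing, keep_terms = NULL)
  rs <- run_slab_ocean(ss$forcing, keep_terms = NULL)
  cool <- function(run, forcing) {
    tr <- attr(forcing, "truth")$tracks[[1]]
    w <- wake_delta(run$fields, "sst", tr)
    mean(w$delta[tr$vmax_ms >= 58], na.rm = TRUE)
  }
  expect_lte(cool(rs, ss$forcing), cool(rf, sf$forcing))
})

test_that("the phytoplankton bloom follows the nutrient entrainment pulse within three weeks", {
  d <- default_run()
  run <- d$run
  tr <- d$tracks[[1]]
  i <- which.max(tr$vmax_ms)
  cells <- stormflux:::circle_cells(run$fields$grid, tr$lon[i], tr$lat[i], 200)
  we <- rowMeans(fs_var(run$fields, "we")[, cells])
  phy <- rowMeans(fs_var(run$fields, "phyto")[, cells])
  t_pulse <- run$fields$time[which.max(we)]
  t_bloom <- run$fields$time[which.max(phy)]
  lag_days <- as.numeric(difftime(t_bloom, t_pulse, units = "days"))
  expect_gte(lag_days, 0)
  expect_lte(lag_days, 21)
  # the storm drives a greater-than-tenfold local increase in NPP
  npp <- rowMeans(fs_var(run$fields, "npp")[, cells])
  expect_gt(max(npp) / mean(npp[1:48]), 10)
})

test_that("mixed-layer heat content change equals integrated surface plus entrainment heating", {
  sc <- small_scenario(days = 7)
  run <- run_slab_ocean(sc$forcing, slab_params(restrat_days = 1e9,
                                                biology = FALSE),
                        keep_terms = c("sst"))
  bt <- emit_budget_terms(run, "sst")
  h <- fs_var(run$fields, "mld"); sst <- fs_var(run$fields, "sst")
  we <- fs_var(run$fields, "we")
  nt <- nrow(h); dt_s <- run$dt_s
  # discrete conservation: delta(h T) = h dT + T dh + dh dT per step
  dH <- h[nt, ] * sst[nt, ] - h[1, ] * sst[1, ]
  d_sst <- sst[-1, , drop = FALSE] - sst[-nt, , drop = FALSE]
  dh <- we[-nt, , drop = FALSE] * dt_s
  rhs <- colSums((bt$surface + bt$vdiff) * h[-nt, , drop = FALSE] * dt_s) +
    colSums(sst[-nt, , drop = FALSE] * dh) + colSums(dh * d_sst)
  expect_lt(max(abs(dH - rhs)) / max(abs(dH)), 1e-3)
})

test_that("with biology off, the column DIC inventory change equals minus the integrated flux", {
  sc <- small_scenario(days = 7)
  p <- slab_params(restrat_days = 1e9, biology = FALSE)
  run <- run_slab_ocean(sc$forcing, p, keep_terms = c("dic"))
  h <- fs_var(run$fields, "mld"); dic <- fs_var(run$fields, "dic")
  we <- fs_var(run$fields, "we")
  f_mol <- fs_var(run$fields, "fco2") / (1000 * 86400)
  nt <- nrow(h); dt_s <- run$dt_s
  dic_base <- stormflux:::deep_value(p$dic0, p$grad_dic_m, h, p$h0_m,
                                     p$grad_extent_m)
  # mixed-layer gain minus what entrainment imported = -integral F dt
  # (discrete bookkeeping includes the dh*dDIC cross term of the product)
  d_ml <- (h[nt, ] * dic[nt, ] - h[1, ] * dic[1, ]) * 1025 * 1e-6  # mol/m^2
  dh <- we[-nt, , drop = FALSE] * dt_s
  d_dic <- dic[-1, , drop = FALSE] - dic[-nt, , drop = FALSE]
  imported <- colSums(dh * dic_base[-nt, , drop = FALSE] + dh * d_dic) *
    1025 * 1e-6
  int_f <- colSums(f_mol[-nt, , drop = FALSE] * dt_s)
  expect_lt(max(abs(d_ml - imported + int_f)) / max(abs(int_f)), 1e-3)
})

test_that("the integrator rejects a non-uniform forcing time axis", {
  g <- sf_grid(c(-52, -50), c(24, 26), res = 0.5)
  t0 <- as.POSIXct("2020-09-01 00:00:00", tz = "UTC")
  expect_error(field_series(g, t0 + c(0, 3600, 9000),
                            list(mslp = matrix(1012, 3, length(g$cell_lon)))),
               "uniform")
})
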