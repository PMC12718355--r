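#' Detect tropical-cyclone candidate points in one snapshot
#'
#' Iteratively selects the global MSLP minimum; if below the candidate
#' threshold the cell is stored as a candidate and all cells within the
#' mask radius are removed, and the search repeats until every remaining
#' cell exceeds the threshold. The candidate's wind is the maximum 10-m
#' wind within `wind_radius_km` of the pressure minimum (wind maxima sit
#' at the radius of maximum wind, not at the centre).
#'
#' @param mslp,wind numeric vectors over grid cells (hPa, m/s), one time.
#' @param grid the shared [sf_grid()].
#' @param p_threshold candidate threshold (hPa); strict `<` rule.
#' @param mask_radius_km masking radius around each stored candidate (km).
#' @param wind_radius_km neighborhood for wind attribution (km).
#' @return data.frame with columns `lat`, `lon`, `mslp_hpa`, `vmax_ms`.
#' @export
detect_candidates <- function(mslp, wind, grid, p_threshold = 1010,
                              mask_radius_km = 800, wind_radius_km = 200) {
  if (length(mslp) != length(grid$cell_lon) || length(wind) != length(mslp))
    stop("mslp/wind must match the grid (one value per cell)")
  active <- !is.na(mslp)
  out <- list()
  repeat {
    if (!any(active)) break
    i <- which(active)[which.min(mslp[active])]
    if (mslp[i] >= p_threshold) break
    d <- gc_dist_km(grid$cell_lon, grid$cell_lat,
                    grid$cell_lon[i], grid$cell_lat[i])
    vmax <- max(wind[d <= wind_radius_km & !is.na(wind)], na.rm = TRUE)
    out[[length(out) + 1]] <- data.frame(
      lat = grid$cell_lat[i], lon = grid$cell_lon[i],
      mslp_hpa = mslp[i], vmax_ms = vmax)
    active[d <= mask_radius_km] <- FALSE
  }
  if (!length(out))
    return(data.frame(lat = numeric(), lon = numeric(),
                      mslp_hpa = numeric(), vmax_ms = numeric()))
  do.call(rbind, out)
}

#' Detect candidates across all times of a field series
#'
#' @param fs a `field_series` containing `mslp` (hPa) and `wind10` (m/s).
#' @inheritParams detect_candidates
#' @return data.frame with `time` (POSIXct) plus the per-snapshot columns.
#' @export
detect_candidates_series <- function(fs, p_threshold = 1010,
                                     mask_radius_km = 800,
                                     wind_radius_km = 200) {
  mslp <- fs_var(fs, "mslp"); wind <- fs_var(fs, "wind10")
  res <- lapply(seq_along(fs$time), function(ti) {
    cc <- detect_candidates(mslp[ti, ], wind[ti, ], fs$grid,
                            p_threshold, mask_radius_km, wind_radius_km)
    if (nrow(cc)) cc$time <- fs$time[ti]
    cc
  })
  res <- res[vapply(res, nrow, 1L) > 0]
  if (!length(res))
    return(data.frame(time = as.POSIXct(character(), tz = "UTC"),
                      lat = numeric(), lon = numeric(),
                      mslp_hpa = numeric(), vmax_ms = numeric()))
  out <- do.call(rbind, res)
  out[order(out$time, out$mslp_hpa), c("time", "lat", "lon", "mslp_hpa", "vmax_ms")]
}

#' Stitch candidate points into cyclone tracks
#'
#' Greedy track construction: the earliest unused hurricane-candidate point
#' inside the genesis latitude band starts a track; the track is extended
#' by the nearest-in-time candidate within the link radius and window
#' (ties at the same time step broken by lowest MSLP; the losing same-time
#' candidates are removed from the pool), until no extension qualifies.
#' Repeats until all candidate points are used or removed.
#'
#' @param candidates data.frame from [detect_candidates_series()].
#' @param wind_min minimum surface wind for a point to enter a track (m/s).
#' @param link_radius_km maximum spatial separation of consecutive points.
#' @param link_window_h maximum temporal separation of consecutive points.
#' @param genesis_band latitude band (degrees) in which tracks may start.
#' @param genesis_hemisphere `"both"` reads the band as absolute latitude;
#'   `"north"` restricts genesis to the northern hemisphere.
#' @return list of `cyclone_track` data.frames with columns `time`, `lat`,
#'   `lon`, `mslp_hpa`, `vmax_ms` and attributes `lifetime_h`, `lmi_ms`.
#' @export
stitch_tracks <- function(candidates, wind_min = 17, link_radius_km = 100,
                          link_window_h = 24, genesis_band = c(0, 35),
                          genesis_hemisphere = c("both", "north")) {
  genesis_hemisphere <- match.arg(genesis_hemisphere)
  cc <- candidates[candidates$vmax_ms >= wind_min, , drop = FALSE]
  if (!nrow(cc)) return(list())
  cc <- cc[order(cc$time, cc$mslp_hpa), , drop = FALSE]
  in_band <- if (genesis_hemisphere == "north")
    cc$lat >= genesis_band[1] & cc$lat <= genesis_band[2]
  else abs(cc$lat) >= genesis_band[1] & abs(cc$lat) <= genesis_band[2]
  used <- rep(FALSE, nrow(cc))
  tracks <- list()
  repeat {
    starts <- which(!used & in_band)
    if (!length(starts)) break
    s <- starts[1]  # earliest time; lowest MSLP among equals (pre-sorted)
    used[s] <- TRUE
    idx <- s
    repeat {
      head_i <- idx[length(idx)]
      dt_h <- as.numeric(difftime(cc$time, cc$time[head_i], units = "hours"))
      ok <- !used & dt_h > 0 & dt_h <= link_window_h
      if (!any(ok)) break
      dist <- rep(Inf, nrow(cc))
      dist[ok] <- gc_dist_km(cc$lon[ok], cc$lat[ok],
                             cc$lon[head_i], cc$lat[head_i])
      ok <- ok & dist <= link_radius_km
      if (!any(ok)) break
      # priority to points closer in time; same time step -> lowest MSLP
      tmin <- min(dt_h[ok])
      same_t <- which(ok & dt_h == tmin)
      pick <- same_t[which.min(cc$mslp_hpa[same_t])]
      used[same_t] <- TRUE  # losing same-time points are removed
      idx <- c(idx, pick)
    }
    tr <- cc[idx, c("time", "lat", "lon", "mslp_hpa", "vmax_ms"), drop = FALSE]
    rownames(tr) <- NULL
    tracks[[length(tracks) + 1]] <- as_cyclone_track(tr)
  }
  tracks
}

as_cyclone_track <- function(df) {
  stopifnot(all(c("time", "lat", "lon", "mslp_hpa", "vmax_ms") %in% names(df)))
  if (is.unsorted(df$time, strictly = FALSE)) df <- df[order(df$time), ]
  attr(df, "lifetime_h") <-
    as.numeric(difftime(df$time[nrow(df)], df$time[1], units = "hours"))
  attr(df, "lmi_ms") <- max(df$vmax_ms)
  class(df) <- c("cyclone_track", "data.frame")
  df
}

#' @export
print.cyclone_track <- function(x, ...) {
  cat(sprintf("<cyclone_track> %d points, lifetime %.1f h, LMI %.1f m/s (%s)\n",
              nrow(x), attr(x, "lifetime_h"), attr(x, "lmi_ms"),
              saffir_simpson_category(attr(x, "lmi_ms"))))
  print.data.frame(x, ...)
  invisible(x)
}

#' Track lifetime in hours
#' @param track a `cyclone_track`.
#' @return numeric hours between first and last point.
#' @export
track_lifetime_h <- function(track) attr(track, "lifetime_h")

#' Lifetime-maximum intensity (m/s)
#' @param track a `cyclone_track`.
#' @return peak along-track wind speed.
#' @export
track_lmi_ms <- function(track) attr(track, "lmi_ms")

#' Retain only long-lived hurricane-strength tracks
#'
#' A track is retained iff its lifetime strictly exceeds `min_lifetime_h`
#' AND its lifetime-maximum intensity strictly exceeds `min_lmi_ms`
#' (hurricane strength). Less intense tropical storms and depressions are
#' dropped.
#'
#' @param tracks list of `cyclone_track`s.
#' @param min_lifetime_h minimum lifetime, hours (strict `>`).
#' @param min_lmi_ms minimum lifetime-maximum intensity, m/s (strict `>`).
#' @return filtered list.
#' @export
filter_tracks <- function(tracks, min_lifetime_h = 24, min_lmi_ms = 33) {
  Filter(function(tr) track_lifetime_h(tr) > min_lifetime_h &&
           track_lmi_ms(tr) > min_lmi_ms, tracks)
}

#' Saffir-Simpson category from sustained surface wind
#'
#' Thresholds (m/s): tropical storm < 33, category 1 >= 33, 2 >= 43,
#' 3 >= 50, 4 >= 58, 5 >= 70.
#'
#' @param wind_ms sustained surface wind speed (m/s), >= 0.
#' @return character vector of labels (`"TS"`, `"cat1"` .. `"cat5"`).
#' @export
saffir_simpson_category <- function(wind_ms) {
  if (any(wind_ms < 0, na.rm = TRUE)) stop("wind_ms must be >= 0")
  cut(wind_ms, breaks = c(-Inf, 33, 43, 50, 58, 70, Inf), right = FALSE,
      labels = c("TS", "cat1", "cat2", "cat3", "cat4", "cat5")) |>
    as.character()
}

#' Run the full tracker on a field series
#'
#' Convenience wrapper: candidate detection, stitching and filtering with
#' the standard thresholds (1,010 hPa, 800 km, 17 m/s, 100 km, 24 h,
#' genesis 0-35 degrees, lifetime > 24 h, LMI > 33 m/s).
#'
#' @param fs `field_series` with `mslp` and `wind10`.
#' @param ... overrides passed on to the stage functions by name
#'   (`p_threshold`, `mask_radius_km`, `wind_radius_km`, `wind_min`,
#'   `link_radius_km`, `link_window_h`, `genesis_band`,
#'   `genesis_hemisphere`, `min_lifetime_h`, `min_lmi_ms`).
#' @return list of `cyclone_track`s.
#' @export
track_cyclones <- function(fs, ...) {
  opts <- list(...)
  arg <- function(name, default) if (name %in% names(opts)) opts[[name]] else default
  cand <- detect_candidates_series(
    fs, p_threshold = arg("p_threshold", 1010),
    mask_radius_km = arg("mask_radius_km", 800),
    wind_radius_km = arg("wind_radius_km", 200))
  tracks <- stitch_tracks(
    cand, wind_min = arg("wind_min", 17),
    link_radius_km = arg("link_radius_km", 100),
    link_window_h = arg("link_window_h", 24),
    genesis_band = arg("genesis_band", c(0, 35)),
    genesis_hemisphere = arg("genesis_hemisphere", "both"))
  filter_tracks(tracks, min_lifetime_h = arg("min_lifetime_h", 24),
                min_lmi_ms = arg("min_lmi_ms", 33))
}
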