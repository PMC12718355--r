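#' Storm translation speed along a track
#'
#' Centered great-circle differences over the native point spacing
#' (one-sided at the endpoints).
#'
#' @param track a `cyclone_track` (>= 2 points).
#' @return numeric vector, m/s, one value per track point.
#' @export
translation_speed <- function(track) {
  n <- nrow(track)
  if (n < 2) stop("translation speed needs >= 2 track points")
  sp <- numeric(n)
  for (i in seq_len(n)) {
    j1 <- max(1, i - 1); j2 <- min(n, i + 1)
    d_km <- gc_dist_km(track$lon[j1], track$lat[j1], track$lon[j2], track$lat[j2])
    dt_s <- as.numeric(difftime(track$time[j2], track$time[j1], units = "secs"))
    sp[i] <- d_km * 1000 / dt_s
  }
  sp
}

#' Area-weighted mean of a field over a great-circle disc
#'
#' Cell-area-weighted mean over cells whose centers lie within `radius_km`
#' of the given location -- the moving-circle composite primitive used by
#' all along-track diagnostics.
#'
#' @param fs a `field_series`.
#' @param var variable name.
#' @param lon,lat circle center (deg).
#' @param time POSIXct; nearest time step is used.
#' @param radius_km circle radius (km).
#' @param area_weighted area weighting (default) or uniform weights.
#' @return scalar mean; NA with a warning when the circle contains no cell.
#' @export
circle_average <- function(fs, var, lon, lat, time, radius_km = 200,
                           area_weighted = TRUE) {
  ti <- fs_time_index(fs, time)
  idx <- circle_cells(fs$grid, lon, lat, radius_km)
  if (!length(idx)) {
    warning(sprintf("no grid cells within %g km of (%.2f, %.2f)",
                    radius_km, lon, lat))
    return(NA_real_)
  }
  vals <- fs_var(fs, var)[ti, idx]
  w <- if (area_weighted) fs$grid$area_m2[idx] else rep(1, length(idx))
  ok <- !is.na(vals)
  if (!any(ok)) return(NA_real_)
  sum(vals[ok] * w[ok]) / sum(w[ok])
}

# indices of grid cells whose centers fall within radius_km of (lon, lat)
circle_cells <- function(grid, lon, lat, radius_km) {
  # cheap bounding-box prefilter, then exact great-circle test
  dlat <- radius_km / 111.2
  cand <- which(abs(grid$cell_lat - lat) <= dlat + grid$res)
  if (!length(cand)) return(integer())
  d <- gc_dist_km(grid$cell_lon[cand], grid$cell_lat[cand], lon, lat)
  cand[d <= radius_km]
}

#' Per-cell (or per-point) time of closest approach of a track
#'
#' The "passage time" convention used for wake deltas, anomaly references
#' and decomposition reference states: the track time at which the storm
#' centre is closest to the given location.
#'
#' @param track a `cyclone_track`.
#' @param lon,lat query location(s), recycled together.
#' @return POSIXct vector of passage times.
#' @export
passage_time <- function(track, lon, lat) {
  n <- max(length(lon), length(lat))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n)
  out <- track$time[rep(1L, n)]
  for (i in seq_len(n)) {
    d <- gc_dist_km(track$lon, track$lat, lon[i], lat[i])
    out[i] <- track$time[which.min(d)]
  }
  out
}

#' Along-track wake delta: after-minus-before circle averages
#'
#' For each track point, the circle-averaged field `lag_h` hours after the
#' passage minus `lead_h` hours before it, with the circle fixed at the
#' track point. The standard cold-wake composite is SST, 24 h after minus
#' 24 h before, over a 200-km circle.
#'
#' @param fs a `field_series`.
#' @param var variable name.
#' @param track a `cyclone_track`.
#' @param lead_h hours before passage for the reference value.
#' @param lag_h hours after passage for the "after" value.
#' @param radius_km circle radius (km).
#' @return data.frame `time`, `lat`, `lon`, `before`, `after`, `delta`
#'   (NA where the series does not cover the window).
#' @export
wake_delta <- function(fs, var, track, lead_h = 24, lag_h = 24,
                       radius_km = 200) {
  dt_h <- fs_dt_hours(fs)
  res <- lapply(seq_len(nrow(track)), function(i) {
    t0 <- track$time[i]
    tb <- t0 - lead_h * 3600; ta <- t0 + lag_h * 3600
    cover <- tb >= fs$time[1] - dt_h * 1800 &
      ta <= fs$time[length(fs$time)] + dt_h * 1800
    if (!cover) return(data.frame(before = NA_real_, after = NA_real_))
    data.frame(
      before = circle_average(fs, var, track$lon[i], track$lat[i], tb, radius_km),
      after = circle_average(fs, var, track$lon[i], track$lat[i], ta, radius_km))
  })
  res <- do.call(rbind, res)
  data.frame(time = track$time, lat = track$lat, lon = track$lon,
             before = res$before, after = res$after,
             delta = res$after - res$before)
}

#' Along-track time diagram of moving-circle averages
#'
#' For every track point, the full-period time series of the field averaged
#' over a circle fixed at that point, optionally as an anomaly with respect
#' to the value `anomaly_ref_offset_h` hours before the local passage time.
#' Rows are annotated with the track-point latitudes (the natural y axis of
#' along-track diagrams).
#'
#' @inheritParams wake_delta
#' @param anomaly one of `"none"` or `"ref"` (subtract the pre-passage
#'   reference value).
#' @param anomaly_ref_offset_h hours before passage defining the reference.
#' @return object of class `along_track_series`: list with `values`
#'   (track-point x time matrix), `time`, `point_lat`, `point_lon`,
#'   `passage` (POSIXct per point), `radius_km`, `var`.
#' @export
along_track_diagram <- function(fs, var, track, radius_km = 200,
                                anomaly = c("none", "ref"),
                                anomaly_ref_offset_h = 12) {
  anomaly <- match.arg(anomaly)
  nt <- length(fs$time); np <- nrow(track)
  vals <- matrix(NA_real_, np, nt)
  m <- fs_var(fs, var)
  for (i in seq_len(np)) {
    idx <- circle_cells(fs$grid, track$lon[i], track$lat[i], radius_km)
    if (!length(idx)) next
    w <- fs$grid$area_m2[idx]
    vals[i, ] <- (m[, idx, drop = FALSE] %*% w) / sum(w)
  }
  pass <- track$time
  if (anomaly == "ref") {
    for (i in seq_len(np)) {
      ri <- fs_time_index(fs, pass[i] - anomaly_ref_offset_h * 3600)
      vals[i, ] <- vals[i, ] - vals[i, ri]
    }
  }
  structure(list(values = vals, time = fs$time, point_lat = track$lat,
                 point_lon = track$lon, passage = pass,
                 radius_km = radius_km, var = var, anomaly = anomaly),
            class = "along_track_series")
}

#' @export
print.along_track_series <- function(x, ...) {
  cat(sprintf(
    "<along_track_series> %s (%s), %d track points x %d times, %g-km circle\n",
    x$var, if (x$anomaly == "ref") "anomaly" else "absolute",
    nrow(x$values), ncol(x$values), x$radius_km))
  invisible(x)
}

#' Fold-increase of the along-track flux over a baseline window
#'
#' Per track point: |circle-mean flux at passage| divided by the time mean
#' of |circle-mean flux| over the baseline window at the same circle.
#' Absolute values in the baseline keep the ratio positive where baseline
#' fluxes change sign.
#'
#' @inheritParams wake_delta
#' @param baseline_window POSIXct length-2, disjoint from the passage.
#' @return data.frame `time`, `lat`, `lon`, `passage_flux`,
#'   `baseline_flux`, `fold` (NA + warning where the baseline mean is 0).
#' @export
fold_increase <- function(fs, var, track, baseline_window, radius_km = 200) {
  bw <- sort(baseline_window)
  if (any(track$time >= bw[1] & track$time <= bw[2]))
    stop("baseline window must be disjoint from the track passage times")
  sel <- fs$time >= bw[1] & fs$time <= bw[2]
  if (!any(sel)) stop("baseline window does not intersect the field series")
  m <- fs_var(fs, var)
  out <- data.frame(time = track$time, lat = track$lat, lon = track$lon,
                    passage_flux = NA_real_, baseline_flux = NA_real_,
                    fold = NA_real_)
  for (i in seq_len(nrow(track))) {
    idx <- circle_cells(fs$grid, track$lon[i], track$lat[i], radius_km)
    if (!length(idx)) next
    w <- fs$grid$area_m2[idx]
    series <- (m[, idx, drop = FALSE] %*% w) / sum(w)
    ti <- fs_time_index(fs, track$time[i])
    base <- mean(abs(series[sel]))
    out$passage_flux[i] <- series[ti]
    out$baseline_flux[i] <- base
    if (base == 0) warning("baseline mean flux is 0; fold-increase undefined")
    else out$fold[i] <- abs(series[ti]) / base
  }
  out
}

#' Time-and-area integral of a flux over the moving track region
#'
#' Sums flux x cell area x time step over all cells within `radius_km` of
#' the storm centre at each time step of the window, converting
#' mmolC m^-2 day^-1 to teragrams of carbon (12.011 g/mol, 1 TgC = 1e12 g).
#' Sign is preserved (negative = net uptake). The footprint is the union of
#' all circles.
#'
#' @param fs a `field_series` whose `var` is a carbon flux in
#'   mmolC m^-2 day^-1, positive upward.
#' @param var flux variable name.
#' @param track a `cyclone_track`.
#' @param radius_km circle radius (km).
#' @param window POSIXct length-2 integration window (default: the track's
#'   life time).
#' @return list with `total_tgc`, `total_g`, `footprint_cells` (cell
#'   indices of the union footprint), `footprint_area_m2`.
#' @export
integrate_track_region <- function(fs, var, track, radius_km = 200,
                                   window = NULL) {
  if (is.na(fs$units[[var]]) || !grepl("mmol", fs$units[[var]]))
    stop(sprintf("flux variable '%s' must carry mmolC m-2 day-1 units (got '%s')",
                 var, fs$units[[var]]))
  if (is.null(window)) window <- range(track$time)
  window <- sort(window)
  dt_day <- fs_dt_hours(fs) / 24
  m <- fs_var(fs, var)
  sel_t <- which(fs$time >= window[1] & fs$time <= window[2])
  total_mmol <- 0
  foot <- integer()
  for (ti in sel_t) {
    # storm centre at this time: nearest track point within the link of time
    dt_tr <- abs(as.numeric(difftime(track$time, fs$time[ti], units = "hours")))
    i <- which.min(dt_tr)
    if (dt_tr[i] > fs_dt_hours(fs)) next  # storm not alive at this time
    idx <- circle_cells(fs$grid, track$lon[i], track$lat[i], radius_km)
    if (!length(idx)) next
    vals <- m[ti, idx]
    ok <- !is.na(vals)
    total_mmol <- total_mmol +
      sum(vals[ok] * fs$grid$area_m2[idx][ok]) * dt_day
    foot <- union(foot, idx)
  }
  total_g <- total_mmol * 1e-3 * 12.011
  list(total_tgc = total_g / 1e12, total_g = total_g,
       footprint_cells = foot,
       footprint_area_m2 = sum(fs$grid$area_m2[foot]))
}

#' Ratio of two track-region carbon integrals, in percent
#'
#' Utility for comparing a storm-passage carbon integral against a seasonal
#' or annual one: 100 * |a| / |b|.
#'
#' @param a_tgc,b_tgc carbon integrals (TgC, any sign).
#' @return percentage |a/b| * 100.
#' @export
carbon_integral_ratio <- function(a_tgc, b_tgc) {
  if (any(b_tgc == 0)) stop("denominator integral is 0")
  100 * abs(a_tgc / b_tgc)
}

#' Cumulative along-track flux from a pre-passage start
#'
#' Running time integral of a per-point circle-averaged flux series,
#' starting `start_offset_h` hours relative to the local passage (default
#' -24 h, i.e. 24 h before). With flux in mmolC m^-2 day^-1 the cumulative
#' series is in mmolC m^-2.
#'
#' @param ats an `along_track_series` (absolute values, not anomalies).
#' @param start_offset_h start of accumulation relative to passage (hours,
#'   negative = before).
#' @return matrix like `ats$values`: 0 before the start, then the running
#'   integral.
#' @export
cumulative_flux <- function(ats, start_offset_h = -24) {
  stopifnot(inherits(ats, "along_track_series"))
  dt_day <- as.numeric(difftime(ats$time[2], ats$time[1], units = "days"))
  out <- ats$values * 0
  for (i in seq_len(nrow(out))) {
    t_start <- ats$passage[i] + start_offset_h * 3600
    if (t_start < ats$time[1])
      stop("series does not cover the accumulation start offset")
    live <- ats$time >= t_start
    cum <- cumsum(ifelse(is.na(ats$values[i, live]), 0,
                         ats$values[i, live])) * dt_day
    out[i, live] <- cum
  }
  out
}
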