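#' Write a field series to CF-convention netCDF
#'
#' Dimensions (time, lat, lon); `time` as CF "hours since" the first
#' sample; every variable carries a `units` attribute and flux variables a
#' `positive = "up"` attribute. Global attributes embed the package
#' version and, when supplied, the provenance (config hash, seed).
#'
#' @param fs a `field_series` on a regular lat-lon [sf_grid()].
#' @param path output file path (.nc).
#' @param provenance optional named list written as global attributes.
#' @return `path`, invisibly.
#' @export
write_fields <- function(fs, path, provenance = NULL) {
  stopifnot(inherits(fs, "field_series"))
  g <- fs$grid
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", g$lon)
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", g$lat)
  origin <- format(fs$time[1], "%Y-%m-%d %H:%M:%S", tz = "UTC")
  tvals <- as.numeric(difftime(fs$time, fs$time[1], units = "hours"))
  dtim <- ncdf4::ncdim_def("time", paste0("hours since ", origin), tvals,
                           unlim = TRUE, calendar = "standard")
  vars <- lapply(names(fs$vars), function(v)
    ncdf4::ncvar_def(v, fs$units[[v]], list(dlon, dlat, dtim),
                     missval = NA_real_, prec = "double"))
  names(vars) <- names(fs$vars)
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc))
  nlon <- g$dims[1]; nlat <- g$dims[2]; nt <- length(fs$time)
  for (v in names(fs$vars)) {
    arr <- array(t(fs$vars[[v]]), dim = c(nlon, nlat, nt))
    ncdf4::ncvar_put(nc, vars[[v]], arr)
    if (!is.na(fs$positive[[v]]))
      ncdf4::ncatt_put(nc, v, "positive", fs$positive[[v]])
  }
  ncdf4::ncatt_put(nc, 0, "Conventions", "CF-1.8")
  ncdf4::ncatt_put(nc, 0, "source",
                   paste0("stormflux ", as.character(utils::packageVersion("stormflux"))))
  for (a in names(provenance))
    ncdf4::ncatt_put(nc, 0, a, as.character(provenance[[a]]))
  invisible(path)
}

#' Read a field series from CF-convention netCDF
#'
#' Expects (time, lat, lon) coordinates with a CF time unit. Variables
#' without a `units` attribute are rejected; a flux variable carrying
#' `positive = "down"` is negated on read so that the in-memory convention
#' is always positive-up.
#'
#' @param path netCDF file path.
#' @return a `field_series`.
#' @export
read_fields <- function(path) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  for (need in c("time", "lat", "lon"))
    if (!need %in% names(nc$dim))
      stop(sprintf("netCDF file is missing the '%s' coordinate", need))
  tdim <- nc$dim$time
  m <- regmatches(tdim$units,
                  regexec("^(seconds|hours|days) since (.+)$", tdim$units))[[1]]
  if (length(m) != 3) stop(sprintf("unrecognized time units '%s'", tdim$units))
  mult <- c(seconds = 1, hours = 3600, days = 86400)[[m[2]]]
  origin <- as.POSIXct(m[3], tz = "UTC")
  if (is.na(origin)) stop(sprintf("cannot parse time origin in '%s'", tdim$units))
  cal <- if (is.null(tdim$calendar)) "standard" else tdim$calendar
  if (!cal %in% c("standard", "gregorian", "proleptic_gregorian"))
    stop(sprintf("unrecognized calendar '%s'", cal))
  time <- origin + as.vector(tdim$vals) * mult
  lon <- nc$dim$lon$vals; lat <- nc$dim$lat$vals
  res <- if (length(lon) > 1) abs(lon[2] - lon[1]) else
    if (length(lat) > 1) abs(lat[2] - lat[1]) else
      stop("degenerate 1x1 grid")
  grid <- sf_grid(c(min(lon) - res / 2, max(lon) + res / 2),
                  c(min(lat) - res / 2, max(lat) + res / 2), res = res)
  vars <- list(); units <- c(); positive <- c()
  nt <- length(time)
  for (v in names(nc$var)) {
    u <- ncdf4::ncatt_get(nc, v, "units")
    if (!u$hasatt) stop(sprintf("variable '%s' has no units attribute", v))
    arr <- ncdf4::ncvar_get(nc, v, collapse_degen = FALSE)
    m2 <- t(matrix(arr, nrow = length(lon) * length(lat), ncol = nt))
    p <- ncdf4::ncatt_get(nc, v, "positive")
    if (p$hasatt && identical(tolower(p$value), "down")) {
      m2 <- -m2
      positive[v] <- "up"
    } else if (p$hasatt) positive[v] <- tolower(p$value)
    vars[[v]] <- m2
    units[v] <- u$value
  }
  field_series(grid, time, vars, units = units,
               positive = if (length(positive)) positive else NULL)
}

#' Write cyclone tracks to CSV
#'
#' Columns: `track_id`, `time` (ISO-8601 UTC), `lat`, `lon`, `mslp_hpa`,
#' `vmax_ms`, `category`. An empty track list yields a header-only file.
#'
#' @param tracks list of `cyclone_track`s.
#' @param path output CSV path.
#' @param provenance optional named list written as `#key: value` header
#'   comment lines.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path, provenance = NULL) {
  rows <- lapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    data.frame(track_id = i,
               time = format(tr$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
               lat = tr$lat, lon = tr$lon, mslp_hpa = tr$mslp_hpa,
               vmax_ms = tr$vmax_ms,
               category = saffir_simpson_category(tr$vmax_ms))
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(track_id = integer(), time = character(), lat = numeric(),
               lon = numeric(), mslp_hpa = numeric(), vmax_ms = numeric(),
               category = character())
  con <- file(path, "w")
  on.exit(close(con))
  for (a in names(provenance))
    writeLines(sprintf("#%s: %s", a, provenance[[a]]), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read cyclone tracks from CSV
#'
#' Inverse of [write_tracks()]; malformed rows raise an error naming the
#' row number.
#'
#' @param path CSV path.
#' @return list of `cyclone_track`s.
#' @export
read_tracks <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("track_id", "time", "lat", "lon", "mslp_hpa", "vmax_ms")
  if (!all(need %in% names(df)))
    stop("track CSV is missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (!nrow(df)) return(list())
  time <- as.POSIXct(df$time, format = "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC")
  bad <- which(is.na(time) | is.na(df$lat) | is.na(df$lon) | is.na(df$mslp_hpa))
  if (length(bad))
    stop(sprintf("malformed track row %d in %s", bad[1], path))
  df$time <- time
  lapply(split(df, df$track_id), function(d)
    as_cyclone_track(d[order(d$time),
                       c("time", "lat", "lon", "mslp_hpa", "vmax_ms")]))
}

#' Export cyclone tracks as GeoJSON LineStrings
#'
#' One LineString feature per track with per-track properties (id,
#' lifetime, LMI, category) and per-point arrays in the properties.
#'
#' @param tracks list of `cyclone_track`s.
#' @param path output path (.geojson).
#' @return `path`, invisibly.
#' @export
write_tracks_geojson <- function(tracks, path) {
  features <- lapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    list(type = "Feature",
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(tr)), function(j)
                           c(tr$lon[j], tr$lat[j]))),
         properties = list(
           track_id = i, lifetime_h = track_lifetime_h(tr),
           lmi_ms = track_lmi_ms(tr),
           category = saffir_simpson_category(track_lmi_ms(tr)),
           times = format(tr$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
           mslp_hpa = tr$mslp_hpa, vmax_ms = tr$vmax_ms))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
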