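#' Regular latitude-longitude grid with spherical cell areas
#'
#' Builds the grid geometry used throughout stormflux: a regular lat-lon
#' mesh with per-cell areas from spherical geometry (Earth radius 6371 km).
#' Cells are stored flattened with longitude varying fastest.
#'
#' @param lon_range numeric length-2, degrees east; normalized to [-180, 180).
#' @param lat_range numeric length-2, degrees north.
#' @param res grid spacing in degrees (same in both directions).
#' @return An object of class `sf_grid`: list with `lon`, `lat` (axis
#'   vectors of cell centers), `cell_lon`, `cell_lat`, `area_m2` (flattened,
#'   lon fastest), `dims` = c(nlon, nlat) and `res`.
#' @examples
#' g <- sf_grid(c(-75, -45), c(15, 45), res = 1)
#' sum(g$area_m2) # area of the domain in m^2
#' @export
sf_grid <- function(lon_range, lat_range, res = 0.5) {
  stopifnot(length(lon_range) == 2, length(lat_range) == 2, res > 0)
  lon <- normalize_lon(seq(lon_range[1] + res / 2, lon_range[2] - res / 2, by = res))
  lat <- seq(lat_range[1] + res / 2, lat_range[2] - res / 2, by = res)
  cells <- expand.grid(lon = lon, lat = lat, KEEP.OUT.ATTRS = FALSE)
  # spherical zonal band area: R^2 * dlam * (sin(lat+)-sin(lat-))
  dlam <- res * pi / 180
  latp <- (cells$lat + res / 2) * pi / 180
  latm <- (cells$lat - res / 2) * pi / 180
  area <- EARTH_RADIUS_M^2 * dlam * (sin(latp) - sin(latm))
  structure(
    list(lon = lon, lat = lat,
         cell_lon = cells$lon, cell_lat = cells$lat,
         area_m2 = area, dims = c(length(lon), length(lat)), res = res),
    class = "sf_grid")
}

#' @export
print.sf_grid <- function(x, ...) {
  cat(sprintf("<sf_grid> %d x %d cells, %.3g deg, lon [%.2f, %.2f], lat [%.2f, %.2f]\n",
              x$dims[1], x$dims[2], x$res, min(x$lon), max(x$lon),
              min(x$lat), max(x$lat)))
  invisible(x)
}

# Earth radius used for all great-circle arithmetic (m)
EARTH_RADIUS_M <- 6371e3

#' Normalize longitudes to [-180, 180)
#' @param lon degrees east, any wrap.
#' @return degrees east in [-180, 180).
#' @export
normalize_lon <- function(lon) {
  ((lon + 180) %% 360) - 180
}

#' Great-circle distance (haversine, Earth radius 6371 km)
#'
#' Vectorized over points; recycling applies between `lon1/lat1` and
#' `lon2/lat2`.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in degrees.
#' @return distances in kilometers.
#' @export
gc_dist_km <- function(lon1, lat1, lon2, lat2) {
  n <- max(length(lon1), length(lon2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_M) / 1000
}

# local tangent-plane offsets (km) of points relative to an origin
local_offsets_km <- function(lon, lat, lon0, lat0) {
  dx <- normalize_lon(lon - lon0) * cos(lat0 * pi / 180) * pi / 180 * EARTH_RADIUS_M / 1000
  dy <- (lat - lat0) * pi / 180 * EARTH_RADIUS_M / 1000
  cbind(dx, dy)
}
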