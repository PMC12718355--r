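#' Vertical column profile
#'
#' Depth-resolved state at one location: depths positive down and strictly
#' increasing, with any of temperature, salinity, density, tracer
#' concentrations or vertical diffusivity at the levels.
#'
#' @param depth_m numeric, strictly increasing, positive down.
#' @param ... named numeric vectors at the levels (e.g. `temp_c`, `sal`,
#'   `density`, `kv`).
#' @return object of class `column_profile`.
#' @export
column_profile <- function(depth_m, ...) {
  vars <- list(...)
  if (any(diff(depth_m) <= 0)) stop("depths must be strictly increasing")
  for (v in names(vars))
    if (length(vars[[v]]) != length(depth_m))
      stop(sprintf("'%s' must have one value per depth level", v))
  if (!is.null(vars$kv) && any(vars$kv < 0, na.rm = TRUE))
    stop("vertical diffusivity kv must be >= 0")
  structure(c(list(depth_m = depth_m), vars), class = "column_profile")
}

#' Linear seawater equation of state
#'
#' sigma = sigma0 - alpha (T - T0) + beta (S - S0), the closed-form EOS
#' used for mixed-layer-depth and stratification tests; a full EOS profile
#' can be supplied directly instead.
#'
#' @param temp_c,sal temperature (degC) and salinity.
#' @param sigma0 reference density (kg/m^3) at (`t0`, `s0`).
#' @param alpha thermal expansion (kg/m^3 per degC).
#' @param beta haline contraction (kg/m^3 per salinity unit).
#' @param t0,s0 reference temperature and salinity.
#' @return density (kg/m^3).
#' @export
linear_density <- function(temp_c, sal, sigma0 = 1025, alpha = 0.2,
                           beta = 0.78, t0 = 15, s0 = 35) {
  sigma0 - alpha * (temp_c - t0) + beta * (sal - s0)
}

#' Mixed-layer depth by the density-threshold criterion
#'
#' The depth at which density first exceeds the surface (shallowest-level)
#' value by `threshold` kg/m^3, linearly interpolated between the
#' bracketing levels; the bottom depth when the threshold is never
#' exceeded. The conventional thresholds are 0.03 and 0.125 kg/m^3.
#'
#' @param profile a [column_profile()] with `density` (kg/m^3).
#' @param threshold density excess over the surface value (kg/m^3).
#' @return mixed-layer depth (m).
#' @export
mixed_layer_depth <- function(profile, threshold = 0.03) {
  stopifnot(inherits(profile, "column_profile"), !is.null(profile$density))
  z <- profile$depth_m; rho <- profile$density
  if (length(z) < 2) stop("density must be defined at >= 2 levels")
  excess <- rho - rho[1]
  above <- which(excess >= threshold)
  if (!length(above)) return(z[length(z)])
  i <- above[1]
  if (i == 1) return(z[1])
  # linear interpolation between bracketing levels
  z[i - 1] + (threshold - excess[i - 1]) / (excess[i] - excess[i - 1]) *
    (z[i] - z[i - 1])
}

#' Brunt-Vaisala frequency squared from a density profile
#'
#' N^2 = (g / rho_ref) * d(rho)/dz at interior levels, centered
#' differences (one-sided at the endpoints); sign preserved, negative
#' where the column is unstably stratified.
#'
#' @param profile a [column_profile()] with `density`.
#' @param rho_ref reference density (kg/m^3).
#' @param g gravitational acceleration (m/s^2).
#' @return N^2 in s^-2, one value per level.
#' @export
brunt_vaisala <- function(profile, rho_ref = 1025, g = 9.81) {
  stopifnot(inherits(profile, "column_profile"), !is.null(profile$density))
  z <- profile$depth_m; rho <- profile$density
  if (length(z) < 2) stop("N^2 needs >= 2 levels")
  n <- length(z)
  drho <- numeric(n)
  drho[1] <- (rho[2] - rho[1]) / (z[2] - z[1])
  drho[n] <- (rho[n] - rho[n - 1]) / (z[n] - z[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    drho[i] <- (rho[i + 1] - rho[i - 1]) / (z[i + 1] - z[i - 1])
  }
  g / rho_ref * drho
}

#' Local inertial period
#'
#' 2*pi / (2*Omega*sin|lat|) with Omega = 7.2921e-5 s^-1, in hours: the
#' rotation-set timescale of the near-inertial currents that storms excite
#' (21.3 h near 34.2 degrees latitude).
#'
#' @param lat_deg latitude (deg); the equator has an infinite period and
#'   returns `Inf`.
#' @return inertial period in hours.
#' @export
inertial_period <- function(lat_deg) {
  omega <- 7.2921e-5
  f <- 2 * omega * sin(abs(lat_deg) * pi / 180)
  ifelse(f == 0, Inf, 2 * pi / f / 3600)
}

#' Reconstruct column profiles from a slab run
#'
#' Builds a depth-resolved view of one cell of a [run_slab_ocean()] result:
#' homogeneous mixed-layer values above the local mixed-layer depth, the
#' scenario's fixed sub-mixed-layer profiles below, and density from
#' [linear_density()]. A convenience for mixed-layer-depth and
#' stratification diagnostics on synthetic runs.
#'
#' @param run a `slab_run`.
#' @param cell cell index.
#' @param time POSIXct (nearest step used).
#' @param depth_m output levels (m, positive down).
#' @return a [column_profile()] with `temp_c`, `sal`, `density`.
#' @export
slab_column_profile <- function(run, cell, time,
                                depth_m = seq(0, 200, by = 2)) {
  fs <- run$fields; p <- run$params
  ti <- fs_time_index(fs, time)
  h <- fs_var(fs, "mld")[ti, cell]
  tml <- fs_var(fs, "sst")[ti, cell]; sml <- fs_var(fs, "sss")[ti, cell]
  temp <- ifelse(depth_m <= h, tml,
                 deep_value(p$sst0_c, p$grad_t_c_m, depth_m, p$h0_m,
                            p$grad_extent_m))
  sal <- ifelse(depth_m <= h, sml,
                deep_value(p$sss0, p$grad_s_m, depth_m, p$h0_m,
                           p$grad_extent_m))
  column_profile(depth_m, temp_c = temp, sal = sal,
                 density = linear_density(temp, sal))
}
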