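#' Residual of a tracer-budget decomposition
#'
#' The total tendency of a tracer decomposes into horizontal and vertical
#' advection, vertical diffusion, surface fluxes and biogeochemical
#' sources/sinks; the residual is tendency minus the sum of the terms and
#' should vanish to integrator tolerance when the bookkeeping is complete.
#'
#' @param terms a `budget_terms` object (e.g. from [emit_budget_terms()])
#'   or a named list with matrices/vectors `tendency`, `hadv`, `vadv`,
#'   `vdiff`, `surface`, `bio` of one shape.
#' @return list with `residual` (same shape), `max_abs_residual`,
#'   `max_abs_tendency` and `normalized` (their ratio; 0 when the tendency
#'   is identically 0).
#' @export
budget_residual <- function(terms) {
  need <- c("tendency", "hadv", "vadv", "vdiff", "surface", "bio")
  missing <- setdiff(need, names(terms))
  if (length(missing))
    stop("missing budget component(s): ", paste(missing, collapse = ", "))
  res <- terms$tendency -
    (terms$hadv + terms$vadv + terms$vdiff + terms$surface + terms$bio)
  mt <- max(abs(terms$tendency), na.rm = TRUE)
  mr <- max(abs(res), na.rm = TRUE)
  list(residual = res, max_abs_residual = mr, max_abs_tendency = mt,
       normalized = if (mt > 0) mr / mt else 0)
}

#' Temperature-dependent remineralization rate
#'
#' rate = r0 * Q10^((T - Tref)/10) * concentration: first-order in the
#' substrate with a Q10 temperature multiplier.
#'
#' @param conc substrate concentration (>= 0, any concentration unit).
#' @param temp_c temperature (degC).
#' @param params a [remin_params()].
#' @return remineralization rate in concentration units per day.
#' @export
remineralization_rate <- function(conc, temp_c, params = remin_params()) {
  stopifnot(inherits(params, "remin_params"))
  if (any(conc < 0, na.rm = TRUE)) stop("substrate concentration must be >= 0")
  params$r0_day * params$q10^((temp_c - params$tref_c) / 10) * conc
}

#' Fixed-temperature remineralization counterfactual
#'
#' Isolates the temperature contribution to remineralization changes:
#' recomputes the rate with temperatures held at a pre-storm profile and
#' reports Delta R(z, t) = R(T(t)) - R(T_pre) together with trapezoidal
#' vertical integrals from the surface to each requested horizon. Surface
#' cooling and subsurface warming produce compensating contributions whose
#' vertical integral is typically small.
#'
#' @param depth_m levels (m, positive down, strictly increasing).
#' @param temp_tz time x depth matrix of temperatures (degC).
#' @param substrate_tz time x depth matrix of substrate concentrations.
#' @param temp_pre pre-storm temperature profile (one value per depth).
#' @param params a [remin_params()].
#' @param horizons_m vertical integration horizons (m); must not exceed the
#'   deepest level.
#' @return list with `delta_r` (time x depth, rate units), `integrals`
#'   (time x horizon matrix, rate units x m) and `horizons_m`.
#' @export
temperature_counterfactual <- function(depth_m, temp_tz, substrate_tz,
                                       temp_pre, params = remin_params(),
                                       horizons_m = c(100, 1000)) {
  stopifnot(is.matrix(temp_tz), all(dim(temp_tz) == dim(substrate_tz)),
            length(temp_pre) == ncol(temp_tz),
            length(depth_m) == ncol(temp_tz))
  if (any(diff(depth_m) <= 0)) stop("depths must be strictly increasing")
  if (any(horizons_m > max(depth_m)))
    stop(sprintf("integration horizon exceeds the deepest level (%g m)",
                 max(depth_m)))
  r_act <- remineralization_rate(substrate_tz, temp_tz, params)
  r_pre <- remineralization_rate(substrate_tz,
                                 matrix(temp_pre, nrow(temp_tz),
                                        ncol(temp_tz), byrow = TRUE), params)
  dr <- r_act - r_pre
  ints <- vapply(horizons_m, function(hz)
    apply(dr, 1, trapz_to_depth, depth_m = depth_m, horizon = hz),
    numeric(nrow(dr)))
  ints <- matrix(ints, nrow = nrow(dr),
                 dimnames = list(NULL, paste0("to_", horizons_m, "m")))
  list(delta_r = dr, integrals = ints, horizons_m = horizons_m)
}

# trapezoidal integral of v(depth) from the surface to `horizon`, with the
# partial end interval handled by linear interpolation
trapz_to_depth <- function(v, depth_m, horizon) {
  if (horizon <= depth_m[1]) return(0)
  inside <- depth_m <= horizon
  z <- depth_m[inside]; y <- v[inside]
  if (horizon > z[length(z)] && any(!inside)) {
    yh <- stats::approx(depth_m, v, xout = horizon)$y
    z <- c(z, horizon); y <- c(y, yh)
  }
  sum(diff(z) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Export ratio with a production-to-export lag
#'
#' Ratio of time-integrated organic-carbon export at depth to
#' time-integrated NPP, with the export series shifted by a fixed lag
#' (about 9 days between integrated NPP and export at 90 m is typical):
#' integral of export(t + lag) over the window divided by the integral of
#' NPP(t).
#'
#' @param time POSIXct axis shared by both series, uniform spacing.
#' @param npp NPP series (e.g. mmolC m^-2 day^-1).
#' @param export export series at the reference depth (same units).
#' @param lag_days lag applied to the export series (days).
#' @param window POSIXct length-2 integration window for NPP (the export
#'   integral uses window + lag; both must be covered).
#' @return dimensionless ratio (0.10 means 10\%).
#' @export
export_ratio <- function(time, npp, export, lag_days = 9, window = NULL) {
  stopifnot(length(time) == length(npp), length(npp) == length(export))
  if (is.null(window)) window <- c(time[1], time[length(time)] - lag_days * 86400)
  window <- sort(window)
  if (window[2] + lag_days * 86400 > time[length(time)] + 1)
    stop("series does not cover window + lag")
  sel_n <- time >= window[1] & time <= window[2]
  sel_e <- time >= window[1] + lag_days * 86400 &
    time <= window[2] + lag_days * 86400
  int_n <- sum(npp[sel_n], na.rm = TRUE)
  int_e <- sum(export[sel_e], na.rm = TRUE)
  if (int_n == 0) stop("integrated NPP is 0; export ratio undefined")
  int_e / int_n
}
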