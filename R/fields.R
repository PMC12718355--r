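#' Gridded surface time series (FieldSeries container)
#'
#' The common container for all gridded inputs/outputs: a set of variables
#' on one `sf_grid` sampled at a shared, uniformly spaced time axis. Each
#' variable is a time x cell matrix. Units and sign conventions are carried
#' explicitly; flux variables use the positive-upward (ocean-to-atmosphere)
#' convention.
#'
#' @param grid an [sf_grid()].
#' @param time POSIXct vector (UTC), strictly increasing, uniform spacing.
#' @param vars named list of matrices, each `length(time)` x `ncell`.
#' @param units named character, one entry per variable.
#' @param positive named character; for flux variables, `"up"` (others NA).
#' @return An object of class `field_series`.
#' @export
field_series <- function(grid, time, vars, units = NULL, positive = NULL) {
  stopifnot(inherits(grid, "sf_grid"), inherits(time, "POSIXct"),
            is.list(vars), length(vars) > 0, !is.null(names(vars)))
  ncell <- length(grid$cell_lon)
  nt <- length(time)
  if (nt > 1) {
    dt <- diff(as.numeric(time))
    if (any(dt <= 0)) stop("time axis must be strictly increasing")
    if (max(dt) - min(dt) > 1e-6 * dt[1])
      stop("time axis must be uniformly spaced")
  }
  for (v in names(vars)) {
    m <- vars[[v]]
    if (!is.matrix(m) || nrow(m) != nt || ncol(m) != ncell)
      stop(sprintf("variable '%s' must be a %d x %d matrix", v, nt, ncell))
  }
  u <- stats::setNames(rep(NA_character_, length(vars)), names(vars))
  if (!is.null(units)) u[names(units)] <- units
  p <- stats::setNames(rep(NA_character_, length(vars)), names(vars))
  if (!is.null(positive)) p[names(positive)] <- positive
  structure(list(grid = grid, time = time, vars = vars, units = u, positive = p),
            class = "field_series")
}

#' @export
print.field_series <- function(x, ...) {
  cat(sprintf("<field_series> %d times (%s .. %s), %d cells\n",
              length(x$time),
              format(x$time[1], "%Y-%m-%d %H:%M", tz = "UTC"),
              format(x$time[length(x$time)], "%Y-%m-%d %H:%M", tz = "UTC"),
              length(x$grid$cell_lon)))
  for (v in names(x$vars))
    cat(sprintf("  %-12s [%s]%s\n", v, x$units[[v]],
                if (!is.na(x$positive[[v]])) paste0(" positive:", x$positive[[v]]) else ""))
  invisible(x)
}

#' Time step of a field series, in hours
#' @param fs a `field_series`.
#' @return numeric scalar (hours); NA for a single-time series.
#' @export
fs_dt_hours <- function(fs) {
  if (length(fs$time) < 2) return(NA_real_)
  as.numeric(difftime(fs$time[2], fs$time[1], units = "hours"))
}

# index of the time closest to `t` (POSIXct); NA if outside axis by > tol_h
fs_time_index <- function(fs, t, tol_h = NULL) {
  d <- abs(as.numeric(difftime(fs$time, t, units = "hours")))
  i <- which.min(d)
  if (!is.null(tol_h) && d[i] > tol_h) return(NA_integer_)
  i
}

#' Extract one variable's matrix from a field series
#' @param fs a `field_series`.
#' @param var variable name.
#' @return time x cell matrix.
#' @export
fs_var <- function(fs, var) {
  if (!var %in% names(fs$vars))
    stop(sprintf("variable '%s' not present (have: %s)", var,
                 paste(names(fs$vars), collapse = ", ")))
  fs$vars[[var]]
}
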