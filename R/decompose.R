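#' Revelle factor approximation from DIC and alkalinity
#'
#' gamma_DIC = (3*Alk*DIC - 2*DIC^2) / ((2*DIC - Alk) * (Alk - DIC)): the
#' logarithmic sensitivity of pCO2 to DIC at fixed alkalinity, in the
#' carbonate-ion approximation. Valid for DIC < Alk < 2*DIC.
#'
#' @param dic,alk DIC and total alkalinity in consistent units (the ratio
#'   is unit-invariant).
#' @return dimensionless Revelle factor (positive for seawater).
#' @examples
#' gamma_dic(2000, 2300) # 11.37
#' @export
gamma_dic <- function(dic, alk) {
  check_gamma_domain(dic, alk)
  (3 * alk * dic - 2 * dic^2) / ((2 * dic - alk) * (alk - dic))
}

#' Alkalinity sensitivity coefficient of pCO2
#'
#' gamma_Alk = -Alk^2 / ((2*DIC - Alk) * (Alk - DIC)): negative on the
#' valid domain, and satisfying the algebraic identity
#' gamma_DIC + gamma_Alk = 1.
#'
#' @inheritParams gamma_dic
#' @return dimensionless coefficient (negative).
#' @export
gamma_alk <- function(dic, alk) {
  check_gamma_domain(dic, alk)
  -alk^2 / ((2 * dic - alk) * (alk - dic))
}

check_gamma_domain <- function(dic, alk) {
  if (any(2 * dic - alk <= 0, na.rm = TRUE))
    stop("gamma undefined: requires 2*DIC - Alk > 0")
  if (any(alk - dic <= 0, na.rm = TRUE))
    stop("gamma undefined: requires Alk - DIC > 0")
  invisible(NULL)
}

#' Reference state for the pCO2 decomposition
#'
#' The local pre-storm state ("ref"), conventionally taken 24 h before the
#' cyclone passage.
#'
#' @param pco2,sst,sss,dic,alk reference surface pCO2 (uatm), temperature
#'   (degC), salinity, DIC and alkalinity (umol/kg).
#' @return object of class `pco2_reference`.
#' @export
pco2_reference <- function(pco2, sst, sss, dic, alk) {
  if (any(pco2 <= 0, na.rm = TRUE)) stop("reference pCO2 must be > 0")
  check_gamma_domain(dic, alk)
  structure(list(pco2 = pco2, sst = sst, sss = sss, dic = dic, alk = alk),
            class = "pco2_reference")
}

#' Decompose a surface-pCO2 change into SST, SSS, DIC and Alk terms
#'
#' Linear (Takahashi-style) decomposition about the reference state:
#' \deqn{\delta pCO_2^{SST} = \gamma_{SST}\, pCO_2^{ref}\, \delta SST}
#' \deqn{\delta pCO_2^{SSS} = \gamma_{SSS}\, pCO_2^{ref}\, \delta SSS / SSS^{ref}}
#' \deqn{\delta pCO_2^{DIC} = \gamma_{DIC}\, pCO_2^{ref}\, \delta DIC / DIC^{ref}}
#' \deqn{\delta pCO_2^{Alk} = \gamma_{Alk}\, pCO_2^{ref}\, \delta Alk / Alk^{ref}}
#' with gamma_SST = 0.0423 per degC (a 1 degC warming raises pCO2 by
#' 4.23\%), gamma_SSS = 1, and gamma_DIC/gamma_Alk evaluated from
#' [gamma_dic()]/[gamma_alk()] at the reference state (or at the
#' current-reference midpoint). The reported total is the exact sum of the
#' four terms; when a simulated current pCO2 is supplied the residual
#' (simulated delta minus reconstructed total) is reported too.
#'
#' @param ref a [pco2_reference()].
#' @param sst,sss,dic,alk current values (same units as the reference).
#' @param pco2_current optional simulated current pCO2 (uatm) for the
#'   residual.
#' @param gamma_sst temperature sensitivity (1/degC).
#' @param gamma_sss salinity coefficient.
#' @param gamma_at where to evaluate gamma_DIC/gamma_Alk: `"reference"`
#'   (default) or `"midpoint"`.
#' @return data.frame with `dpco2_sst`, `dpco2_sss`, `dpco2_dic`,
#'   `dpco2_alk`, `dpco2_total`, `gamma_dic`, `gamma_alk` and (when
#'   `pco2_current` is given) `dpco2_sim` and `residual`, all in uatm.
#' @export
decompose_pco2 <- function(ref, sst, sss, dic, alk, pco2_current = NULL,
                           gamma_sst = 0.0423, gamma_sss = 1,
                           gamma_at = c("reference", "midpoint")) {
  stopifnot(inherits(ref, "pco2_reference"))
  gamma_at <- match.arg(gamma_at)
  gd <- if (gamma_at == "reference") gamma_dic(ref$dic, ref$alk)
  else gamma_dic((ref$dic + dic) / 2, (ref$alk + alk) / 2)
  ga <- if (gamma_at == "reference") gamma_alk(ref$dic, ref$alk)
  else gamma_alk((ref$dic + dic) / 2, (ref$alk + alk) / 2)
  t_sst <- gamma_sst * ref$pco2 * (sst - ref$sst)
  t_sss <- gamma_sss * ref$pco2 * (sss - ref$sss) / ref$sss
  t_dic <- gd * ref$pco2 * (dic - ref$dic) / ref$dic
  t_alk <- ga * ref$pco2 * (alk - ref$alk) / ref$alk
  out <- data.frame(dpco2_sst = t_sst, dpco2_sss = t_sss,
                    dpco2_dic = t_dic, dpco2_alk = t_alk,
                    dpco2_total = t_sst + t_sss + t_dic + t_alk,
                    gamma_dic = gd, gamma_alk = ga)
  if (!is.null(pco2_current)) {
    out$dpco2_sim <- pco2_current - ref$pco2
    out$residual <- out$dpco2_sim - out$dpco2_total
  }
  out
}

#' Along-track pCO2 decomposition with residual statistics
#'
#' Runs [decompose_pco2()] at every track point of a slab run (or any field
#' series carrying `pco2`, `sst`, `sss`, `dic`, `alk`): the reference is
#' the circle average `ref_offset_h` hours before the local passage, the
#' current state the circle average `eval_offset_h` hours after it.
#'
#' @param fs a `field_series` with `pco2`, `sst`, `sss`, `dic`, `alk`.
#' @param track a `cyclone_track`.
#' @param radius_km circle radius (km).
#' @param ref_offset_h reference time before passage (hours).
#' @param eval_offset_h evaluation time after passage (hours).
#' @param ... passed to [decompose_pco2()] (`gamma_at`, coefficients).
#' @return list with `points` (per-track-point data.frame of terms and
#'   residuals) and `summary` (max |residual|, RMS residual, RMS total,
#'   and their ratio).
#' @export
decompose_along_track <- function(fs, track, radius_km = 200,
                                  ref_offset_h = 24, eval_offset_h = 24,
                                  ...) {
  rows <- list()
  for (i in seq_len(nrow(track))) {
    tr_ref <- track$time[i] - ref_offset_h * 3600
    tr_cur <- track$time[i] + eval_offset_h * 3600
    if (tr_ref < fs$time[1] || tr_cur > fs$time[length(fs$time)]) next
    ca <- function(v, t) circle_average(fs, v, track$lon[i], track$lat[i],
                                        t, radius_km)
    ref <- pco2_reference(ca("pco2", tr_ref), ca("sst", tr_ref),
                          ca("sss", tr_ref), ca("dic", tr_ref),
                          ca("alk", tr_ref))
    d <- decompose_pco2(ref, ca("sst", tr_cur), ca("sss", tr_cur),
                        ca("dic", tr_cur), ca("alk", tr_cur),
                        pco2_current = ca("pco2", tr_cur), ...)
    d$time <- track$time[i]; d$lat <- track$lat[i]; d$lon <- track$lon[i]
    rows[[length(rows) + 1]] <- d
  }
  if (!length(rows)) stop("no track point has both reference and evaluation coverage")
  pts <- do.call(rbind, rows)
  rms <- function(x) sqrt(mean(x^2, na.rm = TRUE))
  list(points = pts,
       summary = list(max_abs_residual = max(abs(pts$residual), na.rm = TRUE),
                      rms_residual = rms(pts$residual),
                      rms_total = rms(pts$dpco2_total),
                      residual_fraction = rms(pts$residual) / rms(pts$dpco2_total)))
}
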