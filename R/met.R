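# Meteorological unit conversions: saturation vapour pressure, RH, VPD,
# dewpoint, and the empirical VPD(Tair) relation used in the coupled-model
# demonstration.

#' Saturation vapour pressure
#'
#' Magnus-type formula
#' \eqn{e_s(T) = 0.61078 \exp(17.269 T / (237.3 + T))} with `t` in degC and
#' the result in kPa. Accurate to well within 1% of reference formulations
#' over the valid range.
#'
#' @param t Air temperature, degC, in `[-40, 60]`.
#' @return Saturation vapour pressure, kPa.
#' @export
esat <- function(t) {
  if (any(!is.finite(t)) || any(t < -40) || any(t > 60))
    stop("'t' must be within [-40, 60] degC", call. = FALSE)
  0.61078 * exp(17.269 * t / (237.3 + t))
}

# d esat / dT, kPa K-1 (used by the Penman-Monteith equation)
.esat_slope <- function(t) {
  esat(t) * 17.269 * 237.3 / (237.3 + t)^2
}

#' Humidity conversions
#'
#' Convert between relative humidity, vapour pressure deficit and dewpoint
#' temperature at a given air temperature. All conversions go through
#' [esat()] and are exact round trips of one another.
#'
#' @param rh Relative humidity, percent, in `[0, 100]`.
#' @param vpd Vapour pressure deficit, kPa, in `[0, esat(tair)]`.
#' @param dewpoint Dewpoint temperature, degC, `<= tair`.
#' @param tair Air temperature, degC.
#' @return `rh_to_vpd` and `dew_to_vpd` return kPa; `vpd_to_rh` returns
#'   percent.
#' @examples
#' rh_to_vpd(63, 30)
#' vpd_to_rh(rh_to_vpd(63, 30), 30)  # 63
#' @export
rh_to_vpd <- function(rh, tair) {
  if (any(rh < 0) || any(rh > 100))
    stop("'rh' must be within [0, 100]", call. = FALSE)
  esat(tair) * (1 - rh / 100)
}

#' @rdname rh_to_vpd
#' @export
vpd_to_rh <- function(vpd, tair) {
  es <- esat(tair)
  if (any(vpd < 0) || any(vpd > es))
    stop("'vpd' must be within [0, esat(tair)]", call. = FALSE)
  100 * (1 - vpd / es)
}

#' @rdname rh_to_vpd
#' @export
dew_to_vpd <- function(dewpoint, tair) {
  if (any(dewpoint > tair))
    stop("'dewpoint' must not exceed 'tair'", call. = FALSE)
  esat(tair) - esat(dewpoint)
}

#' Empirical field relation between air temperature and VPD
#'
#' In field conditions vapour pressure deficit rises steeply with air
#' temperature; this empirical power law, `D = 0.000605 * tair^2.39` (kPa),
#' is used to drive the coupled gas-exchange model when exploring combined
#' temperature-humidity responses.
#'
#' @param tair Air temperature, degC (> 0).
#' @return Vapour pressure deficit, kPa.
#' @examples
#' vpd_from_tair(25)  # about 1.33 kPa
#' @export
vpd_from_tair <- function(tair) {
  if (any(!is.finite(tair)) || any(tair <= 0))
    stop("'tair' must be positive", call. = FALSE)
  0.000605 * tair^2.39
}
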