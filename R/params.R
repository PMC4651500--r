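# Parameter containers and default constants.

#' FvCB biochemical parameter set
#'
#' Builds the parameter set used by [aci_demand()], [photosyn()] and the
#' fitting functions. All rates are defined at 25 degC and scaled to leaf
#' temperature internally with [arrhenius()]: plain Arrhenius for the
#' Michaelis constants (Kc, Ko), the CO2 compensation point (GammaStar) and
#' day respiration (Rd); peaked Arrhenius (with deactivation energy and
#' entropy term) for Vcmax and Jmax.
#'
#' Default kinetic constants are the conventional Rubisco parameterization:
#' GammaStar25 = 42.75 umol mol-1, Kc25 = 404.9 umol mol-1,
#' Ko25 = 278.4 mmol mol-1, Oi = 210 mmol mol-1, with quantum yield
#' alpha = 0.24 mol mol-1 and light-response curvature theta_j = 0.85.
#' The hyperbolic-minimum shape parameter `theta_hmin` defaults to 0.9999,
#' which keeps the transition between Rubisco- and RuBP-limited
#' photosynthesis smooth while staying numerically indistinguishable from a
#' strict minimum away from the transition.
#'
#' @param vcmax25 Maximum carboxylation rate at 25 degC, umol m-2 s-1.
#' @param jmax25 Maximum electron transport rate at 25 degC, umol m-2 s-1.
#' @param rd25 Day respiration at 25 degC, umol m-2 s-1.
#' @param gm Mesophyll conductance, mol m-2 s-1, or `NULL`/`Inf` to treat
#'   Ci as the photosynthetic substrate (infinite gm).
#' @param kc25,ko25 Michaelis constants for CO2 (umol mol-1) and O2
#'   (mmol mol-1) at 25 degC.
#' @param gammastar25 CO2 compensation point without Rd at 25 degC,
#'   umol mol-1.
#' @param oi Intercellular O2 mole fraction, mmol mol-1.
#' @param alpha Quantum yield of electron transport, mol electrons
#'   mol-1 photons.
#' @param theta_j Curvature of the electron-transport light response, (0, 1].
#' @param theta_hmin Shape of the hyperbolic minimum of Ac and Aj, (0, 1].
#' @param ea_vcmax,hd_vcmax,ds_vcmax Peaked-Arrhenius constants for Vcmax
#'   (J mol-1, J mol-1, J mol-1 K-1).
#' @param ea_jmax,hd_jmax,ds_jmax Same for Jmax.
#' @param ea_rd Activation energy of Rd, J mol-1.
#' @param ea_kc,ea_ko,ea_gammastar Activation energies of Kc, Ko and
#'   GammaStar, J mol-1.
#' @param tcorrect Logical; if `FALSE`, Vcmax, Jmax and Rd are used as given
#'   (no temperature scaling), while Kc, Ko and GammaStar still follow leaf
#'   temperature.
#' @return An object of class `"biochem_params"` (a validated list).
#' @seealso [aci_demand()], [fit_aci()], [fvcb_defaults()]
#' @export
biochem_params <- function(vcmax25 = 50, jmax25 = 100, rd25 = 1.5, gm = NULL,
                           kc25 = 404.9, ko25 = 278.4, gammastar25 = 42.75,
                           oi = 210, alpha = 0.24, theta_j = 0.85,
                           theta_hmin = 0.9999,
                           ea_vcmax = 58550, hd_vcmax = 200000,
                           ds_vcmax = 629.26,
                           ea_jmax = 29680, hd_jmax = 200000,
                           ds_jmax = 631.88,
                           ea_rd = 46390,
                           ea_kc = 79430, ea_ko = 36380,
                           ea_gammastar = 37830,
                           tcorrect = TRUE) {
  if (is.null(gm) || !is.finite(gm)) gm <- Inf
  p <- list(vcmax25 = vcmax25, jmax25 = jmax25, rd25 = rd25, gm = gm,
            kc25 = kc25, ko25 = ko25, gammastar25 = gammastar25, oi = oi,
            alpha = alpha, theta_j = theta_j, theta_hmin = theta_hmin,
            ea_vcmax = ea_vcmax, hd_vcmax = hd_vcmax, ds_vcmax = ds_vcmax,
            ea_jmax = ea_jmax, hd_jmax = hd_jmax, ds_jmax = ds_jmax,
            ea_rd = ea_rd, ea_kc = ea_kc, ea_ko = ea_ko,
            ea_gammastar = ea_gammastar, tcorrect = isTRUE(tcorrect))
  rates <- c("vcmax25", "jmax25", "rd25", "kc25", "ko25", "gammastar25", "oi")
  for (nm in rates)
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] < 0)
      stop("'", nm, "' must be a single non-negative number", call. = FALSE)
  if (p$gm <= 0) stop("'gm' must be positive when finite", call. = FALSE)
  if (p$theta_j <= 0 || p$theta_j > 1)
    stop("'theta_j' must be in (0, 1]", call. = FALSE)
  if (p$theta_hmin <= 0 || p$theta_hmin > 1)
    stop("'theta_hmin' must be in (0, 1]", call. = FALSE)
  if (p$alpha <= 0) stop("'alpha' must be positive", call. = FALSE)
  structure(p, class = "biochem_params")
}

#' @export
print.biochem_params <- function(x, ...) {
  cat("FvCB biochemical parameter set (rates at 25 degC)\n")
  cat(sprintf("  Vcmax: %-8.4g Jmax: %-8.4g Rd: %-8.4g gm: %s\n",
              x$vcmax25, x$jmax25, x$rd25,
              if (is.infinite(x$gm)) "infinite" else format(x$gm)))
  cat(sprintf("  Kc: %.4g  Ko: %.4g  GammaStar: %.4g  Oi: %.4g\n",
              x$kc25, x$ko25, x$gammastar25, x$oi))
  cat(sprintf("  alpha: %.3g  theta_j: %.3g  theta_hmin: %.6g  tcorrect: %s\n",
              x$alpha, x$theta_j, x$theta_hmin, x$tcorrect))
  invisible(x)
}

#' Package default constants
#'
#' Returns the full table of default physical and biochemical constants used
#' across the package, for documentation and for the command-line
#' `--show-defaults` option.
#'
#' @return A data frame with columns `name`, `value`, `units`.
#' @export
fvcb_defaults <- function() {
  p <- biochem_params()
  data.frame(
    name = c("vcmax25", "jmax25", "rd25", "kc25", "ko25", "gammastar25",
             "oi", "alpha", "theta_j", "theta_hmin",
             "ea_vcmax", "hd_vcmax", "ds_vcmax", "ea_jmax", "hd_jmax",
             "ds_jmax", "ea_rd", "ea_kc", "ea_ko", "ea_gammastar",
             "gas_constant", "g0", "g1", "d0", "ca", "pa", "vpd_floor",
             "stomatal_ratio_co2", "boundary_ratio_co2"),
    value = c(p$vcmax25, p$jmax25, p$rd25, p$kc25, p$ko25, p$gammastar25,
              p$oi, p$alpha, p$theta_j, p$theta_hmin,
              p$ea_vcmax, p$hd_vcmax, p$ds_vcmax, p$ea_jmax, p$hd_jmax,
              p$ds_jmax, p$ea_rd, p$ea_kc, p$ea_ko, p$ea_gammastar,
              .RGAS, 0, 4, 1.5, 400, 101.3, 0.05, 1.6, 1.37),
    units = c("umol m-2 s-1", "umol m-2 s-1", "umol m-2 s-1",
              "umol mol-1", "mmol mol-1", "umol mol-1", "mmol mol-1",
              "mol mol-1", "-", "-",
              "J mol-1", "J mol-1", "J mol-1 K-1", "J mol-1", "J mol-1",
              "J mol-1 K-1", "J mol-1", "J mol-1", "J mol-1", "J mol-1",
              "J mol-1 K-1", "mol m-2 s-1", "kPa^0.5 (medlyn)", "kPa",
              "umol mol-1", "kPa", "kPa", "-", "-"),
    stringsAsFactors = FALSE
  )
}

# Temperature-corrected parameter values at a given leaf temperature.
# Returns a list with vcmax, jmax, rd, kc, ko, gammastar, km.
.t_params <- function(params, tleaf) {
  gammastar <- arrhenius(params$gammastar25, params$ea_gammastar, tleaf)
  kc <- arrhenius(params$kc25, params$ea_kc, tleaf)
  ko <- arrhenius(params$ko25, params$ea_ko, tleaf)
  km <- kc * (1 + params$oi / ko)
  if (params$tcorrect) {
    vcmax <- arrhenius(params$vcmax25, params$ea_vcmax, tleaf,
                       params$hd_vcmax, params$ds_vcmax)
    jmax <- arrhenius(params$jmax25, params$ea_jmax, tleaf,
                      params$hd_jmax, params$ds_jmax)
    rd <- arrhenius(params$rd25, params$ea_rd, tleaf)
  } else {
    vcmax <- rep_len(params$vcmax25, length(tleaf))
    jmax <- rep_len(params$jmax25, length(tleaf))
    rd <- rep_len(params$rd25, length(tleaf))
  }
  list(vcmax = vcmax, jmax = jmax, rd = rd, kc = kc, ko = ko,
       gammastar = gammastar, km = km)
}
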