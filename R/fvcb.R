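# The biochemical demand side: FvCB C3 photosynthesis as a function of CO2.

#' Electron transport rate from irradiance
#'
#' Non-rectangular hyperbola light response of whole-chain electron
#' transport: `j` is the smaller root of
#' \eqn{\theta J^2 - (\alpha Q + J_{max}) J + \alpha Q J_{max} = 0},
#' which rises with quantum yield `alpha` at low light and saturates at
#' `jmax`.
#'
#' @param par Photosynthetically active radiation, umol m-2 s-1 (>= 0).
#' @param jmax Maximum electron transport rate at the current leaf
#'   temperature, umol m-2 s-1.
#' @param alpha Quantum yield, mol electrons mol-1 photons.
#' @param theta_j Curvature parameter in (0, 1].
#' @return Electron transport rate, umol m-2 s-1.
#' @export
electron_transport <- function(par, jmax, alpha = 0.24, theta_j = 0.85) {
  if (any(par < 0)) stop("'par' must be non-negative", call. = FALSE)
  aq <- alpha * par
  disc <- pmax((aq + jmax)^2 - 4 * theta_j * aq * jmax, 0)
  (aq + jmax - sqrt(disc)) / (2 * theta_j)
}

#' Gross CO2-limited assimilation rate
#'
#' The common saturating form shared by the Rubisco-limited and
#' RuBP-regeneration-limited rates: `k1 * (cc - gammastar) / (k2 + cc)`.
#' For the Rubisco-limited rate `k1 = Vcmax`, `k2 = Km`; for the
#' RuBP-limited rate `k1 = J/4`, `k2 = 2 * GammaStar`.
#'
#' @param cc Chloroplastic (or intercellular) CO2, umol mol-1 (>= 0).
#' @param k1 Capacity parameter, umol m-2 s-1.
#' @param k2 Half-saturation parameter, umol mol-1 (> 0).
#' @param gammastar CO2 compensation point without Rd, umol mol-1.
#' @return Gross assimilation rate, umol m-2 s-1.
#' @export
gross_limited_rate <- function(cc, k1, k2, gammastar) {
  if (any(cc < 0)) stop("'cc' must be non-negative", call. = FALSE)
  if (any(k2 <= 0)) stop("'k2' must be positive", call. = FALSE)
  k1 * (cc - gammastar) / (k2 + cc)
}

#' Hyperbolic minimum of two rates
#'
#' Smooth minimum used in place of `min(ac, aj)` when fitting and
#' simulating, to avoid the derivative discontinuity at the transition:
#' the smaller root of \eqn{\theta A_m^2 - (A_c + A_j) A_m + A_c A_j = 0}.
#' With the default shape `theta = 0.9999` the result is within about 1% of
#' the strict minimum at the transition itself and indistinguishable away
#' from it; as `theta` approaches 1 it converges to `min(ac, aj)`.
#'
#' @param ac,aj The two rates, umol m-2 s-1.
#' @param theta Shape parameter in (0, 1].
#' @return The smoothed minimum; always `<= min(ac, aj)`.
#' @export
hyperbolic_min <- function(ac, aj, theta = 0.9999) {
  if (any(theta <= 0) || any(theta > 1))
    stop("'theta' must be in (0, 1]", call. = FALSE)
  disc <- pmax((ac + aj)^2 - 4 * theta * ac * aj, 0)
  (ac + aj - sqrt(disc)) / (2 * theta)
}

# Ethier-Livingston style analytic solution of the pair
#   {An = k1 (Cc - gammastar)/(k2 + Cc) - rd, Cc = ci - An/gm}
# per limitation: quadratic in the net rate An; the lower root is the
# physical one (An <= value at Cc = ci, i.e. Cc <= ci).
.net_rate_gm <- function(ci, gm, k1, k2, gammastar, rd) {
  b <- k1 - rd + gm * (ci + k2)
  cc <- gm * (k1 * (ci - gammastar) - rd * (ci + k2))
  disc <- pmax(b^2 - 4 * cc, 0)
  (b - sqrt(disc)) / 2
}

#' FvCB demand function: assimilation at given intercellular CO2
#'
#' Evaluates the temperature-corrected FvCB model of C3 photosynthesis at
#' one or more intercellular CO2 mole fractions. Net assimilation is the
#' hyperbolic minimum of the Rubisco-limited and RuBP-regeneration-limited
#' gross rates minus day respiration. With a finite mesophyll conductance
#' `gm` in `params`, each limitation is solved analytically for the net rate
#' consistent with `Cc = Ci - An/gm` (a quadratic in An) before the
#' hyperbolic minimum is taken, so the returned rates are chloroplastic.
#'
#' @param ci Intercellular CO2 mole fraction(s), umol mol-1 (>= 0).
#' @param params A [biochem_params()] object.
#' @param tleaf Leaf temperature, degC (recycled along `ci`).
#' @param par Irradiance, umol m-2 s-1 (recycled along `ci`).
#' @return A data frame with one row per `ci`: `an` (net), `ac`, `aj`, `am`
#'   (gross rates), `j`, `vcmax`, `jmax`, `rd` (temperature-corrected),
#'   `km`, `gammastar`, `ci` and `cc`.
#' @examples
#' aci_demand(c(100, 300, 800), biochem_params(), tleaf = 25, par = 1500)
#' @export
aci_demand <- function(ci, params = biochem_params(), tleaf = 25,
                       par = 1800) {
  as.data.frame(.demand_core(ci, params, tleaf, par))
}

# Core demand computation as a plain list of vectors (no data frame
# overhead), for the inner loops of the root solvers and optimizers.
.demand_core <- function(ci, params, tleaf, par) {
  if (any(!is.finite(ci)) || any(ci < 0))
    stop("'ci' must be finite and non-negative", call. = FALSE)
  n <- length(ci)
  tleaf <- rep_len(tleaf, n)
  par <- rep_len(par, n)
  tp <- .t_params(params, tleaf)
  j <- electron_transport(par, tp$jmax, params$alpha, params$theta_j)
  if (is.infinite(params$gm)) {
    cc <- ci
    ac <- gross_limited_rate(cc, tp$vcmax, tp$km, tp$gammastar)
    aj <- gross_limited_rate(cc, j / 4, 2 * tp$gammastar, tp$gammastar)
  } else {
    ac <- .net_rate_gm(ci, params$gm, tp$vcmax, tp$km, tp$gammastar,
                       tp$rd) + tp$rd
    aj <- .net_rate_gm(ci, params$gm, j / 4, 2 * tp$gammastar,
                       tp$gammastar, tp$rd) + tp$rd
  }
  am <- hyperbolic_min(ac, aj, params$theta_hmin)
  an <- am - tp$rd
  cc <- if (is.infinite(params$gm)) ci else ci - an / params$gm
  list(an = an, ac = ac, aj = aj, am = am, j = j,
       vcmax = tp$vcmax, jmax = tp$jmax, rd = tp$rd,
       km = tp$km, gammastar = tp$gammastar, ci = ci, cc = cc)
}

.demand_an <- function(ci, params, tleaf, par) {
  .demand_core(ci, params, tleaf, par)$an
}
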