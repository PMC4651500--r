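# C4 photosynthesis (simulation only; no C4 fitting is provided).

#' C4 photosynthesis parameter set
#'
#' Parameters of the enzyme-limited and light-limited C4 model with bundle
#' sheath conductance. Enzyme rates (Vcmax, Vpmax, Rd) follow a simple Q10
#' temperature scaling; the model is intended for simulation of A-Ci
#' responses, not for fitting.
#'
#' @param vcmax25 Rubisco capacity of the bundle sheath, umol m-2 s-1.
#' @param vpmax25 Maximum PEP carboxylation rate, umol m-2 s-1.
#' @param vpr PEP regeneration limited rate, umol m-2 s-1.
#' @param jmax25 Maximum whole-chain electron transport, umol m-2 s-1.
#' @param kp25 Michaelis constant of PEP carboxylase for CO2, umol mol-1.
#' @param kc25 Rubisco Michaelis constant for CO2, umol mol-1.
#' @param ko25 Rubisco Michaelis constant for O2, mmol mol-1.
#' @param oi O2 mole fraction, mmol mol-1.
#' @param gbs Bundle sheath conductance to CO2, mol m-2 s-1.
#' @param rd25 Leaf mitochondrial respiration, umol m-2 s-1.
#' @param rm_frac Fraction of `rd25` occurring in the mesophyll.
#' @param x_j Partitioning of electron transport to PEP regeneration.
#' @param sco Rubisco CO2/O2 specificity (used for the bundle-sheath
#'   compensation point `0.5 * Oi / sco`).
#' @param alpha_j,theta_j Light-response parameters of electron transport.
#' @param q10 Q10 of the enzyme rates.
#' @return An object of class `"c4_params"`.
#' @export
c4_params <- function(vcmax25 = 60, vpmax25 = 120, vpr = 80, jmax25 = 400,
                      kp25 = 80, kc25 = 650, ko25 = 450, oi = 210,
                      gbs = 0.003, rd25 = 1, rm_frac = 0.5, x_j = 0.4,
                      sco = 2590, alpha_j = 0.385, theta_j = 0.7,
                      q10 = 2) {
  p <- as.list(environment())
  for (nm in c("vcmax25", "vpmax25", "vpr", "jmax25", "kp25", "kc25",
               "ko25", "oi", "gbs", "rd25"))
    if (!is.numeric(p[[nm]]) || p[[nm]] < 0)
      stop("'", nm, "' must be non-negative", call. = FALSE)
  if (gbs <= 0) stop("'gbs' must be positive", call. = FALSE)
  structure(p, class = "c4_params")
}

# Net rate from the bundle-sheath supply/demand quadratic:
#   An + Rd = k1 (Cs - gs_star)/(Cs + k2),  Cs = u - An/gbs,
#   u = Cm + (Vp - Rm)/gbs.
.c4_quad <- function(u, gbs, k1, k2, gs_star, rd) {
  b <- k1 - rd + gbs * (u + k2)
  cc <- gbs * (k1 * (u - gs_star) - rd * (u + k2))
  disc <- pmax(b^2 - 4 * cc, 0)
  (b - sqrt(disc)) / 2
}

#' C4 assimilation as a function of intercellular CO2
#'
#' Simulates the net C4 assimilation rate as the minimum of an
#' enzyme-limited rate (PEP carboxylation feeding Rubisco in the bundle
#' sheath, with leakage through the bundle sheath conductance) and a
#' light-limited rate (electron transport partitioned between PEP
#' regeneration and the C3 cycle). Mesophyll CO2 is taken equal to `ci`.
#'
#' @param ci Intercellular CO2 mole fraction(s), umol mol-1 (>= 0).
#' @param params A [c4_params()] object.
#' @param tleaf Leaf temperature, degC.
#' @param par Irradiance, umol m-2 s-1.
#' @return Data frame with `an`, the limitation-specific net rates
#'   `a_enzyme` and `a_light`, the PEP carboxylation rate `vp`, and `ci`.
#' @export
aci_c4 <- function(ci, params = c4_params(), tleaf = 25, par = 1800) {
  if (!inherits(params, "c4_params"))
    stop("'params' must be a c4_params() object", call. = FALSE)
  if (any(!is.finite(ci)) || any(ci < 0))
    stop("'ci' must be finite and non-negative", call. = FALSE)
  n <- length(ci)
  tleaf <- rep_len(tleaf, n)
  par <- rep_len(par, n)
  q10f <- params$q10^((tleaf - 25) / 10)
  vcmax <- params$vcmax25 * q10f
  vpmax <- params$vpmax25 * q10f
  rd <- params$rd25 * q10f
  rm <- params$rm_frac * rd
  km <- params$kc25 * (1 + params$oi / params$ko25)
  gs_star <- 0.5 * (params$oi * 1000) / params$sco  # umol mol-1
  jt <- electron_transport(par, params$jmax25, params$alpha_j,
                           params$theta_j)

  # enzyme-limited: saturating PEP supply, Rubisco demand in the sheath
  vp <- pmin(ci * vpmax / (ci + params$kp25), params$vpr)
  u_enz <- ci + (vp - rm) / params$gbs
  a_enz <- .c4_quad(u_enz, params$gbs, vcmax, km, gs_star, rd)

  # light-limited: electron transport split between PEP (x_j) and C3 cycle
  vp_j <- params$x_j * jt / 2
  vj <- (1 - params$x_j) * jt / 3
  u_j <- ci + (vp_j - rm) / params$gbs
  a_light <- .c4_quad(u_j, params$gbs, vj, 7 * gs_star / 3, gs_star, rd)

  data.frame(an = pmin(a_enz, a_light), a_enzyme = a_enz,
             a_light = a_light, vp = vp, ci = ci)
}
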