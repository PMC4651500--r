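# Synthetic gas-exchange data with known truth, for testing the fitting
# workflow end to end.

#' Simulate an A-Ci curve with known truth
#'
#' Generates net assimilation from the FvCB demand function at a grid of
#' intercellular CO2 values and adds Gaussian noise to the response only
#' (no error in Ci), matching the error model assumed by the nonlinear
#' least-squares fitters. The default design is 12 Ci points spanning
#' 40-1500 umol mol-1 at 25 degC and saturating light, with an instrument-
#' scale noise of 0.5 umol m-2 s-1. Default capacities (Vcmax 47, Jmax 105,
#' Rd 1.3) are typical of temperate broadleaf A-Ci measurements.
#'
#' @param vcmax,jmax,rd True parameter values at 25 degC, umol m-2 s-1.
#' @param gm True mesophyll conductance, mol m-2 s-1, or `NULL` (infinite).
#' @param ci Ci design points, umol mol-1.
#' @param tleaf Leaf temperature, degC (recycled).
#' @param par Irradiance, umol m-2 s-1 (recycled).
#' @param noise_sd Standard deviation of the additive noise on An,
#'   umol m-2 s-1.
#' @param seed Optional integer seed for reproducibility.
#' @param curve_id Curve label written to the `Curve` column.
#' @param params Base kinetic constants, see [biochem_params()].
#' @return Data frame with analyser-style columns `Curve`, `Ci`, `Photo`,
#'   `Tleaf`, `PARi`. The generating truth is attached as
#'   `attr(, "truth")` and the noiseless response as `attr(, "an_true")`.
#' @examples
#' curve <- simulate_aci(seed = 42)
#' attr(curve, "truth")
#' @export
simulate_aci <- function(vcmax = 47, jmax = 105, rd = 1.3, gm = NULL,
                         ci = c(40, 60, 90, 130, 180, 250, 340, 450,
                                600, 800, 1100, 1500),
                         tleaf = 25, par = 1800, noise_sd = 0.5,
                         seed = NULL, curve_id = "1",
                         params = biochem_params()) {
  if (noise_sd < 0) stop("'noise_sd' must be non-negative", call. = FALSE)
  if (length(ci) == 0L) stop("'ci' design must be non-empty", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  p <- params
  p$vcmax25 <- vcmax
  p$jmax25 <- jmax
  p$rd25 <- rd
  p$gm <- if (is.null(gm) || !is.finite(gm)) Inf else gm
  n <- length(ci)
  tleaf <- rep_len(tleaf, n)
  par <- rep_len(par, n)
  an_true <- aci_demand(ci, p, tleaf = tleaf, par = par)$an
  out <- data.frame(Curve = curve_id, Ci = ci,
                    Photo = an_true + stats::rnorm(n, 0, noise_sd),
                    Tleaf = tleaf, PARi = par, stringsAsFactors = FALSE)
  attr(out, "truth") <- list(vcmax = vcmax, jmax = jmax, rd = rd,
                             gm = p$gm, noise_sd = noise_sd)
  attr(out, "an_true") <- an_true
  out
}

#' Simulate spot gas-exchange data with known truth
#'
#' Generates single-point ("spot") gas-exchange records across a wide range
#' of environmental conditions: drivers are sampled uniformly from the given
#' ranges, net assimilation and stomatal conductance come from the coupled
#' model ([photosyn()]) under the stated stomatal-model truth, and Gaussian
#' noise is added to the observed conductance only. At `noise_sd = 0` the
#' corresponding [fit_bb()] variant recovers the truth exactly.
#'
#' @param n Number of records.
#' @param model,g0,g1,d0 True stomatal model and parameters, see
#'   [gs_predict()].
#' @param noise_sd Standard deviation of the additive noise on gs,
#'   mol m-2 s-1.
#' @param par_range,tleaf_range,d_range,ca_range Uniform sampling ranges of
#'   the drivers (umol m-2 s-1, degC, kPa, umol mol-1).
#' @param seed Optional integer seed.
#' @param params Biochemical truth for the coupled model.
#' @return Data frame with analyser-style columns `Photo`, `Cond`, `CO2S`,
#'   `VpdL`, `Tleaf`, `PARi`, `RH_S`; the truth is attached as
#'   `attr(, "truth")` and the noiseless conductance as `attr(, "gs_true")`.
#' @examples
#' spot <- simulate_spot(n = 30, seed = 7)
#' attr(spot, "truth")
#' @export
simulate_spot <- function(n = 50, model = "medlyn", g0 = 0, g1 = 4,
                          d0 = 1.5, noise_sd = 0.02,
                          par_range = c(200, 2000),
                          tleaf_range = c(15, 35), d_range = c(0.5, 3.5),
                          ca_range = c(380, 420), seed = NULL,
                          params = biochem_params()) {
  if (noise_sd < 0) stop("'noise_sd' must be non-negative", call. = FALSE)
  if (n < 1L) stop("'n' must be at least 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  par <- stats::runif(n, par_range[1], par_range[2])
  tleaf <- stats::runif(n, tleaf_range[1], tleaf_range[2])
  d <- stats::runif(n, d_range[1], d_range[2])
  ca <- stats::runif(n, ca_range[1], ca_range[2])
  sol <- photosyn(par = par, tleaf = tleaf, vpd = d, ca = ca,
                  params = params, gs_model = model, g0 = g0, g1 = g1,
                  d0 = d0)
  out <- data.frame(Photo = sol$an,
                    Cond = sol$gs + stats::rnorm(n, 0, noise_sd),
                    CO2S = ca, VpdL = d, Tleaf = tleaf, PARi = par,
                    RH_S = vpd_to_rh(pmin(d, esat(tleaf)), tleaf),
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- list(model = model, g0 = g0, g1 = g1, d0 = d0,
                             noise_sd = noise_sd)
  attr(out, "gs_true") <- sol$gs
  out
}
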