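# Coupled leaf gas exchange: intersection of the FvCB demand function, the
# diffusion supply function, and a stomatal conductance model.

#' CO2 supply function
#'
#' Diffusion of CO2 through the stomata:
#' `an = (gs / 1.6) * (ca - ci)`, where the factor 1.6 converts stomatal
#' conductance to H2O into conductance to CO2.
#'
#' @param gs Stomatal conductance to H2O, mol m-2 s-1 (>= 0).
#' @param ca Ambient CO2, umol mol-1.
#' @param ci Intercellular CO2, umol mol-1.
#' @return Net CO2 flux, umol m-2 s-1 (linear, decreasing in `ci`).
#' @export
supply_an <- function(gs, ca, ci) {
  if (any(gs < 0)) stop("'gs' must be non-negative", call. = FALSE)
  (gs / 1.6) * (ca - ci)
}

# Solve demand(ci) = supply(ci) for one set of drivers. Returns the ci root
# or NA when no steady state exists (e.g. g0 = 0 in darkness).
.solve_ci <- function(h, ca) {
  lo <- 1e-6
  hi <- ca
  flo <- h(lo)
  fhi <- h(hi)
  while (fhi < 0 && hi < 20 * ca) {   # night-time: Ci may exceed Ca
    hi <- hi * 2
    fhi <- h(hi)
  }
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) return(NA_real_)
  stats::uniroot(h, c(lo, hi), tol = 1e-12)$root
}

# One-row coupled solution. gs_fun(an) must return stomatal conductance to
# H2O; supply_fun(gs, ci) the matching CO2 flux.
.photosyn_row <- function(par, tleaf, d, ca, pa, params, gs_fun,
                          mode) {
  h <- function(x) {
    a <- .demand_an(x, params, tleaf, par)
    a - supply_an(gs_fun(a), ca, x)
  }
  ci <- .solve_ci(h, ca)
  if (is.na(ci)) {
    return(data.frame(an = NA_real_, gs = NA_real_, e = NA_real_,
                      ci = NA_real_, cc = NA_real_, ac = NA_real_,
                      aj = NA_real_, rd = NA_real_, tleaf = tleaf,
                      par = par, vpd = d, ca = ca, ite = NA_real_,
                      mode = mode, converged = FALSE,
                      stringsAsFactors = FALSE))
  }
  dem <- .demand_core(ci, params, tleaf, par)
  gs <- gs_fun(dem$an)
  e <- 1000 * gs * d / pa   # perfect coupling, mmol m-2 s-1
  data.frame(an = dem$an, gs = gs, e = e, ci = ci, cc = dem$cc,
             ac = dem$ac, aj = dem$aj, rd = dem$rd, tleaf = tleaf,
             par = par, vpd = d, ca = ca,
             ite = if (e > 0) dem$an / e else NA_real_,
             mode = mode, converged = TRUE, stringsAsFactors = FALSE)
}

#' Coupled leaf gas exchange model
#'
#' Solves the steady-state leaf CO2 budget. Three modes, chosen by which
#' argument is supplied:
#' \describe{
#'   \item{`ci` given}{evaluates the FvCB demand function directly and
#'     back-computes the stomatal conductance that would sustain it.}
#'   \item{`gs` given}{solves `demand(ci) = supply(gs, ca, ci)` for the
#'     intercellular CO2.}
#'   \item{neither}{full coupling: stomatal conductance follows a
#'     Ball-Berry-type model ([gs_predict()]) of the assimilation rate it
#'     itself controls, and the three equations (demand, supply, gs model)
#'     are solved simultaneously by a bracketed root search in `ci`.}
#' }
#' Transpiration assumes perfect coupling to the atmosphere
#' (`e = gs * d / pa`, reported in mmol m-2 s-1); leaf temperature equals
#' the supplied `tleaf`. See [photosyn_eb()] for the energy-balance variant.
#'
#' When the demand is negative everywhere (darkness), stomatal conductance
#' falls back to `g0` and Ci rises above Ca; with `g0 = 0` no steady state
#' exists and the row is returned unconverged with `NA`s.
#'
#' All driver arguments are vectorised (recycled to the longest).
#'
#' @param ci Optional intercellular CO2, umol mol-1.
#' @param gs Optional stomatal conductance to H2O, mol m-2 s-1.
#' @param par Irradiance, umol m-2 s-1.
#' @param tleaf Leaf temperature, degC.
#' @param vpd Vapour pressure deficit, kPa. Values below `vpd_floor` are
#'   clamped (with a warning): the medlyn humidity response diverges as
#'   D approaches 0.
#' @param ca Ambient CO2, umol mol-1.
#' @param pa Atmospheric pressure, kPa.
#' @param rh Relative humidity, percent; computed from `vpd` and `tleaf`
#'   when needed and not given.
#' @param params A [biochem_params()] object.
#' @param gs_model,g0,g1,d0 Stomatal model and parameters, see
#'   [gs_predict()].
#' @param vpd_floor Lower bound applied to `vpd`, kPa.
#' @return A data frame with one row per driver combination: `an`, `gs`,
#'   `e` (mmol m-2 s-1), `ci`, `cc`, gross `ac` and `aj`, `rd`, the drivers,
#'   `ite` (umol mmol-1), `mode` and a `converged` flag.
#' @examples
#' photosyn(vpd = c(1, 2, 3))
#' photosyn(ci = 275)
#' photosyn(gs = 0.15)
#' @export
photosyn <- function(ci = NULL, gs = NULL, par = 1800, tleaf = 25,
                     vpd = 1.5, ca = 400, pa = 101.3, rh = NULL,
                     params = biochem_params(), gs_model = "medlyn",
                     g0 = 0, g1 = 4, d0 = 1.5, vpd_floor = 0.05) {
  n <- max(length(ci), length(gs), length(par), length(tleaf),
           length(vpd), length(ca), length(pa),
           if (is.null(rh)) 0 else length(rh))
  par <- rep_len(par, n); tleaf <- rep_len(tleaf, n)
  vpd <- rep_len(vpd, n); ca <- rep_len(ca, n); pa <- rep_len(pa, n)
  if (any(vpd < vpd_floor)) {
    warning("vpd below ", vpd_floor, " kPa clamped to the floor",
            call. = FALSE)
    vpd <- pmax(vpd, vpd_floor)
  }
  if (is.null(rh)) rh <- vpd_to_rh(pmin(vpd, esat(tleaf)), tleaf)
  else rh <- rep_len(rh, n)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    if (!is.null(ci)) {
      x <- rep_len(ci, n)[i]
      dem <- aci_demand(x, params, tleaf = tleaf[i], par = par[i])
      gsi <- if (x < ca[i]) 1.6 * dem$an / (ca[i] - x) else NA_real_
      ei <- if (is.finite(gsi) && gsi > 0)
        1000 * gsi * vpd[i] / pa[i] else NA_real_
      rows[[i]] <- data.frame(an = dem$an, gs = gsi, e = ei, ci = x,
                              cc = dem$cc, ac = dem$ac, aj = dem$aj,
                              rd = dem$rd, tleaf = tleaf[i], par = par[i],
                              vpd = vpd[i], ca = ca[i],
                              ite = if (is.finite(ei) && ei > 0)
                                dem$an / ei else NA_real_,
                              mode = "ci_given", converged = TRUE,
                              stringsAsFactors = FALSE)
    } else if (!is.null(gs)) {
      gsi <- rep_len(gs, n)[i]
      if (gsi < 0) stop("'gs' must be non-negative", call. = FALSE)
      rows[[i]] <- .photosyn_row(par[i], tleaf[i], vpd[i], ca[i], pa[i],
                                 params, gs_fun = function(a) gsi,
                                 mode = "gs_given")
      if (gsi == 0) {  # supply is identically 0: an = 0 at the root
        rows[[i]]$gs <- 0
        rows[[i]]$e <- 0
        rows[[i]]$ite <- NA_real_
      }
    } else {
      gf <- local({
        cai <- ca[i]; di <- vpd[i]; rhi <- rh[i]
        function(a) max(g0, gs_predict(a, cai, gs_model, g0 = g0, g1 = g1,
                                       d = di, rh = rhi, d0 = d0))
      })
      rows[[i]] <- .photosyn_row(par[i], tleaf[i], vpd[i], ca[i], pa[i],
                                 params, gs_fun = gf, mode = "coupled")
    }
  }
  out <- do.call(rbind, rows)
  if (any(!out$converged))
    warning(sum(!out$converged),
            " driver combination(s) had no steady state (returned NA)",
            call. = FALSE)
  rownames(out) <- NULL
  out
}
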