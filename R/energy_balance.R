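# Leaf energy balance: Penman-Monteith transpiration and iterative leaf
# temperature solution.

.CP_MOL <- 29.3  # molar heat capacity of air, J mol-1 K-1

# Latent heat of vaporisation, J mol-1, at air temperature (degC)
.lambda_mol <- function(tair) (2501 - 2.365 * tair) * 18.015

#' Penman-Monteith leaf transpiration
#'
#' Combination-equation estimate of leaf transpiration from available
#' energy, vapour pressure deficit and the stomatal and boundary-layer
#' conductances:
#' \deqn{\lambda E = \frac{s R_n + c_p g_h D}{s + \gamma g_h / g_w}}
#' where `s` is the slope of the saturation vapour pressure curve at air
#' temperature (kPa K-1), `cp` the molar heat capacity of air,
#' \eqn{\gamma = c_p P_a / \lambda} the psychrometric constant (kPa K-1),
#' `gh` the conductance to heat and `gw` the total conductance to water
#' vapour (stomata and boundary layer in series). In the limit of an
#' infinite boundary layer with no radiative forcing this reduces to the
#' imposed rate `E = gs * d / pa`.
#'
#' @param rnet Net absorbed radiation, W m-2.
#' @param d Vapour pressure deficit of the air, kPa.
#' @param tair Air temperature, degC.
#' @param gs Stomatal conductance to H2O, mol m-2 s-1 (>= 0).
#' @param gbl Boundary-layer conductance to H2O, mol m-2 s-1 (> 0).
#' @param pa Atmospheric pressure, kPa.
#' @param gh Conductance to heat, mol m-2 s-1; defaults to `gbl`.
#' @return Transpiration rate, mmol m-2 s-1 (never negative).
#' @export
penman_monteith <- function(rnet, d, tair, gs, gbl, pa = 101.3, gh = gbl) {
  if (any(gbl <= 0)) stop("'gbl' must be positive", call. = FALSE)
  if (any(gs < 0)) stop("'gs' must be non-negative", call. = FALSE)
  s <- .esat_slope(tair)
  lam <- .lambda_mol(tair)
  gamma <- .CP_MOL * pa / lam
  gw <- ifelse(gs > 0, 1 / (1 / gs + 1 / gbl), 0)
  le <- ifelse(gw > 0,
               (s * rnet + .CP_MOL * gh * d) / (s + gamma * gh / gw),
               0)
  pmax(1000 * le / lam, 0)
}

#' Leaf boundary-layer conductance to heat
#'
#' Forced-convection flat-plate estimate from wind speed and leaf width:
#' `0.003 * sqrt(wind / leaf_width)` in velocity units (m s-1), converted
#' to molar units with the molar density of air `pa * 1000 / (R * T)`.
#' At 2 m s-1 over a 5 cm leaf this gives about 0.78 mol m-2 s-1 per leaf
#' side.
#'
#' @param wind Wind speed, m s-1 (> 0).
#' @param leaf_width Leaf width, m (> 0).
#' @param tair Air temperature, degC.
#' @param pa Atmospheric pressure, kPa.
#' @return Boundary-layer conductance to heat, one-sided, mol m-2 s-1.
#' @export
boundary_layer_conductance <- function(wind, leaf_width = 0.05, tair = 25,
                                       pa = 101.3) {
  if (any(wind <= 0) || any(leaf_width <= 0))
    stop("'wind' and 'leaf_width' must be positive", call. = FALSE)
  cmolar <- 1000 * pa / (.RGAS * (tair + 273.15))
  0.003 * sqrt(wind / leaf_width) * cmolar
}

#' Coupled gas exchange with leaf energy balance
#'
#' Like [photosyn()] in coupled mode, but leaf temperature is not imposed:
#' it is solved from the leaf energy balance
#' \eqn{R_n = \lambda E + c_p g_h (T_{leaf} - T_{air})}, with transpiration
#' from [penman_monteith()] (so a finite boundary layer decouples the leaf
#' from the air) and CO2 diffusing through the boundary layer (factor 1.37)
#' and stomata (factor 1.6) in series. The humidity signal of the stomatal
#' model is the air vapour pressure deficit. Iteration stops when the leaf
#' temperature update falls below `tol` (degC); the closure residual
#' `rnet - lambda*E - H` is reported.
#'
#' @inheritParams photosyn
#' @param tair Air temperature, degC.
#' @param wind Wind speed, m s-1.
#' @param leaf_width Leaf width, m.
#' @param rnet Net absorbed radiation, W m-2; default `0.15 * par` is a
#'   crude shortwave conversion - supply a measured or modelled value
#'   whenever available.
#' @param max_iter Maximum number of leaf-temperature iterations.
#' @param tol Convergence tolerance on the leaf temperature update, degC.
#' @return Data frame as in [photosyn()], plus `tair`, `eb_residual`
#'   (W m-2), `iterations` and `eb_converged`. `e` is the Penman-Monteith
#'   rate (mmol m-2 s-1).
#' @examples
#' photosyn_eb(par = 1500, tair = 25, vpd = 1.5, wind = 2, rnet = 300)
#' @export
photosyn_eb <- function(par = 1800, tair = 25, vpd = 1.5, ca = 400,
                        pa = 101.3, wind = 2, leaf_width = 0.05,
                        rnet = NULL, params = biochem_params(),
                        gs_model = "medlyn", g0 = 0, g1 = 4, d0 = 1.5,
                        vpd_floor = 0.05, max_iter = 50, tol = 0.01) {
  if (any(wind <= 0) || any(leaf_width <= 0))
    stop("'wind' and 'leaf_width' must be positive", call. = FALSE)
  n <- max(length(par), length(tair), length(vpd), length(ca), length(pa),
           length(wind), length(leaf_width),
           if (is.null(rnet)) 0 else length(rnet))
  par <- rep_len(par, n); tair <- rep_len(tair, n)
  vpd <- pmax(rep_len(vpd, n), vpd_floor); ca <- rep_len(ca, n)
  pa <- rep_len(pa, n); wind <- rep_len(wind, n)
  leaf_width <- rep_len(leaf_width, n)
  rnet <- if (is.null(rnet)) 0.15 * par else rep_len(rnet, n)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    gbh <- boundary_layer_conductance(wind[i], leaf_width[i], tair[i],
                                      pa[i])
    gbv <- 1.075 * gbh     # one-sided vapour conductance
    gh <- 2 * gbh          # heat is exchanged from both leaf sides
    rhi <- vpd_to_rh(min(vpd[i], esat(tair[i])), tair[i])
    gs_fun <- local({
      cai <- ca[i]; di <- vpd[i]
      function(a) max(g0, gs_predict(a, cai, gs_model, g0 = g0, g1 = g1,
                                     d = di, rh = rhi, d0 = d0))
    })
    tleaf <- tair[i]
    ok <- FALSE
    iter <- 0L
    sol <- NULL
    while (iter < max_iter) {
      iter <- iter + 1L
      # coupled CO2 solve at the current leaf temperature, with the
      # boundary layer in the diffusion path
      h <- function(x) {
        a <- .demand_an(x, params, tleaf, par[i])
        gsx <- gs_fun(a)
        gc <- if (gsx > 0) 1 / (1.6 / gsx + 1.37 / gbv) else 0
        a - gc * (ca[i] - x)
      }
      cii <- .solve_ci(h, ca[i])
      if (is.na(cii)) break
      an <- .demand_an(cii, params, tleaf, par[i])
      gsi <- gs_fun(an)
      e_pm <- penman_monteith(rnet[i], vpd[i], tair[i], gsi, gbv, pa[i],
                              gh = gh)
      le <- e_pm / 1000 * .lambda_mol(tair[i])
      sol <- list(ci = cii, an = an, gs = gsi, e = e_pm, le = le)
      tleaf_new <- tair[i] + (rnet[i] - le) / (.CP_MOL * gh)
      delta <- tleaf_new - tleaf
      tleaf <- tleaf_new
      if (abs(delta) < tol) {
        ok <- TRUE
        break
      }
    }
    if (is.null(sol)) {
      rows[[i]] <- data.frame(an = NA_real_, gs = NA_real_, e = NA_real_,
                              ci = NA_real_, tleaf = tleaf,
                              tair = tair[i], par = par[i], vpd = vpd[i],
                              ca = ca[i], rnet = rnet[i],
                              eb_residual = NA_real_, iterations = iter,
                              mode = "coupled_eb",
                              converged = FALSE, eb_converged = FALSE,
                              stringsAsFactors = FALSE)
    } else {
      hflux <- .CP_MOL * gh * (tleaf - tair[i])
      rows[[i]] <- data.frame(an = sol$an, gs = sol$gs, e = sol$e,
                              ci = sol$ci, tleaf = tleaf, tair = tair[i],
                              par = par[i], vpd = vpd[i], ca = ca[i],
                              rnet = rnet[i],
                              eb_residual = rnet[i] - sol$le - hflux,
                              iterations = iter, mode = "coupled_eb",
                              converged = TRUE, eb_converged = ok,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (any(!out$eb_converged))
    warning(sum(!out$eb_converged),
            " row(s) did not reach energy-balance convergence",
            call. = FALSE)
  rownames(out) <- NULL
  out
}
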