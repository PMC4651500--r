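# Numerical optimal stomatal behaviour: the Ci maximizing An - lambda * E
# (Cowan-Farquhar water-cost hypothesis).

#' Cowan-Farquhar objective
#'
#' The quantity maximised by optimal stomata: net assimilation minus the
#' water cost of sustaining it, `an - lambda * E`, evaluated at a candidate
#' intercellular CO2. Assimilation comes from the FvCB demand function, the
#' stomatal conductance from the rearranged supply function
#' `gs = 1.6 * an / (ca - ci)` (clamped at zero when demand is negative),
#' and transpiration from perfect coupling `E = gs * d / pa` (mol m-2 s-1).
#' `lambda` is in mol C mol-1 H2O, so the cost term is scaled by 1e6 to
#' match `an` in umol m-2 s-1.
#'
#' @param ci Candidate intercellular CO2, umol mol-1 (must be `< ca`).
#' @param par,tleaf,vpd,ca,pa Environmental drivers as in [photosyn()].
#' @param params A [biochem_params()] object.
#' @param lambda Marginal cost of water, mol C mol-1 H2O.
#' @return Objective value, umol m-2 s-1 (vectorised over `ci`).
#' @export
cowan_objective <- function(ci, par = 1800, tleaf = 25, vpd = 1.5,
                            ca = 400, pa = 101.3,
                            params = biochem_params(), lambda = 0.002) {
  if (any(ci >= ca)) stop("'ci' must be below 'ca'", call. = FALSE)
  if (lambda < 0) stop("'lambda' must be non-negative", call. = FALSE)
  an <- .demand_an(ci, params, tleaf, par)
  gs <- pmax(1.6 * an / (ca - ci), 0)
  e_mol <- gs * vpd / pa
  an - lambda * 1e6 * e_mol
}

#' Numerically optimal stomatal behaviour
#'
#' Finds the intercellular CO2 that maximises [cowan_objective()] by a
#' coarse grid scan over `[lower, upper]` followed by local refinement
#' (golden-section/parabolic search in the bracket around the best grid
#' point). Concavity is not assumed: the grid-first strategy resolves
#' multi-modal objectives. With `energy_balance = TRUE` each candidate
#' evaluates the leaf energy balance (leaf temperature from the closure,
#' transpiration from [penman_monteith()]); candidates that fail to
#' converge are marked invalid rather than aborting the search.
#'
#' @inheritParams cowan_objective
#' @param lambda Marginal cost of water, mol C mol-1 H2O.
#' @param lower,upper Search bounds on Ci, umol mol-1; defaults
#'   `[0.01 * ca, 0.999 * ca]` (the supply function is singular at
#'   `ci = ca`).
#' @param grid_n Number of grid points in the coarse scan.
#' @param energy_balance If `TRUE`, use the leaf energy balance.
#' @param tair,wind,leaf_width,rnet Energy-balance drivers (used when
#'   `energy_balance = TRUE`), see [photosyn_eb()].
#' @param refine_tol Absolute tolerance of the refinement in Ci,
#'   umol mol-1.
#' @return A one-row data frame: `ci_opt`, `an`, `gs`, `e` (mmol m-2 s-1),
#'   `objective`, `tleaf`, `interior_optimum` (FALSE when the maximum sits
#'   on a search bound) and `ok`.
#' @examples
#' optimal_stomata(vpd = 1.5, lambda = 0.002)
#' @export
optimal_stomata <- function(par = 1800, tleaf = 25, vpd = 1.5, ca = 400,
                            pa = 101.3, params = biochem_params(),
                            lambda = 0.002, lower = 0.01 * ca,
                            upper = 0.999 * ca, grid_n = 500,
                            energy_balance = FALSE, tair = tleaf,
                            wind = 2, leaf_width = 0.05, rnet = NULL,
                            refine_tol = 1e-4) {
  if (lower >= upper || upper > ca)
    stop("need lower < upper <= ca", call. = FALSE)
  if (energy_balance) {
    obj1 <- function(x) .eb_objective(x, par, tair, vpd, ca, pa, params,
                                      lambda, wind, leaf_width, rnet)
    obj <- function(x) vapply(x, obj1, numeric(1))
  } else {
    obj <- function(x) cowan_objective(x, par, tleaf, vpd, ca, pa, params,
                                       lambda)
  }
  grid <- seq(lower, upper, length.out = grid_n)
  val <- obj(grid)
  if (all(!is.finite(val)))
    stop("objective is non-finite across the whole search grid",
         call. = FALSE)
  k <- which.max(val)
  bracket <- c(grid[max(1L, k - 1L)], grid[min(grid_n, k + 1L)])
  ref <- stats::optimize(function(x) {
    v <- obj(x)
    if (!is.finite(v)) -Inf else v
  }, interval = bracket, maximum = TRUE, tol = refine_tol)
  ci_opt <- ref$maximum
  objective <- ref$objective
  if (val[k] > objective) {  # refinement never loses the grid maximum
    ci_opt <- grid[k]
    objective <- val[k]
  }
  interior <- k > 1L && k < grid_n &&
    ci_opt > lower + refine_tol && ci_opt < upper - refine_tol

  if (energy_balance) {
    st <- .eb_state(ci_opt, par, tair, vpd, ca, pa, params, wind,
                    leaf_width, rnet)
    an <- st$an; gs <- st$gs; e <- st$e; tl <- st$tleaf
    ok <- st$ok
  } else {
    an <- .demand_an(ci_opt, params, tleaf, par)
    gs <- max(1.6 * an / (ca - ci_opt), 0)
    e <- 1000 * gs * vpd / pa
    tl <- tleaf
    ok <- TRUE
  }
  data.frame(ci_opt = ci_opt, an = an, gs = gs, e = e,
             objective = objective, tleaf = tl, vpd = vpd, ca = ca,
             lambda = lambda, interior_optimum = interior, ok = ok,
             stringsAsFactors = FALSE)
}

# Energy-balance state at a candidate ci: iterate leaf temperature with
# gs fixed by the rearranged supply function at that ci.
.eb_state <- function(ci, par, tair, vpd, ca, pa, params, wind,
                      leaf_width, rnet, max_iter = 50, tol = 0.01) {
  gbh <- boundary_layer_conductance(wind, leaf_width, tair, pa)
  gbv <- 1.075 * gbh
  gh <- 2 * gbh
  if (is.null(rnet)) rnet <- 0.15 * par
  tleaf <- tair
  ok <- FALSE
  an <- gs <- e <- NA_real_
  for (iter in seq_len(max_iter)) {
    an <- .demand_an(ci, params, tleaf, par)
    gs <- max(1.6 * an / (ca - ci), 0)
    e <- penman_monteith(rnet, vpd, tair, gs, gbv, pa, gh = gh)
    le <- e / 1000 * .lambda_mol(tair)
    tleaf_new <- tair + (rnet - le) / (.CP_MOL * gh)
    delta <- tleaf_new - tleaf
    tleaf <- tleaf_new
    if (abs(delta) < tol) {
      ok <- TRUE
      break
    }
  }
  list(an = an, gs = gs, e = e, tleaf = tleaf, ok = ok)
}

.eb_objective <- function(ci, par, tair, vpd, ca, pa, params, lambda,
                          wind, leaf_width, rnet) {
  st <- .eb_state(ci, par, tair, vpd, ca, pa, params, wind, leaf_width,
                  rnet)
  if (!st$ok) return(NA_real_)
  st$an - lambda * 1e6 * (st$e / 1000)
}

#' Optimal stomatal response to vapour pressure deficit
#'
#' Sweeps [optimal_stomata()] over a vector of vapour pressure deficits,
#' returning one row per `d`. Rows where the optimum sits on a search bound
#' (or, in energy-balance mode, where no optimum can be found) are flagged
#' via `interior_optimum`/`ok`, not dropped.
#'
#' @param d Vapour pressure deficits, kPa (> 0).
#' @param ... Passed to [optimal_stomata()].
#' @return Data frame with one row per `d`.
#' @export
optimal_gs_vpd <- function(d, ...) {
  if (any(d <= 0)) stop("'d' must be positive", call. = FALSE)
  out <- do.call(rbind, lapply(d, function(di)
    optimal_stomata(vpd = di, ...)))
  rownames(out) <- NULL
  out
}
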