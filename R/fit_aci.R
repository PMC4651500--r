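# Nonlinear least-squares fitting of the FvCB model to A-Ci curves.

#' Starting values for an A-Ci fit
#'
#' Inverts the Rubisco-limited form on the lowest-Ci observations to get an
#' initial Vcmax, and the RuBP-regeneration-limited form on the highest-Ci
#' observations (followed by inversion of the light response) for an initial
#' Jmax. The initial Rd is a small fraction of the curve maximum.
#'
#' @param data Data frame with columns `an`, `ci` and optionally `tleaf`,
#'   `par` (logical names, or analyser names per `columns`).
#' @param params A [biochem_params()] object supplying kinetic constants.
#' @param columns Column mapping, see [gx_columns()].
#' @return Named numeric vector `c(vcmax, jmax, rd)`.
#' @export
estimate_starting_values <- function(data, params = biochem_params(),
                                     columns = gx_columns()) {
  d <- .normalize_columns(data, columns, required = c("an", "ci"),
                          defaults = list(tleaf = 25, par = 1800))
  if (nrow(d) < 5L)
    stop("at least 5 observations are needed to fit an A-Ci curve",
         call. = FALSE)
  if (length(unique(d$ci)) < 2L)
    stop("degenerate curve: all ci values identical", call. = FALSE)
  tp <- .t_params(params, d$tleaf)
  # negative assimilation near the compensation point is close to -Rd
  rd0 <- max(0.015 * max(d$an), -min(d$an), 1e-3)
  gross <- d$an + rd0
  usable <- gross > 0 & d$ci > tp$gammastar * 1.05
  if (!any(usable))
    stop("no observations above the compensation point", call. = FALSE)
  ord <- order(d$ci)
  low <- intersect(ord, which(usable))[seq_len(min(3L, sum(usable)))]
  high <- intersect(rev(ord), which(usable))[seq_len(min(3L, sum(usable)))]
  vcmax0 <- stats::median(gross[low] * (d$ci[low] + tp$km[low]) /
                            (d$ci[low] - tp$gammastar[low]))
  jlim <- stats::median(4 * gross[high] *
                          (d$ci[high] + 2 * tp$gammastar[high]) /
                          (d$ci[high] - tp$gammastar[high]))
  # invert the non-rectangular hyperbola at the mean irradiance
  aq <- params$alpha * mean(d$par)
  jmax0 <- if (jlim < aq * 0.95) {
    jlim * (aq - params$theta_j * jlim) / (aq - jlim)
  } else {
    1.5 * jlim
  }
  out <- c(vcmax = vcmax0, jmax = jmax0, rd = rd0)
  if (any(!is.finite(out)) || any(out <= 0))
    stop("could not derive positive starting values", call. = FALSE)
  out
}

# Model function used inside nls: net assimilation at given candidate
# parameters, with per-observation temperature correction.
.aci_model <- function(ci, tleaf, par, vcmax, jmax, rd, base) {
  p <- base
  p$vcmax25 <- vcmax
  p$jmax25 <- jmax
  p$rd25 <- rd
  .demand_an(ci, p, tleaf, par)
}

# Two-limb model for a fixed transition point: observations below the
# transition follow the Rubisco-limited limb, the rest the RuBP limb,
# with a shared Rd.
.aci_model_2limb <- function(ci, tleaf, par, vcmax, jmax, rd, base,
                             citransition) {
  p <- base
  p$vcmax25 <- vcmax
  p$jmax25 <- jmax
  p$rd25 <- rd
  tp <- .t_params(p, tleaf)
  j <- electron_transport(par, tp$jmax, p$alpha, p$theta_j)
  if (is.infinite(p$gm)) {
    ac <- gross_limited_rate(ci, tp$vcmax, tp$km, tp$gammastar) - tp$rd
    aj <- gross_limited_rate(ci, j / 4, 2 * tp$gammastar, tp$gammastar) -
      tp$rd
  } else {
    ac <- .net_rate_gm(ci, p$gm, tp$vcmax, tp$km, tp$gammastar, tp$rd)
    aj <- .net_rate_gm(ci, p$gm, j / 4, 2 * tp$gammastar, tp$gammastar,
                       tp$rd)
  }
  ifelse(ci < citransition, ac, aj)
}

.multistart_grid <- function(start) {
  g <- expand.grid(v = c(1, 0.5, 2), j = c(1, 0.5, 2), r = c(1, 0.5, 2))
  g <- g[order(rowSums(g != 1)), ]  # base start first, then nearby scalings
  lapply(seq_len(nrow(g)), function(i)
    c(vcmax = start[["vcmax"]] * g$v[i], jmax = start[["jmax"]] * g$j[i],
      rd = start[["rd"]] * g$r[i]))
}

# Run nlsLM over the multi-start grid, keep the best SSR. Stops early once
# at least three starts have converged and the last two brought no SSR
# improvement beyond 1e-10.
.fit_multistart <- function(formula, data, starts, lower, upper) {
  best <- NULL
  best_ssr <- Inf
  successes <- 0L
  stale <- 0L
  for (st in starts) {
    st <- pmin(pmax(st[names(lower)], lower * 1.0000001), upper)
    fit <- tryCatch(
      minpack.lm::nlsLM(formula, data = data, start = as.list(st),
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(
                          maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(stats::residuals(fit)^2)
    successes <- successes + 1L
    if (ssr < best_ssr - 1e-10) {
      stale <- 0L
    } else {
      stale <- stale + 1L
    }
    if (ssr < best_ssr) {
      best <- fit
      best_ssr <- ssr
    }
    if (successes >= 3L && stale >= 2L) break
  }
  best
}

#' Fit the FvCB model to an A-Ci curve
#'
#' Estimates Vcmax, Jmax and Rd (all at 25 degC by default) by nonlinear
#' least squares on net assimilation, fitting the hyperbolic minimum of the
#' Rubisco-limited and RuBP-regeneration-limited rates so the transition
#' between limitations is smooth and never has to be supplied by the user.
#' Starting values are estimated from the data and the optimisation is
#' repeated over a grid of scaled starting values, keeping the best
#' residual sum of squares.
#'
#' @param data Data frame with net photosynthesis and intercellular CO2,
#'   plus optional leaf temperature and irradiance. Columns may use logical
#'   names (`an`, `ci`, `tleaf`, `par`) or analyser names per `columns`.
#' @param params Kinetic constants and temperature sensitivities, see
#'   [biochem_params()]. The `vcmax25`, `jmax25`, `rd25` entries are ignored
#'   (they are being estimated).
#' @param rd Optional known day respiration at 25 degC; when supplied it is
#'   fixed, not estimated.
#' @param gm Optional mesophyll conductance (mol m-2 s-1); when supplied the
#'   fitted Vcmax and Jmax are chloroplastic rates.
#' @param citransition Optional fixed transition point (umol mol-1):
#'   observations with `ci` below it are fitted to the Rubisco-limited limb
#'   and the rest to the RuBP-limited limb, sharing Rd.
#' @param tcorrect If `TRUE` (default) parameters are normalised to 25 degC
#'   using each observation's leaf temperature; if `FALSE` they apply at
#'   measurement temperature.
#' @param start Optional named starting values `c(vcmax, jmax, rd)`.
#' @param lower,upper Optional box constraints on `(vcmax, jmax, rd)`.
#' @param columns Column mapping, see [gx_columns()].
#' @return An object of class `"acifit"`: a list with `coefficients`
#'   (vcmax, jmax, rd), `se`, `ci95` (t-based 95% confidence intervals),
#'   `vcov`, `fitted`, `residuals`, `ssr`, `r_squared` (squared correlation
#'   of measured and fitted), `ci_transition`, `converged`, `se_reliable`,
#'   `limb_counts`, the data and settings used, and the underlying `nls`
#'   fit.
#' @examples
#' curve <- simulate_aci(noise_sd = 0, seed = 1)
#' fit <- fit_aci(curve)
#' coef(fit)
#' @export
fit_aci <- function(data, params = biochem_params(), rd = NULL, gm = NULL,
                    citransition = NULL, tcorrect = TRUE, start = NULL,
                    lower = c(vcmax = 1e-6, jmax = 1e-6, rd = 0),
                    upper = c(vcmax = Inf, jmax = Inf, rd = Inf),
                    columns = gx_columns()) {
  d <- .normalize_columns(data, columns, required = c("an", "ci"),
                          defaults = list(tleaf = 25, par = 1800))
  d <- d[is.finite(d$an) & is.finite(d$ci), , drop = FALSE]
  n_par_free <- 3L - !is.null(rd)
  if (nrow(d) < n_par_free + 2L)
    stop("too few observations (", nrow(d), ") for a ", n_par_free,
         "-parameter fit", call. = FALSE)
  if (!is.null(rd) && rd < 0)
    stop("fixed 'rd' must be non-negative", call. = FALSE)
  base <- params
  base$tcorrect <- isTRUE(tcorrect)
  if (!is.null(gm)) {
    if (gm <= 0) stop("'gm' must be positive", call. = FALSE)
    base$gm <- gm
  }
  if (is.null(start))
    start <- estimate_starting_values(d, base, columns = columns)
  starts <- .multistart_grid(start)

  if (!is.null(citransition)) {
    rng <- range(d$ci)
    if (citransition <= rng[1] || citransition > rng[2])
      stop("'citransition' must lie within the observed ci range",
           call. = FALSE)
    n_low <- sum(d$ci < citransition)
    if (n_low < 2L || nrow(d) - n_low < 2L)
      stop("each limb needs at least 2 observations ",
           "(transition at ", citransition, " leaves ", n_low, " / ",
           nrow(d) - n_low, ")", call. = FALSE)
  }

  two_limb <- !is.null(citransition)
  if (is.null(rd)) {
    form <- if (two_limb) {
      an ~ .aci_model_2limb(ci, tleaf, par, vcmax, jmax, rd, base,
                            citransition)
    } else {
      an ~ .aci_model(ci, tleaf, par, vcmax, jmax, rd, base)
    }
    lo <- lower
    hi <- upper
  } else {
    rd_fix <- rd
    form <- if (two_limb) {
      an ~ .aci_model_2limb(ci, tleaf, par, vcmax, jmax, rd_fix, base,
                            citransition)
    } else {
      an ~ .aci_model(ci, tleaf, par, vcmax, jmax, rd_fix, base)
    }
    starts <- lapply(starts, function(s) s[c("vcmax", "jmax")])
    lo <- lower[c("vcmax", "jmax")]
    hi <- upper[c("vcmax", "jmax")]
  }
  env <- new.env(parent = asNamespace("leafgas"))
  env$base <- base
  if (two_limb) env$citransition <- citransition
  if (!is.null(rd)) env$rd_fix <- rd
  environment(form) <- env

  fit <- .fit_multistart(form, d, starts, lo, hi)
  if (is.null(fit))
    stop("A-Ci fit failed to converge from all starting values",
         call. = FALSE)

  est <- stats::coef(fit)
  vc <- stats::vcov(fit)
  se <- sqrt(diag(vc))
  if (!is.null(rd)) {
    est <- c(est, rd = rd)
    se <- c(se, rd = NA_real_)
  }
  est <- est[c("vcmax", "jmax", "rd")]
  se <- se[c("vcmax", "jmax", "rd")]
  dfres <- nrow(d) - n_par_free
  tcrit <- stats::qt(0.975, dfres)
  ci95 <- cbind(lower = est - tcrit * se, upper = est + tcrit * se)
  fitted_an <- as.numeric(stats::fitted(fit))
  res <- d$an - fitted_an
  r2 <- stats::cor(d$an, fitted_an)^2

  fitpar <- base
  fitpar$vcmax25 <- est[["vcmax"]]
  fitpar$jmax25 <- est[["jmax"]]
  fitpar$rd25 <- est[["rd"]]
  trans <- .ci_transition(fitpar, tleaf = mean(d$tleaf), par = mean(d$par))
  dem <- .demand_core(d$ci, fitpar, d$tleaf, d$par)
  limb <- ifelse(dem$ac <= dem$aj, "rubisco", "rubp")
  limb_counts <- c(rubisco = sum(limb == "rubisco"),
                   rubp = sum(limb == "rubp"))
  se_reliable <- c(vcmax = limb_counts[["rubisco"]] > 0,
                   jmax = limb_counts[["rubp"]] > 0)

  out <- list(coefficients = est, se = se, ci95 = ci95, vcov = vc,
              fitted = fitted_an, residuals = res,
              ssr = sum(res^2), r_squared = r2, df_residual = dfres,
              ci_transition = trans, converged = TRUE,
              se_reliable = se_reliable, limb_counts = limb_counts,
              data = d, params = fitpar,
              settings = list(rd_fixed = rd, gm = if (is.null(gm))
                base$gm else gm, tcorrect = isTRUE(tcorrect),
                citransition = citransition),
              nls = fit)
  class(out) <- "acifit"
  out
}

# Ci at which the Rubisco- and RuBP-limited gross rates intersect.
.ci_transition <- function(params, tleaf = 25, par = 1800) {
  f <- function(ci) {
    dd <- .demand_core(ci, params, tleaf, par)
    dd$ac - dd$aj
  }
  g <- arrhenius(params$gammastar25, params$ea_gammastar, tleaf)
  lo <- g + 1
  hi <- 3000
  flo <- f(lo)
  fhi <- f(hi)
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0)
    return(NA_real_)
  stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
}

#' Fit many A-Ci curves at once
#'
#' Splits a table by a grouping column and fits each group with
#' [fit_aci()]. Failures are isolated: a group that cannot be fitted is
#' reported in the result with its error message and does not stop the
#' other fits.
#'
#' @param data Table of many curves.
#' @param group Name of the grouping column (logical name `group` or a file
#'   column name).
#' @param ... Passed to [fit_aci()].
#' @param columns Column mapping, see [gx_columns()].
#' @return An object of class `"acifit_list"`; `coef()` returns a table with
#'   one row per curve (estimates, SEs, confidence limits, R2 and a
#'   convergence flag).
#' @export
fit_aci_batch <- function(data, group = "group", columns = gx_columns(),
                          ...) {
  data <- as.data.frame(data)
  gcol <- if (group %in% names(data)) group
          else if (!is.null(columns["group"]) &&
                   !is.na(columns["group"]) &&
                   columns[["group"]] %in% names(data)) columns[["group"]]
  if (is.null(gcol) || !gcol %in% names(data))
    stop("grouping column '", group, "' not found", call. = FALSE)
  if (nrow(data) == 0L) stop("empty table", call. = FALSE)
  parts <- split(data, data[[gcol]])
  fits <- lapply(names(parts), function(id) {
    tryCatch(fit_aci(parts[[id]], columns = columns, ...),
             error = function(e) structure(
               list(curve = id, error = conditionMessage(e),
                    converged = FALSE),
               class = "acifit_failure"))
  })
  names(fits) <- names(parts)
  structure(fits, class = "acifit_list")
}

#' @export
coef.acifit_list <- function(object, ...) {
  rows <- lapply(names(object), function(id) {
    f <- object[[id]]
    if (inherits(f, "acifit_failure")) {
      data.frame(group = id, vcmax = NA_real_, jmax = NA_real_,
                 rd = NA_real_, vcmax_se = NA_real_, jmax_se = NA_real_,
                 rd_se = NA_real_, r_squared = NA_real_, converged = FALSE,
                 error = f$error, stringsAsFactors = FALSE)
    } else {
      data.frame(group = id, vcmax = f$coefficients[["vcmax"]],
                 jmax = f$coefficients[["jmax"]],
                 rd = f$coefficients[["rd"]],
                 vcmax_se = f$se[["vcmax"]], jmax_se = f$se[["jmax"]],
                 rd_se = f$se[["rd"]], r_squared = f$r_squared,
                 converged = f$converged, error = "",
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' @export
print.acifit_list <- function(x, ...) {
  ok <- sum(vapply(x, function(f) !inherits(f, "acifit_failure"),
                   logical(1)))
  cat("A-Ci batch fit:", length(x), "curves,", ok, "converged\n")
  print(utils::head(coef(x), 10))
  invisible(x)
}

#' @export
coef.acifit <- function(object, ...) object$coefficients

#' @export
fitted.acifit <- function(object, ...) object$fitted

#' @export
residuals.acifit <- function(object, ...) object$residuals

#' @export
vcov.acifit <- function(object, ...) object$vcov

#' @export
print.acifit <- function(x, ...) {
  cat("FvCB model fit to an A-Ci curve (", nrow(x$data),
      " observations)\n", sep = "")
  tab <- cbind(estimate = x$coefficients, se = x$se, x$ci95)
  print(round(tab, 4))
  cat(sprintf("R2 (measured vs fitted): %.4f   SSR: %.4g\n",
              x$r_squared, x$ssr))
  if (is.finite(x$ci_transition))
    cat(sprintf("Transition Ci (Ac = Aj): %.1f umol mol-1\n",
                x$ci_transition))
  if (!all(x$se_reliable))
    cat("note: ", paste(names(x$se_reliable)[!x$se_reliable],
                        collapse = ", "),
        " not constrained by any observation; SE unreliable\n", sep = "")
  invisible(x)
}

#' @export
summary.acifit <- function(object, ...) {
  print(object)
  cat("\nLimb occupancy at the estimates: rubisco =",
      object$limb_counts[["rubisco"]], ", rubp =",
      object$limb_counts[["rubp"]], "\n")
  invisible(object)
}

#' Diagnostic plot of a fitted A-Ci curve
#'
#' Plots measured net assimilation against intercellular CO2 with the
#' fitted FvCB curve and the two limitation-specific rates.
#'
#' @param x An `"acifit"` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.acifit <- function(x, ...) {
  d <- x$data
  grid <- seq(min(d$ci), max(d$ci), length.out = 200)
  dem <- aci_demand(grid, x$params, tleaf = mean(d$tleaf),
                    par = mean(d$par))
  graphics::plot(d$ci, d$an, xlab = expression(C[i] ~ (mu * mol ~ mol^-1)),
                 ylab = expression(A[n] ~ (mu * mol ~ m^-2 ~ s^-1)), ...)
  graphics::lines(grid, dem$an, lwd = 2)
  graphics::lines(grid, dem$ac - dem$rd, col = "firebrick", lty = 2)
  graphics::lines(grid, dem$aj - dem$rd, col = "steelblue", lty = 2)
  graphics::legend("bottomright", bty = "n", lty = c(1, 2, 2), lwd = c(2, 1, 1),
                   col = c("black", "firebrick", "steelblue"),
                   legend = c("fitted", "Rubisco-limited", "RuBP-limited"))
  invisible(x)
}
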