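# Ball-Berry-type stomatal conductance models: prediction, fitting, and the
# closed-form instantaneous transpiration efficiency.

.GS_MODELS <- c("medlyn", "ballberry", "leuning")

#' Predict stomatal conductance from a Ball-Berry-type model
#'
#' All variants share the empirical form `gs = g0 + g1 * An/Ca * f(humidity)`
#' and differ in the humidity response:
#' \describe{
#'   \item{`"ballberry"`}{`gs = g0 + g1 * An * (rh/100) / ca` (original
#'     relative-humidity form; air RH is used as a proxy for leaf-surface
#'     RH).}
#'   \item{`"leuning"`}{`gs = g0 + g1 * An / (ca * (1 + d/d0))` with the
#'     vapour pressure deficit response scaled by `d0` (kPa).}
#'   \item{`"medlyn"`}{`gs = g0 + 1.6 * (1 + g1/sqrt(d)) * An / ca`, the
#'     form implied by optimal stomatal behaviour; here `g1` has units
#'     kPa^0.5 and the factor 1.6 (H2O vs CO2 diffusivity) is explicit, so
#'     `g1` is comparable across studies.}
#' }
#' For the other two variants any diffusivity factor is absorbed into `g1`.
#' Conductances are to H2O throughout.
#'
#' @param an Net assimilation, umol m-2 s-1.
#' @param ca Ambient CO2, umol mol-1 (> 0).
#' @param model One of `"medlyn"`, `"ballberry"`, `"leuning"`.
#' @param g0 Residual conductance, mol m-2 s-1.
#' @param g1 Slope parameter (kPa^0.5 for `"medlyn"`, dimensionless
#'   otherwise).
#' @param d Vapour pressure deficit, kPa (> 0; required for `"medlyn"` and
#'   `"leuning"`).
#' @param rh Relative humidity, percent (required for `"ballberry"`).
#' @param d0 VPD scale of the `"leuning"` variant, kPa.
#' @return Stomatal conductance to H2O, mol m-2 s-1.
#' @examples
#' gs_predict(10, 400, "medlyn", g0 = 0, g1 = 4, d = 1)  # 0.2
#' @export
gs_predict <- function(an, ca, model = c("medlyn", "ballberry", "leuning"),
                       g0 = 0, g1 = 4, d = NULL, rh = NULL, d0 = 1.5) {
  model <- match.arg(model)
  if (any(ca <= 0)) stop("'ca' must be positive", call. = FALSE)
  switch(model,
    ballberry = {
      if (is.null(rh)) stop("'rh' is required for the ballberry variant",
                            call. = FALSE)
      if (any(rh < 0) || any(rh > 100))
        stop("'rh' must be within [0, 100]", call. = FALSE)
      g0 + g1 * an * (rh / 100) / ca
    },
    leuning = {
      if (is.null(d) || any(d <= 0))
        stop("'d' must be positive for the leuning variant", call. = FALSE)
      if (d0 <= 0) stop("'d0' must be positive", call. = FALSE)
      g0 + g1 * an / (ca * (1 + d / d0))
    },
    medlyn = {
      if (is.null(d) || any(d <= 0))
        stop("'d' must be positive for the medlyn variant", call. = FALSE)
      g0 + 1.6 * (1 + g1 / sqrt(d)) * an / ca
    }
  )
}

#' Fit a Ball-Berry-type stomatal conductance model
#'
#' Least-squares fit of one of the three [gs_predict()] variants to spot
#' gas-exchange data. The Ball-Berry and Leuning variants are linear in
#' `(g0, g1)` and are fitted by linear regression; the medlyn variant is
#' fitted by nonlinear least squares. `g0` can be fixed (commonly at 0), in
#' which case only `g1` is estimated.
#'
#' @param data Data frame with stomatal conductance to H2O, net
#'   assimilation, ambient CO2, and VPD and/or RH, using logical names
#'   (`gs`, `an`, `ca`, `d`, `rh`) or analyser names per `columns`.
#' @param model Variant to fit, see [gs_predict()].
#' @param g0 `NULL` to estimate the intercept, or a fixed value.
#' @param d0 Fixed VPD scale of the leuning variant, kPa.
#' @param columns Column mapping, see [gx_columns()].
#' @return Object of class `"bbfit"`: list with `coefficients` (g0, g1),
#'   `se`, `ci95` (t-based), `predicted`, `residuals`, `rmse`, `r_squared`,
#'   `model`, `fit` (the underlying `lm`/`nls` object) and the data used.
#' @examples
#' spot <- simulate_spot(n = 40, noise_sd = 0, seed = 1)
#' fit_bb(spot, model = "medlyn", g0 = 0)
#' @export
fit_bb <- function(data, model = c("medlyn", "ballberry", "leuning"),
                   g0 = NULL, d0 = 1.5, columns = gx_columns()) {
  model <- match.arg(model)
  need <- c("gs", "an", "ca", switch(model, ballberry = "rh", "d"))
  d <- .normalize_columns(data, columns, required = need)
  keep <- Reduce(`&`, lapply(d[need], is.finite))
  d <- d[keep, , drop = FALSE]
  if (nrow(d) < 3L)
    stop("at least 3 complete observations are required", call. = FALSE)
  if (all(d$an == 0))
    stop("all an values are zero: g1 is unidentifiable", call. = FALSE)
  if (!is.null(g0) && !is.finite(g0))
    stop("fixed 'g0' must be finite", call. = FALSE)

  x <- switch(model,
    ballberry = d$an * (d$rh / 100) / d$ca,
    leuning = d$an / (d$ca * (1 + d$d / d0)),
    medlyn = NULL)

  if (model %in% c("ballberry", "leuning")) {
    fit <- if (is.null(g0)) stats::lm(gs ~ x, data = cbind(d, x = x))
           else stats::lm(gs ~ x - 1, data = cbind(d, x = x),
                          offset = rep(g0, nrow(d)))
    cf <- stats::coef(fit)
    se <- sqrt(diag(suppressWarnings(stats::vcov(fit))))
    if (is.null(g0)) {
      est <- c(g0 = unname(cf[1]), g1 = unname(cf[2]))
      ses <- c(g0 = unname(se[1]), g1 = unname(se[2]))
    } else {
      est <- c(g0 = g0, g1 = unname(cf[1]))
      ses <- c(g0 = NA_real_, g1 = unname(se[1]))
    }
  } else {
    g1_0 <- stats::median((pmax(d$gs - (if (is.null(g0)) 0 else g0), 1e-8) *
                             d$ca / (1.6 * pmax(d$an, 1e-8)) - 1) *
                            sqrt(d$d), na.rm = TRUE)
    if (!is.finite(g1_0) || g1_0 <= 0) g1_0 <- 4
    if (is.null(g0)) {
      fit <- minpack.lm::nlsLM(
        gs ~ g0 + 1.6 * (1 + g1 / sqrt(d)) * an / ca, data = d,
        start = list(g0 = 0, g1 = g1_0),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                             ptol = 1e-14))
      est <- stats::coef(fit)[c("g0", "g1")]
      ses <- sqrt(diag(stats::vcov(fit)))[c("g0", "g1")]
    } else {
      g0_fix <- g0
      fit <- minpack.lm::nlsLM(
        gs ~ g0_fix + 1.6 * (1 + g1 / sqrt(d)) * an / ca, data = d,
        start = list(g1 = g1_0),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                             ptol = 1e-14))
      est <- c(g0 = g0, g1 = unname(stats::coef(fit)[["g1"]]))
      ses <- c(g0 = NA_real_, g1 = sqrt(diag(stats::vcov(fit)))[["g1"]])
    }
  }

  pred <- gs_predict(d$an, d$ca, model, g0 = est[["g0"]], g1 = est[["g1"]],
                     d = if (model == "ballberry") NULL else d$d,
                     rh = if (model == "ballberry") d$rh else NULL, d0 = d0)
  res <- d$gs - pred
  n_free <- if (is.null(g0)) 2L else 1L
  dfres <- nrow(d) - n_free
  tcrit <- stats::qt(0.975, dfres)
  ci95 <- cbind(lower = est - tcrit * ses, upper = est + tcrit * ses)
  out <- list(coefficients = est, se = ses, ci95 = ci95, predicted = pred,
              residuals = res, rmse = sqrt(mean(res^2)),
              r_squared = stats::cor(d$gs, pred)^2, model = model,
              d0 = if (model == "leuning") d0 else NA_real_,
              g0_fixed = !is.null(g0), df_residual = dfres,
              data = d, fit = fit)
  class(out) <- "bbfit"
  out
}

#' @export
coef.bbfit <- function(object, ...) object$coefficients

#' @export
print.bbfit <- function(x, ...) {
  cat("Stomatal conductance model fit (variant: ", x$model, ", ",
      nrow(x$data), " observations)\n", sep = "")
  tab <- cbind(estimate = x$coefficients, se = x$se, x$ci95)
  print(round(tab, 5))
  if (x$g0_fixed) cat("g0 was fixed, not estimated\n")
  cat(sprintf("RMSE: %.5f mol m-2 s-1   R2: %.4f\n", x$rmse, x$r_squared))
  invisible(x)
}

#' Instantaneous transpiration efficiency from the optimality-based model
#'
#' Closed-form ratio of net assimilation to transpiration implied by the
#' medlyn variant of [gs_predict()] with `g0 = 0` and perfect coupling of
#' the leaf to the atmosphere (`E = gs * d / pa`):
#' \deqn{A_n/E = \frac{C_a P_a}{1.6 (g_1 \sqrt{D} + D)}}
#' Returned in umol CO2 per mmol H2O (divide `ca * pa / (1.6 * (g1*sqrt(d) +
#' d))`, which is umol mol-1, by 1000).
#'
#' @param ca Ambient CO2, umol mol-1.
#' @param pa Atmospheric pressure, kPa.
#' @param g1 Slope parameter of the medlyn variant, kPa^0.5.
#' @param d Vapour pressure deficit, kPa (> 0).
#' @return Instantaneous transpiration efficiency, umol mmol-1; strictly
#'   decreasing in both `d` and `g1`.
#' @export
ite_medlyn <- function(ca, pa = 101.3, g1 = 4, d = 1.5) {
  if (any(d <= 0)) stop("'d' must be positive", call. = FALSE)
  if (any(pa <= 0)) stop("'pa' must be positive", call. = FALSE)
  ca * pa / (1600 * (g1 * sqrt(d) + d))
}

#' Compare stomatal model variants on one dataset
#'
#' Fits all three [gs_predict()] variants to the same data and tabulates
#' their goodness of fit. A variant that cannot be fitted (e.g. missing RH)
#' appears as a flagged row rather than an error.
#'
#' @inheritParams fit_bb
#' @return Data frame with one row per variant: estimates, RMSE, R2 and a
#'   convergence flag.
#' @export
compare_gs_models <- function(data, g0 = NULL, d0 = 1.5,
                              columns = gx_columns()) {
  rows <- lapply(.GS_MODELS, function(m) {
    f <- tryCatch(fit_bb(data, model = m, g0 = g0, d0 = d0,
                         columns = columns),
                  error = function(e) e)
    if (inherits(f, "error")) {
      data.frame(model = m, g0 = NA_real_, g1 = NA_real_, rmse = NA_real_,
                 r_squared = NA_real_, ok = FALSE,
                 note = conditionMessage(f), stringsAsFactors = FALSE)
    } else {
      data.frame(model = m, g0 = f$coefficients[["g0"]],
                 g1 = f$coefficients[["g1"]], rmse = f$rmse,
                 r_squared = f$r_squared, ok = TRUE, note = "",
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
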