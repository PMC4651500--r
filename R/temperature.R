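# Temperature responses of biochemical rate parameters.

.RGAS <- 8.314      # universal gas constant, J mol-1 K-1
.TREF_K <- 298.15   # reference temperature, K (25 degC)

#' Arrhenius and peaked-Arrhenius temperature response
#'
#' Scales a rate or Michaelis-Menten constant defined at the reference
#' temperature of 25 degC to a given leaf temperature. With
#' `deactivation_energy = 0` the plain Arrhenius form is used,
#'
#' \deqn{k(T) = k_{25} \exp\left(\frac{E_a (T - T_{ref})}{T_{ref} R T}\right)}
#'
#' with temperatures in Kelvin and \eqn{R = 8.314} J mol-1 K-1. With a
#' positive deactivation energy the peaked (optimum) form is used, in which
#' the Arrhenius rise is multiplied by a high-temperature deactivation term
#' controlled by `deactivation_energy` (Hd, J mol-1) and `entropy` (dS,
#' J mol-1 K-1). Both forms return `ref25` exactly at 25 degC.
#'
#' @param ref25 Value of the parameter at 25 degC (must be positive).
#' @param ea Activation energy, J mol-1. Zero gives a temperature-invariant
#'   parameter.
#' @param tleaf Leaf temperature, degC. Must lie in `[-10, 60]`.
#' @param hd Deactivation energy, J mol-1; 0 (default) selects the plain
#'   Arrhenius form.
#' @param ds Entropy term, J mol-1 K-1; used only when `hd > 0`.
#' @return Numeric vector of the parameter at `tleaf`.
#' @examples
#' arrhenius(42.75, 37830, 35)        # CO2 compensation point at 35 degC
#' arrhenius(50, 58550, 40, hd = 2e5, ds = 629.26)  # peaked Vcmax
#' @export
arrhenius <- function(ref25, ea, tleaf, hd = 0, ds = 0) {
  if (any(!is.finite(tleaf)) || any(tleaf < -10) || any(tleaf > 60))
    stop("'tleaf' must be finite and within [-10, 60] degC", call. = FALSE)
  if (any(ref25 <= 0)) stop("'ref25' must be positive", call. = FALSE)
  tk <- tleaf + 273.15
  k <- ref25 * exp(ea * (tk - .TREF_K) / (.TREF_K * .RGAS * tk))
  if (any(hd > 0)) {
    peak <- (1 + exp((.TREF_K * ds - hd) / (.TREF_K * .RGAS))) /
      (1 + exp((tk * ds - hd) / (tk * .RGAS)))
    k <- ifelse(hd > 0, k * peak, k)
  }
  k
}
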