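#' Impedance of a parallel RC block
#'
#' Every reactive block of the chain model is a resistor in parallel with a
#' capacitor, with impedance `Z = R / (1 + j*2*pi*f*R*C)`. `R = Inf` encodes
#' an absent resistive path (pure capacitive reactance); `C = 0` encodes an
#' absent capacitive path (pure resistance).
#'
#' @param R resistance, ohm (`> 0`, `Inf` permitted)
#' @param C capacitance, farad (`>= 0`)
#' @param f frequency, Hz (vectorized, `>= 0`)
#' @return Complex impedance in ohm, one value per frequency. At `f = 0` the
#'   capacitor is open and the impedance equals `R`.
#' @examples
#' element_impedance(12.4e6, 43.9e-12, 0)     # 12.4 MOhm at DC
#' Mod(element_impedance(12.4e6, 43.9e-12, 1e3))
#' @export
element_impedance <- function(R, C, f) {
  check_rc(R, C)
  if (any(!is.finite(f)) || any(f < 0))
    stop("frequencies must be finite and >= 0", call. = FALSE)
  1 / element_admittance(R, C, f)
}

# admittance form: safe for the Inf/0 "absent" sentinels (1/Inf == 0)
element_admittance <- function(R, C, f) {
  1 / R + 1i * 2 * pi * f * C
}

check_rc <- function(R, C) {
  if (!is.numeric(R) || length(R) != 1L || is.na(R) || R <= 0)
    stop("R must be a positive scalar (Inf = absent element)", call. = FALSE)
  if (!is.numeric(C) || length(C) != 1L || !is.finite(C) || C < 0)
    stop("C must be a finite scalar >= 0", call. = FALSE)
  invisible(NULL)
}

#' Tissue-electrode interface impedance (Randles element)
#'
#' Impedance of one line's interface block: the electrolyte resistance `R_E`
#' in series with the faradaic resistance `R_F` in parallel with the
#' Helmholtz double-layer capacitance `C_H`. The spread resistance `R_S` is
#' not included; it forms its own block.
#'
#' @param params a [chain_parameters()] object
#' @param f frequency, Hz (vectorized)
#' @return Complex impedance in ohm. Limits: `R_E + R_F` at DC, `R_E` as
#'   `f -> Inf`.
#' @export
interface_impedance <- function(params, f) {
  stopifnot(inherits(params, "chain_parameters"))
  randles_impedance(params$R_E, params$R_F, params$C_H, f)
}

#' Randles circuit forward model
#'
#' `Z(f) = R_E + R_F / (1 + j*2*pi*f*R_F*C_H)` — the series electrolyte
#' resistance plus charge-transfer resistance in parallel with the
#' double-layer capacitance. This is the forward model fitted to electrode
#' impedance spectra by [fit_randles()].
#'
#' @param R_E series (electrolyte) resistance, ohm
#' @param R_F faradaic resistance, ohm
#' @param C_H double-layer capacitance, farad
#' @param f frequency, Hz (vectorized)
#' @return Complex impedance in ohm.
#' @export
randles_impedance <- function(R_E, R_F, C_H, f) {
  if (!is.numeric(R_E) || length(R_E) != 1L || is.na(R_E) || R_E <= 0)
    stop("R_E must be a positive scalar", call. = FALSE)
  check_rc(R_F, C_H)
  if (any(!is.finite(f)) || any(f < 0))
    stop("frequencies must be finite and >= 0", call. = FALSE)
  R_E + 1 / element_admittance(R_F, C_H, f)
}

#' Newman spread resistance of a disk electrode
#'
#' Analytic resistance to current flow from a half-space of resistivity
#' `rho` into a disk electrode of radius `r`: `R = rho / (4 r)`. With dura
#' mater resistivity at the lower end of its reported range (1 kOhm cm =
#' 10 Ohm m) and a 50 um disk radius this evaluates to 50 kOhm, the same
#' order as the experimentally extracted access resistance.
#'
#' @param rho medium resistivity, ohm meter
#' @param r disk radius, meter
#' @return Spread resistance in ohm.
#' @examples
#' spread_resistance_disk(10, 50e-6)   # 50 kOhm
#' @export
spread_resistance_disk <- function(rho, r) {
  if (!is.numeric(rho) || any(!is.finite(rho)) || any(rho <= 0))
    stop("rho must be positive and finite (Ohm*m)", call. = FALSE)
  if (!is.numeric(r) || any(!is.finite(r)) || any(r <= 0))
    stop("r must be positive and finite (m)", call. = FALSE)
  rho / (4 * r)
}
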