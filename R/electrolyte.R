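#' Electrolyte description for the soft-layer model
#'
#' Bundles the bulk-solution properties that set the electrostatic screening
#' and viscous drag in the electrokinetic model. The default is physiological
#' saline (0.145 mol/L 1:1 electrolyte) at 25 C.
#'
#' @param ionic_strength Ionic strength in mol/L (1:1 electrolyte assumed).
#' @param temperature Absolute temperature in K.
#' @param viscosity Dynamic viscosity in Pa.s.
#' @param relative_permittivity Relative permittivity of the solvent
#'   (dimensionless).
#'
#' @return An object of class `electrolyte`: a list with the four fields
#'   above. The Debye parameter is always derived on demand with
#'   [debye_parameter()], never stored.
#' @export
#' @examples
#' el <- electrolyte()
#' 1 / debye_parameter(el) * 1e9   # Debye length in nm, ~0.8
electrolyte <- function(ionic_strength = 0.145,
                        temperature = 298.15,
                        viscosity = 8.9e-4,
                        relative_permittivity = 78.5) {
  check_positive(ionic_strength, "ionic_strength")
  check_positive(temperature, "temperature")
  check_positive(viscosity, "viscosity")
  check_positive(relative_permittivity, "relative_permittivity")
  structure(list(ionic_strength = ionic_strength,
                 temperature = temperature,
                 viscosity = viscosity,
                 relative_permittivity = relative_permittivity),
            class = "electrolyte")
}

#' @export
print.electrolyte <- function(x, ...) {
  cat("Electrolyte (1:1)\n")
  cat(sprintf("  ionic strength : %g mol/L\n", x$ionic_strength))
  cat(sprintf("  temperature    : %g K\n", x$temperature))
  cat(sprintf("  viscosity      : %g Pa.s\n", x$viscosity))
  cat(sprintf("  rel. permittivity: %g\n", x$relative_permittivity))
  cat(sprintf("  Debye length   : %.3g nm\n", 1e9 / debye_parameter(x)))
  invisible(x)
}

#' Debye screening parameter of a 1:1 electrolyte
#'
#' Computes \eqn{\kappa = \sqrt{2 e^2 N_A I \cdot 1000 / (\epsilon_r
#' \epsilon_0 k_B T)}}, the inverse Debye length. At physiological ionic
#' strength the Debye length \eqn{\kappa^{-1}} is about 0.8 nm, an order of
#' magnitude below the 7.8 nm glycocalyx thickness, which is what makes the
#' flat-plate soft-layer treatment appropriate.
#'
#' @param el An [electrolyte()] object.
#' @return Inverse Debye length in 1/m.
#' @export
debye_parameter <- function(el) {
  stopifnot(inherits(el, "electrolyte"))
  k <- .const
  sqrt(2 * k$e^2 * k$N_A * el$ionic_strength * 1000 /
         (el$relative_permittivity * k$eps0 * k$k_B * el$temperature))
}
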