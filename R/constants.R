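## Physical constants (CODATA 2018), SI units.
.const <- list(
  e       = 1.602176634e-19,   # elementary charge, C
  N_A     = 6.02214076e23,     # Avogadro, 1/mol
  k_B     = 1.380649e-23,      # Boltzmann, J/K
  eps0    = 8.8541878128e-12   # vacuum permittivity, F/m
)

#' Physical constants used by the electrokinetic model
#'
#' Returns the CODATA values for the elementary charge, Avogadro constant,
#' Boltzmann constant and vacuum permittivity used throughout the package.
#'
#' @return Named list with elements `e` (C), `N_A` (1/mol), `k_B` (J/K) and
#'   `eps0` (F/m).
#' @export
#' @examples
#' glyx_constants()$e
glyx_constants <- function() .const
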