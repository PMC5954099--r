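#' Closed-form mobility for a single uniform soft layer
#'
#' Exact solution of the flat-plate model when the friction coefficient and
#' fixed charge density are piecewise constant: a uniform layer on
#' `[0, beta]` (friction `f0 > 0`, charge density `rho0`) and bare
#' electrolyte on `(beta, L]`. The potential and velocity are
#' piecewise-exponential; the eight integration constants are obtained from
#' the boundary and matching conditions by solving two small linear systems.
#' This is an independent route to the same physics as the finite-difference
#' solvers and is used to validate them.
#'
#' The closed form requires `f0 > 0` and the Brinkman screening parameter
#' \eqn{\lambda = \sqrt{f_0/\eta}} distinct from \eqn{\kappa} (the generic,
#' non-resonant case).
#'
#' @param beta Layer thickness, m.
#' @param f0 Friction coefficient inside the layer, kg/(m^3 s).
#' @param rho0 Fixed charge density inside the layer, C/m^3.
#' @param el An [electrolyte()].
#' @param membrane_surface_charge Charge on the membrane plane, C/m^2.
#' @param L Domain length, m (default `beta + 10/kappa`).
#' @return List with `mobility` (m^2/(V.s)), and vectorised functions
#'   `psi_at(z)` and `u_at(z)` evaluating the exact potential and velocity.
#' @export
#' @examples
#' el <- electrolyte()
#' mobility_two_region(7.8e-9, 1e13, -2e6, el)$mobility
mobility_two_region <- function(beta, f0, rho0, el,
                                membrane_surface_charge = 0, L = NULL) {
  stopifnot(inherits(el, "electrolyte"))
  check_positive(beta, "beta")
  check_positive(f0, "f0")
  kappa <- debye_parameter(el)
  if (is.null(L)) L <- beta + 10 / kappa
  eps <- el$relative_permittivity * .const$eps0
  eta <- el$viscosity
  lam <- sqrt(f0 / eta)
  if (abs(lam - kappa) < 1e-6 * kappa)
    stop_glyx("resonant case lambda == kappa not supported by the closed form",
              "glyx_invalid_parameter")

  ## Bounded exponential bases keep the matching matrices well-conditioned
  ## for arbitrarily thick layers / strong friction:
  ##   psi1 = A e^{k(z-beta)} + B e^{-kz} + psi_p  on [0, beta]
  ##   psi2 = C e^{-k(z-beta)} + D e^{-k(L-z)}     on (beta, L]
  psi_p <- rho0 / (eps * kappa^2)
  eb <- exp(-kappa * beta)          # e^{-k beta}
  et <- exp(-kappa * (L - beta))    # e^{-k (L-beta)}
  M <- rbind(
    c(eb, -1, 0, 0),          # psi1'(0) / kappa
    c(1, eb, -1, -et),        # continuity at beta
    c(1, -eb, 1, -et),        # derivative / kappa at beta
    c(0, 0, et, 1))           # psi2(L) = 0
  rhs <- c(-membrane_surface_charge / (eps * kappa), -psi_p, 0, 0)
  co <- solve(M, rhs)
  A <- co[1]; B <- co[2]; C <- co[3]; D <- co[4]

  psi1  <- function(z) A * exp(kappa * (z - beta)) + B * exp(-kappa * z) + psi_p
  dpsi1 <- function(z) kappa * (A * exp(kappa * (z - beta)) - B * exp(-kappa * z))
  psi2  <- function(z) C * exp(-kappa * (z - beta)) + D * exp(-kappa * (L - z))
  dpsi2 <- function(z) kappa * (-C * exp(-kappa * (z - beta)) + D * exp(-kappa * (L - z)))

  ## velocity: u1 = P e^{l(z-beta)} + Q e^{-lz} + particular(psi1)
  ##           u2 = a + b z + (eps/eta) psi2(z)
  denom <- eta * kappa^2 - f0
  mA <- eps * kappa^2 * A / denom
  mB <- eps * kappa^2 * B / denom
  u_c <- -eps * kappa^2 * psi_p / f0
  g <- eps / eta
  lb <- exp(-lam * beta)
  part1  <- function(z) mA * exp(kappa * (z - beta)) + mB * exp(-kappa * z) + u_c
  dpart1 <- function(z) kappa * (mA * exp(kappa * (z - beta)) - mB * exp(-kappa * z))
  part2  <- function(z) g * psi2(z)
  dpart2 <- function(z) g * dpsi2(z)
  Mu <- rbind(
    c(lb, 1, 0, 0),           # u1(0) = 0
    c(1, lb, -1, -beta),      # continuity at beta
    c(lam, -lam * lb, 0, -1), # derivative at beta
    c(0, 0, 0, 1))            # u2'(L) = 0
  rhsu <- c(-part1(0),
            part2(beta) - part1(beta),
            dpart2(beta) - dpart1(beta),
            -dpart2(L))
  cu <- solve(Mu, rhsu)
  P <- cu[1]; Q <- cu[2]; a <- cu[3]; b <- cu[4]

  psi_at <- function(z) ifelse(z <= beta, psi1(z), psi2(z))
  u_at <- function(z) {
    ifelse(z <= beta,
           P * exp(lam * (z - beta)) + Q * exp(-lam * z) + part1(z),
           a + b * z + part2(z))
  }
  list(mobility = -u_at(L), psi_at = psi_at, u_at = u_at)
}
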