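## Finite-difference solvers for the flat-plate soft-layer electrokinetic
## model: linearised Poisson-Boltzmann electrostatics and Brinkman-damped
## electroosmotic flow on the profile grid.

## Solve a symmetric tridiagonal system given the three bands.
tridiag_solve <- function(lower, diag, upper, rhs) {
  n <- length(diag)
  A <- Matrix::bandSparse(n, n, k = c(-1, 0, 1),
                          diagonals = list(lower, diag, upper))
  as.numeric(Matrix::solve(A, rhs))
}

#' Electrostatic potential of the charged soft layer
#'
#' Solves the linearised Poisson-Boltzmann boundary-value problem
#' \deqn{\psi'' = \kappa^2 \psi - \rho_{fix}(z) / (\epsilon_r \epsilon_0)}
#' on the profile grid, with a flux condition at the membrane,
#' \eqn{\psi'(0) = -\sigma_m / (\epsilon_r \epsilon_0)}, and \eqn{\psi = 0}
#' at the outer edge of the domain. Discretisation is second-order central
#' differences with a ghost node at the membrane.
#'
#' @param profile A [build_profile()] result.
#' @param el Electrolyte; defaults to the one stored in the profile.
#' @return Numeric vector: potential in volts at every grid node.
#' @export
solve_potential <- function(profile, el = profile$electrolyte) {
  stopifnot(inherits(profile, "layer_profile"), inherits(el, "electrolyte"))
  z <- profile$grid
  n <- length(z)
  h <- z[2] - z[1]
  kappa <- debye_parameter(el)
  eps <- el$relative_permittivity * .const$eps0

  diag <- rep(2 / h^2 + kappa^2, n)
  lower <- rep(-1 / h^2, n - 1)
  upper <- rep(-1 / h^2, n - 1)
  rhs <- profile$fixed_charge_density / eps

  ## membrane (z = 0): ghost-node Neumann, psi'(0) = -sigma_m / eps
  upper[1] <- -2 / h^2
  rhs[1] <- rhs[1] + 2 * profile$membrane_surface_charge / (h * eps)
  ## far edge: Dirichlet psi(L) = 0 (row scaled like the interior rows)
  lower[n - 1] <- 0
  rhs[n] <- 0

  psi <- tridiag_solve(lower, diag, upper, rhs)
  res <- check_residual(lower, diag, upper, rhs, psi)
  if (res > 1e-8)
    stop_glyx(sprintf("potential solve did not converge (residual %.3g)", res),
              "glyx_solver_error")
  psi
}

check_residual <- function(lower, diag, upper, rhs, x) {
  n <- length(x)
  Ax <- diag * x
  Ax[-1] <- Ax[-1] + lower * x[-n]
  Ax[-n] <- Ax[-n] + upper * x[-1]
  scale <- max(abs(rhs), max(abs(diag)) * max(abs(x)), .Machine$double.xmin)
  max(abs(Ax - rhs)) / scale
}

#' Electrophoretic mobility of the soft-layered cell
#'
#' Couples the potential from [solve_potential()] to Stokes flow with
#' Brinkman friction: at unit applied field the fluid velocity obeys
#' \deqn{\eta u'' - f(z) u = -\rho_e(z), \qquad
#'       \rho_e(z) = -\epsilon_r \epsilon_0 \kappa^2 \psi(z),}
#' with no slip at the membrane (`u(0) = 0`) and vanishing shear at the
#' outer edge (`u'(L) = 0`). In the cell frame the far-field electroosmotic
#' velocity at unit field is `u(L)`, so the mobility is defined as
#' \eqn{\mu = -u(L)}: a negatively charged layer yields a negative mobility,
#' matching the electrophoresis sign convention for red blood cells.
#'
#' @param profile A [build_profile()] result.
#' @param el Electrolyte; defaults to the profile's.
#' @param psi Optional precomputed potential (the potential is independent
#'   of neutral grafts, so sweeps over graft number can reuse it).
#' @return An object of class `mobility_solution` with fields `mobility`
#'   (m^2/(V.s)), `potential_profile` (V), `velocity_profile` (m^2/(V.s) at
#'   unit field), `grid`, `converged` and `residual_norm`.
#' @export
#' @examples
#' el <- electrolyte()
#' prof <- build_profile(glycocalyx_model(), NULL, el)
#' sol <- solve_mobility(prof, el)
#' sol$mobility * 1e8   # ~ -1.1 in 1e-8 m^2/(V.s) = um.cm/(V.s)
solve_mobility <- function(profile, el = profile$electrolyte, psi = NULL) {
  stopifnot(inherits(profile, "layer_profile"), inherits(el, "electrolyte"))
  z <- profile$grid
  n <- length(z)
  h <- z[2] - z[1]
  kappa <- debye_parameter(el)
  eps <- el$relative_permittivity * .const$eps0
  eta <- el$viscosity

  if (max(z) < profile$thickness_beta + 8 / kappa)
    stop_glyx("domain too short: L must be at least beta + 8/kappa",
              "glyx_invalid_parameter")

  if (is.null(psi)) psi <- solve_potential(profile, el)

  f <- profile$friction_coefficient
  ## -eta u'' + f u = -eps kappa^2 psi
  diag <- 2 * eta / h^2 + f
  lower <- rep(-eta / h^2, n - 1)
  upper <- rep(-eta / h^2, n - 1)
  rhs <- -eps * kappa^2 * psi

  ## membrane: no slip (row scaled like the interior rows)
  upper[1] <- 0; rhs[1] <- 0
  ## outer edge: ghost-node u'(L) = 0
  lower[n - 1] <- -2 * eta / h^2

  u <- tridiag_solve(lower, diag, upper, rhs)
  res <- check_residual(lower, diag, upper, rhs, u)
  converged <- res <= 1e-8
  if (!converged)
    stop_glyx(sprintf("mobility solve did not converge (residual %.3g)", res),
              "glyx_solver_error")

  structure(list(mobility = -u[n],
                 potential_profile = psi,
                 velocity_profile = u,
                 grid = z,
                 converged = converged,
                 residual_norm = res),
            class = "mobility_solution")
}

#' @export
print.mobility_solution <- function(x, ...) {
  cat(sprintf("Mobility solution: mu = %.4g m^2/(V.s) (%.4g um.cm/(V.s))\n",
              x$mobility, x$mobility * 1e8))
  cat(sprintf("  %d nodes, residual %.2g, converged: %s\n",
              length(x$grid), x$residual_norm, x$converged))
  invisible(x)
}

#' Mobility as a function of graft number for a depth scenario
#'
#' Sweeps the soft-layer model over a grid of grafted-molecule counts for
#' one of the two study scenarios: grafting `"uniform"`ly throughout the
#' glycocalyx (depth interval `[0, beta]`) or `"outer"`-directed grafting
#' (`[z_lo_outer, beta]`, default lower bound 2.7 nm). Because grafts are
#' electrically neutral the potential is solved once and reused across the
#' sweep.
#'
#' @param glx A [glycocalyx_model()].
#' @param el An [electrolyte()].
#' @param molecules_grid Non-negative, non-decreasing vector of grafted
#'   molecules per cell.
#' @param scenario `"uniform"` or `"outer"`.
#' @param z_lo_outer Lower depth bound of the outer scenario, m.
#' @param graft_segment_radius,cell_area,segments_per_molecule Graft
#'   parameters passed to [graft_distribution()].
#' @param n_nodes,L Grid controls passed to [build_profile()].
#' @return Data frame with columns `molecules_per_cell` and `mobility`
#'   (m^2/(V.s)).
#' @export
#' @examples
#' mc <- mobility_curve(glycocalyx_model(), electrolyte(),
#'                      c(0, 5e5, 1e6), "outer", n_nodes = 400)
mobility_curve <- function(glx, el, molecules_grid,
                           scenario = c("uniform", "outer"),
                           z_lo_outer = 2.7e-9,
                           graft_segment_radius = hpg_segment_radius(20000),
                           cell_area = 1.4e-10,
                           segments_per_molecule = 1,
                           n_nodes = 2000, L = NULL) {
  scenario <- match.arg(scenario)
  stopifnot(is.numeric(molecules_grid), all(molecules_grid >= 0),
            !is.unsorted(molecules_grid))
  z_lo <- if (scenario == "uniform") 0 else z_lo_outer
  base <- build_profile(glx, NULL, el, L = L, n_nodes = n_nodes)
  psi <- solve_potential(base, el)
  mob <- vapply(molecules_grid, function(nm) {
    prof <- if (nm > 0) {
      g <- graft_distribution(nm, z_lo = z_lo, z_hi = glx$thickness_beta,
                              cell_area = cell_area,
                              graft_segment_radius = graft_segment_radius,
                              segments_per_molecule = segments_per_molecule)
      build_profile(glx, g, el, L = L, n_nodes = n_nodes)
    } else base
    solve_mobility(prof, el, psi = psi)$mobility
  }, numeric(1))
  data.frame(molecules_per_cell = molecules_grid, mobility = mob)
}
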