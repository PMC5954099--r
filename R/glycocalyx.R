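#' Charged, penetrable glycocalyx layer on the cell surface
#'
#' Describes the native glycocalyx as a flat soft layer of thickness
#' \eqn{\beta} carrying hydrodynamically resistive segments (Stokes radius
#' \eqn{a}, areal density \eqn{N_s}) and a fixed charge distributed uniformly
#' through the layer. Defaults describe the red-blood-cell glycocalyx:
#' thickness 7.8 nm, with segment density and total charge calibrated so
#' that the ungrafted mobility in physiological saline lands at the
#' textbook RBC value (about -1.08 um.cm/(V.s)); they are adjustable inputs,
#' not measurements.
#'
#' @param thickness_beta Layer thickness \eqn{\beta} in m.
#' @param segment_radius_a Stokes effective radius of a native glycocalyx
#'   segment, m.
#' @param segment_surface_density Native segments per m^2 of membrane.
#' @param total_surface_charge Fixed charge of the layer per unit membrane
#'   area, C/m^2 (negative for the sialic-acid-rich glycocalyx), distributed
#'   uniformly over `[0, thickness_beta]`.
#' @param membrane_surface_charge Additional charge on the membrane plane
#'   itself, C/m^2 (default 0).
#'
#' @return An object of class `glycocalyx_model`.
#' @export
#' @examples
#' glx <- glycocalyx_model()
glycocalyx_model <- function(thickness_beta = 7.8e-9,
                             segment_radius_a = 0.5e-9,
                             segment_surface_density = 3e16,
                             total_surface_charge = -0.0046,
                             membrane_surface_charge = 0) {
  check_positive(thickness_beta, "thickness_beta")
  check_positive(segment_radius_a, "segment_radius_a")
  check_nonneg(segment_surface_density, "segment_surface_density")
  stopifnot(is.numeric(total_surface_charge), length(total_surface_charge) == 1L,
            is.finite(total_surface_charge),
            is.numeric(membrane_surface_charge), is.finite(membrane_surface_charge))
  structure(list(thickness_beta = thickness_beta,
                 segment_radius_a = segment_radius_a,
                 segment_surface_density = segment_surface_density,
                 total_surface_charge = total_surface_charge,
                 membrane_surface_charge = membrane_surface_charge),
            class = "glycocalyx_model")
}

#' @export
print.glycocalyx_model <- function(x, ...) {
  cat("Glycocalyx soft layer\n")
  cat(sprintf("  thickness beta      : %.3g nm\n", x$thickness_beta * 1e9))
  cat(sprintf("  segment radius a    : %.3g nm\n", x$segment_radius_a * 1e9))
  cat(sprintf("  segment density     : %.3g /m^2\n", x$segment_surface_density))
  cat(sprintf("  layer charge        : %.3g C/m^2\n", x$total_surface_charge))
  cat(sprintf("  membrane charge     : %.3g C/m^2\n", x$membrane_surface_charge))
  invisible(x)
}

#' Hydrodynamic segment radius of a grafted hyperbranched polymer
#'
#' Compact hyperbranched polyglycerols scale as \eqn{R_h = c M^{0.4}}; the
#' default prefactor puts a 20 kDa HPG at about 2.6 nm.
#'
#' @param molar_mass Polymer molar mass in g/mol.
#' @param prefactor Scaling prefactor `c` in m (default 5e-11).
#' @param exponent Scaling exponent (default 0.4, compact/branched regime).
#' @return Hydrodynamic radius in m.
#' @export
#' @examples
#' hpg_segment_radius(20000) * 1e9   # ~2.6 nm
hpg_segment_radius <- function(molar_mass, prefactor = 5e-11, exponent = 0.4) {
  check_positive(molar_mass, "molar_mass")
  prefactor * molar_mass^exponent
}

#' Depth distribution of grafted polymer on the glycocalyx
#'
#' Describes `molecules_per_cell` polymer grafts spread uniformly over the
#' depth interval `[z_lo, z_hi]` of the glycocalyx (z measured outward from
#' the membrane). The two study scenarios are grafting throughout the layer
#' (`z_lo = 0`) and grafting directed to the outer surface
#' (`z_lo = 2.7` nm for a 7.8 nm layer).
#'
#' @param molecules_per_cell Number of grafted polymer molecules per cell.
#' @param z_lo,z_hi Depth interval occupied by the grafts, m.
#' @param cell_area Cell surface area in m^2 (default 1.4e-10, human RBC).
#' @param graft_segment_radius Stokes radius of one graft segment, m
#'   (default: 20 kDa HPG via [hpg_segment_radius()]).
#' @param segments_per_molecule Resistive segments contributed per grafted
#'   molecule (default 1).
#'
#' @return An object of class `graft_distribution`. The areal graft density
#'   `molecules_per_cell / cell_area` is always derived, never stored.
#' @export
#' @examples
#' graft_distribution(9.5e5, z_lo = 2.7e-9, z_hi = 7.8e-9)
graft_distribution <- function(molecules_per_cell,
                               z_lo, z_hi,
                               cell_area = 1.4e-10,
                               graft_segment_radius = hpg_segment_radius(20000),
                               segments_per_molecule = 1) {
  check_nonneg(molecules_per_cell, "molecules_per_cell")
  check_positive(cell_area, "cell_area")
  check_positive(graft_segment_radius, "graft_segment_radius")
  check_positive(segments_per_molecule, "segments_per_molecule")
  check_nonneg(z_lo, "z_lo")
  if (!is.numeric(z_hi) || z_hi <= z_lo)
    stop_glyx("'z_hi' must exceed 'z_lo'", "glyx_invalid_parameter")
  structure(list(molecules_per_cell = molecules_per_cell,
                 z_lo = z_lo, z_hi = z_hi,
                 cell_area = cell_area,
                 graft_segment_radius = graft_segment_radius,
                 segments_per_molecule = segments_per_molecule),
            class = "graft_distribution")
}

#' @export
print.graft_distribution <- function(x, ...) {
  cat(sprintf("Graft distribution: %.3g molecules/cell over %.2g-%.2g nm (a = %.2g nm)\n",
              x$molecules_per_cell, x$z_lo * 1e9, x$z_hi * 1e9,
              x$graft_segment_radius * 1e9))
  invisible(x)
}

#' Discretise glycocalyx and grafts into friction and charge profiles
#'
#' Builds the 1-D layer profile used by the boundary-value solvers: a grid
#' from the membrane (z = 0) to the domain edge `L`, with the Brinkman
#' friction coefficient \eqn{f(z) = 6\pi\eta a\, n(z)} summed over native
#' segments (uniform over `[0, beta]`) and graft segments (uniform over
#' `[z_lo, z_hi]`), and the fixed charge density uniform over `[0, beta]`
#' integrating to the layer's total surface charge. Friction and charge are
#' zero beyond `beta` (and beyond `z_hi` for grafts).
#'
#' @param glx A [glycocalyx_model()].
#' @param graft A [graft_distribution()] or `NULL` for the native layer.
#' @param el An [electrolyte()] (supplies the viscosity for the friction
#'   coefficient).
#' @param L Domain length in m; default `beta + 10 / kappa`.
#' @param n_nodes Number of uniform grid nodes (>= 200; default 2000).
#'
#' @return An object of class `layer_profile` with fields `grid` (m),
#'   `friction_coefficient` (kg m^-3 s^-1 per node), `fixed_charge_density`
#'   (C/m^3 per node), plus the membrane charge and electrolyte carried
#'   along for the solvers.
#' @export
#' @examples
#' el <- electrolyte()
#' prof <- build_profile(glycocalyx_model(), NULL, el)
build_profile <- function(glx, graft = NULL, el = electrolyte(),
                          L = NULL, n_nodes = 2000) {
  stopifnot(inherits(glx, "glycocalyx_model"), inherits(el, "electrolyte"))
  beta <- glx$thickness_beta
  if (is.null(L)) L <- beta + 10 / debye_parameter(el)
  if (L <= beta)
    stop_glyx("domain length L must exceed the layer thickness",
              "glyx_invalid_parameter")
  if (n_nodes < 200)
    stop_glyx("n_nodes must be at least 200", "glyx_invalid_parameter")
  z <- seq(0, L, length.out = n_nodes)
  eta <- el$viscosity

  ## Each node represents a finite-volume cell; box profiles are
  ## cell-averaged so that the weighted node sum integrates the underlying
  ## step function exactly (charge conservation to machine precision).
  h <- z[2] - z[1]
  cell_lo <- pmax(z - h / 2, 0)
  cell_hi <- pmin(z + h / 2, L)
  w <- cell_hi - cell_lo
  box_avg <- function(lo, hi, amplitude) {
    ov <- pmax(0, pmin(hi, cell_hi) - pmax(lo, cell_lo))
    amplitude * ov / w
  }

  ## native segments: volume density = areal density / thickness
  f <- 6 * pi * eta * glx$segment_radius_a *
    box_avg(0, beta, glx$segment_surface_density / beta)

  if (!is.null(graft)) {
    stopifnot(inherits(graft, "graft_distribution"))
    if (graft$z_lo < 0 || graft$z_hi > beta + 1e-15)
      stop_glyx("graft interval must lie within [0, thickness_beta]",
                "glyx_invalid_parameter")
    Gamma <- graft$molecules_per_cell * graft$segments_per_molecule /
      graft$cell_area
    f <- f + 6 * pi * eta * graft$graft_segment_radius *
      box_avg(graft$z_lo, graft$z_hi, Gamma / (graft$z_hi - graft$z_lo))
  }

  rho <- box_avg(0, beta, glx$total_surface_charge / beta)

  structure(list(grid = z,
                 node_weights = w,
                 friction_coefficient = f,
                 fixed_charge_density = rho,
                 membrane_surface_charge = glx$membrane_surface_charge,
                 thickness_beta = beta,
                 electrolyte = el),
            class = "layer_profile")
}

#' @export
print.layer_profile <- function(x, ...) {
  cat(sprintf("Layer profile: %d nodes on [0, %.3g nm], beta = %.3g nm\n",
              length(x$grid), max(x$grid) * 1e9, x$thickness_beta * 1e9))
  cat(sprintf("  max friction: %.3g kg/(m^3 s); layer charge density: %.3g C/m^3\n",
              max(x$friction_coefficient), min(x$fixed_charge_density)))
  invisible(x)
}
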