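## YAML run configuration: schema-checked, unknown keys rejected, resolved
## copy written next to every run's outputs.

config_schema <- list(
  top = c("experiment", "seed", "output_dir", "electrokinetics", "channels",
          "z_step", "k_sigma", "quadrant_mode", "stack", "doses",
          "compression", "cytometry", "mobility", "n_slices", "pixel_size"),
  electrokinetics = c("ionic_strength", "temperature", "viscosity",
                      "relative_permittivity", "thickness_beta",
                      "segment_radius_a", "segment_surface_density",
                      "total_surface_charge", "membrane_surface_charge",
                      "z_lo_outer", "cell_area", "graft_molar_mass",
                      "graft_radius_prefactor", "graft_radius_exponent",
                      "segments_per_molecule", "n_nodes"),
  stack = c("n_slices", "z_step", "xy_shape", "membrane_z", "membrane_width",
            "glyx_height", "probe_distribution", "psf_sigma_z", "photon_gain",
            "read_noise_sd", "bleach_per_slice", "shot_noise", "with_nuclei",
            "with_reference", "seed"),
  cytometry = c("antigens", "control_mfi", "protection_noncrowded",
                "protection_crowded", "cv", "n_events", "n_replicates"),
  mobility = c("scenario", "molecules_grid", "noise_sd", "free_params")
)

check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop_glyx(sprintf("unknown config key(s) in %s: %s", where,
                      paste(unknown, collapse = ", ")),
              "glyx_config_error")
  invisible(x)
}

#' Read and validate a run configuration
#'
#' Reads a YAML run configuration, rejects unknown keys at every level,
#' and fills defaults (seed 1, z-step 0.2 um, k_sigma 2, median quadrant
#' mode, output directory `glyx-results`).
#'
#' @param path YAML file path.
#' @return A validated list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop_glyx(paste("no such config:", path), "glyx_config_error")
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A configuration list (as parsed from YAML).
#' @export
validate_run_config <- function(cfg) {
  check_keys(cfg, config_schema$top, "top level")
  if (is.null(cfg$experiment) ||
      !cfg$experiment %in% c("distribution", "collapse", "camouflage",
                             "mobility"))
    stop_glyx("experiment must be one of distribution, collapse, camouflage, mobility",
              "glyx_config_error")
  for (sec in c("electrokinetics", "stack", "cytometry", "mobility"))
    if (!is.null(cfg[[sec]]))
      check_keys(cfg[[sec]], config_schema[[sec]], sec)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$z_step)) cfg$z_step <- 0.2
  if (is.null(cfg$k_sigma)) cfg$k_sigma <- 2
  if (is.null(cfg$quadrant_mode)) cfg$quadrant_mode <- "median"
  if (is.null(cfg$output_dir)) cfg$output_dir <- "glyx-results"
  class(cfg) <- "run_config"
  cfg
}

ek_from_config <- function(cfg) {
  ek <- if (is.null(cfg$electrokinetics)) list() else cfg$electrokinetics
  el <- electrolyte(
    ionic_strength = ek$ionic_strength %||% 0.145,
    temperature = ek$temperature %||% 298.15,
    viscosity = ek$viscosity %||% 8.9e-4,
    relative_permittivity = ek$relative_permittivity %||% 78.5)
  glx <- glycocalyx_model(
    thickness_beta = ek$thickness_beta %||% 7.8e-9,
    segment_radius_a = ek$segment_radius_a %||% 0.5e-9,
    segment_surface_density = ek$segment_surface_density %||% 3e16,
    total_surface_charge = ek$total_surface_charge %||% -0.0046,
    membrane_surface_charge = ek$membrane_surface_charge %||% 0)
  graft_radius <- hpg_segment_radius(
    ek$graft_molar_mass %||% 20000,
    prefactor = ek$graft_radius_prefactor %||% 5e-11,
    exponent = ek$graft_radius_exponent %||% 0.4)
  list(el = el, glx = glx,
       z_lo_outer = ek$z_lo_outer %||% 2.7e-9,
       cell_area = ek$cell_area %||% 1.4e-10,
       graft_segment_radius = graft_radius,
       segments_per_molecule = ek$segments_per_molecule %||% 1,
       n_nodes = ek$n_nodes %||% 800)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
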