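#' Run a named experiment end to end
#'
#' Wires the generators, quantification and statistics into the study's
#' analyses: `mobility` (simulate a mobility dataset from the soft-layer
#' model, fit both depth scenarios, select one), `distribution` (synthesise
#' non-crowded/uniform vs crowded/outer stacks and quantify quadrant
#' fractions), `collapse` (crowder dose series: quadrants vs dose, height
#' before/during/after, density ratio, photobleach-normalised profiles) and
#' `camouflage` (synthetic cytometry; protection, fold enhancement, Welch
#' tests). Outputs are tidy CSVs plus a JSON provenance record (seed,
#' config hash, package version) and the resolved config, all written under
#' the config's `output_dir`. Identical seeds give identical CSVs.
#'
#' @param config A `run_config` (from [read_run_config()] /
#'   [validate_run_config()]) or a YAML path.
#' @return The result bundle (named list of data frames / objects),
#'   invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) config <- validate_run_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  message(sprintf("[glyx] experiment '%s', seed %d -> %s",
                  config$experiment, config$seed, config$output_dir))

  bundle <- switch(config$experiment,
                   mobility = pipeline_mobility(config),
                   distribution = pipeline_distribution(config),
                   collapse = pipeline_collapse(config),
                   camouflage = pipeline_camouflage(config))

  cfg_path <- file.path(config$output_dir, "resolved-config.yaml")
  cfg_plain <- unclass(config)
  yaml::write_yaml(cfg_plain, cfg_path)
  prov <- list(package = "glyx",
               version = as.character(utils::packageVersion("glyx")),
               experiment = config$experiment,
               seed = config$seed,
               config_md5 = unname(tools::md5sum(cfg_path)),
               outputs = names(bundle$files))
  jsonlite::write_json(prov, file.path(config$output_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  message("[glyx] done")
  invisible(bundle)
}

write_tidy_csv <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

pipeline_mobility <- function(cfg) {
  ek <- ek_from_config(cfg)
  mcfg <- cfg$mobility %||% list()
  scenario <- mcfg$scenario %||% "outer"
  ## as.numeric: YAML scientific notation like 2.5e5 may arrive as character
  grid <- as.numeric(unlist(mcfg$molecules_grid %||%
                              c(0, 2.5e5, 5e5, 7.5e5, 9.5e5)))
  noise <- mcfg$noise_sd %||% 0.02
  dat <- gen_mobility_dataset(ek$glx, ek$el, scenario, grid,
                              noise_sd = noise, seed = cfg$seed,
                              z_lo_outer = ek$z_lo_outer,
                              graft_segment_radius = ek$graft_segment_radius,
                              cell_area = ek$cell_area,
                              segments_per_molecule = ek$segments_per_molecule,
                              n_nodes = ek$n_nodes)
  fit <- fit_scenario(dat, ek$glx, ek$el,
                      free_params = unlist(mcfg$free_params %||%
                                             "total_surface_charge"),
                      z_lo_outer = ek$z_lo_outer,
                      cell_area = ek$cell_area,
                      segments_per_molecule = ek$segments_per_molecule,
                      n_nodes = ek$n_nodes)
  curves <- do.call(rbind, lapply(c("uniform", "outer"), function(sc) {
    mc <- mobility_curve(ek$glx, ek$el, grid, sc,
                         z_lo_outer = ek$z_lo_outer,
                         graft_segment_radius = ek$graft_segment_radius,
                         cell_area = ek$cell_area,
                         segments_per_molecule = ek$segments_per_molecule,
                         n_nodes = ek$n_nodes)
    mc$scenario <- sc
    mc$mobility_um_cm_per_V_s <- mc$mobility * 1e8
    mc
  }))
  dat_out <- dat
  dat_out$mobility_um_cm_per_V_s <- dat_out$mobility * 1e8
  files <- c(
    measurements = write_tidy_csv(dat_out, cfg$output_dir,
                                  "mobility-measurements.csv"),
    curves = write_tidy_csv(curves, cfg$output_dir, "mobility-curves.csv"))
  jsonlite::write_json(
    list(best_scenario = fit$best_scenario, sse = as.list(fit$sse),
         params = fit$params),
    file.path(cfg$output_dir, "mobility-fit.json"),
    auto_unbox = TRUE, digits = NA)
  list(fit = fit, measurements = dat, curves = curves, files = files)
}

stack_spec_from_config <- function(cfg, overrides = list()) {
  sc <- cfg$stack %||% list()
  sc[names(overrides)] <- overrides
  args <- list(
    n_slices = sc$n_slices %||% 40, z_step = sc$z_step %||% cfg$z_step,
    xy_shape = unlist(sc$xy_shape %||% c(24, 24)),
    membrane_z = sc$membrane_z %||% 1.1,
    membrane_width = sc$membrane_width %||% 0.25,
    glyx_height = sc$glyx_height %||% 4,
    probe_distribution = sc$probe_distribution %||% list(type = "uniform"),
    psf_sigma_z = sc$psf_sigma_z %||% 0.1,
    photon_gain = sc$photon_gain %||% 1000,
    read_noise_sd = sc$read_noise_sd %||% 2,
    bleach_per_slice = sc$bleach_per_slice %||% 0.985,
    shot_noise = sc$shot_noise %||% TRUE,
    seed = sc$seed %||% cfg$seed)
  do.call(stack_spec, args)
}

pipeline_distribution <- function(cfg) {
  sp_u <- stack_spec_from_config(cfg, list(
    probe_distribution = list(type = "uniform")))
  base_z <- membrane_slice(sp_u) * sp_u$z_step
  sp_o <- stack_spec_from_config(cfg, list(
    probe_distribution = list(type = "outer",
                              z_lo = base_z + (2.7 / 7.8) * sp_u$glyx_height),
    seed = sp_u$seed + 1000L))
  rows <- lapply(list(noncrowded = sp_u, crowded = sp_o), function(sp) {
    st <- gen_zstack(sp)
    start <- find_membrane_reference(st) + 1L
    top <- estimate_top(st, start = start, k_sigma = cfg$k_sigma)
    q <- quadrant_fractions(st, start = start, top = top,
                            mode = cfg$quadrant_mode)
    cbind(as.data.frame(q), height_um = (top - start + 1) * st$z_step)
  })
  tab <- cbind(condition = names(rows), do.call(rbind, rows))
  rownames(tab) <- NULL
  files <- c(quadrants = write_tidy_csv(tab, cfg$output_dir,
                                        "distribution-quadrants.csv"))
  list(quadrants = tab, files = files)
}

pipeline_collapse <- function(cfg) {
  sp <- stack_spec_from_config(cfg)
  doses <- unlist(cfg$doses %||% c(0, 60, 120, 230))
  cmap <- unlist(cfg$compression %||%
                   stats::setNames(seq(1, 0.5, length.out = length(doses)),
                                   doses))
  ## Fig-3e-style trend: grafted probe rides the washout re-expansion outward
  regraft <- gen_collapse_series(sp, doses, cmap, mode = "regraft")
  dr <- dose_response(regraft$series, k_sigma = cfg$k_sigma,
                      mode = cfg$quadrant_mode)

  ## during-crowding imaging: height collapse, density, FITC concentration
  ser <- gen_collapse_series(sp, doses, cmap, mode = "collapse")
  before <- ser$series[[1]]$stack           # dose 0 = before crowder
  during <- ser$series[[length(ser$series)]]$stack
  after <- ser$washout
  heights <- data.frame(
    condition = c("before", "during", "after"),
    height_um = c(glycocalyx_height(before, k_sigma = cfg$k_sigma),
                  glycocalyx_height(during, k_sigma = cfg$k_sigma),
                  glycocalyx_height(after, k_sigma = cfg$k_sigma)),
    density_ratio = c(density_ratio(before, k_sigma = cfg$k_sigma),
                      density_ratio(during, k_sigma = cfg$k_sigma),
                      density_ratio(after, k_sigma = cfg$k_sigma)))

  norm_mean <- function(st) {
    start <- find_membrane_reference(st) + 1L
    top <- estimate_top(st, start = start, k_sigma = cfg$k_sigma)
    inside <- axial_profile(st, "probe")
    outside <- axial_profile(st, "reference_out")
    nrm <- photobleach_normalize(inside, outside)
    mean(nrm$mfi[start:top])
  }
  fitc <- data.frame(condition = c("before", "during"),
                     normalized_mfi = c(norm_mean(before), norm_mean(during)))

  files <- c(
    dose_response = write_tidy_csv(dr, cfg$output_dir, "collapse-dose-response.csv"),
    heights = write_tidy_csv(heights, cfg$output_dir, "collapse-heights.csv"),
    fitc = write_tidy_csv(fitc, cfg$output_dir, "collapse-fitc.csv"))
  list(dose_response = dr, heights = heights, fitc = fitc, files = files)
}

pipeline_camouflage <- function(cfg) {
  cy <- cfg$cytometry %||% list()
  antigens <- unlist(cy$antigens %||% c("RhD", "CD47"))
  ctrl <- cy$control_mfi %||% 1000
  p_nc <- cy$protection_noncrowded %||% 30
  p_cr <- cy$protection_crowded %||% 60
  cv <- cy$cv %||% 0.1
  n_events <- cy$n_events %||% 10000
  n_rep <- cy$n_replicates %||% 5
  tabs <- lapply(seq_along(antigens), function(i) {
    truths <- c(control = ctrl,
                noncrowded = ctrl * (1 - p_nc / 100),
                crowded = ctrl * (1 - p_cr / 100))
    t <- gen_cytometry(truths, cv = cv, n_events = n_events,
                       n_replicates = n_rep, seed = cfg$seed + i)
    data.frame(antigen = antigens[i], condition = t$group,
               replicate = t$replicate, mfi = t$mfi)
  })
  mfi_table <- do.call(rbind, tabs)
  res <- analyze_protection(mfi_table)
  tests <- do.call(rbind, lapply(names(res$tests), function(ag) {
    tt <- res$tests[[ag]]
    data.frame(antigen = ag, t_statistic = tt$t_statistic,
               welch_df = tt$welch_df, p_value = tt$p_value)
  }))
  files <- c(
    mfi = write_tidy_csv(mfi_table, cfg$output_dir, "camouflage-mfi.csv"),
    protection = write_tidy_csv(res$protection, cfg$output_dir,
                                "camouflage-protection.csv"),
    fold = write_tidy_csv(res$fold, cfg$output_dir, "camouflage-fold.csv"),
    tests = write_tidy_csv(tests, cfg$output_dir, "camouflage-tests.csv"))
  list(mfi_table = mfi_table, protection = res$protection, fold = res$fold,
       tests = res$tests, files = files)
}
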