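## Seeded generators for every input the pipeline consumes: confocal-like
## z-stacks with known axial structure, mobility datasets drawn from the
## electrokinetic model, and log-normal cytometry populations.

#' Specification of a synthetic confocal z-stack
#'
#' Describes the geometry, axial probe distribution, optics and noise of a
#' generated stack. Defaults emulate the study acquisitions: 0.2 um slices
#' and an endothelial-scale glycocalyx a few micrometres tall.
#'
#' @param n_slices Number of z slices.
#' @param z_step Slice spacing, um (default 0.2).
#' @param xy_shape Lateral size `c(ny, nx)` in pixels.
#' @param membrane_z Axial position of the membrane stain peak, um.
#' @param membrane_width Axial Gaussian width of the membrane stain, um.
#' @param glyx_height Glycocalyx height above the membrane, um.
#' @param probe_distribution Axial probe density: `list(type = "uniform")`,
#'   `list(type = "outer", z_lo = <um, absolute>)` or
#'   `list(type = "compressed", c = <factor in (0, 1]>)` (uniform density
#'   compressed toward the membrane, mass conserved).
#' @param psf_sigma_z Axial Gaussian PSF sigma, um (0 = no blur).
#' @param photon_gain Expected photons per slice-mass unit (scales the
#'   Poisson rate); with `shot_noise = FALSE` it is a plain intensity scale.
#' @param read_noise_sd Gaussian read noise SD, intensity units.
#' @param bleach_per_slice Geometric per-slice bleaching factor in (0, 1],
#'   applied to all channels of slice k as `bleach^(k-1)`.
#' @param shot_noise Poisson-resample the expected intensities.
#' @param with_nuclei,with_reference Include the nuclei channel / the
#'   outside-glycocalyx bleaching reference channel.
#' @param seed Integer seed; a fixed seed gives identical output.
#' @return An object of class `stack_spec`.
#' @export
stack_spec <- function(n_slices = 40, z_step = 0.2, xy_shape = c(24, 24),
                       membrane_z = 1.1, membrane_width = 0.25,
                       glyx_height = 4,
                       probe_distribution = list(type = "uniform"),
                       psf_sigma_z = 0, photon_gain = 1000,
                       read_noise_sd = 0, bleach_per_slice = 1,
                       shot_noise = TRUE,
                       with_nuclei = TRUE, with_reference = TRUE,
                       seed = 1L) {
  check_positive(n_slices, "n_slices")
  check_positive(z_step, "z_step")
  check_positive(glyx_height, "glyx_height")
  check_positive(membrane_z, "membrane_z")
  if (bleach_per_slice <= 0 || bleach_per_slice > 1)
    stop_glyx("bleach_per_slice must be in (0, 1]", "glyx_invalid_spec")
  if (glyx_height > n_slices * z_step - membrane_z)
    stop_glyx("glycocalyx does not fit in the stack above the membrane",
              "glyx_invalid_spec")
  if (!is.list(probe_distribution) ||
      !probe_distribution$type %in% c("uniform", "outer", "compressed"))
    stop_glyx("probe_distribution type must be uniform, outer or compressed",
              "glyx_invalid_spec")
  if (probe_distribution$type == "compressed") {
    cc <- probe_distribution$c
    if (is.null(cc) || cc <= 0 || cc > 1)
      stop_glyx("compression factor c must be in (0, 1]", "glyx_invalid_spec")
  }
  structure(list(n_slices = as.integer(n_slices), z_step = z_step,
                 xy_shape = xy_shape, membrane_z = membrane_z,
                 membrane_width = membrane_width, glyx_height = glyx_height,
                 probe_distribution = probe_distribution,
                 psf_sigma_z = psf_sigma_z, photon_gain = photon_gain,
                 read_noise_sd = read_noise_sd,
                 bleach_per_slice = bleach_per_slice,
                 shot_noise = shot_noise,
                 with_nuclei = with_nuclei, with_reference = with_reference,
                 seed = as.integer(seed)),
            class = "stack_spec")
}

## slice index whose extent [(m-1) dz, m dz) contains the membrane peak
membrane_slice <- function(spec) max(1L, ceiling(spec$membrane_z / spec$z_step))

## Per-slice probe mass (sums to 1 when mass is conserved and the support
## fits): exact integral of the axial density over each slice extent.
## `compress` is an additional affine compression toward the membrane.
probe_slice_mass <- function(spec, compress = 1, conserve_mass = TRUE) {
  dz <- spec$z_step
  z0 <- membrane_slice(spec) * dz      # glycocalyx base: top of membrane slice
  H <- spec$glyx_height
  pd <- spec$probe_distribution
  if (pd$type == "compressed") {
    compress <- compress * pd$c
    lo <- z0; hi <- z0 + H
  } else if (pd$type == "outer") {
    if (is.null(pd$z_lo))
      stop_glyx("outer distribution needs z_lo (um, absolute)",
                "glyx_invalid_spec")
    lo <- pd$z_lo; hi <- z0 + H
    if (lo < z0 || lo >= hi)
      stop_glyx("outer z_lo must lie within the glycocalyx span",
                "glyx_invalid_spec")
  } else {
    lo <- z0; hi <- z0 + H
  }
  ## affine compression toward the base z0, amplitude rescaled iff mass
  ## is conserved
  lo_c <- z0 + compress * (lo - z0)
  hi_c <- z0 + compress * (hi - z0)
  dens <- 1 / (hi_c - lo_c)
  if (!conserve_mass) dens <- dens * compress
  edges <- seq(0, spec$n_slices * dz, by = dz)
  ov <- pmax(0, pmin(edges[-1], hi_c) - pmax(edges[-length(edges)], lo_c))
  ov * dens
}

gaussian_blur_1d <- function(v, sigma_slices) {
  if (sigma_slices <= 0) return(v)
  half <- max(1L, ceiling(4 * sigma_slices))
  kern <- stats::dnorm(seq(-half, half), sd = sigma_slices)
  kern <- kern / sum(kern)
  n <- length(v)
  padded <- c(rep(0, half), v, rep(0, half))
  out <- vapply(seq_len(n), function(i)
    sum(padded[i:(i + 2 * half)] * rev(kern)), numeric(1))
  out
}

#' Generate a synthetic multichannel z-stack
#'
#' Builds the membrane channel as a Gaussian axial profile peaked at
#' `membrane_z`, the probe channel from the chosen axial density on the
#' glycocalyx span (blurred by the axial PSF, scaled by `photon_gain`,
#' Poisson-sampled, plus Gaussian read noise, times the per-slice bleaching
#' factor), an optional nuclei channel below the membrane and an optional
#' constant `reference_out` channel carrying the same bleaching. Fully
#' deterministic for a fixed spec seed.
#'
#' @param spec A [stack_spec()].
#' @param compress Additional compression factor applied to the probe
#'   density (used by [gen_collapse_series()]).
#' @param conserve_mass Conserve total probe mass under compression.
#' @return A [zstack()].
#' @export
#' @examples
#' st <- gen_zstack(stack_spec(seed = 7, shot_noise = FALSE))
gen_zstack <- function(spec, compress = 1, conserve_mass = TRUE) {
  stopifnot(inherits(spec, "stack_spec"))
  dz <- spec$z_step
  nz <- spec$n_slices
  ny <- spec$xy_shape[1]; nx <- spec$xy_shape[2]
  zc <- (seq_len(nz) - 0.5) * dz

  probe_ax <- probe_slice_mass(spec, compress, conserve_mass) *
    spec$photon_gain
  probe_ax <- gaussian_blur_1d(probe_ax, spec$psf_sigma_z / dz)
  membrane_ax <- spec$photon_gain *
    exp(-(zc - spec$membrane_z)^2 / (2 * spec$membrane_width^2))
  bleach <- spec$bleach_per_slice^(seq_len(nz) - 1L)

  build_channel <- function(ax) {
    arr <- array(rep(ax, each = ny * nx), c(ny, nx, nz))
    if (spec$shot_noise)
      arr[] <- stats::rpois(length(arr), lambda = arr)
    if (spec$read_noise_sd > 0)
      arr[] <- arr + stats::rnorm(length(arr), 0, spec$read_noise_sd)
    arr <- sweep(arr, 3, bleach, `*`)
    arr[arr < 0] <- 0
    arr
  }

  channels <- with_seed(spec$seed, {
    ch <- list(membrane = build_channel(membrane_ax),
               probe = build_channel(probe_ax))
    if (spec$with_nuclei) {
      nuc_z <- spec$membrane_z * 0.5
      nuc_ax <- 0.5 * spec$photon_gain *
        exp(-(zc - nuc_z)^2 / (2 * (spec$membrane_width * 2)^2))
      ch$nuclei <- build_channel(nuc_ax)
    }
    if (spec$with_reference)
      ch$reference_out <- build_channel(rep(0.25 * spec$photon_gain, nz))
    ch
  })
  zstack(channels, z_step = dz,
         metadata = list(spec_seed = spec$seed, compress = compress))
}

#' Generate a crowder dose series of collapsing stacks
#'
#' Two emulations share the dose -> compression map:
#'
#' * `mode = "collapse"` images the layer *during* crowding: the probe
#'   density is compressed toward the membrane by the dose's factor `c`
#'   (mass conserved by default, emulating fluid expulsion without probe
#'   loss), so the apparent height scales by `c` and the per-slice density
#'   by `1/c`.
#' * `mode = "regraft"` images grafted probe *after* washout: material
#'   deposited while the layer was collapsed to `c` of its height rides the
#'   re-expansion outward and occupies the outer `c` fraction of the
#'   restored layer (uniform over `[(1 - c) H, H]` above the membrane), so
#'   stronger crowding shifts occupancy from Q1 toward Q4.
#'
#' Both return an after-washout stack regenerated at `c = 1` to emulate the
#' reversible recovery of the layer.
#'
#' @param base A [stack_spec()] with a `uniform` probe distribution; each
#'   dose reuses it with a dose-specific seed offset so stacks are
#'   independent but reproducible.
#' @param doses Numeric crowder doses, mg/mL.
#' @param compression_map Named numeric (names = doses) or function
#'   dose -> compression factor in (0, 1], non-increasing in dose.
#' @param conserve_mass Conserve total probe mass (default TRUE).
#' @param mode `"collapse"` (during-crowding imaging) or `"regraft"`
#'   (post-washout graft distribution).
#' @return List with `series` (list of `list(dose, stack)`) and `washout`
#'   (a [zstack()] at `c = 1`).
#' @export
gen_collapse_series <- function(base, doses, compression_map,
                                conserve_mass = TRUE,
                                mode = c("collapse", "regraft")) {
  mode <- match.arg(mode)
  stopifnot(inherits(base, "stack_spec"))
  if (length(doses) < 2L)
    stop_glyx("need at least two doses", "glyx_invalid_spec")
  cmap <- if (is.function(compression_map)) compression_map(doses)
  else compression_map[as.character(doses)]
  cmap <- as.numeric(cmap)
  if (any(!is.finite(cmap)) || any(cmap <= 0) || any(cmap > 1))
    stop_glyx("compression factors must lie in (0, 1]", "glyx_invalid_spec")
  if (any(diff(cmap) > 0))
    stop_glyx("compression must be non-increasing in dose", "glyx_invalid_spec")
  if (mode == "regraft" && base$probe_distribution$type != "uniform")
    stop_glyx("regraft mode requires a uniform base distribution",
              "glyx_invalid_spec")
  series <- lapply(seq_along(doses), function(i) {
    sp <- base
    sp$seed <- base$seed + i
    st <- if (mode == "collapse") {
      gen_zstack(sp, compress = cmap[i], conserve_mass = conserve_mass)
    } else {
      z0 <- membrane_slice(sp) * sp$z_step
      sp$probe_distribution <- list(
        type = "outer", z_lo = z0 + (1 - cmap[i]) * sp$glyx_height)
      gen_zstack(sp)
    }
    list(dose = doses[i], stack = st)
  })
  sp_w <- base
  sp_w$seed <- base$seed + length(doses) + 1L
  list(series = series,
       washout = gen_zstack(sp_w, compress = 1,
                            conserve_mass = conserve_mass))
}

#' Generate a synthetic mobility dataset from the electrokinetic model
#'
#' Evaluates [mobility_curve()] on the molecule grid and adds seeded
#' Gaussian noise proportional to each point's mobility magnitude.
#'
#' @param glx A [glycocalyx_model()].
#' @param el An [electrolyte()].
#' @param scenario `"uniform"` or `"outer"`.
#' @param molecules_grid Graft counts per cell.
#' @param noise_sd Relative noise level (0.02 = 2%).
#' @param seed Integer seed.
#' @param ... Passed to [mobility_curve()] (e.g. `graft_segment_radius`,
#'   `n_nodes`).
#' @return Data frame `molecules_per_cell`, `mobility`, `sd` (SI units),
#'   ready for [fit_scenario()].
#' @export
gen_mobility_dataset <- function(glx, el, scenario, molecules_grid,
                                 noise_sd = 0.02, seed = 1L, ...) {
  check_nonneg(noise_sd, "noise_sd")
  mc <- mobility_curve(glx, el, molecules_grid, scenario, ...)
  sd_abs <- pmax(noise_sd * abs(mc$mobility), 1e-6 * abs(mc$mobility))
  noisy <- if (noise_sd > 0)
    with_seed(seed, mc$mobility + stats::rnorm(nrow(mc), 0, sd_abs))
  else mc$mobility
  data.frame(molecules_per_cell = mc$molecules_per_cell,
             mobility = noisy, sd = sd_abs)
}

#' Generate log-normal cytometry replicate MFIs
#'
#' Event intensities are log-normal per group with `meanlog = log(truth)`
#' and `sdlog = cv` (CV on the log scale), so the replicate MFI — the
#' median of the acquired events — is an unbiased estimate of the group
#' truth.
#'
#' @param mfi_true_by_group Named numeric vector of true group MFIs.
#' @param cv Event-level coefficient of variation (log scale), > 0.
#' @param n_events Events acquired per replicate (>= 100; default 10000).
#' @param n_replicates Replicates per group.
#' @param seed Integer seed.
#' @return Data frame with `group`, `replicate`, `mfi`.
#' @export
#' @examples
#' gen_cytometry(c(control = 1000, crowded = 400), cv = 0.1,
#'               n_events = 500, n_replicates = 3, seed = 1)
gen_cytometry <- function(mfi_true_by_group, cv, n_events = 10000,
                          n_replicates = 5, seed = 1L) {
  if (is.null(names(mfi_true_by_group)) || any(!nzchar(names(mfi_true_by_group))))
    stop_glyx("mfi_true_by_group must be a named vector", "glyx_invalid_spec")
  if (any(mfi_true_by_group <= 0))
    stop_glyx("group MFI truths must be positive", "glyx_invalid_spec")
  check_positive(cv, "cv")
  if (n_events < 100)
    stop_glyx("n_events must be at least 100", "glyx_invalid_spec")
  with_seed(seed, {
    rows <- lapply(names(mfi_true_by_group), function(g) {
      mfis <- vapply(seq_len(n_replicates), function(r)
        replicate_mfi(stats::rlnorm(n_events,
                                    meanlog = log(mfi_true_by_group[[g]]),
                                    sdlog = cv)), numeric(1))
      data.frame(group = g, replicate = seq_len(n_replicates), mfi = mfis)
    })
    do.call(rbind, rows)
  })
}
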