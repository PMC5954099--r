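#' Multichannel confocal z-stack container
#'
#' Holds one or more fluorescence channels as 3-D arrays indexed
#' `[y, x, z]`, with slice 1 the bottom (basal) slice. Channels are named by
#' role; quantification requires at least `membrane` and `probe`, with
#' optional `nuclei` (nuclear stain, cell-number proxy) and `reference_out`
#' (signal outside the glycocalyx used for photobleach normalisation).
#'
#' @param channels Named list of non-negative numeric arrays, identical
#'   dimensions, names from `membrane`, `probe`, `nuclei`, `reference_out`.
#' @param z_step Axial slice spacing in micrometres (default 0.2).
#' @param pixel_size Lateral pixel size in micrometres.
#' @param metadata Free-form list.
#' @return An object of class `zstack`.
#' @export
zstack <- function(channels, z_step = 0.2, pixel_size = 0.1, metadata = list()) {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels))))
    stop_glyx("channels must be a named list of arrays", "glyx_format_error")
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, integer(1)) != 3L))
    stop_glyx("each channel must be a 3-D array [y, x, z]", "glyx_format_error")
  if (length(unique(dims)) != 1L)
    stop_glyx("all channels must share the same dimensions", "glyx_format_error")
  if (any(vapply(channels, function(a) any(a < 0), logical(1))))
    stop_glyx("channel intensities must be non-negative", "glyx_format_error")
  check_positive(z_step, "z_step")
  structure(list(channels = channels, z_step = z_step,
                 pixel_size = pixel_size, metadata = metadata),
            class = "zstack")
}

#' @export
print.zstack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("zstack: %d x %d pixels, %d slices (z_step %.3g um)\n",
              d[1], d[2], d[3], x$z_step))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

n_slices <- function(stack) dim(stack$channels[[1]])[3]

require_channels <- function(stack, roles) {
  missing <- setdiff(roles, names(stack$channels))
  if (length(missing))
    stop_glyx(paste("stack is missing channel(s):",
                    paste(missing, collapse = ", ")), "glyx_format_error")
  invisible(stack)
}

default_roi <- function(stack) {
  d <- dim(stack$channels[[1]])
  matrix(TRUE, d[1], d[2])
}

check_roi <- function(stack, roi) {
  if (is.null(roi)) return(default_roi(stack))
  d <- dim(stack$channels[[1]])
  if (!is.logical(roi) || !identical(dim(roi), d[1:2]))
    stop_glyx("roi must be a logical [y, x] matrix matching the stack",
              "glyx_format_error")
  if (!any(roi))
    stop_glyx("roi must contain at least one pixel", "glyx_format_error")
  roi
}

#' Per-slice intensity profile of one channel within an ROI
#'
#' @param stack A [zstack()].
#' @param channel Channel role name.
#' @param roi Logical `[y, x]` mask, or `NULL` for the whole field.
#' @param statistic `"median"` (per-slice MFI, the default) or `"sum"`
#'   (integrated intensity).
#' @return Data frame with columns `slice_index` and `mfi`.
#' @export
axial_profile <- function(stack, channel, roi = NULL,
                          statistic = c("median", "sum")) {
  stopifnot(inherits(stack, "zstack"))
  statistic <- match.arg(statistic)
  require_channels(stack, channel)
  roi <- check_roi(stack, roi)
  arr <- stack$channels[[channel]]
  fun <- if (statistic == "median") stats::median else sum
  v <- vapply(seq_len(dim(arr)[3]),
              function(k) fun(arr[, , k][roi]), numeric(1))
  data.frame(slice_index = seq_along(v), mfi = v)
}

#' Write a z-stack as multi-page TIFF with a JSON sidecar
#'
#' Pages are written channel-major (all slices of the first channel, then
#' the next), as 32-bit float TIFF scaled to `[0, 1]`; the scale factor,
#' channel roles, slice count, z-step and pixel size go to `<path>.json`.
#'
#' @param stack A [zstack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_zstack <- function(stack, path) {
  stopifnot(inherits(stack, "zstack"))
  scale <- max(1, vapply(stack$channels, max, numeric(1)))
  pages <- list()
  for (ch in names(stack$channels)) {
    arr <- stack$channels[[ch]] / scale
    for (k in seq_len(dim(arr)[3])) pages[[length(pages) + 1L]] <- arr[, , k]
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(roles = names(stack$channels),
               n_slices = n_slices(stack),
               z_step = stack$z_step,
               pixel_size = stack$pixel_size,
               intensity_scale = scale)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a z-stack written by [write_zstack()] (or described by a config)
#'
#' Metadata is resolved sidecar-first (`<path>.json`), then from the
#' config's `channels`/`n_slices`/`z_step` entries, then the 0.2 um z-step
#' default.
#'
#' @param path TIFF path.
#' @param config Optional list (e.g. from [read_run_config()]) with
#'   `channels` (named list role -> 0-based channel index), `n_slices` and
#'   `z_step` used when no sidecar is present; its `z_step` also overrides
#'   the default when the sidecar lacks one.
#' @return A [zstack()].
#' @export
read_zstack <- function(path, config = NULL) {
  if (!file.exists(path))
    stop_glyx(paste("no such file:", path), "glyx_format_error")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    roles <- meta$roles
    nz <- meta$n_slices
    z_step <- meta$z_step
    scale <- meta$intensity_scale
    pixel_size <- if (!is.null(meta$pixel_size)) meta$pixel_size else 0.1
  } else {
    if (is.null(config) || is.null(config$channels) || is.null(config$n_slices))
      stop_glyx("no sidecar metadata: config must supply channels and n_slices",
                "glyx_format_error")
    idx <- order(unlist(config$channels))
    roles <- names(config$channels)[idx]
    nz <- config$n_slices
    z_step <- if (!is.null(config$z_step)) config$z_step else 0.2
    scale <- 1
    pixel_size <- if (!is.null(config$pixel_size)) config$pixel_size else 0.1
  }
  if (length(pages) != length(roles) * nz)
    stop_glyx(sprintf(
      "page count %d does not match %d channel(s) x %d slice(s)",
      length(pages), length(roles), nz), "glyx_format_error")
  d <- dim(pages[[1]])
  channels <- list()
  for (i in seq_along(roles)) {
    arr <- array(0, c(d[1], d[2], nz))
    for (k in seq_len(nz)) arr[, , k] <- pages[[(i - 1L) * nz + k]] * scale
    channels[[roles[i]]] <- arr
  }
  zstack(channels, z_step = z_step, pixel_size = pixel_size,
         metadata = list(source = path))
}
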