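## Quadrant quantification of axial probe distributions, glycocalyx
## height/density under crowding, and photobleach normalisation.

#' Locate the membrane reference slice
#'
#' Returns the index of the slice whose within-ROI membrane MFI is maximal
#' (ties broken to the lowest index). Downstream glycocalyx measurements
#' start at the slice immediately following this reference, mirroring the
#' rule that intensity is compiled from slices after the membrane stain is
#' in focus at maximal intensity.
#'
#' @param stack A [zstack()] with a `membrane` channel.
#' @param roi Logical mask or `NULL`.
#' @return Slice index (1-based).
#' @export
find_membrane_reference <- function(stack, roi = NULL) {
  require_channels(stack, "membrane")
  prof <- axial_profile(stack, "membrane", roi)$mfi
  bg <- top_slice_background(prof, k_sigma = 2)
  peak <- max(prof)
  if (peak <= bg || all(prof == prof[1]))
    stop_glyx("no membrane peak detected (flat or background-level profile)",
              "glyx_no_membrane")
  which.max(prof)   # which.max already takes the lowest index on ties
}

## background = mean + k_sigma * SD of the top 10% of slices (assumed
## signal-free above the glycocalyx)
top_slice_background <- function(profile, k_sigma = 2) {
  nz <- length(profile)
  n_top <- max(1L, ceiling(0.1 * nz))
  top_vals <- profile[(nz - n_top + 1L):nz]
  s <- stats::sd(top_vals)
  if (is.na(s)) s <- 0
  mean(top_vals) + k_sigma * s
}

#' Detect the apical extent of the glycocalyx
#'
#' Background is estimated from the top 10% of slices (mean + `k_sigma`
#' standard deviations of the probe MFI); the top is the highest slice at
#' or above `start` whose probe MFI exceeds that background.
#'
#' @param stack A [zstack()] with a `probe` channel.
#' @param roi Logical mask or `NULL`.
#' @param start First measurement slice (membrane reference + 1).
#' @param k_sigma Background threshold multiplier (default 2).
#' @param min_frac Relative floor: a slice must also exceed this fraction
#'   of the profile maximum, guarding the background rule when the top
#'   slices are noise-dominated near zero (default 0.01).
#' @return Top slice index, guaranteed greater than `start`.
#' @export
estimate_top <- function(stack, roi = NULL, start, k_sigma = 2,
                         min_frac = 0.01) {
  require_channels(stack, "probe")
  prof <- axial_profile(stack, "probe", roi)$mfi
  nz <- length(prof)
  if (start < 1L || start > nz)
    stop_glyx("start slice out of bounds", "glyx_invalid_parameter")
  bg <- max(top_slice_background(prof, k_sigma), min_frac * max(prof))
  above <- which(prof > bg)
  above <- above[above >= start]
  if (!length(above) || max(above) <= start)
    stop_glyx("no probe signal above background beyond the start slice",
              "glyx_no_signal")
  max(above)
}

#' Quadrant fractions of the axial probe distribution
#'
#' Splits the continuous measurement span — from the bottom of slice
#' `start` to the top of slice `top` — into four equal sub-intervals (Q1
#' basal, next to the membrane; Q4 apical) and apportions each slice's
#' probe signal to quadrants by the overlap of its one-slice extent with
#' each quadrant, so no slice is dropped for spans not divisible by four.
#'
#' @param stack A [zstack()] with a `probe` channel.
#' @param roi Logical mask or `NULL`.
#' @param start,top First and last measurement slices (`top > start`).
#' @param mode Per-slice statistic: `"median"` (MFI, default) or
#'   `"integrated"` (summed intensity).
#' @return An object of class `quadrant_result` with fields `q1`..`q4`
#'   (fractions summing to 1), `start_slice`, `top_slice`, `total_signal`.
#' @export
quadrant_fractions <- function(stack, roi = NULL, start, top,
                               mode = c("median", "integrated")) {
  mode <- match.arg(mode)
  require_channels(stack, "probe")
  if (top <= start)
    stop_glyx("top slice must exceed start slice", "glyx_invalid_parameter")
  prof <- axial_profile(stack, "probe", roi,
                        statistic = if (mode == "median") "median" else "sum")
  v <- prof$mfi[start:top]
  total <- sum(v)
  if (total <= 0)
    stop_glyx("zero total probe signal in the measurement span",
              "glyx_undefined_fraction")
  nsl <- length(v)           # span length in slice units
  w <- nsl / 4               # quadrant width, slice units
  qsum <- numeric(4)
  for (j in seq_len(nsl)) {  # slice j occupies [j-1, j)
    for (q in 1:4) {
      ov <- max(0, min(j, q * w) - max(j - 1, (q - 1) * w))
      qsum[q] <- qsum[q] + v[j] * ov
    }
  }
  fr <- qsum / sum(qsum)
  structure(list(q1 = fr[1], q2 = fr[2], q3 = fr[3], q4 = fr[4],
                 start_slice = start, top_slice = top,
                 total_signal = total, mode = mode),
            class = "quadrant_result")
}

#' @export
print.quadrant_result <- function(x, ...) {
  cat(sprintf("Quadrant fractions (slices %d-%d, %s mode):\n",
              x$start_slice, x$top_slice, x$mode))
  cat(sprintf("  Q1 %.3f  Q2 %.3f  Q3 %.3f  Q4 %.3f\n", x$q1, x$q2, x$q3, x$q4))
  invisible(x)
}

#' @export
as.data.frame.quadrant_result <- function(x, ...) {
  data.frame(q1 = x$q1, q2 = x$q2, q3 = x$q3, q4 = x$q4,
             start_slice = x$start_slice, top_slice = x$top_slice,
             total_signal = x$total_signal)
}

#' Inner/outer split of quadrant fractions
#'
#' Collapses the four quadrants into the inner (Q1 + Q2, membrane-proximal)
#' and outer (Q3 + Q4, apical) halves of the glycocalyx.
#'
#' @param q A [quadrant_fractions()] result.
#' @return Named numeric vector `c(inner = , outer = )`, summing to 1.
#' @export
inner_outer_shift <- function(q) {
  stopifnot(inherits(q, "quadrant_result"))
  c(inner = q$q1 + q$q2, outer = q$q3 + q$q4)
}

#' Quadrant fractions across a crowder dose series
#'
#' @param stacks List of entries `list(dose = <mg/mL>, stack = <zstack>)`.
#' @param roi Logical mask or `NULL`.
#' @param k_sigma Background multiplier for [estimate_top()].
#' @param mode Quadrant mode, see [quadrant_fractions()].
#' @return Data frame: one row per dose with `dose`, `q1`..`q4`,
#'   `start_slice`, `top_slice`, `height_um`.
#' @export
dose_response <- function(stacks, roi = NULL, k_sigma = 2,
                          mode = c("median", "integrated")) {
  mode <- match.arg(mode)
  if (length(stacks) < 2L)
    stop_glyx("dose series needs at least two doses", "glyx_invalid_parameter")
  rows <- lapply(stacks, function(entry) {
    dose <- entry$dose
    st <- entry$stack
    res <- tryCatch({
      start <- find_membrane_reference(st, roi) + 1L
      top <- estimate_top(st, roi, start, k_sigma)
      q <- quadrant_fractions(st, roi, start, top, mode)
      cbind(data.frame(dose = dose), as.data.frame(q),
            height_um = (top - start + 1) * st$z_step)
    }, glyx_error = function(e)
      stop_glyx(sprintf("dose %g: %s", dose, conditionMessage(e)),
                class(e)[1]))
    res
  })
  do.call(rbind, rows)
}

#' Glycocalyx height from membrane reference to detected top
#'
#' @param stack A [zstack()] with `membrane` and `probe` channels.
#' @param roi Logical mask or `NULL`.
#' @param k_sigma Background multiplier.
#' @return Height in micrometres: `(top - start + 1) * z_step`.
#' @export
glycocalyx_height <- function(stack, roi = NULL, k_sigma = 2) {
  require_channels(stack, c("membrane", "probe"))
  start <- find_membrane_reference(stack, roi) + 1L
  top <- estimate_top(stack, roi, start, k_sigma)
  (top - start + 1) * stack$z_step
}

#' Probe density normalised to cell number
#'
#' Integrated probe intensity over the glycocalyx span divided by the
#' integrated nuclear-stain intensity, the cell-number proxy. With
#' `count_nuclei = TRUE` the denominator is instead the number of connected
#' nuclear components above the Otsu-like half-max threshold in the
#' maximum-intensity projection.
#'
#' @param stack A [zstack()] with `membrane`, `probe` and `nuclei` channels.
#' @param roi Logical mask or `NULL`.
#' @param k_sigma Background multiplier.
#' @param count_nuclei Use connected-component nucleus counting instead of
#'   integrated nuclear intensity.
#' @return Dimensionless density ratio.
#' @export
density_ratio <- function(stack, roi = NULL, k_sigma = 2,
                          count_nuclei = FALSE) {
  require_channels(stack, c("membrane", "probe", "nuclei"))
  roi_m <- check_roi(stack, roi)
  start <- find_membrane_reference(stack, roi) + 1L
  top <- estimate_top(stack, roi, start, k_sigma)
  probe <- stack$channels$probe
  probe_total <- sum(vapply(start:top,
                            function(k) sum(probe[, , k][roi_m]), numeric(1)))
  nuc <- stack$channels$nuclei
  if (count_nuclei) {
    proj <- apply(nuc, c(1, 2), max)
    denom <- count_components(proj > max(proj) / 2 & roi_m)
  } else {
    denom <- sum(vapply(seq_len(dim(nuc)[3]),
                        function(k) sum(nuc[, , k][roi_m]), numeric(1)))
  }
  if (denom <= 0)
    stop_glyx("zero nuclei signal: cannot normalise to cell number",
              "glyx_no_signal")
  probe_total / denom
}

## 4-connected component count by flood fill (small masks only)
count_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nlab <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (mask[i, j] && lab[i, j] == 0L) {
      nlab <- nlab + 1L
      queue <- list(c(i, j))
      while (length(queue)) {
        p <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
        if (p[1] < 1 || p[2] < 1 || p[1] > nrow(mask) || p[2] > ncol(mask))
          next
        if (!mask[p[1], p[2]] || lab[p[1], p[2]] != 0L) next
        lab[p[1], p[2]] <- nlab
        queue <- c(queue, list(p + c(1, 0)), list(p - c(1, 0)),
                   list(p + c(0, 1)), list(p - c(0, 1)))
      }
    }
  }
  nlab
}

#' Photobleach normalisation of an axial profile
#'
#' Divides the in-glycocalyx profile by a same-stack reference profile
#' taken outside the glycocalyx. Any per-slice multiplicative bleaching
#' factor common to both profiles cancels exactly, which is the point: the
#' stepwise acquisition bleaches each successive slice, and the outside
#' signal carries the same decay.
#'
#' @param inside Data frame with `slice_index`, `mfi`: profile within the
#'   glycocalyx.
#' @param outside Data frame with the same `slice_index` and strictly
#'   positive `mfi`: reference profile outside the glycocalyx.
#' @return Data frame with `slice_index` and normalised `mfi`.
#' @export
photobleach_normalize <- function(inside, outside) {
  if (!identical(inside$slice_index, outside$slice_index))
    stop_glyx("inside and outside profiles must share slice indices",
              "glyx_invalid_parameter")
  if (any(outside$mfi <= 0))
    stop_glyx("outside reference intensity must be positive at every slice",
              "glyx_division_guard")
  data.frame(slice_index = inside$slice_index,
             mfi = inside$mfi / outside$mfi)
}
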