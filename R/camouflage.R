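## Immunocamouflage metrics from flow-cytometry MFIs: relative protection,
## fold enhancement and Welch group comparisons.

#' Relative protection of a membrane antigen
#'
#' Percent reduction in antibody-binding MFI on modified cells relative to
#' the unmodified control:
#' \deqn{P = 100 (1 - MFI_{modified} / MFI_{control}).}
#' Negative values (binding above control) are reported, not clipped —
#' clipping would hide failed grafting — and flagged via the
#' `above_control` attribute.
#'
#' @param mfi_modified MFI of the polymer-grafted sample (>= 0).
#' @param mfi_control MFI of the unmodified control (> 0).
#' @return Protection in percent, with attribute `above_control` set when
#'   negative.
#' @export
#' @examples
#' relative_protection(500, 1000)   # 50
relative_protection <- function(mfi_modified, mfi_control) {
  if (any(mfi_control <= 0))
    stop_glyx("control MFI must be positive", "glyx_invalid_parameter")
  if (any(mfi_modified < 0))
    stop_glyx("modified MFI must be non-negative", "glyx_invalid_parameter")
  p <- 100 * (1 - mfi_modified / mfi_control)
  attr(p, "above_control") <- p < 0
  p
}

#' Fold enhancement of protection by crowded grafting
#'
#' Ratio of the protection achieved under crowded grafting to that under
#' non-crowded grafting; the effect-size form in which outward-directed
#' grafting of ~9.5e5 HPG molecules per cell roughly doubles RhD
#' camouflage.
#'
#' @param protection_crowded Protection (%) under crowded grafting.
#' @param protection_noncrowded Protection (%) under non-crowded grafting
#'   (> 0).
#' @return Fold enhancement (dimensionless).
#' @export
#' @examples
#' fold_enhancement(40, 20)   # 2
fold_enhancement <- function(protection_crowded, protection_noncrowded) {
  if (any(protection_noncrowded <= 0))
    stop_glyx("non-crowded protection must be positive for a fold ratio",
              "glyx_invalid_parameter")
  protection_crowded / protection_noncrowded
}

#' Welch two-sample comparison
#'
#' Two-tailed t-test with Welch's correction (unequal variances,
#' Satterthwaite degrees of freedom) between two groups of replicate
#' measurements.
#'
#' @param groupA,groupB Numeric vectors, each of length >= 2.
#' @return An object of class `group_comparison`: `t_statistic`,
#'   `welch_df`, `p_value`, `group_means`, `group_sds`, `n_per_group`.
#' @export
#' @examples
#' welch_compare(c(1, 2, 3), c(11, 12, 13))$p_value
welch_compare <- function(groupA, groupB) {
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop_glyx("each group needs at least two values", "glyx_invalid_parameter")
  if (stats::var(groupA) == 0 && stats::var(groupB) == 0) {
    if (mean(groupA) == mean(groupB)) {
      ## identical groups: no evidence of difference
      out <- list(t_statistic = 0, welch_df = length(groupA) + length(groupB) - 2,
                  p_value = 1,
                  group_means = c(mean(groupA), mean(groupB)),
                  group_sds = c(0, 0),
                  n_per_group = c(length(groupA), length(groupB)))
      class(out) <- "group_comparison"
      return(out)
    }
    stop_glyx("zero variance in both groups with unequal means",
              "glyx_invalid_parameter")
  }
  tt <- stats::t.test(groupA, groupB, var.equal = FALSE,
                      alternative = "two.sided")
  out <- list(t_statistic = unname(tt$statistic),
              welch_df = unname(tt$parameter),
              p_value = tt$p.value,
              group_means = c(mean(groupA), mean(groupB)),
              group_sds = c(stats::sd(groupA), stats::sd(groupB)),
              n_per_group = c(length(groupA), length(groupB)))
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Welch two-sample comparison: t = %.4g, df = %.3f, p = %.4g\n",
              x$t_statistic, x$welch_df, x$p_value))
  cat(sprintf("  means %.4g vs %.4g (n = %d, %d)\n",
              x$group_means[1], x$group_means[2],
              x$n_per_group[1], x$n_per_group[2]))
  invisible(x)
}

#' Median event intensity per replicate
#'
#' Event-level reducer: replicate MFI is the median of the acquired events
#' (typically 10000 per replicate).
#'
#' @param events Numeric vector of event intensities.
#' @return Median intensity.
#' @export
replicate_mfi <- function(events) {
  if (!length(events))
    stop_glyx("no events", "glyx_invalid_parameter")
  stats::median(events)
}

#' Full protection analysis of a replicate MFI table
#'
#' Takes the long-format table (`antigen`, `condition` in
#' `control`/`noncrowded`/`crowded`, `replicate`, `mfi`), computes per
#' antigen the relative protection of each grafted condition against the
#' control mean, the crowded-vs-noncrowded fold enhancement, and the Welch
#' comparison of crowded vs non-crowded replicate MFIs.
#'
#' @param mfi_table Data frame with the four columns above.
#' @return List with `protection` (data frame: antigen, condition,
#'   mfi_control, mfi_modified, relative_protection), `fold` (data frame:
#'   antigen, fold_enhancement), and `tests` (named list of
#'   [welch_compare()] results per antigen).
#' @export
analyze_protection <- function(mfi_table) {
  req <- c("antigen", "condition", "replicate", "mfi")
  if (!is.data.frame(mfi_table) || !all(req %in% names(mfi_table)))
    stop_glyx("mfi_table must have columns antigen, condition, replicate, mfi",
              "glyx_invalid_parameter")
  bad <- setdiff(unique(mfi_table$condition),
                 c("control", "noncrowded", "crowded"))
  if (length(bad))
    stop_glyx(paste("unknown condition(s):", paste(bad, collapse = ", ")),
              "glyx_invalid_parameter")
  prot <- NULL; fold <- NULL; tests <- list()
  for (ag in unique(mfi_table$antigen)) {
    sub <- mfi_table[mfi_table$antigen == ag, ]
    ctrl <- sub$mfi[sub$condition == "control"]
    if (!length(ctrl))
      stop_glyx(paste("no control replicates for antigen", ag),
                "glyx_invalid_parameter")
    m_ctrl <- mean(ctrl)
    p <- list()
    for (cond in c("noncrowded", "crowded")) {
      mm <- sub$mfi[sub$condition == cond]
      if (!length(mm)) next
      p[[cond]] <- relative_protection(mean(mm), m_ctrl)
      prot <- rbind(prot, data.frame(
        antigen = ag, condition = cond,
        mfi_control = m_ctrl, mfi_modified = mean(mm),
        relative_protection = as.numeric(p[[cond]])))
    }
    if (!is.null(p$crowded) && !is.null(p$noncrowded)) {
      fold <- rbind(fold, data.frame(
        antigen = ag,
        fold_enhancement = fold_enhancement(as.numeric(p$crowded),
                                            as.numeric(p$noncrowded))))
      a <- sub$mfi[sub$condition == "crowded"]
      b <- sub$mfi[sub$condition == "noncrowded"]
      if (length(a) >= 2 && length(b) >= 2)
        tests[[ag]] <- welch_compare(a, b)
    }
  }
  list(protection = prot, fold = fold, tests = tests)
}
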