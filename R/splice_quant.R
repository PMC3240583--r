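# Splice-isoform quantification: PSI from two-isoform intensities,
# between-condition t-tests, qRT-PCR standard-curve quantification, and
# read-mapping report summaries.

#' Percent spliced in (PSI) from isoform intensities
#'
#' With molar correction (the default) intensities are divided by the
#' RT-PCR product lengths before forming the ratio, since longer products
#' incorporate proportionally more dye:
#' `PSI = 100 (I_inc/L_inc) / (I_inc/L_inc + I_skip/L_skip)`.
#' Without it the raw intensity ratio is used. All arguments are
#' vectorized.
#'
#' @param inclusion_intensity,skip_intensity Nonnegative intensities
#'   (arbitrary units); both zero is an error.
#' @param inclusion_length,skip_length Product lengths in bp (defaults are
#'   the 714 nt inclusion and 438 nt skip products of the Sfrs10
#'   poison-exon assay).
#' @param molar_correction Divide intensities by product length first
#'   (default `TRUE`).
#' @return PSI in `[0, 100]`.
#' @export
compute_psi <- function(inclusion_intensity, skip_intensity,
                        inclusion_length = 714, skip_length = 438,
                        molar_correction = TRUE) {
  if (any(inclusion_intensity < 0) || any(skip_intensity < 0)) {
    stop("intensities must be nonnegative")
  }
  if (any(inclusion_intensity == 0 & skip_intensity == 0)) {
    stop("PSI undefined when both isoform intensities are zero")
  }
  if (any(inclusion_length <= 0) || any(skip_length <= 0)) {
    stop("product lengths must be positive")
  }
  inc <- if (molar_correction) inclusion_intensity / inclusion_length else
    inclusion_intensity
  skp <- if (molar_correction) skip_intensity / skip_length else
    skip_intensity
  100 * inc / (inc + skp)
}

#' PSI of a readout table
#'
#' Convenience wrapper applying [compute_psi()] to the output of
#' [generate_quant_readouts()] or an equivalently shaped intensity table.
#'
#' @param readouts Data frame with `inclusion_intensity`, `skip_intensity`,
#'   `inclusion_length`, `skip_length`.
#' @param molar_correction See [compute_psi()].
#' @return Numeric vector of PSI values, one per row.
#' @export
psi_from_readouts <- function(readouts, molar_correction = TRUE) {
  compute_psi(readouts$inclusion_intensity, readouts$skip_intensity,
              readouts$inclusion_length, readouts$skip_length,
              molar_correction = molar_correction)
}

#' Two-sample t-test between PSI groups
#'
#' Independent two-sample t-test of PSI levels between two conditions;
#' Welch's unequal-variance variant by default. Each group should contain
#' at least 3 biological replicates; fewer than 2 is an error.
#'
#' @param group_a,group_b Numeric vectors of PSI values.
#' @param var_equal Use the pooled-variance Student form (default `FALSE`,
#'   i.e. Welch).
#' @return List: `t`, `p`, `df`, `mean_a`, `mean_b`.
#' @export
compare_psi <- function(group_a, group_b, var_equal = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 replicates (3 or more recommended)")
  }
  tt <- stats::t.test(group_a, group_b, var.equal = var_equal)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter),
       mean_a = mean(group_a), mean_b = mean(group_b))
}

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of cycle threshold on log10 concentration over a
#' dilution series. The amplification efficiency is derived as
#' `10^(-1/slope)` (2 for perfect doubling, giving slope
#' `-1/log10(2) ~ -3.3219`).
#'
#' @param dilution_concentrations Positive concentrations (at least 3
#'   distinct values).
#' @param ct_values Observed cycle thresholds, same length.
#' @return A list with class `standard_curve`: `slope`, `intercept`,
#'   `r_squared`, `efficiency`.
#' @export
fit_standard_curve <- function(dilution_concentrations, ct_values) {
  if (length(dilution_concentrations) != length(ct_values)) {
    stop("concentrations and Ct values must have equal length")
  }
  if (length(dilution_concentrations) < 3) {
    stop("a standard curve needs at least 3 dilution points")
  }
  if (any(dilution_concentrations <= 0)) stop("concentrations must be positive")
  if (length(unique(dilution_concentrations)) < 2) {
    stop("degenerate regression: all concentrations identical")
  }
  fit <- stats::lm(ct_values ~ log10(dilution_concentrations))
  slope <- unname(stats::coef(fit)[2])
  # noiseless dilution series are legitimate input; silence the
  # "essentially perfect fit" note summary.lm emits for them
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 efficiency = 10^(-1 / slope)),
            class = "standard_curve")
}

#' Quantify an unknown sample from a standard curve
#'
#' Inverts the fitted line: `concentration = 10^((ct - intercept)/slope)`.
#'
#' @param curve A [fit_standard_curve()] result.
#' @param ct Cycle threshold(s) of the unknown.
#' @return Estimated concentration(s) on the standard's scale.
#' @export
quantify_unknown <- function(curve, ct) {
  stopifnot(inherits(curve, "standard_curve"))
  10^((ct - curve$intercept) / curve$slope)
}

#' Normalize a target quantity to a reference gene
#'
#' Technical duplicates are averaged by the arithmetic mean before the
#' ratio is formed, matching the duplicate-measurement design of the qPCR
#' protocol (normalization against Gapdh).
#'
#' @param target_quantity Numeric vector of target measurements.
#' @param reference_quantity Numeric vector of reference measurements
#'   (mean must be positive).
#' @return Ratio of means, target over reference.
#' @export
normalize_to_reference <- function(target_quantity, reference_quantity) {
  ref <- mean(reference_quantity)
  if (!(ref > 0)) stop("reference quantity must be positive")
  mean(target_quantity) / ref
}

#' Read-mapping report
#'
#' Summarizes the outcome of aligning CLIP reads: counts of processed,
#' aligned, failed-to-align and suppressed (multi-hit) reads must be
#' consistent, and percentages are rendered to two decimals.
#'
#' @param processed,aligned,failed,suppressed Nonnegative integers with
#'   `aligned + failed + suppressed == processed`.
#' @return A list with class `mapping_report`: the counts plus
#'   `pct_aligned`, `pct_failed`, `pct_suppressed`.
#' @export
mapping_report <- function(processed, aligned, failed, suppressed) {
  counts <- c(processed, aligned, failed, suppressed)
  if (any(counts < 0)) stop("read counts must be nonnegative")
  if (aligned + failed + suppressed != processed) {
    stop("aligned + failed + suppressed must equal processed")
  }
  if (processed == 0) stop("no reads processed")
  structure(list(
    processed = processed, aligned = aligned, failed = failed,
    suppressed = suppressed,
    pct_aligned = round(100 * aligned / processed, 2),
    pct_failed = round(100 * failed / processed, 2),
    pct_suppressed = round(100 * suppressed / processed, 2)
  ), class = "mapping_report")
}

#' @export
print.mapping_report <- function(x, ...) {
  cat(sprintf("%d reads processed: %d (%.2f%%) aligned, %d (%.2f%%) failed, %d (%.2f%%) suppressed\n",
              x$processed, x$aligned, x$pct_aligned, x$failed, x$pct_failed,
              x$suppressed, x$pct_suppressed))
  invisible(x)
}
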