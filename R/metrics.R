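#' Per-tissue descriptive statistics of a field amplitude
#'
#' Order statistics (median, 25th and 75th percentiles, minimum, maximum)
#' of the field amplitude over a tissue mask; percentiles use linear
#' interpolation between order statistics. The `peak` equals the literal
#' maximum by default; setting `robust_peak = TRUE` uses the 99.9th
#' percentile instead, which is less sensitive to isolated numerical
#' artifacts at tissue interfaces.
#'
#' @param amp numeric array of non-negative amplitudes.
#' @param mask logical array of the same shape, non-empty.
#' @param tissue tissue name recorded in the result.
#' @param robust_peak use the 99.9th percentile as the peak.
#' @return A one-row data frame: `tissue`, `median`, `q25`, `q75`, `min`,
#'   `max`, `peak`, `voxel_count`.
#' @export
tissue_descriptive_stats <- function(amp, mask, tissue = NA_character_,
                                     robust_peak = FALSE) {
  v <- amp[mask]
  if (length(v) == 0) stop("empty tissue mask")
  q <- unname(quantile(v, c(0.25, 0.5, 0.75), type = 7))
  peak <- if (robust_peak) unname(quantile(v, 0.999, type = 7)) else max(v)
  data.frame(tissue = tissue, median = q[2], q25 = q[1], q75 = q[3],
             min = min(v), max = max(v), peak = peak,
             voxel_count = length(v), stringsAsFactors = FALSE)
}

#' Focality volume fraction (V70 / V50)
#'
#' Percentage of a tissue's volume where the field amplitude is strictly
#' greater than `threshold_fraction` times its within-tissue peak. The
#' conventional thresholds 0.7 and 0.5 correspond to amplitude reductions
#' of about 3 dB and 6 dB from the peak.
#'
#' @inheritParams tissue_descriptive_stats
#' @param threshold_fraction fraction of the peak in (0, 1); 0.7 for V70,
#'   0.5 for V50.
#' @return Percentage in (0, 100].
#' @export
focality_volume_fraction <- function(amp, mask, threshold_fraction,
                                     robust_peak = FALSE) {
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("threshold_fraction must be in (0, 1)")
  v <- amp[mask]
  if (length(v) == 0) stop("empty tissue mask")
  peak <- if (robust_peak) unname(quantile(v, 0.999, type = 7)) else max(v)
  100 * sum(v > threshold_fraction * peak) / length(v)
}

#' Coefficient of variability across models, in dB
#'
#' CV is the sample standard deviation divided by the mean of the values
#' observed across the phantom family. The decibel mapping is
#' `20 * log10(1 + CV)` by default, so identical values give 0 dB and
#' CV = 1 maps to about 6 dB, consistent with the amplitude-dB convention
#' in which the 70% and 50% thresholds are about 3 dB and 6 dB below the
#' peak. The alternative raw mapping `20 * log10(CV)` is selectable.
#'
#' @param values positive values of one statistic across models (>= 2).
#' @param convention `"one_plus_cv"` (default) or `"raw"`.
#' @param sd_denominator `"n-1"` (sample, default) or `"n"`.
#' @return CV in dB (non-negative under the default convention; 0 iff all
#'   values are identical).
#' @export
cv_db <- function(values, convention = c("one_plus_cv", "raw"),
                  sd_denominator = c("n-1", "n")) {
  convention <- match.arg(convention)
  sd_denominator <- match.arg(sd_denominator)
  if (length(values) < 2) stop("need at least 2 values for a CV")
  mu <- mean(values)
  if (!(mu > 0)) stop("mean must be positive for a CV")
  s <- sd(values)
  if (sd_denominator == "n")
    s <- s * sqrt((length(values) - 1) / length(values))
  cv <- s / mu
  if (convention == "one_plus_cv") 20 * log10(1 + cv) else 20 * log10(cv)
}

#' Decibel reduction for an amplitude fraction
#'
#' `20 * log10(1 / fraction)`: 0.7 gives about 3 dB, 0.5 about 6 dB.
#'
#' @param fraction amplitude fraction in (0, 1].
#' @return Reduction in dB.
#' @export
db_reduction <- function(fraction) {
  if (any(fraction <= 0)) stop("fraction must be positive")
  if (any(fraction > 1)) stop("fraction must be <= 1")
  20 * log10(1 / fraction)
}
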