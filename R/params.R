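#' Tunable constants for metric calculations
#'
#' Collects every threshold, exponent, scaling constant and window length used
#' by the metric and visualisation layers into one validated list, so that a
#' single object can be passed through an analysis and overridden field by
#' field.
#'
#' @param targets_above mg/dL thresholds for [percent_above()].
#' @param targets_below mg/dL thresholds for [percent_below()].
#' @param ranges_in list of `c(lo, hi)` mg/dL pairs for [percent_in_range()].
#' @param ULTR upper limit of the target range (mg/dL) for [hyper_index()].
#' @param LLTR lower limit of the target range (mg/dL) for [hypo_index()].
#'   The source literature's scheme uses 80 mg/dL; exposed here because
#'   conventions differ across software.
#' @param hyper_exponent,hyper_scale exponent `a` and divisor `c` of the
#'   hyperglycemia index.
#' @param hypo_exponent,hypo_scale exponent `b` and divisor `d` of the
#'   hypoglycemia index.
#' @param mvalue_ref reference glucose `r` (mg/dL) for [m_value()].
#' @param conga_n lag in hours for [conga()].
#' @param mag_n sampling interval in minutes for [mag()].
#' @param roc_timelag lag in minutes for [roc()] and [sd_roc()].
#' @param inter_gap largest gap (minutes) across which linear interpolation is
#'   allowed when gridding; larger gaps become missing cells. A gap of exactly
#'   `inter_gap` minutes is interpolated.
#' @param dt0 grid period in minutes, or `NULL` to infer it from the data as
#'   the rounded median of successive time differences.
#' @param quantile_probs percent scale probabilities for [summary_glu()]
#'   quantiles.
#' @param agp_cutoffs the four standardized AGP band cutoffs (mg/dL).
#' @param lasagna_midpoint glucose value at the centre of the lasagna colour
#'   gradient (mg/dL).
#' @param lasagna_limits `c(lo, hi)` colour range limits (mg/dL).
#' @param grade_eugly_range euglycemic range for the GRADE attribution
#'   percentages.
#' @param mad_constant scale factor for the median absolute deviation
#'   (1.4826 gives normal consistency, matching [stats::mad()]).
#'
#' @return A list of class `"metric_params"`.
#' @examples
#' p <- metric_params(targets_above = c(160, 200))
#' p$targets_above
#' @export
metric_params <- function(targets_above = c(140, 180, 250),
                          targets_below = c(54, 70),
                          ranges_in = list(c(70, 180), c(63, 140)),
                          ULTR = 140,
                          LLTR = 80,
                          hyper_exponent = 1.1,
                          hyper_scale = 30,
                          hypo_exponent = 2,
                          hypo_scale = 30,
                          mvalue_ref = 90,
                          conga_n = 1,
                          mag_n = 60,
                          roc_timelag = 15,
                          inter_gap = 45,
                          dt0 = NULL,
                          quantile_probs = c(0, 25, 50, 75, 100),
                          agp_cutoffs = c(54, 70, 180, 250),
                          lasagna_midpoint = 105,
                          lasagna_limits = c(50, 500),
                          grade_eugly_range = c(70, 140),
                          mad_constant = 1.4826) {
  stopifnot(
    all(targets_above > 0), all(targets_below > 0),
    ULTR > 0, LLTR > 0, hyper_exponent > 0, hypo_exponent > 0,
    hyper_scale > 0, hypo_scale > 0, mvalue_ref > 0,
    conga_n > 0, mag_n > 0, roc_timelag > 0, inter_gap > 0,
    is.null(dt0) || (length(dt0) == 1 && dt0 > 0),
    all(quantile_probs >= 0 & quantile_probs <= 100),
    length(agp_cutoffs) == 4, !is.unsorted(agp_cutoffs),
    length(lasagna_limits) == 2,
    lasagna_limits[1] < lasagna_midpoint, lasagna_midpoint < lasagna_limits[2],
    length(grade_eugly_range) == 2, grade_eugly_range[1] < grade_eugly_range[2],
    mad_constant > 0
  )
  for (r in ranges_in) {
    if (length(r) != 2 || r[1] >= r[2]) {
      stop("each element of `ranges_in` must be an ordered pair c(lo, hi) with lo < hi",
           call. = FALSE)
    }
  }
  structure(
    list(
      targets_above = targets_above, targets_below = targets_below,
      ranges_in = ranges_in, ULTR = ULTR, LLTR = LLTR,
      hyper_exponent = hyper_exponent, hyper_scale = hyper_scale,
      hypo_exponent = hypo_exponent, hypo_scale = hypo_scale,
      mvalue_ref = mvalue_ref, conga_n = conga_n, mag_n = mag_n,
      roc_timelag = roc_timelag, inter_gap = inter_gap, dt0 = dt0,
      quantile_probs = quantile_probs, agp_cutoffs = agp_cutoffs,
      lasagna_midpoint = lasagna_midpoint, lasagna_limits = lasagna_limits,
      grade_eugly_range = grade_eugly_range, mad_constant = mad_constant
    ),
    class = "metric_params"
  )
}
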