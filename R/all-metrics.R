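#' Compute the full metric panel for every subject
#'
#' Runs every distribution and temporal metric in the package on each subject
#' and assembles one wide tibble: one row per subject, one column per metric.
#' A metric that cannot be computed for a subject (too little data, no
#' qualifying observations) yields `NA` in that cell, with a warning naming
#' the subject; it is never silently reported as 0.
#'
#' Column order is fixed: data sufficiency (`active_percent`, `ndays`),
#' distribution summary (`mean` ... quantiles), time-in-range percentages,
#' mean-based indices (`ea1c`, `gmi`), composite indices (`j_index`,
#' `m_value`, GRADE family, `lbgi`/`hbgi`, hyper/hypo/igc, `cogi`, `mage`),
#' then the temporal metrics (`conga`, `modd`, SD subtypes, CV subtypes,
#' `adrr`, `gvp`, `mag`, `auc`, `sd_roc`).
#'
#' @param data a CGM data frame (`id`, `time`, `gl`).
#' @param params a [metric_params()] object.
#' @param tz timezone for timestamp interpretation.
#' @return A tibble, subjects x metrics.
#' @examples
#' x <- make_phenotype_panel(seed = 1)
#' m <- all_metrics(x)
#' dim(m)
#' @export
all_metrics <- function(data, params = metric_params(), tz = "UTC") {
  data <- ensure_cgm(data, tz = tz)
  ap <- active_percent(data, params = params, tz = tz)
  pieces <- list(
    ap[c("id", "active_percent", "ndays")],
    summary_glu(data, params = params),
    percent_above(data, targets = params$targets_above),
    percent_below(data, targets = params$targets_below),
    percent_in_range(data, ranges = params$ranges_in),
    ea1c(data),
    gmi(data),
    j_index(data),
    m_value(data, r = params$mvalue_ref),
    grade_family(data, eugly_range = params$grade_eugly_range),
    bgi(data),
    hyper_index(data, ULTR = params$ULTR, a = params$hyper_exponent,
                c_scale = params$hyper_scale),
    hypo_index(data, LLTR = params$LLTR, b = params$hypo_exponent,
               d_scale = params$hypo_scale),
    igc(data, params = params),
    cogi(data),
    mage(data),
    conga(data, n = params$conga_n, params = params),
    modd(data, params = params),
    sd_measures(data, params = params),
    cv_measures(data, params = params),
    adrr(data, tz = tz),
    gvp(data, params = params),
    mag(data, n = params$mag_n, params = params),
    auc(data, params = params),
    sd_roc(data, timelag = params$roc_timelag, params = params)
  )
  purrr::reduce(pieces, dplyr::left_join, by = "id")
}
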