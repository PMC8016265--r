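#' Cross-validate against the published five-subject example dataset
#'
#' The five-subject Dexcom G4 example dataset that circulates with other CGM
#' software has published console outputs for several metrics. This helper
#' recomputes those quantities from a local copy of that dataset (a CSV with
#' columns `id`, `time`, `gl`), so users who have it can check agreement to
#' the printed precision. The dataset is not bundled with gluvar; CONGA is
#' deliberately not included because published CONGA values disagree across
#' software packages (interpolation and missing-data conventions differ).
#'
#' @param path path to the example dataset CSV.
#' @return A list with `hyper_index_subject1`, `above_percent_subject2`
#'   (vector at 140/180/250), `active_percent_subject4`, `ndays_subject4`,
#'   `sdw_subject5`, `mean_subject1`, `sd_subject1`.
#' @export
crosscheck_published_example <- function(path) {
  data <- read_cgm_csv(path)
  ids <- levels(data$id)
  stopifnot(length(ids) == 5)
  hi <- hyper_index(data)
  ab <- percent_above(data)
  ap <- active_percent(data)
  sdm <- sd_measures(data)
  sg <- summary_glu(data)
  list(
    hyper_index_subject1 = hi$hyper_index[1],
    above_percent_subject2 = unlist(ab[2, -1]),
    active_percent_subject4 = ap$active_percent[4],
    ndays_subject4 = ap$ndays[4],
    sdw_subject5 = sdm$SdW[5],
    mean_subject1 = sg$mean[1],
    sd_subject1 = sg$sd[1]
  )
}
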