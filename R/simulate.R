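#' Configuration of the synthetic CGM generator
#'
#' Describes a panel of simulated subjects: each subject's glucose is a
#' baseline level plus a diurnal sinusoid, meal pulses with exponential
#' decay, and AR(1) sensor noise, floored at 40 mg/dL. Timestamps sit on a
#' regular `dt0`-minute grid with optional per-reading jitter (emulating the
#' clock misalignment of real sensors), and missingness is injected both as
#' independent per-reading dropout and as contiguous gap blocks (emulating
#' sensor warm-ups and detachments).
#'
#' Per-subject parameters (`baseline`, `diurnal_amplitude`, `ar_sd`,
#' `meal_amplitude`) may be scalars (recycled) or vectors of length
#' `n_subjects`.
#'
#' @param n_subjects number of subjects.
#' @param days days of wear per subject.
#' @param dt0 nominal sensor period in minutes (must divide 1440).
#' @param baseline mean glucose level(s), mg/dL.
#' @param diurnal_amplitude amplitude of the 24-h sinusoid, mg/dL.
#' @param diurnal_peak hour of day of the sinusoid peak.
#' @param ar_sd stationary SD of the AR(1) noise, mg/dL.
#' @param ar_coef AR(1) coefficient per step, in `[0, 1)`.
#' @param meals_per_day expected number of meal pulses per day (Poisson).
#' @param meal_amplitude peak meal excursion, mg/dL.
#' @param meal_decay exponential decay time of a meal pulse, minutes.
#' @param dropout_prob independent per-reading dropout probability.
#' @param gap_rate expected number of long gap blocks per day (Poisson).
#' @param gap_length length of each gap block, minutes.
#' @param jitter_sd SD of timestamp jitter, seconds.
#' @param start first day of wear (date or string).
#' @param seed integer seed fixing the whole stream.
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_subjects = 2, days = 3, seed = 7)
#' simulate_cgm(cfg)
#' @export
sim_config <- function(n_subjects = 5, days = 14, dt0 = 5,
                       baseline = 140, diurnal_amplitude = 25,
                       diurnal_peak = 17, ar_sd = 20, ar_coef = 0.7,
                       meals_per_day = 3, meal_amplitude = 60,
                       meal_decay = 90, dropout_prob = 0.02,
                       gap_rate = 0.3, gap_length = 120,
                       jitter_sd = 5, start = "2020-03-01", seed = 1) {
  stopifnot(
    n_subjects >= 1, days >= 1, dt0 > 0, 1440 %% dt0 == 0,
    all(baseline > 0), all(diurnal_amplitude >= 0),
    diurnal_peak >= 0, diurnal_peak < 24,
    all(ar_sd >= 0), ar_coef >= 0, ar_coef < 1,
    meals_per_day >= 0, all(meal_amplitude >= 0), meal_decay > 0,
    dropout_prob >= 0, dropout_prob <= 1,
    gap_rate >= 0, gap_length > 0, jitter_sd >= 0
  )
  structure(list(
    n_subjects = n_subjects, days = days, dt0 = dt0,
    baseline = rep_len(baseline, n_subjects),
    diurnal_amplitude = rep_len(diurnal_amplitude, n_subjects),
    diurnal_peak = diurnal_peak,
    ar_sd = rep_len(ar_sd, n_subjects), ar_coef = ar_coef,
    meals_per_day = meals_per_day,
    meal_amplitude = rep_len(meal_amplitude, n_subjects),
    meal_decay = meal_decay,
    dropout_prob = dropout_prob, gap_rate = gap_rate,
    gap_length = gap_length, jitter_sd = jitter_sd,
    start = as.Date(start), seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a CGM panel
#'
#' Generates multi-day CGM traces according to a [sim_config()]: for each
#' subject, glucose at minute `t` of day is
#' `baseline + A * cos(2 * pi * (t / 60 - peak) / 24) + meal pulses + AR(1)
#' noise`, floored at 40 mg/dL. The stream is fully determined by the
#' config seed.
#'
#' @param config a [sim_config()].
#' @return A `cgm_tbl` with subjects `"Subject 1"`, `"Subject 2"`, ...
#' @export
simulate_cgm <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  dt0 <- config$dt0
  n_per_day <- 1440 / dt0
  n <- config$days * n_per_day
  t_min <- (seq_len(n) - 1) * dt0           # minutes since start midnight
  start_time <- as.POSIXct(paste(config$start, "00:00:00"), tz = "UTC")

  rows <- lapply(seq_len(config$n_subjects), function(s) {
    diurnal <- config$diurnal_amplitude[s] *
      cos(2 * pi * ((t_min / 60) %% 24 - config$diurnal_peak) / 24)

    # meal pulses: instant rise, exponential decay
    meal <- numeric(n)
    n_meals <- stats::rpois(1, config$meals_per_day * config$days)
    if (n_meals > 0) {
      onset <- sort(stats::runif(n_meals, 0, config$days * 1440))
      amp <- config$meal_amplitude[s] * stats::runif(n_meals, 0.5, 1.2)
      for (k in seq_len(n_meals)) {
        after <- t_min >= onset[k]
        meal[after] <- meal[after] +
          amp[k] * exp(-(t_min[after] - onset[k]) / config$meal_decay)
      }
    }

    # AR(1) noise with stationary sd ar_sd
    noise <- if (config$ar_sd[s] > 0) {
      innov_sd <- config$ar_sd[s] * sqrt(1 - config$ar_coef^2)
      as.numeric(stats::arima.sim(list(ar = config$ar_coef), n = n, sd = innov_sd))
    } else {
      numeric(n)
    }

    gl <- pmax(config$baseline[s] + diurnal + meal + noise, 40)

    jitter <- if (config$jitter_sd > 0) stats::rnorm(n, 0, config$jitter_sd) else 0
    time <- start_time + round(t_min * 60 + jitter)

    keep <- rep(TRUE, n)
    if (config$dropout_prob > 0) {
      keep <- stats::runif(n) >= config$dropout_prob
    }
    n_gaps <- stats::rpois(1, config$gap_rate * config$days)
    if (n_gaps > 0) {
      gstart <- stats::runif(n_gaps, 0, config$days * 1440 - config$gap_length)
      for (g in gstart) {
        keep[t_min >= g & t_min < g + config$gap_length] <- FALSE
      }
    }
    tibble::tibble(id = paste("Subject", s), time = time[keep], gl = gl[keep])
  })
  as_cgm_table(dplyr::bind_rows(rows))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' A five-subject panel with engineered phenotypes
#'
#' Builds a fixed 14-day, 5-minute panel contrasting glucose phenotypes, for
#' tests and examples:
#' \describe{
#'   \item{Subject 1, 3, 4}{intermediate mean (115-150 mg/dL) and moderate
#'     variability.}
#'   \item{Subject 2}{sustained hyperglycemia: high baseline (220 mg/dL),
#'     low variability.}
#'   \item{Subject 5}{highest variability: large AR noise, large diurnal
#'     swing and large meal excursions around a mid baseline.}
#' }
#'
#' @param seed integer seed.
#' @return A `cgm_tbl` of 5 subjects.
#' @examples
#' panel <- make_phenotype_panel(seed = 1)
#' hyper_index(panel)
#' @export
make_phenotype_panel <- function(seed = 42) {
  simulate_cgm(sim_config(
    n_subjects = 5, days = 14, dt0 = 5,
    baseline = c(115, 220, 150, 125, 150),
    diurnal_amplitude = c(15, 8, 20, 15, 40),
    ar_sd = c(12, 10, 18, 12, 45),
    ar_coef = 0.7,
    meals_per_day = 3,
    meal_amplitude = c(40, 25, 50, 40, 80),
    dropout_prob = 0.02, gap_rate = 0.3, gap_length = 120,
    jitter_sd = 5, seed = seed
  ))
}

#' Write a simulation config as JSON
#'
#' @param config a [sim_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  x$start <- as.character(x$start)
  jsonlite::write_json(x, path, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a simulation config from JSON
#'
#' Missing mandatory fields raise an error naming the field; fields absent
#' from the file fall back to [sim_config()] defaults only if optional.
#'
#' @param path path to a JSON file as written by [write_sim_config()].
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  mandatory <- c("n_subjects", "days", "dt0", "seed")
  for (f in mandatory) {
    if (is.null(x[[f]])) stop("config is missing mandatory field: ", f, call. = FALSE)
  }
  allowed <- names(formals(sim_config))
  unknown <- setdiff(names(x), allowed)
  if (length(unknown) > 0) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(sim_config, x)
}
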