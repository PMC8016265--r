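#' Infer the sensor sampling period
#'
#' The grid period `dt0` is taken as the median of successive time
#' differences, rounded to the nearest whole minute, then snapped to the
#' nearest divisor of 1440 so that a whole number of grid slots fits in a day.
#' The median makes the estimate robust to occasional sensor gaps.
#'
#' @param timestamps ordered POSIXct times of one subject.
#' @return the grid period in minutes (integer-valued, >= 1).
#' @examples
#' t0 <- as.POSIXct("2020-01-01 00:00:00", tz = "UTC")
#' infer_dt0(t0 + 60 * seq(0, 100, by = 5)) # 5
#' @export
infer_dt0 <- function(timestamps) {
  if (length(timestamps) < 2) {
    stop("need at least 2 timestamps to infer the sampling period", call. = FALSE)
  }
  d <- as.numeric(diff(as.numeric(timestamps))) / 60
  dt0 <- max(1, round(stats::median(d)))
  divisors <- which(1440 %% seq_len(1440) == 0)
  divisors[which.min(abs(divisors - dt0))]
}

#' Project a subject's readings onto an equidistant day-by-day grid
#'
#' Builds the per-subject matrix of interpolated glucose values used by all
#' metrics that require evenly spaced measurements (CONGA, MODD, MAG, AUC,
#' rate of change, the SD and CV decompositions) and by the lasagna and AGP
#' plots. Rows are calendar days (first to last day of observation,
#' consecutive), columns are times of day on an equidistant grid: column `j`
#' represents `j * dt0` minutes after local midnight, giving `1440 / dt0`
#' columns.
#'
#' Each grid point is filled by linear interpolation between its two
#' bracketing observations, but only if those observations are at most
#' `inter_gap` minutes apart; wider gaps produce missing cells. No
#' extrapolation is performed before the first or after the last observation,
#' so the leading cells of the first day and trailing cells of the last day
#' are missing.
#'
#' @param data readings of a single subject (a `cgm_tbl` slice or a
#'   data frame with `time` and `gl`).
#' @param params a [metric_params()] object supplying `dt0` and `inter_gap`.
#' @param dt0,inter_gap optional overrides of the corresponding `params`
#'   fields; `dt0 = NULL` infers the period with [infer_dt0()].
#' @param tz timezone defining local midnight.
#' @return An object of class `day_grid`: a list with elements
#'   \describe{
#'     \item{gd2d}{numeric matrix, days x times-of-day, mg/dL, `NA` where
#'       interpolation was not permitted.}
#'     \item{actual_dates}{`Date` vector mapping rows to calendar days.}
#'     \item{dt0}{the grid period in minutes.}
#'   }
#' @examples
#' x <- simulate_cgm(sim_config(n_subjects = 1, days = 2, seed = 1))
#' g <- day_by_day(x)
#' dim(g$gd2d)
#' @export
day_by_day <- function(data, params = metric_params(), dt0 = params$dt0,
                       inter_gap = params$inter_gap, tz = "UTC") {
  data <- ensure_cgm(data, tz = tz)
  if (length(unique(data$id)) > 1) {
    stop("day_by_day() works on a single subject; got ",
         length(unique(data$id)), call. = FALSE)
  }
  if (nrow(data) < 2) stop("need at least 2 readings to build a grid", call. = FALSE)

  time <- data$time
  gl <- data$gl
  if (is.null(dt0)) dt0 <- infer_dt0(time)
  if (dt0 <= 0 || 1440 %% dt0 != 0) {
    stop("dt0 = ", dt0, " does not divide 1440 minutes; supply dt0 explicitly ",
         "(e.g. 5, 10, 15) via metric_params(dt0 = ...)", call. = FALSE)
  }

  day0 <- lubridate::floor_date(time[1], unit = "day")
  dates <- seq(as.Date(day0), as.Date(lubridate::floor_date(time[length(time)], "day")),
               by = "day")
  ndays <- length(dates)
  ncols <- 1440L / as.integer(dt0)

  obs_min <- as.numeric(difftime(time, day0, units = "mins"))
  grid_min <- seq(dt0, ndays * 1440, by = dt0)

  vals <- rep(NA_real_, length(grid_min))
  idx <- findInterval(grid_min, obs_min)
  n <- length(obs_min)

  inner <- which(idx >= 1 & idx < n)
  if (length(inner) > 0) {
    lo <- idx[inner]
    gap <- obs_min[lo + 1] - obs_min[lo]
    ok <- gap <= inter_gap + 1e-9
    w <- (grid_min[inner] - obs_min[lo]) / gap
    vals[inner][ok] <- ((1 - w) * gl[lo] + w * gl[lo + 1])[ok]
  }
  # grid points coinciding exactly with an observation take its value,
  # including the final observation which findInterval leaves unbracketed
  hit <- match(round(grid_min * 60), round(obs_min * 60))
  vals[!is.na(hit)] <- gl[hit[!is.na(hit)]]

  gd2d <- matrix(vals, nrow = ndays, ncol = ncols, byrow = TRUE,
                 dimnames = list(
                   as.character(dates),
                   sprintf("%02d:%02d", (seq_len(ncols) * dt0) %/% 60 %% 24,
                           (seq_len(ncols) * dt0) %% 60)
                 ))
  structure(list(gd2d = gd2d, actual_dates = dates, dt0 = dt0),
            class = "day_grid")
}

#' @export
print.day_grid <- function(x, ...) {
  cat("<day_grid> ", nrow(x$gd2d), " days x ", ncol(x$gd2d),
      " slots (dt0 = ", x$dt0, " min), ",
      sum(!is.na(x$gd2d)), " non-missing cells\n", sep = "")
  invisible(x)
}

#' Export a day grid as a CSV matrix
#'
#' Debug/export helper: ISO dates as row labels, HH:MM times as column labels.
#'
#' @param grid a [day_by_day()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_day_grid_csv <- function(grid, path) {
  stopifnot(inherits(grid, "day_grid"))
  df <- as.data.frame(grid$gd2d)
  df <- cbind(date = rownames(grid$gd2d), df)
  readr::write_csv(tibble::as_tibble(df), path, progress = FALSE)
  invisible(path)
}

#' Percentage of time the sensor was active
#'
#' Quantifies data sufficiency: the number of distinct grid slots with an
#' observed reading, as a percentage of the number of slots expected between
#' the first and last reading at the sensor period `dt0`
#' (`floor(span / dt0) + 1`), capped at 100.
#'
#' @param data a `cgm_tbl` or data frame with `id`, `time`, `gl`.
#' @param params a [metric_params()] object (`dt0` used if set, else
#'   inferred per subject).
#' @param tz timezone for timestamp parsing.
#' @return A tibble with one row per subject: `id`, `active_percent`,
#'   `ndays` (fractional days spanned), `start_date`, `end_date`.
#' @examples
#' x <- simulate_cgm(sim_config(n_subjects = 2, days = 3, seed = 1))
#' active_percent(x)
#' @export
active_percent <- function(data, params = metric_params(), tz = "UTC") {
  data <- ensure_cgm(data, tz = tz)
  out <- metric_by_subject(data, function(sub) {
    if (nrow(sub) < 2) stop("need at least 2 readings")
    dt0 <- if (is.null(params$dt0)) infer_dt0(sub$time) else params$dt0
    span_min <- as.numeric(difftime(sub$time[nrow(sub)], sub$time[1], units = "mins"))
    expected <- floor(span_min / dt0) + 1
    observed <- length(unique(round(
      as.numeric(difftime(sub$time, sub$time[1], units = "mins")) / dt0
    )))
    c(active_percent = min(100, 100 * observed / expected),
      ndays = span_min / 1440)
  }, na_names = c("active_percent", "ndays"))
  ends <- dplyr::summarise(dplyr::group_by(data, .data$id),
                           start_date = min(.data$time),
                           end_date = max(.data$time))
  dplyr::left_join(out, ends, by = "id")
}
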