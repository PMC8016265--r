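#' @title Time-dependent glucose metrics
#' @description
#' Metrics in this file depend on when readings were taken. CONGA, MODD,
#' MAG, AUC, rate of change and the SD/CV decompositions are computed on the
#' equidistant [day_by_day()] grid (they require evenly spaced measurements);
#' ADRR and GVP operate on the raw timed readings. Each function accepts
#' either a `day_grid` (where applicable), a single-subject data frame, or a
#' multi-subject CGM data frame, returning a per-subject tibble in the last
#' case.
#' @name metrics_temporal
NULL

# Dispatch helper for grid-based metrics: day_grid -> fn(grid);
# data frame -> per-subject grid + fn.
grid_metric <- function(data, fn, params, na_names) {
  if (inherits(data, "day_grid")) return(fn(data))
  metric_by_subject(data, function(sub) fn(day_by_day(sub, params = params)),
                    na_names = na_names)
}

# Row-major flattening: day 1's slots, then day 2's, ... (one concatenated
# day-aligned series).
flatten_grid <- function(grid) as.vector(t(grid$gd2d))

sample_sd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) NA_real_ else stats::sd(x)
}

#' Continuous overall net glycemic action (CONGA)
#'
#' The sample SD of differences between grid values `n` hours apart, over all
#' pairs where both cells are non-missing. Days are concatenated in order, so
#' lagged pairs may span midnight.
#'
#' @param data a `day_grid`, or a CGM data frame (gridded per subject).
#' @param n lag in hours.
#' @param params a [metric_params()] object (gridding parameters).
#' @return CONGA in mg/dL (`NA` if no valid pair), or a per-subject tibble.
#' @export
conga <- function(data, n = metric_params()$conga_n, params = metric_params()) {
  grid_metric(data, function(grid) {
    lag <- round(n * 60 / grid$dt0)
    if (lag < 1) stop("conga lag shorter than the grid period")
    v <- flatten_grid(grid)
    if (length(v) <= lag) stop("grid shorter than the conga lag")
    d <- v[(lag + 1):length(v)] - v[1:(length(v) - lag)]
    c(conga = sample_sd(d))
  }, params, na_names = "conga")
}

#' Mean of daily differences (MODD)
#'
#' Mean absolute difference between grid values exactly 24 hours apart:
#' `mean |x[day + 1, slot] - x[day, slot]|` over all pairs with both cells
#' non-missing.
#'
#' @inheritParams conga
#' @return MODD in mg/dL, or a per-subject tibble.
#' @export
modd <- function(data, params = metric_params()) {
  grid_metric(data, function(grid) {
    m <- grid$gd2d
    if (nrow(m) < 2) stop("MODD needs at least 2 days of data")
    d <- abs(m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE])
    d <- d[!is.na(d)]
    c(modd = if (length(d) == 0) NA_real_ else mean(d))
  }, params, na_names = "modd")
}

#' Rodbard's SD decomposition
#'
#' Six standard-deviation subtypes separating within-day, between-day and
#' between-timepoint variability, all sample-based (n - 1) with pairwise
#' deletion of missing cells; rows/columns/blocks with fewer than two values
#' are skipped.
#' \describe{
#'   \item{SdW}{mean over days of the within-day SD.}
#'   \item{SdHHMM}{SD over times of day of the per-time means (the SD of the
#'     average day profile).}
#'   \item{SdWSH}{mean of the SDs within consecutive non-overlapping 1-hour
#'     blocks of the concatenated series.}
#'   \item{SdDM}{SD of the daily means.}
#'   \item{SdB}{mean over times of day of the across-day SD.}
#'   \item{SdBDM}{SdB after centring each day at its own mean.}
#' }
#'
#' @inheritParams conga
#' @return Named vector / per-subject tibble with the six subtypes (mg/dL).
#' @export
sd_measures <- function(data, params = metric_params()) {
  nm <- c("SdW", "SdHHMM", "SdWSH", "SdDM", "SdB", "SdBDM")
  grid_metric(data, function(grid) {
    m <- grid$gd2d
    if (nrow(m) < 2 || ncol(m) < 2) stop("SD decomposition needs >= 2 days and >= 2 slots")

    row_sds <- apply(m, 1, sample_sd)
    SdW <- mean(row_sds, na.rm = TRUE)

    col_means <- colMeans(m, na.rm = TRUE)
    col_means[is.nan(col_means)] <- NA
    SdHHMM <- sample_sd(col_means)

    block <- max(1, round(60 / grid$dt0))
    v <- flatten_grid(grid)
    nblocks <- floor(length(v) / block)
    block_sds <- vapply(seq_len(nblocks), function(b) {
      sample_sd(v[((b - 1) * block + 1):(b * block)])
    }, 0)
    SdWSH <- mean(block_sds, na.rm = TRUE)

    day_means <- rowMeans(m, na.rm = TRUE)
    day_means[is.nan(day_means)] <- NA
    SdDM <- sample_sd(day_means)

    col_sds <- apply(m, 2, sample_sd)
    SdB <- mean(col_sds, na.rm = TRUE)

    centred <- m - day_means
    SdBDM <- mean(apply(centred, 2, sample_sd), na.rm = TRUE)

    out <- c(SdW = SdW, SdHHMM = SdHHMM, SdWSH = SdWSH,
             SdDM = SdDM, SdB = SdB, SdBDM = SdBDM)
    out[is.nan(out)] <- NA
    out
  }, params, na_names = nm)
}

#' Within-day coefficient of variation: mean and SD across days
#'
#' Per day `i` with at least two non-missing grid cells,
#' `CV_i = 100 * sd_i / mean_i`; `CVmean` is the mean and `CVsd` the sample
#' SD of the daily CVs (`CVsd` is `NA` with fewer than two usable days).
#'
#' @inheritParams conga
#' @return Named vector / per-subject tibble with `CVmean` and `CVsd` (%).
#' @export
cv_measures <- function(data, params = metric_params()) {
  grid_metric(data, function(grid) {
    m <- grid$gd2d
    cvs <- apply(m, 1, function(row) {
      row <- row[!is.na(row)]
      if (length(row) < 2) NA_real_ else 100 * stats::sd(row) / mean(row)
    })
    cvs <- cvs[!is.na(cvs)]
    if (length(cvs) == 0) stop("no day with >= 2 non-missing cells")
    c(CVmean = mean(cvs), CVsd = if (length(cvs) >= 2) stats::sd(cvs) else NA_real_)
  }, params, na_names = c("CVmean", "CVsd"))
}

#' Average daily risk range (ADRR)
#'
#' Readings are grouped by local calendar day; within each day the Kovatchev
#' low/high risks `rl`, `rh` (see [bgi()]) are computed per reading and the
#' daily risk range is `max(rl) + max(rh)` (a side with no readings of that
#' sign contributes 0). ADRR is the mean daily risk range over days with any
#' readings.
#'
#' @param data a CGM data frame (single- or multi-subject).
#' @param tz timezone defining calendar days.
#' @return ADRR (unitless), or a per-subject tibble.
#' @export
adrr <- function(data, tz = "UTC") {
  data <- ensure_cgm(data, tz = tz)
  metric_by_subject(data, function(sub) {
    day <- as.Date(lubridate::floor_date(sub$time, "day"))
    risks <- bgi_risks(sub$gl)
    daily <- vapply(split(seq_along(day), day), function(i) {
      max(risks$rl[i]) + max(risks$rh[i])
    }, 0)
    c(adrr = mean(daily))
  }, na_names = "adrr")
}

#' Glucose variability percentage (GVP)
#'
#' The excess arc length of the glucose trace relative to a flat line: over
#' consecutive reading pairs at most `inter_gap` minutes apart,
#' `L = sum(sqrt(dt^2 + dgl^2))` (dt in minutes, dgl in mg/dL) and
#' `L0 = sum(dt)`; `GVP = 100 * (L / L0 - 1)`. Segments spanning wider gaps
#' are excluded.
#'
#' @param data a CGM data frame.
#' @param params a [metric_params()] object (`inter_gap`).
#' @return GVP in %, or a per-subject tibble.
#' @export
gvp <- function(data, params = metric_params()) {
  data <- ensure_cgm(data)
  metric_by_subject(data, function(sub) {
    dt <- diff(as.numeric(sub$time)) / 60
    dg <- diff(sub$gl)
    keep <- dt > 0 & dt <= params$inter_gap + 1e-9
    if (!any(keep)) stop("no segment within inter_gap")
    L <- sum(sqrt(dt[keep]^2 + dg[keep]^2))
    L0 <- sum(dt[keep])
    c(gvp = 100 * (L / L0 - 1))
  }, na_names = "gvp")
}

#' Mean absolute glucose change per hour (MAG)
#'
#' The concatenated grid is sampled every `n` minutes; MAG is the sum of
#' absolute changes between successive non-missing samples divided by the
#' hours elapsed between the first and last sample used.
#'
#' @inheritParams conga
#' @param n sampling interval in minutes.
#' @return MAG in mg/dL per hour, or a per-subject tibble.
#' @export
mag <- function(data, n = metric_params()$mag_n, params = metric_params()) {
  grid_metric(data, function(grid) {
    step <- max(1, round(n / grid$dt0))
    v <- flatten_grid(grid)
    idx <- seq(1, length(v), by = step)
    use <- idx[!is.na(v[idx])]
    if (length(use) < 2) stop("fewer than 2 usable samples for MAG")
    hours <- (use[length(use)] - use[1]) * grid$dt0 / 60
    c(mag = sum(abs(diff(v[use]))) / hours)
  }, params, na_names = "mag")
}

#' Hourly-average area under the glucose curve
#'
#' Per day, the trapezoidal area over adjacent non-missing cell pairs
#' (each of width `dt0 / 60` hours) divided by the total width covered,
#' giving an hourly average in mg/dL; the result is the mean over days with
#' at least one pair.
#'
#' @inheritParams conga
#' @return AUC (mg/dL, hourly average), or a per-subject tibble.
#' @export
auc <- function(data, params = metric_params()) {
  grid_metric(data, function(grid) {
    m <- grid$gd2d
    daily <- apply(m, 1, function(row) {
      a <- row[-length(row)]
      b <- row[-1]
      ok <- !is.na(a) & !is.na(b)
      if (!any(ok)) return(NA_real_)
      # trapezoid areas divided by summed width: hourly average level
      sum((a[ok] + b[ok]) / 2) / sum(ok)
    })
    daily <- daily[!is.na(daily)]
    if (length(daily) == 0) stop("no day with an adjacent non-missing pair")
    c(auc = mean(daily))
  }, params, na_names = "auc")
}

#' Rate of change of glucose
#'
#' `roc_t = (gl_t - gl_(t - timelag)) / timelag` in mg/dL per minute over the
#' concatenated grid, defined where both cells are non-missing.
#'
#' @inheritParams conga
#' @param timelag lag in minutes.
#' @return For a `day_grid`: the numeric vector of rates aligned with the
#'   flattened grid (leading `NA`s for the first `timelag` minutes). For a
#'   data frame: a tibble with `id`, `time`, `gl`, `roc` at grid times.
#' @export
roc <- function(data, timelag = metric_params()$roc_timelag,
                params = metric_params()) {
  roc_of_grid <- function(grid) {
    lag <- max(1, round(timelag / grid$dt0))
    v <- flatten_grid(grid)
    out <- rep(NA_real_, length(v))
    if (length(v) > lag) {
      out[(lag + 1):length(v)] <-
        (v[(lag + 1):length(v)] - v[1:(length(v) - lag)]) / (lag * grid$dt0)
    }
    out
  }
  if (inherits(data, "day_grid")) return(roc_of_grid(data))
  data <- ensure_cgm(data)
  ids <- as.character(unique(data$id))
  purrr::list_rbind(lapply(ids, function(s) {
    sub <- data[data$id == s, , drop = FALSE]
    grid <- day_by_day(sub, params = params)
    v <- flatten_grid(grid)
    day0 <- as.POSIXct(paste(grid$actual_dates[1], "00:00:00"),
                       tz = lubridate::tz(sub$time))
    times <- day0 + 60 * grid$dt0 * seq_along(v)
    tibble::tibble(id = factor(s, levels = ids), time = times,
                   gl = v, roc = roc_of_grid(grid))
  }))
}

#' Standard deviation of the rate of change
#'
#' Sample SD of the [roc()] values (mg/dL per minute), a measure of local
#' glucose variability.
#'
#' @inheritParams roc
#' @return sd_roc, or a per-subject tibble.
#' @export
sd_roc <- function(data, timelag = metric_params()$roc_timelag,
                   params = metric_params()) {
  grid_metric(data, function(grid) {
    c(sd_roc = sample_sd(roc(grid, timelag = timelag)))
  }, params, na_names = "sd_roc")
}
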