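#' The CGM data contract
#'
#' All analysis functions in gluvar operate on long-format CGM data: a data
#' frame with one row per sensor reading and three columns, `id` (subject
#' identifier), `time` (date-time of the reading) and `gl` (glucose in mg/dL).
#' `as_cgm_table()` coerces and validates such a data frame: timestamps are
#' parsed, rows with unparseable times or non-positive / missing glucose are
#' dropped (and counted), readings are sorted by time within subject, and
#' exact duplicate (id, time) pairs are collapsed to the first occurrence.
#'
#' Timestamps are treated as naive local clock times; they are parsed in the
#' timezone `tz` (default UTC) and day boundaries throughout the package are
#' local midnight in that zone.
#'
#' @param data a data frame with columns `id`, `time`, `gl` (or names mapped
#'   via `column_map`).
#' @param column_map optional named character vector mapping the canonical
#'   names to the names present in `data`, e.g.
#'   `c(id = "subject", time = "timestamp", gl = "glucose")`.
#' @param tz timezone used to interpret character timestamps.
#'
#' @return A tibble of class `cgm_tbl` with columns `id` (factor, levels in
#'   order of first appearance), `time` (POSIXct) and `gl` (double, mg/dL).
#'   A validation report is attached as attribute `"report"`; retrieve it
#'   with [validation_report()].
#' @seealso [read_cgm_csv()], [validation_report()]
#' @examples
#' tbl <- as_cgm_table(data.frame(
#'   id = "S1",
#'   time = c("2020-01-01 00:00:00", "2020-01-01 00:05:00"),
#'   gl = c(110, 118)
#' ))
#' validation_report(tbl)$n_retained
#' @export
as_cgm_table <- function(data, column_map = NULL, tz = "UTC") {
  stopifnot(is.data.frame(data))
  if (!is.null(column_map)) {
    missing_src <- setdiff(unname(column_map), names(data))
    if (length(missing_src) > 0) {
      stop("column_map refers to columns not in the data: ",
           paste(missing_src, collapse = ", "), call. = FALSE)
    }
    for (canon in names(column_map)) {
      names(data)[names(data) == column_map[[canon]]] <- canon
    }
  }
  needed <- c("id", "time", "gl")
  if (!all(needed %in% names(data))) {
    stop("cannot resolve required columns: ",
         paste(setdiff(needed, names(data)), collapse = ", "),
         " (expected id/time/gl or a column_map)", call. = FALSE)
  }
  n_raw <- nrow(data)
  id <- as.character(data$id)
  time <- parse_cgm_time(data$time, tz = tz)
  gl <- suppressWarnings(as.numeric(data$gl))

  bad <- is.na(id) | is.na(time) | !is.finite(gl) | gl <= 0
  n_dropped <- sum(bad)
  out <- tibble::tibble(id = id[!bad], time = time[!bad], gl = gl[!bad])
  if (nrow(out) == 0) {
    stop("no valid readings (", n_raw, " raw rows, ", n_dropped, " dropped)",
         call. = FALSE)
  }

  # subjects keep their order of first appearance; readings sorted in time
  out$id <- factor(out$id, levels = unique(out$id))
  out <- dplyr::arrange(out, .data$id, .data$time)
  dup <- duplicated(out[c("id", "time")])
  n_duplicates <- sum(dup)
  out <- out[!dup, , drop = FALSE]

  report <- list(
    n_raw = n_raw,
    n_dropped = n_dropped,
    n_duplicates = n_duplicates,
    n_retained = nrow(out),
    per_subject = dplyr::count(out, .data$id, name = "n_readings")
  )
  attr(out, "report") <- report
  class(out) <- c("cgm_tbl", class(out))
  out
}

#' @rdname as_cgm_table
#' @param x a `cgm_tbl`.
#' @export
validation_report <- function(x) {
  attr(x, "report")
}

#' Read long-format CGM data from CSV
#'
#' Reads a CSV file with columns `id`, `time`, `gl` (glucose in mg/dL) and
#' returns a validated [as_cgm_table()] object. Times are accepted as
#' ISO-8601 or `"YYYY-MM-DD HH:MM:SS"`.
#'
#' @inheritParams as_cgm_table
#' @param path path to a CSV file with a header row.
#' @return A `cgm_tbl`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("id,time,gl", "S1,2020-01-01 08:00:00,120"), f)
#' read_cgm_csv(f)
#' @export
read_cgm_csv <- function(path, column_map = NULL, tz = "UTC") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- tryCatch(
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE),
    error = function(e) stop("no valid readings (unreadable CSV: ",
                             conditionMessage(e), ")", call. = FALSE)
  )
  if (nrow(raw) == 0) stop("no valid readings (empty file)", call. = FALSE)
  as_cgm_table(raw, column_map = column_map, tz = tz)
}

# Parse character / numeric / POSIXct timestamps to POSIXct in tz.
parse_cgm_time <- function(x, tz = "UTC") {
  if (inherits(x, "POSIXct")) return(lubridate::force_tz(x, tzone = tz))
  if (inherits(x, "Date")) return(as.POSIXct(as.character(x), tz = tz))
  x <- as.character(x)
  out <- suppressWarnings(lubridate::parse_date_time(
    x, orders = c("Ymd HMS", "Ymd HM", "Ymd"), tz = tz, quiet = TRUE
  ))
  out
}

#' Convert glucose units between mg/dL and mmol/L
#'
#' The conversion divisor is 18.0, consistent with the `g/18` rescaling used
#' by the GRADE transform.
#'
#' @param values positive finite glucose values.
#' @param direction `"mgdl_to_mmol"` or `"mmol_to_mgdl"`.
#' @return numeric vector of converted values.
#' @examples
#' convert_units(180, "mgdl_to_mmol") # 10
#' @export
convert_units <- function(values, direction = c("mgdl_to_mmol", "mmol_to_mgdl")) {
  direction <- match.arg(direction)
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("glucose values must be finite and positive", call. = FALSE)
  }
  switch(direction,
    mgdl_to_mmol = values / 18,
    mmol_to_mgdl = values * 18
  )
}

#' Write a per-subject metric table to CSV
#'
#' Writes one row per subject with a header row at full floating point
#' precision (no display rounding), so that re-reading reproduces the values.
#'
#' @param result a data frame with an `id` column and metric columns.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(result, path) {
  stopifnot(is.data.frame(result))
  if (nrow(result) == 0) stop("metric result is empty", call. = FALSE)
  readr::write_csv(result, path, progress = FALSE)
  invisible(path)
}

# Internal: coerce input to a validated cgm_tbl without re-validating twice.
ensure_cgm <- function(data, tz = "UTC") {
  if (inherits(data, "cgm_tbl")) return(data)
  as_cgm_table(data, tz = tz)
}

# Internal: apply a per-subject function returning a named list/vector,
# assembling the tibble-shaped per-subject metric result. Errors in fn are
# captured as NA missing-markers (named after `na_names`) with a warning.
metric_by_subject <- function(data, fn, na_names = "value") {
  data <- ensure_cgm(data)
  ids <- as.character(unique(data$id)) # subsets may carry unused levels
  rows <- lapply(ids, function(s) {
    sub <- data[data$id == s, , drop = FALSE]
    vals <- tryCatch(fn(sub), error = function(e) {
      warning("subject ", s, ": ", conditionMessage(e), call. = FALSE)
      stats::setNames(rep(NA_real_, length(na_names)), na_names)
    })
    c(list(id = s), as.list(vals))
  })
  out <- dplyr::bind_rows(rows)
  out$id <- factor(out$id, levels = ids)
  out
}
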