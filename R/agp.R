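#' Ambulatory glucose profile summary
#'
#' Computes the quantities of a standardized one-page AGP for one subject,
#' using the most recent `maxd` days of data: the collection period, sensor
#' active percentage, mean glucose, GMI, %CV, the percentage of readings in
#' the five standardized glycemic bands, and per-time-of-day quantile curves
#' from the [day_by_day()] grid.
#'
#' Band assignment (cutoffs 54/70/180/250 mg/dL): very low `< 54`, low
#' `54-69` (54 inclusive), target `70-180` (both inclusive), high `181-250`
#' (250 inclusive), very high `> 250`. Every reading falls in exactly one
#' band, so the five percentages sum to 100.
#'
#' @param data readings of a single subject.
#' @param params a [metric_params()] object.
#' @param maxd maximum number of most recent days to use (default 14).
#' @param quantiles probabilities (%) of the per-time-of-day curves.
#' @param tz timezone.
#' @return An object of class `agp_summary`: a list with `start`, `end`,
#'   `ndays`, `active_percent`, `mean`, `gmi`, `cv`, `bands` (named
#'   percentage vector) and `profile` (tibble: `minute_of_day` plus one
#'   column per quantile).
#' @examples
#' x <- simulate_cgm(sim_config(n_subjects = 1, days = 3, seed = 1))
#' s <- agp_summary(x)
#' sum(s$bands)
#' @export
agp_summary <- function(data, params = metric_params(), maxd = 14,
                        quantiles = c(5, 25, 50, 75, 95), tz = "UTC") {
  data <- ensure_cgm(data, tz = tz)
  if (length(unique(data$id)) > 1) {
    stop("agp_summary() works on a single subject", call. = FALSE)
  }
  end <- max(data$time)
  data <- data[data$time > end - maxd * 86400, , drop = FALSE]
  span <- as.numeric(difftime(max(data$time), min(data$time), units = "days"))
  if (span < 0.8) {
    stop("need at least a day of data within the AGP window", call. = FALSE)
  }

  cuts <- params$agp_cutoffs
  g <- data$gl
  bands <- c(
    very_low = 100 * mean(g < cuts[1]),
    low = 100 * mean(g >= cuts[1] & g < cuts[2]),
    target = 100 * mean(g >= cuts[2] & g <= cuts[3]),
    high = 100 * mean(g > cuts[3] & g <= cuts[4]),
    very_high = 100 * mean(g > cuts[4])
  )

  grid <- day_by_day(data, params = params, tz = tz)
  qmat <- apply(grid$gd2d, 2, function(col) {
    col <- col[!is.na(col)]
    if (length(col) == 0) return(rep(NA_real_, length(quantiles)))
    stats::quantile(col, probs = quantiles / 100, names = FALSE, type = 7)
  })
  profile <- tibble::as_tibble(t(qmat), .name_repair = "minimal")
  names(profile) <- paste0("q_", quantiles)
  profile <- dplyr::bind_cols(
    tibble::tibble(minute_of_day = seq_len(ncol(grid$gd2d)) * grid$dt0),
    profile
  )

  ap <- active_percent(data, params = params, tz = tz)
  s <- summary_glu(data$gl, params = params)
  structure(list(
    id = as.character(data$id[1]),
    start = min(data$time), end = end,
    ndays = as.numeric(difftime(end, min(data$time), units = "days")),
    active_percent = ap$active_percent[1],
    mean = unname(s[["mean"]]),
    gmi = unname(gmi(data$gl)),
    cv = unname(s[["cv"]]),
    bands = bands,
    profile = profile,
    dt0 = grid$dt0
  ), class = "agp_summary")
}

#' @export
print.agp_summary <- function(x, ...) {
  cat("AGP summary for", x$id, "\n")
  cat(sprintf("  period: %s to %s (%.1f days, %.1f%% active)\n",
              format(x$start), format(x$end), x$ndays, x$active_percent))
  cat(sprintf("  mean %.1f mg/dL | GMI %.1f%% | CV %.1f%%\n",
              x$mean, x$gmi, x$cv))
  b <- x$bands
  cat(sprintf("  bands: <54: %.1f%% | 54-69: %.1f%% | 70-180: %.1f%% | 181-250: %.1f%% | >250: %.1f%%\n",
              b[1], b[2], b[3], b[4], b[5]))
  invisible(x)
}

#' Ambulatory glucose profile report
#'
#' Renders the AGP for one subject: a stacked band bar of time in the
#' standardized glycemic ranges, a quantile ribbon plot over time of day
#' (5-95% and 25-75% shading around the median), and optional per-day
#' mini-panels. Optionally writes PNG files and a self-contained HTML report
#' to `out_dir`.
#'
#' @inheritParams agp_summary
#' @param daily also build per-day mini-panels.
#' @param out_dir if non-`NULL`, write `agp_profile.png`, `agp_bands.png`
#'   (and `agp_daily.png`), a JSON sidecar `agp_summary.json`, and
#'   `agp_report.html` there.
#' @return A list with `summary` (the [agp_summary()]), `profile_plot`,
#'   `bands_plot` and (if `daily`) `daily_plot` ggplot objects, and `files`
#'   (paths written, if any).
#' @export
agp_report <- function(data, params = metric_params(), maxd = 14,
                       daily = FALSE, out_dir = NULL, tz = "UTC") {
  s <- agp_summary(data, params = params, maxd = maxd, tz = tz)

  prof <- s$profile
  profile_plot <- ggplot2::ggplot(prof, ggplot2::aes(x = .data$minute_of_day / 60)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q_5, ymax = .data$q_95),
                         fill = "#a6cee3", alpha = 0.5, na.rm = TRUE) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q_25, ymax = .data$q_75),
                         fill = "#1f78b4", alpha = 0.5, na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$q_50), colour = "#08306b",
                       linewidth = 0.8, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = params$agp_cutoffs[2:3],
                        linetype = "dashed", colour = "darkgreen") +
    ggplot2::scale_x_continuous(breaks = seq(0, 24, by = 3)) +
    ggplot2::labs(x = "Time of day (h)", y = "Glucose (mg/dL)",
                  title = paste("Ambulatory glucose profile:", s$id),
                  subtitle = sprintf("median with 25-75%% and 5-95%% bands; %.1f days, %.1f%% active",
                                     s$ndays, s$active_percent)) +
    ggplot2::theme_minimal()

  band_df <- tibble::tibble(
    band = factor(names(s$bands),
                  levels = rev(c("very_low", "low", "target", "high", "very_high"))),
    percent = as.numeric(s$bands)
  )
  band_cols <- c(very_low = "#8B0000", low = "#CD5C5C", target = "#2E8B57",
                 high = "#E8B00F", very_high = "#CC7722")
  bands_plot <- ggplot2::ggplot(band_df,
                                ggplot2::aes(x = "", y = .data$percent, fill = .data$band)) +
    ggplot2::geom_col(width = 0.5) +
    ggplot2::scale_fill_manual(values = band_cols) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "% of readings",
                  title = "Time in standardized glycemic ranges (54/70/180/250 mg/dL)") +
    ggplot2::theme_minimal()

  out <- list(summary = s, profile_plot = profile_plot, bands_plot = bands_plot)

  if (daily) {
    sub <- ensure_cgm(data, tz = tz)
    sub <- sub[sub$time > max(sub$time) - maxd * 86400, , drop = FALSE]
    day_df <- dplyr::mutate(
      sub,
      date = as.Date(lubridate::floor_date(.data$time, "day")),
      hour = as.numeric(difftime(.data$time,
                                 lubridate::floor_date(.data$time, "day"),
                                 units = "hours"))
    )
    out$daily_plot <- ggplot2::ggplot(day_df,
                                      ggplot2::aes(x = .data$hour, y = .data$gl)) +
      ggplot2::geom_line(linewidth = 0.3, na.rm = TRUE) +
      ggplot2::facet_wrap(~date) +
      ggplot2::labs(x = "Hour of day", y = "Glucose (mg/dL)",
                    title = "Daily glucose profiles") +
      ggplot2::theme_minimal()
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(
      profile = file.path(out_dir, "agp_profile.png"),
      bands = file.path(out_dir, "agp_bands.png")
    )
    ggplot2::ggsave(files[["profile"]], profile_plot, width = 8, height = 4, dpi = 120)
    ggplot2::ggsave(files[["bands"]], bands_plot, width = 8, height = 2, dpi = 120)
    if (daily) {
      files[["daily"]] <- file.path(out_dir, "agp_daily.png")
      ggplot2::ggsave(files[["daily"]], out$daily_plot, width = 8, height = 6, dpi = 120)
    }
    sidecar <- file.path(out_dir, "agp_summary.json")
    jsonlite::write_json(list(
      id = s$id, start = format(s$start), end = format(s$end),
      ndays = s$ndays, active_percent = s$active_percent,
      mean = s$mean, gmi = s$gmi, cv = s$cv, bands = as.list(s$bands)
    ), sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files[["sidecar"]] <- sidecar
    html <- file.path(out_dir, "agp_report.html")
    write_agp_html(s, files, html)
    files[["html"]] <- html
    out$files <- files
  }
  out
}

# Self-contained HTML: PNGs inlined as base64 data URIs.
write_agp_html <- function(s, files, path) {
  b64 <- function(f) {
    if (is.na(f) || !file.exists(f)) return(NULL)
    paste0("data:image/png;base64,",
           jsonlite::base64_enc(readBin(f, "raw", file.info(f)$size)))
  }
  imgs <- vapply(files[names(files) %in% c("profile", "bands", "daily")],
                 function(f) paste0("<img src='", b64(f), "' style='max-width:100%'>"),
                 "")
  b <- s$bands
  html <- c(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    paste0("<title>AGP report: ", s$id, "</title></head><body>"),
    paste0("<h1>Ambulatory Glucose Profile &mdash; ", s$id, "</h1>"),
    sprintf("<p>Collection period: %s to %s (%.1f days, %.1f%% sensor active)</p>",
            format(s$start), format(s$end), s$ndays, s$active_percent),
    sprintf("<p>Mean glucose %.1f mg/dL &middot; GMI %.1f%% &middot; CV %.1f%%</p>",
            s$mean, s$gmi, s$cv),
    "<table border='1' cellpadding='4'><tr><th>&lt;54</th><th>54&ndash;69</th><th>70&ndash;180</th><th>181&ndash;250</th><th>&gt;250</th></tr>",
    sprintf("<tr><td>%.1f%%</td><td>%.1f%%</td><td>%.1f%%</td><td>%.1f%%</td><td>%.1f%%</td></tr></table>",
            b[1], b[2], b[3], b[4], b[5]),
    imgs,
    "</body></html>"
  )
  writeLines(html, path)
  invisible(path)
}
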