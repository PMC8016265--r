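#' Time-series plot of glucose traces
#'
#' One panel per subject, with horizontal lines marking the target range.
#'
#' @param data a CGM data frame.
#' @param target_range `c(lo, hi)` mg/dL, drawn as red reference lines.
#' @param log plot glucose on a semilogarithmic scale.
#' @param tz timezone.
#' @return A ggplot object with one facet per subject.
#' @examples
#' x <- simulate_cgm(sim_config(n_subjects = 2, days = 2, seed = 1))
#' plot_glu(x)
#' @export
plot_glu <- function(data, target_range = c(70, 180), log = FALSE, tz = "UTC") {
  data <- ensure_cgm(data, tz = tz)
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$time, y = .data$gl)) +
    ggplot2::geom_line(linewidth = 0.3, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = target_range, colour = "red") +
    ggplot2::facet_wrap(~id, scales = "free_x") +
    ggplot2::labs(x = "Time", y = "Glucose (mg/dL)") +
    ggplot2::theme_minimal()
  if (log) p <- p + ggplot2::scale_y_log10()
  p
}

# Colour scales shared by the lasagna plots. blue-red: continuous gradient,
# blue at the lower limit through the midpoint to red at the upper limit.
# red-orange: 4-anchor gradient red -> green -> yellow -> orange with green
# at the midpoint (values in the target region).
lasagna_scale <- function(color_scheme, midpoint, limits) {
  if (color_scheme == "blue-red") {
    ggplot2::scale_fill_gradient2(
      low = "blue", mid = "white", high = "red",
      midpoint = midpoint, limits = limits, oob = scales::squish,
      name = "mg/dL"
    )
  } else {
    anchors <- scales::rescale(
      c(limits[1], midpoint, (midpoint + limits[2]) / 2, limits[2]),
      from = limits
    )
    ggplot2::scale_fill_gradientn(
      colours = c("red", "green", "yellow", "orange"),
      values = anchors, limits = limits, oob = scales::squish,
      name = "mg/dL"
    )
  }
}

# Build the matrix rendered by a lasagna plot (rows x grid columns),
# so sorting contracts can be tested without reading pixels.
lasagna_matrix <- function(data, datatype = c("all", "average"),
                           lasagnatype = c("unsorted", "timesorted", "subjectsorted"),
                           params = metric_params(), tz = "UTC") {
  datatype <- match.arg(datatype)
  lasagnatype <- match.arg(lasagnatype)
  data <- ensure_cgm(data, tz = tz)
  ids <- as.character(unique(data$id))
  grids <- lapply(ids, function(s) {
    day_by_day(data[data$id == s, , drop = FALSE], params = params, tz = tz)
  })
  if (datatype == "average") {
    ncols <- min(vapply(grids, function(g) ncol(g$gd2d), 0L))
    m <- t(vapply(grids, function(g) {
      cm <- colMeans(g$gd2d[, seq_len(ncols), drop = FALSE], na.rm = TRUE)
      cm[is.nan(cm)] <- NA
      cm
    }, numeric(ncols)))
  } else {
    flat <- lapply(grids, flatten_grid)
    len <- max(vapply(flat, length, 0L))
    m <- t(vapply(flat, function(v) c(v, rep(NA_real_, len - length(v))),
                  numeric(len)))
  }
  rownames(m) <- ids
  # sorting modes: values are sorted descending, NAs kept at the end
  desc_sort <- function(x) c(sort(x, decreasing = TRUE), rep(NA_real_, sum(is.na(x))))
  if (lasagnatype == "timesorted") {
    m <- apply(m, 2, desc_sort)
    rownames(m) <- NULL
  } else if (lasagnatype == "subjectsorted") {
    m <- t(apply(m, 1, desc_sort))
  }
  m
}

#' Lasagna plot of glucose values
#'
#' A heatmap of the longitudinal glucose traces: for multiple subjects, rows
#' are subjects over the whole time domain (`datatype = "all"`) or over the
#' average 24-hour day (`datatype = "average"`); for a single subject use
#' [plot_lasagna_1subject()]. Glucose is mapped to colour with the gradient
#' centred at `midpoint` and clipped to `limits`.
#'
#' Sorting modes: `"timesorted"` sorts the values within each time column
#' (descending top to bottom), revealing population-level time-of-day trends;
#' `"subjectsorted"` sorts within each subject's row, comparing glucose
#' distributions across subjects.
#'
#' @param data a CGM data frame.
#' @param datatype `"all"` or `"average"`.
#' @param lasagnatype `"unsorted"`, `"timesorted"` or `"subjectsorted"`.
#' @param color_scheme `"blue-red"` (default) or `"red-orange"`.
#' @param midpoint glucose at the gradient centre (mg/dL).
#' @param limits colour range `c(lo, hi)` mg/dL; data outside are clamped to
#'   the end colours (with a warning).
#' @param params,tz gridding parameters and timezone.
#' @return A ggplot object.
#' @export
plot_lasagna <- function(data, datatype = c("all", "average"),
                         lasagnatype = c("unsorted", "timesorted", "subjectsorted"),
                         color_scheme = c("blue-red", "red-orange"),
                         midpoint = metric_params()$lasagna_midpoint,
                         limits = metric_params()$lasagna_limits,
                         params = metric_params(), tz = "UTC") {
  datatype <- match.arg(datatype)
  lasagnatype <- match.arg(lasagnatype)
  color_scheme <- match.arg(color_scheme)
  m <- lasagna_matrix(data, datatype, lasagnatype, params = params, tz = tz)
  if (any(m < limits[1] | m > limits[2], na.rm = TRUE)) {
    warning("glucose values outside colour limits are clamped", call. = FALSE)
  }
  df <- lasagna_df(m)
  xlab <- if (datatype == "average") "Time of day (slot)" else "Time (slot)"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$gl)) +
    ggplot2::geom_tile() +
    lasagna_scale(color_scheme, midpoint, limits) +
    ggplot2::labs(x = xlab, y = NULL) +
    ggplot2::theme_minimal()
}

#' Lasagna plot for a single subject
#'
#' Rows are days of measurement; `lasagnatype = "timesorted"` sorts within
#' each time-of-day column across days.
#'
#' @inheritParams plot_lasagna
#' @param lasagnatype `"unsorted"` or `"timesorted"`.
#' @return A ggplot object.
#' @export
plot_lasagna_1subject <- function(data, lasagnatype = c("unsorted", "timesorted"),
                                  color_scheme = c("blue-red", "red-orange"),
                                  midpoint = metric_params()$lasagna_midpoint,
                                  limits = metric_params()$lasagna_limits,
                                  params = metric_params(), tz = "UTC") {
  lasagnatype <- match.arg(lasagnatype)
  color_scheme <- match.arg(color_scheme)
  data <- ensure_cgm(data, tz = tz)
  if (length(unique(data$id)) > 1) {
    stop("plot_lasagna_1subject() works on a single subject", call. = FALSE)
  }
  grid <- day_by_day(data, params = params, tz = tz)
  m <- grid$gd2d
  rownames(m) <- as.character(grid$actual_dates)
  if (lasagnatype == "timesorted") {
    m <- apply(m, 2, function(x) c(sort(x, decreasing = TRUE),
                                   rep(NA_real_, sum(is.na(x)))))
    rownames(m) <- NULL
  }
  df <- lasagna_df(m)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$gl)) +
    ggplot2::geom_tile() +
    lasagna_scale(color_scheme, midpoint, limits) +
    ggplot2::labs(x = "Time of day (slot)", y = NULL) +
    ggplot2::theme_minimal()
}

lasagna_df <- function(m) {
  rn <- rownames(m)
  if (is.null(rn)) rn <- as.character(seq_len(nrow(m)))
  tibble::tibble(
    row = factor(rep(rn, times = ncol(m)), levels = rev(rn)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    gl = as.vector(m)
  )
}

# ROC categories used by plot_roc / hist_roc: breaks in mg/dL/min mapped
# blue (falling) -> white (stable) -> red (rising).
roc_breaks <- c(-Inf, -3, -2, -1, 1, 2, 3, Inf)
roc_colors <- c("#0025FA", "#197DE3", "#B3FFF8", "white",
                "#FEC7B6", "#FB5454", "#9F0909")

roc_category <- function(r) {
  cut(r, breaks = roc_breaks, right = FALSE,
      labels = c("(-Inf,-3)", "[-3,-2)", "[-2,-1)", "[-1,1)",
                 "[1,2)", "[2,3)", "[3,Inf)"))
}

#' Glucose time series coloured by rate of change
#'
#' Points with a stable rate of change (within 1 mg/dL/min) are white;
#' increasingly rapid rises are red and drops blue.
#'
#' @param data a CGM data frame.
#' @param subjects optional character vector restricting the panel set.
#' @param timelag ROC lag in minutes.
#' @param params,tz gridding parameters and timezone.
#' @return A ggplot object, one facet per subject.
#' @export
plot_roc <- function(data, subjects = NULL, timelag = 15,
                     params = metric_params(), tz = "UTC") {
  df <- roc_plot_data(data, subjects, timelag, params, tz)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$gl,
                                   colour = .data$category)) +
    ggplot2::geom_point(size = 0.6, na.rm = TRUE) +
    ggplot2::scale_colour_manual(values = stats::setNames(roc_colors,
                                                          levels(df$category)),
                                 drop = FALSE, name = "ROC (mg/dL/min)") +
    ggplot2::facet_wrap(~id, scales = "free_x") +
    ggplot2::labs(x = "Time", y = "Glucose (mg/dL)") +
    ggplot2::theme_dark()
}

#' Histogram of rate-of-change values
#'
#' @inheritParams plot_roc
#' @return A ggplot object, one facet per subject.
#' @export
hist_roc <- function(data, subjects = NULL, timelag = 15,
                     params = metric_params(), tz = "UTC") {
  df <- roc_plot_data(data, subjects, timelag, params, tz)
  df <- df[!is.na(df$roc), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$roc, fill = .data$category)) +
    ggplot2::geom_histogram(bins = 60, na.rm = TRUE) +
    ggplot2::scale_fill_manual(values = stats::setNames(roc_colors,
                                                        levels(df$category)),
                               drop = FALSE, name = "ROC (mg/dL/min)") +
    ggplot2::facet_wrap(~id) +
    ggplot2::labs(x = "Rate of change (mg/dL/min)", y = "Count") +
    ggplot2::theme_minimal()
}

roc_plot_data <- function(data, subjects, timelag, params, tz) {
  data <- ensure_cgm(data, tz = tz)
  if (!is.null(subjects)) {
    missing_ids <- setdiff(subjects, levels(data$id))
    if (length(missing_ids) > 0) {
      stop("unknown subject(s): ", paste(missing_ids, collapse = ", "),
           call. = FALSE)
    }
    data <- data[data$id %in% subjects, , drop = FALSE]
    data$id <- droplevels(data$id)
  }
  df <- roc(data, timelag = timelag, params = params)
  df$category <- roc_category(df$roc)
  df
}
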