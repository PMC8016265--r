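panel2 <- function() simulate_cgm(sim_config(n_subjects = 2, days = 3, seed = 31))

test_that("AGP bands partition the readings with the documented boundary rule", {
  x <- simulate_cgm(sim_config(n_subjects = 1, days = 3, baseline = 120,
                               ar_sd = 60, ar_coef = 0.5, seed = 32))
  s <- agp_summary(x)
  expect_equal(sum(s$bands), 100, tolerance = 1e-9)
  # boundary values 54 / 70 / 180 / 250 land in low / target / target / high
  probe <- cgm_frame(rep(c(54, 70, 180, 250), each = 80), by = 5)
  sp <- agp_summary(probe)
  expect_equal(unname(sp$bands),
               c(0, 25, 50, 25, 0))
})

test_that("a constant subject yields flat quantile curves in one band", {
  x <- cgm_frame(rep(100, 2 * 288), by = 5)
  s <- agp_summary(x)
  expect_equal(unname(s$bands), c(0, 0, 100, 0, 0))
  prof <- s$profile
  for (q in c("q_5", "q_25", "q_50", "q_75", "q_95")) {
    vals <- prof[[q]][!is.na(prof[[q]])]
    expect_true(all(vals == 100))
  }
})

test_that("quantile curves are ordered pointwise", {
  x <- simulate_cgm(sim_config(n_subjects = 1, days = 6, seed = 33))
  prof <- agp_summary(x)$profile
  ok <- stats::complete.cases(prof)
  expect_true(all(prof$q_5[ok] <= prof$q_25[ok]))
  expect_true(all(prof$q_25[ok] <= prof$q_50[ok]))
  expect_true(all(prof$q_50[ok] <= prof$q_75[ok]))
  expect_true(all(prof$q_75[ok] <= prof$q_95[ok]))
})

test_that("the AGP window honours maxd and short data errors out", {
  x <- simulate_cgm(sim_config(n_subjects = 1, days = 20, seed = 34))
  s <- agp_summary(x, maxd = 14)
  expect_lte(s$ndays, 14)
  short <- cgm_frame(c(100, 110, 120), by = 5)
  expect_error(agp_summary(short), "day")
})

test_that("agp_report writes figures, sidecar and self-contained HTML", {
  x <- simulate_cgm(sim_config(n_subjects = 1, days = 3, seed = 35))
  dir <- withr::local_tempdir()
  res <- agp_report(x, daily = TRUE, out_dir = dir)
  for (f in res$files) {
    expect_true(file.exists(f))
    expect_gt(file.info(f)$size, 0)
  }
  side <- jsonlite::read_json(file.path(dir, "agp_summary.json"))
  expect_equal(side$mean, res$summary$mean, tolerance = 1e-9)
  expect_equal(sum(unlist(side$bands)), 100, tolerance = 1e-9)
  html <- readLines(file.path(dir, "agp_report.html"))
  expect_true(any(grepl("data:image/png;base64", html)))
})

test_that("plot_glu builds one panel per subject, optionally on a log scale", {
  x <- panel2()
  p <- plot_glu(x)
  b <- ggplot2::ggplot_build(p)
  expect_equal(length(levels(b$layout$layout$id)), 2)
  plog <- plot_glu(x, log = TRUE)
  blog <- ggplot2::ggplot_build(plog)
  # on the log10 scale the rendered y range lives near log10(glucose)
  expect_lt(max(blog$layout$panel_params[[1]]$y.range), 10)
})

test_that("lasagna matrices respect their sorting contracts", {
  x <- panel2()
  m <- gluvar:::lasagna_matrix(x, "average", "unsorted")
  expect_equal(nrow(m), 2)
  ts <- gluvar:::lasagna_matrix(x, "average", "timesorted")
  for (j in seq_len(ncol(ts))) {
    col <- ts[, j][!is.na(ts[, j])]
    expect_false(is.unsorted(rev(col))) # non-increasing top to bottom
  }
  ss <- gluvar:::lasagna_matrix(x, "average", "subjectsorted")
  for (i in seq_len(nrow(ss))) {
    row <- ss[i, ][!is.na(ss[i, ])]
    expect_false(is.unsorted(rev(row)))
  }
  # sorting permutes values within columns, never invents new ones
  expect_equal(sort(as.vector(ts[!is.na(ts)])), sort(as.vector(m[!is.na(m)])))
})

test_that("lasagna colour mapping is monotone in glucose (blue-red scheme)", {
  sc <- gluvar:::lasagna_scale("blue-red", midpoint = 105, limits = c(50, 500))
  cols <- sc$palette(scales::rescale(c(60, 105, 200, 400), from = c(50, 500)))
  blue <- grDevices::col2rgb(cols)["blue", ]
  red <- grDevices::col2rgb(cols)["red", ]
  expect_false(is.unsorted(rev(blue))) # blue channel non-increasing
  expect_false(is.unsorted(red)) # red channel non-decreasing
  # figures render without error in both schemes
  x <- panel2()
  expect_s3_class(plot_lasagna(x, "average", "unsorted", "red-orange",
                               midpoint = 140, limits = c(60, 400)), "ggplot")
  one <- x[x$id == "Subject 1", ]
  expect_s3_class(plot_lasagna_1subject(one, "timesorted"), "ggplot")
})

test_that("ROC plots categorise stability and honour the subjects filter", {
  const <- cgm_frame(rep(100, 600), by = 5)
  df <- gluvar:::roc_plot_data(const, NULL, 15, metric_params(), "UTC")
  cats <- df$category[!is.na(df$roc)]
  expect_true(all(cats == "[-1,1)"))

  ramp <- cgm_frame(40 + 2 * 5 * (1:250), by = 5) # slope 2 mg/dL/min
  df2 <- gluvar:::roc_plot_data(ramp, NULL, 15, metric_params(), "UTC")
  expect_true(all(df2$category[!is.na(df2$roc)] == "[2,3)"))

  x <- simulate_cgm(sim_config(n_subjects = 3, days = 2, seed = 36))
  p <- plot_roc(x, subjects = c("Subject 1", "Subject 3"))
  b <- ggplot2::ggplot_build(p)
  expect_equal(nrow(b$layout$layout), 2)
  expect_error(plot_roc(x, subjects = "nobody"), "unknown subject")
  expect_s3_class(hist_roc(x, subjects = "Subject 2"), "ggplot")
})

test_that("plotting never mutates the input table", {
  x <- panel2()
  before <- suppressWarnings(all_metrics(x))
  invisible(plot_glu(x))
  invisible(plot_lasagna(x, "average"))
  invisible(plot_roc(x))
  after <- suppressWarnings(all_metrics(x))
  expect_identical(before, after)
})
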