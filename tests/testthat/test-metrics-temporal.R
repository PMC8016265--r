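const_grid <- function(value = 100, ndays = 3, ncols = 48) {
  grid_from_matrix(matrix(value, ndays, ncols))
}

test_that("constant and structured grids give the expected CONGA/MODD", {
  expect_equal(unname(conga(const_grid())), 0)
  # linear ramp in time: all lagged differences equal -> sd 0
  ramp <- grid_from_matrix(matrix(seq(100, 243.5, by = 0.5), 2, 144, byrow = TRUE))
  expect_equal(unname(conga(ramp)), 0, tolerance = 1e-9)

  expect_equal(unname(modd(const_grid())), 0)
  day1 <- runif(48, 80, 200)
  shifted <- grid_from_matrix(rbind(day1, day1 + 7))
  expect_equal(unname(modd(shifted)), 7, tolerance = 1e-12)
  expect_error(modd(grid_from_matrix(matrix(100, 1, 48))), "2 days")
})

test_that("SD decomposition closed forms hold", {
  expect_equal(unname(sd_measures(const_grid())),
               rep(0, 6), tolerance = 1e-12)
  # day i constant at c_i
  cs <- c(100, 130, 190)
  g <- grid_from_matrix(matrix(rep(cs, each = 48), 3, 48, byrow = TRUE))
  s <- sd_measures(g)
  expect_equal(unname(s[["SdW"]]), 0)
  expect_equal(unname(s[["SdHHMM"]]), 0)
  expect_equal(unname(s[["SdDM"]]), sd(cs))
  expect_equal(unname(s[["SdB"]]), sd(cs))
  expect_equal(unname(s[["SdBDM"]]), 0)
  # every day the same non-constant profile v
  set.seed(20)
  v <- runif(48, 80, 250)
  g2 <- grid_from_matrix(matrix(rep(v, 3), 3, 48, byrow = TRUE))
  s2 <- sd_measures(g2)
  expect_equal(unname(s2[["SdW"]]), sd(v), tolerance = 1e-12)
  expect_equal(unname(s2[["SdHHMM"]]), sd(v), tolerance = 1e-12)
  expect_equal(unname(s2[["SdDM"]]), 0, tolerance = 1e-12)
  expect_equal(unname(s2[["SdB"]]), 0, tolerance = 1e-9)
  expect_equal(unname(s2[["SdBDM"]]), 0, tolerance = 1e-9)
})

test_that("CV subtypes summarise the daily CVs", {
  expect_equal(unname(cv_measures(const_grid())), c(0, 0))
  # engineer two days with known CVs 10% and 20%
  day_cv <- function(m, cv) {
    s <- cv / 100 * m
    c(m - s / sqrt(2), m + s / sqrt(2))
  }
  g <- grid_from_matrix(rbind(day_cv(100, 10), day_cv(100, 20)), dt0 = 720)
  res <- cv_measures(g)
  expect_equal(unname(res[["CVmean"]]), 15, tolerance = 1e-9)
  expect_equal(unname(res[["CVsd"]]), sd(c(10, 20)), tolerance = 1e-9)
})

test_that("ADRR matches the risk-transform construction", {
  g0 <- exp(5.381^(1 / 1.084))
  flat <- cgm_frame(rep(g0, 600), by = 5)
  expect_equal(adrr(flat)$adrr, 0, tolerance = 1e-12)

  low <- cgm_frame(rep(50, 288), by = 5)
  f50 <- 1.509 * (log(50)^1.084 - 5.381)
  expect_equal(adrr(low)$adrr, 10 * f50^2, tolerance = 1e-9)
})

test_that("GVP measures excess arc length", {
  expect_equal(gvp(cgm_frame(rep(120, 100)))$gvp, 0)
  seg <- cgm_frame(c(100, 105), by = 5)
  expect_equal(gvp(seg)$gvp, 100 * (sqrt(50) / 5 - 1), tolerance = 1e-9)
  # non-negative by the triangle inequality; gap-spanning segments excluded
  set.seed(21)
  x <- cgm_frame(runif(400, 60, 300))
  expect_gte(gvp(x)$gvp, 0)
  gappy <- x[-(100:150), ]
  expect_gte(gvp(gappy)$gvp, 0)
})

test_that("MAG equals total absolute change per hour", {
  expect_equal(unname(mag(const_grid())), 0)
  # ramp of 1 mg/dL per minute
  ramp <- grid_from_matrix(matrix(40 + 5 * (1:288), 1, 288, byrow = TRUE), dt0 = 5)
  expect_equal(unname(mag(ramp)), 60, tolerance = 1e-9)
  # telescoping: halving n leaves MAG unchanged on monotone gap-free data
  expect_equal(unname(mag(ramp, n = 30)), unname(mag(ramp, n = 60)),
               tolerance = 1e-9)
})

test_that("AUC is the hourly-average glucose and sits between min and max", {
  expect_equal(unname(auc(const_grid(100))), 100)
  lin <- grid_from_matrix(matrix(seq(100, 200, length.out = 288), 1, 288,
                                 byrow = TRUE), dt0 = 5)
  expect_equal(unname(auc(lin)), 150, tolerance = 1e-9)
  set.seed(22)
  g <- random_grid(3, 48, na_frac = 0.1)
  a <- unname(auc(g))
  expect_true(a >= min(g$gd2d, na.rm = TRUE) && a <= max(g$gd2d, na.rm = TRUE))
})

test_that("rate of change is zero on constants, the slope on ramps", {
  expect_equal(unname(sd_roc(const_grid())), 0)
  r <- roc(const_grid(), timelag = 30)
  expect_true(all(r[!is.na(r)] == 0))

  slope <- 0.5 # mg/dL per minute
  ramp <- grid_from_matrix(matrix(40 + slope * 5 * (1:288), 1, 288, byrow = TRUE),
                           dt0 = 5)
  rr <- roc(ramp, timelag = 15)
  expect_equal(unique(rr[!is.na(rr)]), slope, tolerance = 1e-12)
  expect_equal(unname(sd_roc(ramp)), 0, tolerance = 1e-12)
  # constant day-offsets do not create spurious rate of change within days
  two <- grid_from_matrix(rbind(100 + 0.1 * (1:48), 150 + 0.1 * (1:48)))
  rr2 <- roc(two, timelag = 60)
  inner <- rr2[c(4:48, 52:96)] # exclude the cross-midnight lag positions
  expect_equal(sd(inner[!is.na(inner)] - mean(inner, na.rm = TRUE)), 0,
               tolerance = 1e-9)
})

test_that("grid metrics agree with brute-force oracles on random grids", {
  set.seed(23)
  for (i in 1:200) {
    ncols <- sample(c(24, 48), 1)
    g <- random_grid(ndays = sample(2:5, 1), ncols = ncols,
                     na_frac = runif(1, 0, 0.3))
    expect_equal(unname(conga(g)), oracle_conga(g), tolerance = 1e-9)
    expect_equal(unname(modd(g)), oracle_modd(g), tolerance = 1e-9)
    expect_equal(unname(sd_measures(g)), unname(oracle_sd_measures(g)),
                 tolerance = 1e-9)
    expect_equal(unname(cv_measures(g)), unname(oracle_cv_measures(g)),
                 tolerance = 1e-9)
  }
})

test_that("ADRR agrees with a per-day brute force on random traces", {
  set.seed(24)
  for (i in 1:200) {
    n <- sample(50:200, 1)
    df <- cgm_frame(runif(n, 40, 400), by = 30)
    expect_equal(adrr(df)$adrr, oracle_adrr(df), tolerance = 1e-9)
  }
})

test_that("temporal metrics are invariant under a 24-hour shift", {
  x <- simulate_cgm(sim_config(n_subjects = 1, days = 4, seed = 25))
  y <- dplyr::mutate(x, time = time + 86400)
  for (f in list(conga, modd, gvp, mag, auc, sd_roc)) {
    expect_equal(f(x)[[2]], f(y)[[2]], tolerance = 1e-9)
  }
  expect_equal(adrr(x)$adrr, adrr(y)$adrr, tolerance = 1e-9)
})

test_that("gvp from the grid matches gvp from raw readings when gap-free", {
  x <- simulate_cgm(sim_config(n_subjects = 1, days = 2, dropout_prob = 0,
                               gap_rate = 0, jitter_sd = 0, seed = 26))
  g <- day_by_day(x)
  v <- as.vector(t(g$gd2d))
  ok <- !is.na(v)
  grid_df <- cgm_frame(v[ok], by = g$dt0)
  # the first reading falls at midnight, one slot before the grid starts;
  # drop it so both series cover exactly the same segments
  expect_equal(gvp(grid_df)$gvp, gvp(x[-1, ])$gvp, tolerance = 1e-9)
})

test_that("all_metrics assembles one deterministic row per subject", {
  x <- make_phenotype_panel(seed = 3)
  m1 <- suppressWarnings(all_metrics(x))
  expect_equal(nrow(m1), 5)
  expect_gte(ncol(m1) - 1, 30)
  m2 <- suppressWarnings(all_metrics(x))
  expect_identical(m1, m2)
  # dropping a subject drops exactly one row, others unchanged
  m4 <- suppressWarnings(all_metrics(x[x$id != "Subject 3", ]))
  expect_equal(nrow(m4), 4)
  expect_equal(m4$mean, m1$mean[-3], tolerance = 1e-12)
  expect_equal(m4$conga, m1$conga[-3], tolerance = 1e-12)
  # missing-markers propagate instead of zeros
  const <- cgm_frame(rep(100, 600))
  mc <- suppressWarnings(all_metrics(const))
  expect_true(is.na(mc$mage))
})
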