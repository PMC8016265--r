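test_that("summary statistics match hand computations", {
  s <- summary_glu(c(100, 200))
  expect_equal(unname(s[["mean"]]), 150)
  expect_equal(unname(s[["sd"]]), 100 / sqrt(2), tolerance = 1e-9)
  expect_equal(unname(s[["range"]]), 100)

  k <- summary_glu(rep(100, 10))
  expect_equal(unname(k[c("mean", "sd", "cv", "iqr", "range", "mad")]),
               c(100, 0, 0, 0, 0, 0))
  # quantiles are non-decreasing in probability
  set.seed(1)
  q <- summary_glu(runif(101, 50, 350))
  expect_false(is.unsorted(q[paste0("q_", c(0, 25, 50, 75, 100))]))
})

test_that("above/below/in-range respect their boundary conventions", {
  expect_equal(unname(percent_above(c(100, 150, 200, 300), targets = c(140, 250))),
               c(75, 25))
  expect_equal(unname(percent_above(rep(100, 5), targets = 140)), 0)
  expect_equal(unname(percent_below(c(50, 60, 100))), c(100 / 3, 200 / 3))
  expect_equal(unname(percent_in_range(c(50, 100, 200), list(c(70, 180)))), 100 / 3)
  # inclusive in-range boundary, strict above/below
  expect_equal(unname(percent_in_range(70, list(c(70, 180)))), 100)
  expect_equal(unname(percent_above(140, targets = 140)), 0)
  expect_equal(unname(percent_below(54, targets = 54)), 0)
})

test_that("above + below + equal partition the readings exactly", {
  set.seed(2)
  for (i in 1:20) {
    v <- sample(c(round(runif(50, 40, 400)), rep(140, 7)))
    above <- unname(percent_above(v, targets = 140))
    below <- unname(percent_below(v, targets = 140))
    equal <- 100 * mean(v == 140)
    expect_equal(above + below + equal, 100)
  }
})

test_that("mean-based indices follow their formulas and depend only on the mean", {
  expect_equal(unname(ea1c(rep(100, 4))), 146.7 / 28.7)
  expect_equal(unname(ea1c(rep(154, 4))), (154 + 46.7) / 28.7)
  expect_equal(round(unname(gmi(rep(123.7, 3))), 1), 6.3)
  expect_equal(round(unname(gmi(rep(218.5, 3))), 1), 8.5)
  # permutations and different dispersion, same mean -> same value
  expect_equal(unname(gmi(c(100, 200))), unname(gmi(c(50, 250))))
  expect_equal(unname(ea1c(c(100, 200))), unname(ea1c(c(150, 150))))
})

test_that("J-index, M-value and GRADE match closed forms", {
  expect_equal(unname(j_index(rep(100, 5))), 10)
  # mean 123.7, sd 33.3 built from a two-point sample
  v <- 123.7 + c(-1, 1) * 33.3 / sqrt(2)
  expect_equal(round(unname(j_index(v)), 1), 24.6)

  expect_equal(unname(m_value(rep(90, 5))), 0)
  expect_equal(unname(m_value(180)), (10 * log10(2))^3, tolerance = 1e-9)
  expect_equal(unname(m_value(45)), unname(m_value(180)), tolerance = 1e-9)

  g0 <- 18 * 10^(10^-0.16)
  gr <- grade_family(rep(g0, 5))
  expect_equal(unname(gr[["grade"]]), 0, tolerance = 1e-9)
  # per-reading contribution capped at 50 for extreme hyperglycemia
  expect_equal(unname(grade_family(rep(800, 3))[["grade"]]), 50)
  expect_lt(unname(grade_family(rep(600, 3))[["grade"]]), 50)
  set.seed(3)
  gr2 <- grade_family(runif(200, 45, 350))
  expect_equal(sum(gr2[c("grade_eugly", "grade_hypo", "grade_hyper")]), 100)
  expect_warning(grade_family(c(10, 100)), "clamped")
})

test_that("risk indices are one-sided, vanish at the transform root", {
  g0 <- exp(5.381^(1 / 1.084))
  expect_equal(g0, 112.5, tolerance = 0.1)
  b0 <- bgi(rep(g0, 4))
  expect_equal(unname(b0[["lbgi"]]), 0, tolerance = 1e-12)
  expect_equal(unname(b0[["hbgi"]]), 0, tolerance = 1e-12)

  b50 <- bgi(rep(50, 4))
  f50 <- 1.509 * (log(50)^1.084 - 5.381)
  expect_equal(unname(b50[["lbgi"]]), 10 * f50^2, tolerance = 1e-9)
  expect_equal(round(unname(b50[["lbgi"]]), 1), 22.5)
  expect_equal(unname(b50[["hbgi"]]), 0)
  # rl and rh never simultaneously positive
  set.seed(4)
  v <- runif(500, 40, 400)
  b <- bgi(v)
  expect_true(unname(b[["lbgi"]]) >= 0 && unname(b[["hbgi"]]) >= 0)
})

test_that("hyper/hypo indices and IGC match closed forms", {
  expect_equal(unname(hyper_index(rep(120, 5))), 0)
  expect_equal(unname(hyper_index(170)), 30^0.1, tolerance = 1e-12)
  expect_equal(unname(hypo_index(50)), 900 / 30)
  set.seed(5)
  v <- runif(300, 40, 350)
  expect_equal(unname(igc(v)),
               unname(hyper_index(v)) + unname(hypo_index(v)), tolerance = 1e-12)
})

test_that("COGI spans [0, 100], hits its extremes, and matches its formula", {
  expect_equal(unname(cogi(rep(120, 20))), 100)
  expect_equal(unname(cogi(c(rep(40, 10), rep(400, 10)))), 0)
  set.seed(6)
  for (i in 1:10) {
    v <- runif(200, 40, 400)
    w1 <- 100 * mean(v >= 70 & v <= 180)
    w2 <- 100 * (1 - min(100 * mean(v < 70), 15) / 15)
    w3 <- 100 * min(max((108 - sd(v)) / 90, 0), 1)
    expect_equal(unname(cogi(v)), 0.5 * w1 + 0.35 * w2 + 0.15 * w3,
                 tolerance = 1e-12)
    expect_true(cogi(v) >= 0 && cogi(v) <= 100)
  }
})

test_that("naive MAGE averages 1-SD exceedances and flags empty sets as NA", {
  expect_equal(unname(mage(c(100, 100, 100, 200))), 75)
  expect_true(is.na(mage(rep(100, 10))))
  # brute-force re-implementation on random series
  set.seed(7)
  for (i in 1:200) {
    v <- runif(sample(10:60, 1), 40, 400)
    m <- mean(v)
    s <- sd(v)
    dev <- abs(v - m)
    expected <- if (any(dev > s)) mean(dev[dev > s]) else NA_real_
    expect_equal(unname(mage(v)), expected, tolerance = 1e-12)
  }
  # the moving-average variant exists behind a flag and stays non-negative
  set.seed(8)
  v <- 150 + 60 * sin(seq(0, 12 * pi, length.out = 400)) + rnorm(400, 0, 10)
  mm <- mage(v, variant = "ma_crossing")
  expect_true(is.na(mm) || mm > 0)
})

test_that("scale equivariance: k-scaling moves sd/iqr/range/mad, leaves cv fixed", {
  set.seed(9)
  v <- runif(300, 60, 300)
  k <- 2.7
  s1 <- summary_glu(v)
  s2 <- summary_glu(k * v)
  for (f in c("mean", "sd", "iqr", "range", "mad")) {
    expect_equal(unname(s2[[f]]), k * unname(s1[[f]]), tolerance = 1e-9)
  }
  expect_equal(unname(s2[["cv"]]), unname(s1[["cv"]]), tolerance = 1e-9)
})

test_that("data-frame input yields a tibble-shaped per-subject result", {
  x <- simulate_cgm(sim_config(n_subjects = 3, days = 2, seed = 10))
  res <- gmi(x)
  expect_s3_class(res, "tbl_df")
  expect_equal(nrow(res), 3)
  expect_equal(names(res), c("id", "gmi"))
  one <- x[x$id == "Subject 2", ]
  expect_equal(res$gmi[2], unname(gmi(one$gl)))
})
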