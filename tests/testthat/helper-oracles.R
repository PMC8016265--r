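# Independent brute-force oracles, written as plain loops directly from the
# metric definitions. They deliberately share no code with the package.

oracle_conga <- function(grid, n_hours = 1) {
  v <- as.vector(t(grid$gd2d))
  k <- round(n_hours * 60 / grid$dt0)
  d <- c()
  for (t in seq_along(v)) {
    if (t > k && !is.na(v[t]) && !is.na(v[t - k])) {
      d <- c(d, v[t] - v[t - k])
    }
  }
  if (length(d) < 2) NA_real_ else stats::sd(d)
}

oracle_modd <- function(grid) {
  m <- grid$gd2d
  d <- c()
  for (i in seq_len(nrow(m) - 1)) {
    for (j in seq_len(ncol(m))) {
      if (!is.na(m[i, j]) && !is.na(m[i + 1, j])) {
        d <- c(d, abs(m[i + 1, j] - m[i, j]))
      }
    }
  }
  if (length(d) == 0) NA_real_ else mean(d)
}

oracle_sd_measures <- function(grid) {
  m <- grid$gd2d
  dt0 <- grid$dt0
  sdv <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) NA_real_ else stats::sd(x)
  }
  mean_na <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) NA_real_ else mean(x)
  }
  sdw <- mean_na(vapply(seq_len(nrow(m)), function(i) sdv(m[i, ]), 0))
  col_means <- vapply(seq_len(ncol(m)), function(j) mean_na(m[, j]), 0)
  sdhhmm <- sdv(col_means)
  v <- as.vector(t(m))
  block <- round(60 / dt0)
  bs <- c()
  b <- 1
  while (b * block <= length(v)) {
    bs <- c(bs, sdv(v[((b - 1) * block + 1):(b * block)]))
    b <- b + 1
  }
  sdwsh <- mean_na(bs)
  day_means <- vapply(seq_len(nrow(m)), function(i) mean_na(m[i, ]), 0)
  sddm <- sdv(day_means)
  sdb <- mean_na(vapply(seq_len(ncol(m)), function(j) sdv(m[, j]), 0))
  cm <- m
  for (i in seq_len(nrow(m))) cm[i, ] <- m[i, ] - day_means[i]
  sdbdm <- mean_na(vapply(seq_len(ncol(cm)), function(j) sdv(cm[, j]), 0))
  c(SdW = sdw, SdHHMM = sdhhmm, SdWSH = sdwsh,
    SdDM = sddm, SdB = sdb, SdBDM = sdbdm)
}

oracle_cv_measures <- function(grid) {
  m <- grid$gd2d
  cvs <- c()
  for (i in seq_len(nrow(m))) {
    row <- m[i, ][!is.na(m[i, ])]
    if (length(row) >= 2) cvs <- c(cvs, 100 * stats::sd(row) / mean(row))
  }
  c(CVmean = if (length(cvs) == 0) NA_real_ else mean(cvs),
    CVsd = if (length(cvs) < 2) NA_real_ else stats::sd(cvs))
}

oracle_adrr <- function(df) {
  days <- unique(as.Date(df$time))
  total <- 0
  for (d in seq_along(days)) {
    sub <- df[as.Date(df$time) == days[d], ]
    lr <- 0
    hr <- 0
    for (g in sub$gl) {
      f <- 1.509 * (log(g)^1.084 - 5.381)
      if (f < 0 && 10 * f^2 > lr) lr <- 10 * f^2
      if (f > 0 && 10 * f^2 > hr) hr <- 10 * f^2
    }
    total <- total + lr + hr
  }
  total / length(days)
}
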