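# Shared fixture builders. All fixtures are generated in code; no data files.

t0 <- function(day = "2020-01-01", time = "00:00:00") {
  as.POSIXct(paste(day, time), tz = "UTC")
}

# A single-subject CGM frame with readings every `by` minutes.
cgm_frame <- function(gl, start = t0(), by = 5, id = "S1") {
  data.frame(
    id = id,
    time = start + 60 * by * (seq_along(gl) - 1),
    gl = gl
  )
}

# A day_grid built directly from a matrix (rows = days, columns = slots).
grid_from_matrix <- function(m, dt0 = 1440 / ncol(m), start = as.Date("2020-01-01")) {
  stopifnot(1440 %% ncol(m) == 0 || 1440 %% dt0 == 0)
  structure(
    list(gd2d = m,
         actual_dates = seq(start, by = "day", length.out = nrow(m)),
         dt0 = dt0),
    class = "day_grid"
  )
}

# Random small grid with missing cells, for oracle-equivalence trials.
random_grid <- function(ndays = 3, ncols = 24, na_frac = 0.15) {
  m <- matrix(stats::runif(ndays * ncols, 50, 350), nrow = ndays)
  m[stats::runif(length(m)) < na_frac] <- NA
  grid_from_matrix(m, dt0 = 1440 / ncols)
}
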