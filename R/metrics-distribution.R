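#' @title Time-independent glucose metrics
#' @description
#' Every metric in this file is computed on a subject's pooled glucose
#' values, ignoring when they were measured. Each function accepts either a
#' bare numeric vector of glucose values (mg/dL), returning the metric value
#' directly, or a long-format CGM data frame (`id`, `time`, `gl`), returning
#' a tibble with one row per subject.
#' @name metrics_distribution
NULL

# Dispatch helper: vector -> fn(values); data frame -> per-subject tibble.
dist_metric <- function(data, fn, na_names) {
  if (is.numeric(data)) {
    v <- data[is.finite(data)]
    if (length(v) == 0) stop("no glucose values", call. = FALSE)
    return(fn(v))
  }
  metric_by_subject(data, function(sub) fn(sub$gl), na_names = na_names)
}

#' Distribution summary of glucose values
#'
#' Mean, median, sample SD, coefficient of variation (`100 * sd / mean`, %),
#' IQR, range (max - min), scaled median absolute deviation and quantiles at
#' `params$quantile_probs` (linear interpolation of order statistics, R's
#' default type-7 rule).
#'
#' @param data numeric glucose vector (mg/dL) or CGM data frame.
#' @param params a [metric_params()] object.
#' @return Named vector (vector input) or per-subject tibble with columns
#'   `mean`, `median`, `sd`, `cv`, `iqr`, `range`, `mad` and `q_<p>` per
#'   quantile probability.
#' @examples
#' summary_glu(c(100, 120, 140))
#' @export
summary_glu <- function(data, params = metric_params()) {
  probs <- params$quantile_probs
  k <- params$mad_constant
  dist_metric(data, function(v) {
    qs <- stats::quantile(v, probs = probs / 100, names = FALSE, type = 7)
    c(mean = mean(v), median = stats::median(v),
      sd = if (length(v) >= 2) stats::sd(v) else NA_real_,
      cv = if (length(v) >= 2) 100 * stats::sd(v) / mean(v) else NA_real_,
      iqr = unname(stats::quantile(v, 0.75) - stats::quantile(v, 0.25)),
      range = max(v) - min(v),
      mad = stats::mad(v, constant = k),
      stats::setNames(qs, paste0("q_", probs)))
  }, na_names = c("mean", "median", "sd", "cv", "iqr", "range", "mad",
                  paste0("q_", probs)))
}

#' Percent of readings above glucose thresholds
#'
#' `100 * #\{gl > t\} / n` for each threshold `t` (strict inequality).
#'
#' @inheritParams summary_glu
#' @param targets mg/dL thresholds.
#' @return Named vector `above_<t>` or per-subject tibble.
#' @examples
#' percent_above(c(100, 150, 200, 300), targets = c(140, 250))
#' @export
percent_above <- function(data, targets = metric_params()$targets_above) {
  dist_metric(data, function(v) {
    stats::setNames(vapply(targets, function(t) 100 * mean(v > t), 0),
                    paste0("above_", targets))
  }, na_names = paste0("above_", targets))
}

#' Percent of readings below glucose thresholds
#'
#' `100 * #\{gl < t\} / n` for each threshold `t` (strict inequality).
#'
#' @inheritParams summary_glu
#' @param targets mg/dL thresholds.
#' @return Named vector `below_<t>` or per-subject tibble.
#' @export
percent_below <- function(data, targets = metric_params()$targets_below) {
  dist_metric(data, function(v) {
    stats::setNames(vapply(targets, function(t) 100 * mean(v < t), 0),
                    paste0("below_", targets))
  }, na_names = paste0("below_", targets))
}

#' Percent of readings inside target ranges
#'
#' `100 * #\{lo <= gl <= hi\} / n` for each range (inclusive at both ends, so
#' together with the strict [percent_above()] / [percent_below()] the three
#' partition the readings).
#'
#' @inheritParams summary_glu
#' @param ranges list of `c(lo, hi)` mg/dL pairs.
#' @return Named vector `in_range_<lo>_<hi>` or per-subject tibble.
#' @export
percent_in_range <- function(data, ranges = metric_params()$ranges_in) {
  nm <- vapply(ranges, function(r) paste0("in_range_", r[1], "_", r[2]), "")
  dist_metric(data, function(v) {
    stats::setNames(
      vapply(ranges, function(r) 100 * mean(v >= r[1] & v <= r[2]), 0), nm)
  }, na_names = nm)
}

#' Estimated A1c from mean glucose
#'
#' `eA1c = (mean + 46.7) / 28.7`, the ADAG study linear re-expression of mean
#' glucose on the HbA1c percent scale.
#'
#' @inheritParams summary_glu
#' @return %A1c estimate.
#' @examples
#' ea1c(rep(100, 10)) # 5.112
#' @export
ea1c <- function(data) {
  dist_metric(data, function(v) c(ea1c = (mean(v) + 46.7) / 28.7),
              na_names = "ea1c")
}

#' Glucose management indicator
#'
#' `GMI = 3.31 + 0.02392 * mean`, in %.
#'
#' @inheritParams summary_glu
#' @return GMI in %.
#' @examples
#' gmi(rep(123.7, 4)) # 6.27, rounds to 6.3
#' @export
gmi <- function(data) {
  dist_metric(data, function(v) c(gmi = 3.31 + 0.02392 * mean(v)),
              na_names = "gmi")
}

#' J-index
#'
#' `J = 0.001 * (mean + sd)^2`, combining level and variability in one score.
#'
#' @inheritParams summary_glu
#' @return J-index (unitless).
#' @export
j_index <- function(data) {
  dist_metric(data, function(v) {
    s <- if (length(v) >= 2) stats::sd(v) else 0
    c(j_index = 0.001 * (mean(v) + s)^2)
  }, na_names = "j_index")
}

#' M-value of Schlichtkrull
#'
#' `M = mean(|10 * log10(gl / r)|^3)` with reference value `r` (default
#' 90 mg/dL); symmetric on the log scale, so readings at `r/2` and `2r`
#' contribute equally.
#'
#' @inheritParams summary_glu
#' @param r reference glucose in mg/dL.
#' @return M-value (unitless).
#' @export
m_value <- function(data, r = metric_params()$mvalue_ref) {
  dist_metric(data, function(v) c(m_value = mean(abs(10 * log10(v / r))^3)),
              na_names = "m_value")
}

# GRADE per-reading contribution, capped at 50. The double log is undefined
# for gl <= 18 mg/dL (log10 argument <= 1); such physiologically impossible
# values are clamped just above 18 with a warning.
grade_h <- function(v) {
  if (any(v <= 18)) {
    warning("glucose values <= 18 mg/dL clamped for the GRADE transform",
            call. = FALSE)
    v <- pmax(v, 18 + 1e-6)
  }
  pmin(425 * (log10(log10(v / 18)) + 0.16)^2, 50)
}

#' GRADE and its eu-/hypo-/hyperglycemia attribution
#'
#' The glycemic risk assessment diabetes equation assigns each reading the
#' risk `h(gl) = 425 * (log10(log10(gl / 18)) + 0.16)^2`, capped at 50.
#' `grade` is the mean risk; `grade_eugly`, `grade_hypo` and `grade_hyper`
#' attribute the total risk to readings inside the euglycemic range, below
#' it and above it (percentages summing to 100).
#'
#' @inheritParams summary_glu
#' @param eugly_range euglycemic range `c(lo, hi)` in mg/dL.
#' @return Named vector / tibble with `grade`, `grade_eugly`, `grade_hypo`,
#'   `grade_hyper`.
#' @export
grade_family <- function(data, eugly_range = metric_params()$grade_eugly_range) {
  nm <- c("grade", "grade_eugly", "grade_hypo", "grade_hyper")
  dist_metric(data, function(v) {
    h <- grade_h(v)
    tot <- sum(h)
    if (tot == 0) {
      # zero total risk: attribute everything to the euglycemic component
      return(c(grade = 0, grade_eugly = 100, grade_hypo = 0, grade_hyper = 0))
    }
    c(grade = mean(h),
      grade_eugly = 100 * sum(h[v >= eugly_range[1] & v <= eugly_range[2]]) / tot,
      grade_hypo = 100 * sum(h[v < eugly_range[1]]) / tot,
      grade_hyper = 100 * sum(h[v > eugly_range[2]]) / tot)
  }, na_names = nm)
}

# Kovatchev symmetrizing transform and one-sided risks.
bgi_risks <- function(v) {
  f <- 1.509 * (log(v)^1.084 - 5.381)
  list(rl = ifelse(f < 0, 10 * f^2, 0), rh = ifelse(f > 0, 10 * f^2, 0))
}

#' Low and high blood glucose indices
#'
#' Kovatchev's risk indices: the glucose scale is symmetrized by
#' `f(gl) = 1.509 * ((ln gl)^1.084 - 5.381)`; each reading carries a low risk
#' `rl = 10 f^2` when `f < 0` and a high risk `rh = 10 f^2` when `f > 0`
#' (never both). LBGI and HBGI are the means of `rl` and `rh`.
#'
#' @inheritParams summary_glu
#' @return Named vector / tibble with `lbgi` and `hbgi`.
#' @examples
#' bgi(rep(50, 5)) # lbgi about 22.5, hbgi 0
#' @export
bgi <- function(data) {
  dist_metric(data, function(v) {
    r <- bgi_risks(v)
    c(lbgi = mean(r$rl), hbgi = mean(r$rh))
  }, na_names = c("lbgi", "hbgi"))
}

#' Hyperglycemia index
#'
#' `HI = sum((gl - ULTR)^a) / (n * c)` over readings above the upper limit of
#' the target range.
#'
#' @inheritParams summary_glu
#' @param ULTR upper limit of target range (mg/dL).
#' @param a exponent (default 1.1).
#' @param c_scale scaling divisor (default 30).
#' @return Hyperglycemia index (unitless).
#' @export
hyper_index <- function(data, ULTR = metric_params()$ULTR, a = 1.1, c_scale = 30) {
  dist_metric(data, function(v) {
    c(hyper_index = sum(pmax(v - ULTR, 0)^a) / (length(v) * c_scale))
  }, na_names = "hyper_index")
}

#' Hypoglycemia index
#'
#' `HO = sum((LLTR - gl)^b) / (n * d)` over readings below the lower limit of
#' the target range.
#'
#' @inheritParams summary_glu
#' @param LLTR lower limit of target range (mg/dL).
#' @param b exponent (default 2).
#' @param d_scale scaling divisor (default 30).
#' @return Hypoglycemia index (unitless).
#' @export
hypo_index <- function(data, LLTR = metric_params()$LLTR, b = 2, d_scale = 30) {
  dist_metric(data, function(v) {
    c(hypo_index = sum(pmax(LLTR - v, 0)^b) / (length(v) * d_scale))
  }, na_names = "hypo_index")
}

#' Index of glycemic control
#'
#' `IGC = hyper_index + hypo_index` (same parameters as the two components).
#'
#' @inheritParams summary_glu
#' @param params a [metric_params()] object.
#' @return IGC (unitless).
#' @export
igc <- function(data, params = metric_params()) {
  dist_metric(data, function(v) {
    hi <- sum(pmax(v - params$ULTR, 0)^params$hyper_exponent) /
      (length(v) * params$hyper_scale)
    ho <- sum(pmax(params$LLTR - v, 0)^params$hypo_exponent) /
      (length(v) * params$hypo_scale)
    c(igc = hi + ho)
  }, na_names = "igc")
}

#' Continuous glucose monitoring index (COGI)
#'
#' Weighted composite `0.5 w1 + 0.35 w2 + 0.15 w3` in `[0, 100]`, where
#' `w1` is percent of time in 70-180 mg/dL, `w2 = 100 * (1 - min(TBR70, 15) / 15)`
#' rewards little time below 70, and `w3 = 100 * clamp((108 - sd) / 90, 0, 1)`
#' rewards low variability.
#'
#' @inheritParams summary_glu
#' @return COGI score in `[0, 100]`.
#' @export
cogi <- function(data) {
  dist_metric(data, function(v) {
    w1 <- 100 * mean(v >= 70 & v <= 180)
    tbr <- 100 * mean(v < 70)
    w2 <- 100 * (1 - min(tbr, 15) / 15)
    s <- if (length(v) >= 2) stats::sd(v) else 0
    w3 <- 100 * min(max((108 - s) / 90, 0), 1)
    c(cogi = 0.5 * w1 + 0.35 * w2 + 0.15 * w3)
  }, na_names = "cogi")
}

#' Mean amplitude of glycemic excursions (MAGE)
#'
#' The default (`variant = "naive"`) follows the classical 1-SD rule: with
#' `m` the mean and `s` the sample SD of all values, MAGE is the mean of
#' `|gl - m|` over readings whose deviation strictly exceeds `s`. If no
#' reading qualifies (e.g. a constant series) the result is `NA`, never 0.
#'
#' `variant = "ma_crossing"` is a moving-average-crossing heuristic: the
#' series is smoothed, excursion turning points are located between smoother
#' crossings, and amplitudes exceeding one SD are averaged. It is provided
#' for comparison and is not the default.
#'
#' @inheritParams summary_glu
#' @param variant `"naive"` (default) or `"ma_crossing"`.
#' @param short_ma,long_ma moving-average window lengths (readings) for the
#'   crossing variant.
#' @return MAGE in mg/dL, or `NA` when no excursion qualifies.
#' @examples
#' mage(c(100, 100, 100, 200)) # 75
#' @export
mage <- function(data, variant = c("naive", "ma_crossing"),
                 short_ma = 5, long_ma = 32) {
  variant <- match.arg(variant)
  dist_metric(data, function(v) {
    if (length(v) < 3) stop("need at least 3 values for MAGE")
    if (variant == "naive") {
      m <- mean(v)
      s <- stats::sd(v)
      dev <- abs(v - m)
      qualifying <- dev[dev > s]
      return(c(mage = if (length(qualifying) == 0) NA_real_
               else mean(qualifying)))
    }
    c(mage = mage_ma_crossing(v, short_ma, long_ma))
  }, na_names = "mage")
}

# Moving-average crossing variant. Crossings of a short over a long moving
# average delimit excursions; the amplitude of each excursion is the range of
# the raw values between consecutive crossings, and amplitudes exceeding the
# overall sample SD are averaged.
mage_ma_crossing <- function(v, short_ma = 5, long_ma = 32) {
  n <- length(v)
  short_ma <- min(short_ma, n)
  long_ma <- min(long_ma, n)
  if (short_ma >= long_ma) return(NA_real_)
  run_mean <- function(x, k) as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
  sm <- run_mean(v, short_ma)
  lm_ <- run_mean(v, long_ma)
  diff_ma <- sm - lm_
  ok <- which(!is.na(diff_ma))
  if (length(ok) < 2) return(NA_real_)
  sign_change <- which(diff(sign(diff_ma[ok])) != 0)
  crossings <- ok[sign_change]
  bounds <- unique(c(1, crossings, n))
  if (length(bounds) < 3) return(NA_real_)
  amps <- vapply(seq_len(length(bounds) - 1), function(i) {
    seg <- v[bounds[i]:bounds[i + 1]]
    max(seg) - min(seg)
  }, 0)
  s <- stats::sd(v)
  qualifying <- amps[amps > s]
  if (length(qualifying) == 0) NA_real_ else mean(qualifying)
}
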