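---
title: "Methods: CGM metrics, gridding and design choices in gluvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CGM metrics, gridding and design choices in gluvar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gluvar)
```

gluvar computes glucose-control and glucose-variability metrics from
continuous glucose monitor (CGM) traces. This vignette records the model
behind each computation, the conventions we fixed where the field's
literature leaves room, and what the test suite's synthetic data does and
does not establish about behaviour on real data.

## Data model and validation

The input contract is a long-format table of readings `(id, time, gl)` with
glucose in mg/dL. Validation (`as_cgm_table()`) makes three deliberate
choices that the CGM literature does not standardise:

* **Non-positive or non-finite glucose is dropped, not an error.** Sensor
  artifacts (zeros, negative calibration transients) are common; dropping
  with a per-table count in the validation report keeps the pipeline
  auditable without crashing batch runs. A file with *no* valid rows is a
  hard error.
* **Duplicate `(id, time)` pairs keep the first occurrence.** Deterministic
  and stable under re-ordering of the remaining rows.
* **Timestamps are naive local clock times**, parsed in a user-supplied
  timezone (default UTC) with day boundaries at local midnight. CGM exports
  rarely carry zone information; fixing "a day is the local calendar day"
  makes the day-by-day grid and ADRR's day grouping well defined. We do not
  model daylight-saving discontinuities; traces spanning a DST change in a
  non-UTC zone will have one 23- or 25-hour "day".

mg/dL is the canonical internal unit. `convert_units()` uses the divisor
18.0 exactly (not the molar-mass value 18.016), matching the `g/18`
rescaling inside the GRADE transform so the two cannot disagree.

## The day-by-day grid

Metrics that compare readings a fixed lag apart (CONGA, MODD, MAG, rate of
change, the SD/CV decompositions) need evenly spaced values, but real
sensors drift, jitter and drop out. `day_by_day()` projects a subject's
readings onto an equidistant grid:

* **Grid period `dt0`** defaults to the rounded median of successive time
  differences, snapped to the nearest divisor of 1440 so a whole number of
  slots fits a day. The median is robust to occasional long gaps; a
  5-minute sensor with a 40-minute dropout still grids at 5 minutes.
* **Column convention**: column `j` (1-based) represents time-of-day
  `j * dt0` minutes after local midnight, so a 5-minute grid has
  `(24*60)/5 = 288` columns and the last column of each day falls on the
  following midnight. A fixed convention is required for MODD and the
  between-day SDs to align columns across days; other software may index
  from offset 0, shifting everything by one column, which is why
  cross-package comparisons of grid-based metrics can differ slightly.
* **Gap-aware linear interpolation**: a grid point is filled only when its
  two bracketing observations are at most `inter_gap` minutes apart
  (default 45; a gap of exactly 45 minutes *is* interpolated — the boundary
  had to be fixed one way and `<=` is the testable choice we document).
  Wider gaps yield missing cells. No extrapolation occurs before the first
  or after the last observation, so the grid never invents data at the
  edges of wear.

`active_percent()` quantifies sufficiency as observed distinct grid slots
over expected slots `floor(span/dt0) + 1`, with the span taken between the
actual first and last reading (not whole days) so the reported `ndays` is
fractional, matching how wear time is reported in practice.

## Metric definitions and parameter defaults

Defaults live in one validated object, `metric_params()`. The ones that
matter most, with units:

| parameter | default | role |
|---|---|---|
| `targets_above` | 140, 180, 250 mg/dL | `percent_above` thresholds |
| `targets_below` | 54, 70 mg/dL | `percent_below` thresholds |
| `ranges_in` | [70,180], [63,140] mg/dL | inclusive time-in-range bands |
| `ULTR` / `LLTR` | 140 / 80 mg/dL | hyper/hypo index limits |
| `conga_n` | 1 h | CONGA lag |
| `mag_n` | 60 min | MAG sampling interval |
| `roc_timelag` | 15 min | rate-of-change lag |
| `inter_gap` | 45 min | interpolation gap limit |
| `mvalue_ref` | 90 mg/dL | M-value reference |
| `agp_cutoffs` | 54/70/180/250 mg/dL | AGP bands |

Conventions worth calling out:

* **Strict above/below, inclusive in-range.** With both conventions fixed,
  `percent_above(t) + percent_below(t) + percent(gl == t) = 100` exactly —
  a partition identity the tests enforce. Published CGM software does not
  state its boundary behaviour; ours is chosen so the identity holds.
* **Sample SD (n−1) everywhere**, and type-7 quantiles (linear
  interpolation of order statistics, R's default), so our summary
  statistics agree with the values other R-based CGM software prints.
* **GRADE domain**: the double logarithm is undefined for glucose ≤ 18
  mg/dL. Such values are physiologically impossible but can arise in
  synthetic edge cases; we clamp to 18 + 1e−6 with a warning rather than
  error. The per-reading contribution is capped at 50; note the cap engages
  only around 620 mg/dL (h(600) ≈ 49.9).
* **Hypoglycemia index lower limit** defaults to 80 mg/dL following the
  original index's published scheme; software conventions differ, so the
  limit is an exposed parameter rather than a constant.
* **MAGE** defaults to the classical naive rule — mean absolute deviation
  of readings deviating more than one SD from the mean — which is exactly
  reproducible and matches the era of the metric's definition. A
  moving-average-crossing variant (`variant = "ma_crossing"`) is provided
  for users who want excursion-based behaviour, but it is a heuristic
  (smoother windows 5/32 readings) and not the default.
* **Missing-markers, never zero.** A metric whose qualifying set is empty
  (MAGE on a constant series, CONGA with no complete lagged pair, CVsd with
  one usable day) returns `NA`. Zero is always a *valid* metric value, so
  ambiguity between "no information" and "no variability" must stay
  visible. In `all_metrics()` a per-subject failure becomes `NA` in that
  cell plus a warning, so one bad subject cannot sink a cohort run.

## Temporal metrics: missing data and day boundaries

All grid-based metrics use **pairwise deletion**: a lagged difference, a
24-hour pair, a column SD or an hourly block enters the computation only if
every cell it touches is observed; rows, columns or blocks with fewer than
two values are skipped. This is explicit and testable, at the cost of
weighting days unevenly when missingness is uneven.

CONGA concatenates the day rows into one series before lagging, so pairs
may span midnight. Published CONGA values are known to disagree across
software because of exactly these interpolation and missing-data choices;
we therefore treat cross-software CONGA agreement as approximate, not
exact. SdWSH uses consecutive *non-overlapping* 1-hour blocks (`60/dt0`
cells) rather than a rolling window — the simplest reproducible reading of
"short-term within-series variability"; a rolling implementation would give
slightly smoother values.

ADRR and GVP deliberately work on the raw timed readings, not the grid:
ADRR needs per-calendar-day extremes of the Kovatchev risks, and GVP's arc
length is defined by actual consecutive samples. GVP excludes segments
whose time step exceeds `inter_gap`, since a single multi-hour gap would
otherwise dominate the flat-line baseline `L0`.

## AGP and visualisations

The AGP band rule places values exactly at 54, 70, 180, 250 mg/dL into the
bands 54–69, 70–180, 70–180 and 181–250 respectively (the consensus
convention); the five band percentages always sum to 100. Quantile ribbons
(5/25/50/75/95%) are computed per grid column across days,
pairwise-complete, so days with missing stretches still contribute where
observed.

Lasagna plots map glucose to colour with a gradient centred at `midpoint`
(default 105 mg/dL) and clipped to `limits` (default [50, 500] mg/dL,
values outside clamped with a warning). The blue-red scheme is a
blue-white-red diverging gradient — monotone in glucose, which the tests
verify channel-wise. The red-orange scheme is a documented 4-anchor
gradient (red → green → yellow → orange with green at the midpoint); pixel
parity with any other package's palette is out of scope. Sorting modes
operate on the rendered matrix (descending within column for `timesorted`,
within row for `subjectsorted`) and are tested on the matrix itself rather
than on pixels. Rendering is deterministic: no plot uses randomness.

## The synthetic generator

`simulate_cgm()` emulates the structure CGM analytics must survive:
multi-day wear at a nominal sensor period, per-reading timestamp jitter
(clock misalignment across subjects), independent dropout plus contiguous
gap blocks (warm-ups, detachments), a diurnal sinusoid, meal pulses with
exponential decay, and AR(1) sensor noise floored at 40 mg/dL. AR(1) noise
(rather than white) is essential: white noise makes rate-of-change and
CONGA-type metrics degenerate into pure sampling-period artifacts, whereas
autocorrelated noise gives them realistic temporal structure. The floor at
40 mg/dL keeps the GRADE and risk transforms in-domain while still
exercising the hypoglycemia bands.

`make_phenotype_panel()` fixes a 5-subject, 14-day, 5-minute panel
contrasting phenotypes: Subject 2 has sustained hyperglycemia (baseline
220 mg/dL, low noise), Subject 5 the highest variability (AR SD 45 mg/dL,
diurnal amplitude 40, large meals), Subjects 1/3/4 intermediate profiles
(baselines 115–150, AR SD 12–18). These parameters were chosen once, as
plausible type-II-diabetes-like contrasts, and the tests then verify the
implied orderings (Subject 2 maximises hyper_index and above_180, Subject 5
maximises sd_roc and SdW).

What the generator does **not** emulate: sensor calibration drift and error
models, glucose–insulin physiology, day/night behavioural asymmetry beyond
a single sinusoid, or vendor export quirks. Passing tests on this synthetic
data therefore establish the *mathematics* of the metrics (definitions,
identities, missing-data handling) — they do not validate clinical
interpretation on any particular sensor's data.

## Numerical choices

* Oracle-equivalence tests compare every grid metric against independent
  brute-force loop implementations on ~1000 random small grids (2–5 days ×
  24–48 slots, up to 30% missing) at tolerance 1e−9.
* Grid interpolation matches observations exactly when a reading falls on a
  grid slot (timestamp equality at 1-second resolution), and reproduces
  affine signals to 1e−9 relative.
* Test and acceptance problem sizes — 14-day 5-minute panels (~4000
  readings/subject), 180 simulated days for noise-recovery — were chosen so
  the full suite runs in well under a minute while keeping Monte-Carlo
  checks comfortably powered.
* `sim_config()$seed` fixes the entire stream; two runs with one config are
  byte-identical.

## Known limitations

* No excursion counting and no day/night metric splits; both are natural
  extensions of the grid layer.
* CONGA values should not be expected to match other software to printed
  precision (interpolation-scheme sensitivity, above).
* The M-value is computed without the (rarely used) amplitude correction
  term of its original definition.
* The CLI reads pre-formatted CSV only; vendor export formats (Dexcom,
  Libre raw files) must be converted upstream.
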