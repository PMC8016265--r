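# gluvar

Glucose control and glucose variability analytics for continuous glucose
monitor (CGM) data.

CGM sensors record interstitial glucose every few minutes for days to weeks.
Clinicians and researchers summarise those traces with a large catalogue of
metrics — some computable straight from the pooled readings (time in range,
GMI, J-index, LBGI/HBGI, MAGE, ...), others requiring the readings to be
projected first onto an equidistant time grid so that values a fixed lag or
exactly 24 h apart can be compared (CONGA, MODD, MAG, rate of change,
Rodbard's SD decomposition). gluvar implements the full catalogue, the
gridding step, ambulatory glucose profile (AGP) summaries and reports,
lasagna/time-series/rate-of-change visualisations, a synthetic CGM generator
for testing, and a command-line front end. It is aimed at biostatisticians
and clinical researchers who receive CGM exports as long-format CSV.

## Data contract

A data frame (or CSV) with three columns:

| column | meaning                                  |
|--------|------------------------------------------|
| `id`   | subject identifier                       |
| `time` | timestamp (`YYYY-MM-DD HH:MM:SS` or ISO) |
| `gl`   | glucose in mg/dL                         |

All metrics assume mg/dL internally; `convert_units()` (divisor 18.0)
handles mmol/L at the I/O edge.

## The core quantities

With glucose readings g_1..g_n (mg/dL):

- **Time in/above/below range**: percentages of readings in [lo, hi]
  (inclusive), above t or below t (strict), defaults 70–180 / 63–140,
  140/180/250 above, 54/70 below.
- **GMI** = 3.31 + 0.02392·mean(g); **eA1c** = (mean(g) + 46.7)/28.7.
- **J-index** = 0.001·(mean + SD)²; **M-value** = mean(|10·log10(g/90)|³).
- **GRADE**: mean of h(g) = 425·(log10(log10(g/18)) + 0.16)², capped at 50,
  with eu-/hypo-/hyperglycemia attribution percentages.
- **LBGI/HBGI**: f(g) = 1.509·((ln g)^1.084 − 5.381); LBGI = mean(10 f² ;
  f<0), HBGI = mean(10 f² ; f>0). **ADRR** averages the per-day maxima of
  the two risks.
- **Hyper/hypo indices**: Σ(g−140)^1.1/(30 n) and Σ(80−g)²/(30 n); their sum
  is **IGC**. **COGI** = 0.5·TIR + 0.35·(TBR reward) + 0.15·(SD reward).
- **MAGE** (naive): mean |g − mean| over readings deviating more than one SD.
- **Grid metrics**, computed on the day-by-day matrix built by
  `day_by_day()` (rows = days, columns = times of day every `dt0` minutes,
  linear interpolation only across gaps ≤ 45 min): **CONGA(n)** = SD of
  differences n hours apart; **MODD** = mean |difference 24 h apart|;
  **MAG** = Σ|Δg| per hour; **AUC** = hourly-average trapezoidal area;
  **ROC/sd_roc** = lagged differences per minute and their SD; the six
  Rodbard SD subtypes (SdW, SdHHMM, SdWSH, SdDM, SdB, SdBDM) and the daily
  CV summaries (CVmean, CVsd).

## Worked example

```r
library(gluvar)

panel <- make_phenotype_panel(seed = 42)  # 5 simulated subjects, 14 days, 5-min sensor
hyper_index(panel)
#> # A tibble: 5 × 2
#>   id        hyper_index
#>   <fct>           <dbl>
#> 1 Subject 1      0.0853
#> 2 Subject 2      4.31
#> 3 Subject 3      0.997
#> 4 Subject 4      0.173
#> 5 Subject 5      1.95

sd_roc(panel)
#> # A tibble: 5 × 2
#>   id        sd_roc
#>   <fct>      <dbl>
#> 1 Subject 1  0.995
#> 2 Subject 2  0.786
#> 3 Subject 3  1.45
#> 4 Subject 4  0.966
#> 5 Subject 5  3.44
```

Subject 2 is engineered with sustained hyperglycemia (baseline 220 mg/dL)
and dominates the hyperglycemia index — it spends the most time above the
140 mg/dL upper target. Subject 5 is engineered with the largest
variability and dominates the SD of the rate of change (mg/dL per minute):
its glucose swings fastest, independently of its average level.

```r
all_metrics(panel)          # subjects x ~50 metric columns
g <- day_by_day(panel[panel$id == "Subject 1", ])
dim(g$gd2d)                 # days x 288 slots at dt0 = 5 min
agp_report(panel[panel$id == "Subject 1", ], out_dir = "agp/")  # PNG + HTML + JSON
```

From a shell:

```sh
Rscript inst/cli/cgm-tools.R metrics --input data.csv --output metrics.csv
Rscript inst/cli/cgm-tools.R agp --input data.csv --subject "Subject 1" --outdir report/
Rscript inst/cli/cgm-tools.R simulate --config cfg.json --output sim.csv
```

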