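# actipat

Physical-activity-pattern analysis for epoch-labelled accelerometry from
nursing-home residents, for researchers in geriatric epidemiology and
physical-behaviour measurement.

Institutionalised older adults spend almost their entire day sitting or
lying, and what little activity remains is fragmented into short bouts. The
questions this package operationalises are *how* that time is structured —
minutes per activity over the full 24 h, bout-duration histograms,
sedentary-to-active posture transitions — and whether those patterns are
associated with neuropsychiatric symptoms (NPI-NH subsyndromes) and physical
function (SPPB) across cognitive-impairment and dementia-severity groups.

## What it computes

From per-epoch activity labels (one of `walking`, `standing`, `sitting`,
`lying` per 60-s epoch; `cycling`/`running` are remapped to walking on
ingest), per participant:

* **Time-use** — mean min/day per activity over complete 24-h windows
  (always summing to 1440), and the sedentary share
  `100·(sitting + lying)/1440`.
* **Bouts** — maximal runs of one activity, binned half-open at
  1–2/2–3/3–10/10–30/>30 min (walking, standing) and
  1–5/5–10/10–30/30–60/>60 min (sitting, lying), as mean daily counts.
* **Transitions** — daily mean count of the adjacent-epoch pairs
  lying→standing, lying→walking, sitting→standing, sitting→walking.

Clinical scoring (NPI-NH subsyndromes agitation/psychosis/affective/apathy,
SPPB totals with attempted-but-failed sub-tests scored 0, CDR sum-of-boxes
severity staging), tie-corrected Kruskal–Wallis + Dunn group comparison, and
gamma/log-link GLMs,

```
log E[activity metric] = β0 + β·(NPI subsyndromes, SPPB, severity ordinal),
```

with Pearson dispersion, Wald inference and percent-change readings
`100·(exp(β) − 1)`, complete the pipeline. A semi-Markov synthetic-cohort
generator with analytic calibration and a known-truth ledger makes every
stage testable without access to restricted cohort data.

## Worked example

Simulate a 163-resident cohort (severity groups 25/73/47/18, two wear days),
screen wear time, summarise patterns, and fit the association models:

```r
library(actipat)
library(dplyr)

coh       <- simulate_cohort(default_cohort_config(wear_days = 2, seed = 42))
segments  <- find_valid_segments(coh$epochs, quiet = TRUE)
summaries <- summarize_cohort(segments)

summaries |>
  select(participant_id, minutes_walking, minutes_sitting,
         pct_sedentary, transitions_daily)
#> # A tibble: 163 × 5
#>   participant_id minutes_walking minutes_sitting pct_sedentary transitions_daily
#>   <chr>                    <dbl>           <dbl>         <dbl>             <dbl>
#> 1 p0001                     10              730.          97.7               8.5
#> 2 p0002                     21              754           96.7              28.5
#> 3 p0003                     15.5            563           97.4              15.5
#> 4 p0004                     16              382.          96.9               5
#> # ℹ 159 more rows

mean(summaries$pct_sedentary)   # 94.2 — the cohort is ~94% sedentary
```

Each row is one resident's daily means: p0001 walks 10 min/day and moves
from sitting/lying to standing/walking 8.5 times a day. Group comparison and
the association suite:

```r
clinical <- score_clinical(coh$clinical)

kruskal_wallis(summaries$transitions_daily[match(clinical$participant_id,
                                                 summaries$participant_id)],
               clinical$severity)
#> Kruskal-Wallis (tie-corrected): H = 22.36, df = 3, p = 5.502e-05 (n = 163)

suite <- run_association_suite(summaries, clinical)
tidy(suite) |> filter(outcome == "minutes_walking") |>
  select(term, estimate, std.error, p.value, pct_change)
#> # A tibble: 6 × 5
#>   term          estimate std.error  p.value pct_change
#>   <chr>            <dbl>     <dbl>    <dbl>      <dbl>
#> 1 nps_agitation  0.0339     0.0105 1.26e- 3      3.44
#> 2 nps_psychosis  0.0112     0.0165 4.96e- 1      1.13
#> 3 nps_affective -0.0179     0.0122 1.41e- 1     -1.77
#> 4 nps_apathy     0.00673    0.0217 7.56e- 1      0.675
#> 5 sppb_total     0.0244     0.0197 2.16e- 1      2.47
#> 6 severity_code -0.447      0.0608 1.99e-13    -36.1
```

The transitions differ strongly across severity groups (H = 22.4), and in
this simulated cohort each severity step is associated with a 36% lower
expected daily walking time (`exp(-0.447) ≈ 0.64`); the generator implants
group-level activity differences, so the severity ordinal — which indexes
the groups — is the predictor that picks them up. `autoplot(suite)` draws
the coefficient forest; `plot_time_use()` and `plot_bout_histogram()` cover
the descriptive side. Real data enter the same pipeline through
`read_epoch_csv()` and `read_clinical_csv()`.

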