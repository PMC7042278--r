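# floodring

Dendroecology of flood-pulse forests: tree-ring cross-dating, chronology
building, climate–growth correlation, sigmoidal age–diameter growth
modelling, population age-structure reconstruction, and flood-duration
estimation — as one tested, reproducible R pipeline.

## The scientific problem

Monodominant stands of flood-tolerant trees on tropical floodplains (the
motivating system is an *Erythrina fusca* stand on the upper Paraguay
River) record their environment in annual growth rings. From dated
ring-width series, a monthly climate record and a daily river-gauge
record, a dendroecological study answers three questions:

1. **Does the stand share a common, climate-driven growth signal?**
   Series are cross-dated pairwise with the *Gleichläufigkeit*
   (percentage of parallel run)

   `GLK = 100 · mean(score of year-to-year sign agreement)`

   and the Baillie–Pilcher *t* value, `t = r √((n−2)/(1−r²))`, with *r*
   the Pearson correlation of the two 5-year-moving-average-indexed,
   log-transformed segments. Admitted series are indexed
   (`index_i = width_i / MA5_i`), averaged into a master chronology, and
   summarised by the mean sensitivity
   `MS = mean(|2(x_i − x_{i−1})/(x_i + x_{i−1})|)` (MS > 0.40 is
   conventionally "high"). The chronology is then screened against
   monthly climate — precipitation, Niño 1+2/3/3.4/4 SST anomalies, SOI,
   PDO, river level — over a 24-month window from October of the
   previous year, with per-cell significance at the two-sided critical
   correlation `r_crit = t_crit/√(n−2+t_crit²)`.

2. **How old is the population?** Cumulative diameter curves of the
   ring-width sample, rescaled to field DBH, are fitted to the sigmoidal
   model

   `DBH = β₀ / (1 + (β₁/age)^β₂)`

   whose closed-form inverse `age = β₁/(β₀/DBH − 1)^(1/β₂)` converts
   every inventoried DBH (DBH = CBH/π, inclusion at CBH ≥ 15 cm) into an
   age. Diameter classes follow Sturges' rule `K = round(1 + 3.3 log₁₀ N)`
   with constant width `(max−min)/K`.

3. **Does the flood regime shape recruitment?** Plot water marks plus
   the gauge record give per-plot flood durations (days/yr above the
   plot's elevation, averaged over ten years); plots split into two
   categories at the midpoint of the flood gradient; a category × class
   chi-square tests for differential recruitment, one-way ANOVA + Tukey
   compares the environmental history of the young age classes, and
   Welch's *t* compares annual gauge minima before/after a breakpoint.

Because studies of this kind rarely release their field data, the
package ships a first-class synthetic-data generator (`sim_config()`,
`simulate_study()`) with planted ground truth — a known growth curve, a
positive December(-1) precipitation effect, a negative ENSO effect, a
monomodal flood pulse, and a recruitment deficit confined to the
shorter-flooded plots — so every stage can be validated by recovery of
known signals.

## Worked example

```r
library(floodring)
report <- run_study(sim_config(), seed = 42)
print(report)
```

```
Synthetic dendroecological study report
  chronology 1981-2014 from 19/36 admitted series
  mean sensitivity 0.321 (chronology), 0.411 (series mean, high); MDI 14.99 mm/yr
  21 significant climate cells of 192 screened
  growth fit b0 = 77.3 cm, b1 = 23.2 yr, b2 = 1.40 (r2 = 0.999)
  increment peak 2.05 cm/yr at 6.5 yr
  flood classes chi2 = 18.86 (df 7, p = 0.0086)
  annual-minima decline p = 0.0000
```

Reading the output: 19 of the 36 simulated series passed the
leave-one-out cross-dating screen (GLK ≥ 60, t ≥ 2.0) and built a
34-year chronology whose series-mean sensitivity (0.411) is "high",
i.e. the stand is climate-sensitive. The correlation screen finds the
planted signals — e.g. the December(-1) precipitation cell is positive
and significant, the Niño cells around the austral summer are negative
and significant — while river level stays non-significant, as planted.
The sigmoidal fit to the mean diameter growth curve and its analytic
derivative place the fastest diameter growth near age 7; the
category × class chi-square detects the planted recruitment deficit in
the shorter-flooded plots, and the Welch test detects the planted
decline in annual gauge minima.

Individual stages are plain functions on plain objects — `read_rwl()`,
`glk()`, `t_value_bp()`, `crossdate_set()`, `index_series()`,
`build_chronology()`, `monthly_correlations()`, `fit_sigmoidal()`
(a classed model object with `coef`/`predict`/`plot`/`summary`
methods), `age_from_dbh()`, `make_classes()`, `flood_days()`,
`split_categories()`, `flood_class_chisq()`, `climate_by_age_class()`,
`annual_min_trend_test()` — so any subset of the pipeline can be run on
real data read from Tucson/RWL archives and long-form CSV tables.

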