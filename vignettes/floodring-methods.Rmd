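---
title: "Methods: dendroecology of a flood-pulse forest stand"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dendroecology of a flood-pulse forest stand}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floodring)
```

## Scope and design

`floodring` implements the analysis chain of a dendroecological study
of a monodominant, flood-tolerant tropical tree stand: cross-dating of
ring-width series, chronology construction, climate–growth correlation,
sigmoidal age–diameter modelling with age inversion, diameter/age class
structure, and flood-duration estimation from a river gauge. Because
field data of this kind are typically unreleased, the package pairs the
analysis chain with a synthetic-data generator whose defaults define a
complete study with known ground truth; the validation suite then
demands that each stage recovers what was planted.

This vignette documents the models, the defaults and why they were
chosen, the numerical choices, and the limits of what the synthetic
validation shows.

## Cross-dating statistics

**Gleichläufigkeit.** Over the *n*−1 year-to-year intervals of the
aligned overlap, an interval scores 1 when both series move the same
way (both up, both down, or both unchanged), 0 when they oppose, and ½
when exactly one is unchanged — the classical sign-agreement convention
for ties. GLK is 100 × the mean score. The ½ tie rule matters for
measurement data quantised at 0.01 mm, where exact repeats occur.

**Baillie–Pilcher t.** Each segment is first indexed by its centred
5-year moving average and log-transformed, then `t = r√((n−2)/(1−r²))`
from the Pearson *r* of the transformed segments. Perfect correlation
is capped at t = 100 rather than returned as infinity. The classical
moving-average/log pre-transform is adopted because "a t value" in
dendrochronological usage refers to this statistic unless another
detrending is named.

**Admission.** `crossdate_set()` scores each series at lag 0 against
the mean raw-width curve of the others (leave-one-out) and iteratively
drops the single worst series failing GLK ≥ 60 or t ≥ 2.0 until all
pass. The thresholds are the conventional working values; site studies
rarely publish their cut-offs, so they are explicit configuration
rather than inferred. Leave-one-out iteration (not all-pairs clique
search) keeps the procedure deterministic and O(rounds × n). Ties on
the drop choice resolve by lowest t, then input order. Lag search in
`best_lag()` ranks by GLK with t as tie-break and prefers the smaller
absolute lag (positive before negative) so that noiseless cases have a
unique, symmetric answer.

## Chronology

Indices are `width / MA5`, the centred 5-year moving-average ratio. At
the series edges the window clips to the available years (3- and 4-term
means); a `truncate` option blanks the two edge years instead, for
users who prefer not to index against asymmetric windows. The
chronology is the unweighted per-year arithmetic mean of available
indices with sample depth recorded; Tukey's biweight mean (c = 9) is
available but off by default, since the plain average is what "mean
chronology" denotes and the index distributions here are not
heavy-tailed.

Mean sensitivity `MS = mean(|2Δx/(x_i + x_{i−1})|)` lies in [0, 2) for
positive series and is scale-free. The package reports it both for the
chronology index and as the mean over the admitted raw series; the
series-level mean is the quantity usually quoted, and values above
0.40 are flagged "high". Averaging across trees removes uncorrelated
variance, so the chronology-level MS is systematically lower than the
series-level mean.

## Climate–growth screen

A ring is labelled by the calendar year in which its growth season
starts (season onset October; the wood layer itself forms around
December–January). Ring year *t* is screened against each climate
variable in each month from October(*t*−1) through September(*t*+1) —
24 cells per variable. Significance per cell is the two-sided critical
correlation `r_crit = t_crit/√(n−2+t_crit²)` at α = 0.05 (≈ 0.339 at
n = 34). No multiple-testing correction is applied: this mirrors the
dashed-line convention of correlation-function plots in this
literature and is a knowingly liberal choice — with 8 variables × 24
cells, about 10 null cells will cross the line by chance, so isolated
hits off the planted season deserve no interpretation. The screen is
plain Pearson correlation, not a bootstrapped response function; the
false-positive behaviour of the plain screen is itself verified in the
test suite (≈ 5% per cell under the null).

## Growth model

The cumulative diameter of a dated series is twice the running sum of
radial widths, proportionally rescaled so its final value equals the
field DBH. The rescale is multiplicative, not additive: bark and
off-centre bias inflate the field measurement roughly in proportion to
size, and a multiplicative correction preserves the relative shape of
the curve.

The age–diameter model `DBH = β₀/(1+(β₁/age)^β₂)` is fitted by
Levenberg–Marquardt least squares (`minpack.lm::nlsLM`, positivity
bounds at 10⁻⁸, up to 200 iterations) to the per-age mean diameter
curve by default — fitting the mean curve is the convention this
analysis follows; pooled-point fitting is available
(`average = FALSE`) and both r² flavours are always reported, since the
mean-curve r² is substantially higher by construction and the two are
often conflated. Initialisation: β₀ at 1.2 × max DBH, β₁ at the age
whose mean DBH is nearest half of that, β₂ = 1.

The inverse `age = β₁/(β₀/DBH − 1)^(1/β₂)` is exact for
0 < DBH < β₀. Inventory trees at or above the fitted asymptote are
flagged and assigned the age of the largest invertible DBH rather than
dropped, so class counts stay complete. The annual increment maximum is
located by evaluating the analytic derivative on a 0.01-yr grid (first
grid index wins ties, so the answer is deterministic); for β₂ ≤ 1 the
increment is monotone decreasing and the boundary result is flagged.

The diameter–height relation uses the saturating hyperbola
`H = a·DBH/(b + DBH)`. The source analysis names only "a non-linear
regression" for this step, so the functional form is an explicit
package choice, swappable via the `formula` argument. Starting values
come from the linearisation `1/H = 1/a + (b/a)(1/DBH)`, which makes the
fit converge immediately on clean data and avoids singular-gradient
starts.

**Known limitation — asymptote extrapolation.** A ring-width sample of
young trees (ages ≤ ~34) barely constrains β₀; fitted asymptotes can
exceed the true one by 50% or more with near-perfect r², and inverted
ages of large inventory trees are then underestimated. This is a
property of the method, not of the implementation: the parameter
recovery tests use age ranges spanning well past β₁, where all three
parameters are identified.

## Population structure

Diameter classes use Sturges' count K = 1 + 3.3 log₁₀N, rounded half
up (the analysis this follows reports integer class counts and no
rounding rule; half-up is the package's documented choice, and K can be
forced). Class width is (max−min)/K from the minimum; intervals are
half-open except the last, which closes at the maximum so the partition
conserves N exactly.

The category × class chi-square is Pearson's statistic without
continuity correction. Classes with expected counts below 1 are pooled
into their lower neighbour, from the sparse top end downwards, before
testing — the upper tail of a diameter distribution is always sparse
and would otherwise invalidate the asymptotic reference distribution.

For the environmental comparison across young classes, establishment
spans come from inverting the class DBH boundaries to ages (survey year
minus age bounds, rounded inwards). Classes qualify while they hold
more than five individuals, up to the first five classes — larger
classes thin out for demographic reasons (mortality, breakage) and
would confound an environmental signal. Per establishment year the
package collects the annual gauge maximum, the annual gauge minimum,
and total precipitation; each variable is compared across classes by
one-way ANOVA, with Tukey HSD and compact letter display at 5% when the
ANOVA rejects.

## Flooding

Plot elevation on the gauge datum is `annual gauge maximum − water
mark`, resting on the flat-terrain assumption that the water surface at
the plots tracks the gauge (no tributaries between gauge and site).
Flood duration is the mean over a ten-year window of days with gauge
level above the plot elevation. Gauge gaps of up to five days are
linearly interpolated; longer gaps are excluded from the denominator
and the year's count is rescaled to a full year, with the handling
logged. Gauge datum units are configurable, cm by default. The
two-category split halves the gradient [min, max] at its midpoint;
boundary plots go to the shorter-flooded category. The before/after
comparison of annual minima is Welch's two-sample t-test — the source
analysis reports only a significance statement without naming a test,
and Welch's is the default-safe choice under unequal variances.

## The synthetic study: what is planted and why

The generator's defaults are the study conditions, not tuning knobs:

* **Design scale:** 34 ring years (1981–2014), 36 ring-width trees (7
  discs, 29 cores), 153 inventory trees in 24 plots of 50 × 5 m
  (0.6 ha), survey in 2015, ages 6–34 in the ring sample and 4–54 in
  the population.
* **Growth truth:** β₀ = 84 cm, β₁ = 33.5 yr, β₂ = 1.3. These were
  solved once, in closed form, so that the increment peak
  (`u = (β₂+1)/(β₂−1)`, `a* = β₁u^(−1/β₂)`) sits at ≈ 7 yr and
  ≈ 1.6 cm/yr — the fast-pioneer pattern of the motivating stand.
* **Climate:** one latent monthly AR(1) ENSO state (φ = 0.9, unit
  variance) projected onto the four Niño indices (loadings
  0.95/0.95/0.90/0.85), SOI as its negative correlate, PDO an
  independent slow AR(1); precipitation as a Pantanal-like seasonal
  profile (~1240 mm/yr, wet November–March) × lognormal noise ×
  `max(1 − 0.1·max(latent, 0), 0.05)`, so warm events are dry.
* **Ring response:** expected width = growth-model increment ×
  `exp(0.12·z[precip Dec(−1)] − 0.15·z[ENSO Dec(−1)–Feb] + 0·z[flood])`
  × shared stand AR(1) noise (sd 0.15) × per-tree lognormal noise
  (sd 0.30). The flood coefficient is zero by design: the motivating
  system shows no direct flood–growth correlation. The effect sizes
  place the chronology-level correlations near r ≈ 0.5, i.e. ≈ 80%
  power at n = 34 against r_crit ≈ 0.34 by the Fisher-z calculation —
  a realistic, not cartoonish, signal; the shared stand noise exists
  precisely so that per-tree averaging cannot push power to 1. A side
  effect is that roughly half to two thirds of the 36 series pass the
  default admission thresholds in any one realisation, which is
  ordinary attrition for noisy tropical material.
* **Flood pulse:** daily sinusoid (base 250 cm, amplitude 150 cm, peak
  mid-March) with lognormal annual amplitude variation (sd 0.05) and
  daily AR(1) noise (sd 8 cm); the final nine years have their
  dry-season trough lowered by 40 cm, leaving peaks unchanged. Plot
  elevations are spaced across the band whose closed-form
  days-above-threshold (`365.25·acos((e−base)/amp)/π`) spans 42–117
  days/yr.
* **Population:** lognormal recruitment-age profile (meanlog log 13,
  sdlog 0.70), longer-flooded plots 1.5 × denser (≈ 62/91 category
  split), DBH = growth curve × lognormal noise (sd 0.10) truncated at
  the CBH 15 cm threshold, heights from `H = 28·DBH/(15+DBH)` ± 1.5 m.
  Recruitment in the final nine years is multiplied by 0 in the
  shorter-flooded plots. The age profile and deficit factor were fixed
  by a one-off design power calculation (500-replicate simulation at
  the design stage) giving ≈ 85% detection for the category × class
  chi-square at α = 0.05 and ≈ 5% rejection with the deficit disabled;
  they were then frozen.

**What passing tests do and do not show.** The generator shares the
analysis chain's own modelling assumptions: multiplicative lognormal
noise, an exactly sigmoidal growth law, a stationary AR(1) ENSO, no
missing or false rings, no dating error, and plots that truly obey the
flat-terrain gauge assumption. Recovery of planted signals therefore
validates the implementation and the statistical power of the design —
it does not validate those assumptions against real wood, which can
carry wedging rings, non-stationary climate response, and
size-dependent measurement error that this generator deliberately does
not emulate.

## Numerical choices and degenerate inputs

* Ring widths are rounded to 0.01 mm on simulation and floored at
  0.01 mm (bench resolution); RWL output is the 0.01 mm dialect with
  sentinel 999, both dialects accepted on read.
* `t_value_bp` errors on zero-variance transformed segments and caps
  |t| at 100; `glk` requires overlap ≥ 2; lag search requires overlap
  ≥ max(min_overlap, 5) so the moving-average transform is defined.
* `fit_sigmoidal` refuses fewer than 3 distinct ages and
  constant-DBH input; non-convergence propagates as an error carrying
  the optimiser message.
* Degenerate chi-square tables (all cells equal) return statistic 0,
  p = 1 without invoking the asymptotic machinery.
* `split_categories` errors when all plots flood equally (no gradient
  to halve); `annual_min_trend_test` requires ≥ 3 years per side and
  errors on zero variance in both periods.
* Problem sizes in the validation suite — 1000-instance oracle sweeps,
  100 noisy fit replicates at 200 points, 1000-replicate null screens,
  500-replicate power checks — were chosen so the whole suite completes
  in about a minute on one CPU while keeping Monte-Carlo error well
  inside the asserted bands.

## Reproducibility

Every generator consumes the R RNG; `simulate_study()` and
`run_study()` seed it once from their `seed` argument, so a seed fixes
the entire study bit for bit. `scripts/acceptance.R --seed N --out f`
re-runs the default study and writes the main computed quantities as
JSON.
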