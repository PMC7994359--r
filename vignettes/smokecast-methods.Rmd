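---
title: "Methods: blended smoke forecasts and syndromic count forecasting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: blended smoke forecasts and syndromic count forecasting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smokecast)
```

`smokecast` forecasts two quantities per administrative health area
each morning: the 24-h mean PM2.5 concentration for today (day 0) and
tomorrow (day +1), and the daily count of reliever-inhaler
dispensations — a timely, high-volume proxy for population respiratory
stress — over the same two days. This vignette documents the models,
their assumptions, the tunable parameters, the synthetic world used to
exercise them, and the numerical design decisions.

## Exposure geography

All geometry is planar, in kilometres, with Euclidean distances.
Projecting real (geodetic) coordinates into a suitable planar CRS is
the caller's responsibility; at the scale of one province a single
projection is adequate, and keeping the package free of geodesy makes
every spatial operation exactly testable.

Exposure moves through three layers:

* **grid cells** (5 × 5 km) carry the daily gridded PM2.5 field;
* **dissemination areas** (DAs, census units of 400–700 residents)
  inherit the value of the cell whose centroid is nearest their own
  centroid — a deliberate simplification that avoids polygon-topology
  machinery while matching the cell-assignment intent;
* **health areas** average their member DAs weighted by population
  (`pop_weighted_mean`), or take the *maximum* over populated cells
  (`hsda_forecast_exposure`) when feeding the health model, so health
  forecasts reflect the worst case within the area.

Nearest-neighbour ties are broken by the lowest identifier, and radius
boundaries are inclusive, so every query is deterministic. Two
domain-specific conventions: fire radiative power with no detected fire
within 100 km is 0 (absence of fire is a real zero, not missing data),
while aerosol optical depth with no retrieval within 50 km is missing
and later median-imputed.

All gridded estimates and forecasts are capped at 150 µg/m³
(`cap_pm`), the ceiling of the historic training data for the
observation-based exposure model. The cap is a reporting constraint on
outputs: the day +1 average is computed first and capped after.
Monitor observations are never capped, which is what makes them a fair
verification reference when concentrations exceed the cap.

## The blended PM2.5 forecast

Numerical smoke-dispersion forecasts systematically overestimate
concentrations near active fires. The blend corrects this by letting a
random forest re-weight the numerical forecast against five
observation-based predictors, all lagged one day (the information
actually available at morning issue time):

| predictor   | units  | definition |
|-------------|--------|------------|
| `pm25_lag1` | µg/m³  | yesterday's 24-h mean at the nearest monitor |
| `aod`       | —      | yesterday's nearest satellite AOD within 50 km |
| `frp`       | MW     | yesterday's mean fire radiative power within 100 km |
| `hms`       | 0/1    | yesterday's analyst-traced smoke-plume flag at the cell |
| `vi`        | 1–100  | yesterday's venting index at the nearest station |
| `firework`  | µg/m³  | today's daily-mean numerical smoke forecast |

The target is today's observed 24-h monitor mean, truncated at
150 µg/m³ for consistency with the historic exposure field. One
provincial model pools all stations and dates; per-station models were
rejected because single stations see too few smoky days to support a
forest. Defaults are 1,000 trees with 3 candidate predictors per split,
and an explicit seed is required — the whole train→forecast path is
bit-reproducible.

Skill is measured out-of-bag: each row is predicted only by trees that
did not sample it, and the averaged OOB predictions give the RMSE and
the pseudo-R² (1 − OOB MSE / population variance of the target). The
pseudo-R² is reported unclipped; values below 0 mean the model is worse
than the target mean.

Missing AOD is imputed with the training-set median, which is recorded
in the model and reused at prediction time (forests need complete
rows; the operational handling of missing satellite covariates is not
otherwise specified, so recorded-median imputation is this package's
choice). Predictions are floored at 0 and capped at 150. Tomorrow's
blend is the arithmetic mean of today's blend and the numerical
forecast's day +1 daily mean (hours 25–48 of the 48-h issue), capped
after averaging; whether the operational system capped before or after
this average is unstated, and capping after treats the cap consistently
as an output constraint.

## The health forecast

Daily dispensation counts per health area are forecast by a second
random forest on five features: current and lagged population-weighted
PM2.5; the trailing mean count on the same day of week over the past
12 weeks and 4 weeks; and the ISO-8601 week of year. The trailing
means carry the strong weekly cycle (many pharmacies close on
weekends) and the secular level of each area, which is also what lets
one pooled model serve all areas.

"Accounting for holidays" is implemented as exclusion: holiday dates
are skipped in the trailing same-weekday means, extending the lookback
to at most twice the nominal window until enough qualifying dates are
found, because holiday closures would drag the weekday trend downward.
The mechanism is not defined by the operational system's description;
exclusion-with-extension is the simplest rule that removes the bias.
A built-in statutory calendar (`stat_holidays`) is provided and any
`Date` vector can be substituted. ISO week numbering is computed
arithmetically (nearest-Thursday rule) to stay locale-independent.

Training keeps every date whose exposure exceeds 15 µg/m³ — the
smoke-affected dates that carry the exposure signal — plus a seeded
random sample (default fraction 0.25) of the remaining low-exposure
dates; the fraction is configurable since only "a random sample" is
specified. Hyperparameters default to 1,000 trees with 2 of 5 features
per split (unstated operationally; 2 ≈ p/3 is the regression-forest
convention) and are configurable. The health model consumes capped
exposure values, consistent with the capped field upstream.

At issue time the substitution scheme replaces the exposure features
with forecasts: today's forecast uses (blended day 0, yesterday's
observed exposure); tomorrow's uses (blended day +1, blended day 0).
The trailing means and week are recomputed at each horizon's own date
from observed history only, which ends the day before the issue date —
a corruption test in the suite verifies that altering any observed
stream after a cutoff leaves all forecasts issued up to the cutoff
byte-identical. Count forecasts are real-valued ensemble means, floored
at zero; they are rounded to one decimal only for reporting, and
verification uses the unrounded values.

## Verification

`rmse`, `ioa`, `pct_within`, `rate_per_10k`, `percent_change`,
`pop_weighted_metric` and `pearson` implement the verification suite;
each is checked against an independent brute-force oracle to 1e-12 in
the tests. Conventions worth stating:

* the within-20 % boundary is inclusive, and a zero observation (a
  holiday closure) is matched only by a zero forecast;
* the index of agreement returns 1 when both series are constant and
  equal (zero denominator means zero potential error);
* province-level IOA is the population-weighted mean of per-area IOA
  values, not a pooled IOA over concatenated series — matching how
  per-area ranges are reported alongside the weighted average;
* each day's two forecasts are verified both separately per horizon
  and pooled ("both", 126 forecasts per area for a 63-day season);
  the day +1 forecast issued on the final day is verified against the
  observation one day past the window, so all 126 are scored.

The station comparator series weights each monitor by the population
of the DAs for which it is the nearest monitor. The description
"population-weighted average for all stations" does not pin down the
weights, so the simple station mean is also available
(`weights = "equal"`); nearest-population weighting is the default
because it approximates the population actually represented by each
monitor. Areas with no monitor are excluded from PM verification with
a warning — they still receive count forecasts.

## The synthetic world

`scenario_config()` + `make_scenario()` generate a complete seeded
season. What it emulates, and what it does not:

* **Geography**: a square province tiled into rectangular health-area
  blocks; DAs cluster around 2–3 town centres per block with uniform
  populations in 400–700; monitors sit near town centres (every area
  has at least one). Default 4 health areas × 150 DAs ≈ 82,000
  residents each — matching the least-populous real health area in the
  motivating setting (75,104), so count volumes are realistic at desk
  scale; the real range extends tenfold higher, where count noise is
  proportionally smaller.
* **Smoke**: episodes are Gaussian in space (decay length 30 km) and
  triangular in time (6–15 days, peaks 60–140 µg/m³) over a 4.2 µg/m³
  background — the mild-season provincial mean. Three episodes per
  summer. The closed forms make every field value hand-checkable.
  There is no plume transport, terrain, or fire growth.
* **Predictors**: AOD ∝ truth PM with log-normal noise and 30 %
  missingness; FRP points at active episode centres; plume flags where
  truth exceeds 20 µg/m³; venting index low on episode-active days.
* **Numerical forecast**: daily means equal truth × bias × exp(noise),
  with bias 3 within one decay length of an active episode centre and
  1 elsewhere — a stylised near-fire overestimate. Hourly values are
  recovered through a fixed diurnal shape with exactly unit mean.
* **Counts**: Poisson with mean
  `base_rate · pop/10⁴ · dow(d) · hol(d) · exp(β · PM)`. The weekday
  base rate 2.4 per 10,000 reproduces mild-season dispensation volumes;
  weekend multipliers 0.35/0.25 and a holiday multiplier 0.3 emulate
  pharmacy closures; β = log(1.3)/22 calibrates a 22 µg/m³ season-mean
  exposure to ≈ 30 % excess dispensations, the magnitude observed in
  the severe season. An overdispersion knob switches to negative
  binomial; Poisson is the default as the simplest count model
  consistent with the weekly structure.

Every generator is a pure function of (config, seed); geography can be
pinned separately (`geo_seed`) so smoke and noise re-draw on a fixed
map. The generating parameters are recoverable from the output — the
tests verify β within 15 % by Poisson regression (the consistent
estimator for this exactly log-linear count model) and the monitor
noise sd within 10 % — so passing tests demonstrate that the pipeline
recovers known structure. They do not demonstrate performance on real
data, whose spatial error correlation, reporting artefacts, and
behavioural responses the generator deliberately omits.

## Problem sizes and determinism

Test and example scenarios are sized for a desktop: the default world
is 4 health areas, 600 DAs, 16 monitors and a 20 × 20 grid, with two
history years and one 63-day evaluation window; property checks use
10 replicate seeds (20 for the β-recovery check at ~3 years of daily
data). A full simulate–train–forecast–verify cycle runs in roughly
twenty seconds; the whole suite in a few minutes.

Degenerate inputs are rejected loudly rather than patched: negative
concentrations, a constant training target, empty weighting sets, an
issue date whose forecasts are missing. Fewer than 50 training rows
warns; a missing numerical-forecast covariate at prediction time is an
error rather than imputable, because the forecast is the one input the
blend cannot do without.

## Known limitations

* Planar geometry only; callers own the projection.
* One pooled model per process (blend, health); areas with strongly
  heterogeneous exposure–response would need stratified fits.
* The 150 µg/m³ cap — kept for fidelity to the system being modelled —
  guarantees underprediction of extreme seasons; the verification
  design (uncapped monitors as reference) makes that visible rather
  than hiding it.
* The synthetic forecast bias is binary (near fire / elsewhere); real
  dispersion error is smoother and flow-dependent.
* Count forecasts assume a stationary exposure–response; the generator
  can produce, but the model does not exploit, responses outside the
  historically observed exposure range.
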