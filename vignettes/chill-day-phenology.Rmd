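---
title: "Chill-day phenology modelling with bloomcast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chill-day phenology modelling with bloomcast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bloomcast)
```

## The model

bloomcast implements a two-stage thermal-time model for the spring
phenology of temperate deciduous trees, applied here to the peak bloom
date (PBD) of flowering cherries — the day on which about 70% of the
blossoms on the monitored trees are open. The flowering process is
split into sequential dormancy and flowering stages:

1. **Endodormancy (rest).** From a fixed onset on October 1, each day
   contributes *chill days* `Cd <= 0` depending on how much of the
   diurnal temperature course lies in the chilling band. The running
   sum `Dc` decreases until it reaches the cultivar's chilling
   requirement `Rc < 0`; that day releases rest.
2. **Forcing (quiescence to bloom).** From the day after release, each
   day contributes *anti-chill days* `Ca >= 0` measuring warmth above
   the threshold. Bloom is predicted on the first day the running sum
   `Dh` reaches the heating requirement `Rh > 0`.

Daily contributions use the single-triangle diurnal model: the day's
temperature course is a triangle wave between `Tn = tmin` and
`Tx = tmax` with mean `Ta = (Tx + Tn)/2`, a base threshold `Tc`, and a
0 °C lower bound. The five closed-form cases (see `?chill_day`) are
exactly the time-averages of the triangle wave: forcing is the mean
excess over `Tc`, chilling is minus the mean of the band between
`max(Tn, 0)` and `min(T, Tc)`. The test suite verifies this equivalence
against direct numerical integration of the triangle wave, to 1e-3
chill days over 10^4 random inputs.

Assumptions worth stating: dormancy onset is fixed at October 1 (autumn
dormancy-induction dynamics are not modelled); photoperiod and
precipitation are ignored (cherries are weakly sensitive to both);
threshold crossings are whole-day (the first date whose end-of-day sum
meets the requirement — bloom records are integer dates, so sub-day
interpolation would be false precision); forcing accumulated before
release is discarded, and chill accumulation is frozen once forcing
begins (the strictly sequential reading of the two stages); seasons are
evaluated through June 30, after which a season is flagged
`no-release` or `no-bloom`.

Two degenerate daily cases are defined by continuity: isothermal days
(`Tx == Tn`) take the collapsed-triangle limit `Cd = 0`,
`Ca = max(0, Ta - Tc)`, and days entirely below 0 °C contribute
nothing. The threshold `Tc` is required to be non-negative because the
case formulas place it at or above the 0 °C lower bound.

## Parameters

| parameter | meaning | units | typical cherries |
|---|---|---|---|
| `Tc` | base threshold separating chilling from forcing | °C | 4.3–7.0 |
| `Rc` | chilling requirement (released when `Dc <= Rc`) | chill days (negative) | −78.9 to −114.0 |
| `Rh` | heating requirement after release | anti-chill days | 123.5–289.1 |

## Weather input and quality control

`read_daily_weather()` accepts daily CSV exports (configurable headers,
so NOAA daily summaries work directly), drops physically inconsistent
rows (`tmax < tmin`) and unparseable rows with line-numbered
diagnostics, and *flags but keeps* temperatures outside ±60 °C.
`extract_season()` assembles the 273/274-day October–June season and
fills interior gaps of at most 3 consecutive days by linear
interpolation of `tmax` and `tmin` independently; longer gaps reject
the season. The 3-day policy is this package's own: chill accumulation
is a running sum, so silently bridging long gaps would bias release
dates, while rejecting every season with a single missing day would
discard most real station records.

## Calibration

`calibrate()` estimates `(Tc, Rc, Rh)` by exhaustive grid search
minimising a penalised RMSE between predicted and observed PBD,
followed by a local coordinate-descent refinement that halves its steps
until they fall below 5% of the grid steps. The default grid spans
`Tc` 0–12 °C by 0.1, `Rc` −200 to −20 by 1, `Rh` 50–400 by 1,
bracketing published cherry estimates with a wide margin. Because, for
fixed `Tc`, a season's cumulative chill and forcing sums are fixed, the
whole `(Rc, Rh)` plane reduces to two monotone searches per season, so
the ~7.7-million-point default grid evaluates in seconds.

Seasons in which a candidate parameter set never blooms contribute a
fixed 60-day error (`penalized_rmse()`) rather than being dropped —
dropping would reward parameter sets that fail to bloom. Ties in the
objective are broken deterministically: smallest absolute bias, then
smallest `Tc`, then `Rc` closest to zero, then smallest `Rh`.

**Identifiability caveat.** With integer-valued bloom dates the
objective is piecewise constant, and in spring-blooming regimes (large
`Rh`, release well before bloom) the zero-error plateau can span more
than one grid step in each direction: several parameter triples predict
identical integer dates for every season. Calibration then returns a
deterministic representative of the equivalence class (per the
tie-break rules), not necessarily the generating truth. The
parameter-recovery tests therefore use a sharply identified regime
(truth `(5, -20, 50)`, where bloom follows release closely and every
parameter perturbs some predicted date); users calibrating real
cultivars should read the reported parameters as one member of a
near-equivalent set, which is also the honest reading of any published
estimates obtained this way.

## Evaluation

`evaluate_fit()` reports RMSE, MAE, bias, and r². Two conventions are
fixed here because the field literature leaves them ambiguous: bias is
`mean(pred - obs)` (positive = model predicts later than observed), and
r² is the squared Pearson correlation of predictions and observations
(not `1 - SSE/SST`). r² is reported as `NA` when either series is
constant. The identities `rmse >= mae >= |bias|` and
`rmse² = bias² + var_pop(e)` are enforced by tests.

## Temporal downscaling of monthly normals

Climate-scenario inputs arrive as 30-year monthly normals (12 `tmax` +
12 `tmin` values per location × period). `trig_interpolate_monthly()`
converts each 12-vector to a 365-day series by *exact* trigonometric
interpolation — mean, harmonics 1–5, and the sixth-harmonic cosine,
twelve coefficients solved exactly at the mid-month anchor days 15, 46,
74, 105, 135, 166, 196, 227, 258, 288, 319, 349. Exact interpolation
was chosen over a truncated least-squares harmonic fit because it is
deterministic, testable (anchor exactness to 1e-6), linear, and nests
every lower-order fit; mid-month anchoring is the standard convention
for monthly normals. Monthly means of the daily curve are
*approximately* preserved for smooth annual cycles (tested to within
0.5 °C); exact mean preservation is deliberately not claimed. The
normal year has 365 days — climatological normals have no leap
identity — and all normal-year date arithmetic uses the non-leap
day-of-year scale. `tmax` and `tmin` are interpolated independently;
days where the curves cross are clamped to their common midpoint and
counted in a diagnostic.

## Projection and reporting

`project_pbd()` runs the calibrated model once on each location ×
scenario × period climatology (`climatology_to_season()` wraps day 274
through day 181 into an October–June season). The projected PBD of a
normal period is that single run — normals are run directly, not
resampled into synthetic years. Summaries use the sample (n−1)
standard deviation of non-leap day-of-year values across locations,
reported to one decimal, and advancements are baseline DOY minus
projected DOY (positive = earlier bloom). Cells that fail to release
or bloom are flagged, never silently dropped, and bloom dates outside
February–June are marked anomalous.

The package ships a published reference table of projected bloom dates
for four Mid-Atlantic cities (`mid_atlantic_pbd_table()`) with the
observed 1971–2000 Tidal Basin baselines
(`tidal_basin_baselines()`); the acceptance suite reproduces the
published cross-location SDs and mean advancements from it. One known
discrepancy is documented: the published Yoshino A2 2080s
cross-location SD of 5.4 days is not reproducible from the published
dates (which give 5.0); every other printed cross-location SD
reproduces exactly. The per-city cross-period SD columns of such
tables follow a convention we could not reproduce with either the
sample or the population estimator, so they are not asserted.
Similarly, where narrative text and table disagree (e.g. a text date a
day or two off the tabulated one), the table is treated as
authoritative.

## The synthetic-data generator

`simulate_weather()` emulates what the analysis actually assumes about
mid-latitude station weather and nothing more: a sinusoidal annual
cycle in the daily mean (period 365.25 days so multi-year series stay
calendar-aligned without leap-day bookkeeping), stationary AR(1)
Gaussian noise (default marginal SD 1.5 °C, lag-1 autocorrelation 0.7)
so chill sums see realistic day-to-day persistence, and a jittered
diurnal range (mean 9 °C, floored at 0.5 °C) splitting the mean into
`tmax`/`tmin`. Defaults (annual mean 12 °C, amplitude 12 °C, coldest
day January 15) put January means near 0 °C and July near 24 °C — a
humid mid-latitude East-Coast climate. It does not emulate weather
fronts, skewed temperature distributions, heat waves, station moves,
or missing data; a green parameter-recovery test therefore establishes
that the estimator inverts the forward model under the assumed
statistical structure, not that it is robust to real station
pathology. `simulate_pbd()` adds rounded Gaussian observation noise to
forward-model bloom dates; both generators are pure functions of their
arguments and seed.

## Numerical choices

* Release/bloom are the first days whose end-of-day cumulative sums
  meet the requirement; ties in cumulative sums resolve to the
  earliest day.
* The grid engine and the scalar season runner are independent code
  paths; tests assert their agreement point by point against a
  `run_season()`-based oracle.
* Refinement respects the parameter domain (`Tc >= 0`, `Rc < 0`,
  `Rh > 0`) but may leave the grid's bounding box.
* Penalised-objective ties during refinement use a 1e-9 comparison
  tolerance.

## Limitations

* No autumn dormancy-induction model: the October 1 onset is imposed,
  so the model cannot express delayed dormancy under autumn warming.
* Parameter equivalence classes (above) mean calibrated parameters are
  not uniquely interpretable physiologically.
* Spatial downscaling of climate-model output is out of scope; the
  package consumes pre-made monthly normals.
* The harmonic order and anchor convention of the interpolation are a
  documented package choice; other conventions shift daily values by
  tenths of a degree and projected dates by a day or so.
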