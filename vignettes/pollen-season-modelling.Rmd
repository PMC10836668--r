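---
title: "Modelling the spring pollen season of paper mulberry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the spring pollen season of paper mulberry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollenseason)
```

Paper mulberry (*Broussonetia papyrifera*) sheds enormous amounts of
allergenic pollen over a short spring window — in Islamabad daily
concentrations can reach ~40,000 grains/m³, and the season typically opens
around 8 March.  Patients who know the start and peak days a week or two
in advance can begin preventer medication and plan exposure.  This package
implements, end to end, the two model families used for that forecast:
window-searched stepwise linear regression, and thermal-forcing
phenological models calibrated by brute force.  Because the original
pollen-count and simulated-weather records are proprietary, the package
ships a synthetic generator with known ground truth; every claim the test
suite makes is about data whose answer is known by construction.

## Season definitions

For each calendar year, daily concentrations define:

* **start day** — the first day on which the running cumulative sum
  (from 1 January) reaches 2.5% or 5% of the *annual* total.  Both
  thresholds are in common use, so all models come in a 2.5% and a 5%
  flavour.  "Reaches" is read as ≥ (the first day the threshold *has
  accumulated*).  The annual total is the full calendar-year sum, not a
  spring-only sum, matching the standard main-pollen-season definitions;
  the distinction is testable via the configurable peak window if a
  sensitivity check is ever needed.
* **peak day** — the day of the year's maximum concentration, searched in
  days 1–181 (January–June) by default so a secondary late-summer rise
  can never capture the argmax; ties break to the earliest day.

Evaluation throughout is the mean absolute error
MAE = Σ|PDᵢ − ADᵢ|/n over evaluation years, in days.

## Linear regression models

For a candidate averaging window (fixed month-day bounds, identical every
year), each training year contributes the window means of eight daily
weather variables — temperature `T` (°C), humidity `H` (%), rainfall `Rf`
(mm), cloud cover `Cc` (%), sunshine duration `Sd` (h), wind speed `Ws`,
gust `Wg` (km/h) and direction `Wd` (degrees) — and the response is that
year's season day.  The procedure per window:

1. **Forward stepwise selection.**  Variables are added one at a time,
   each step keeping the candidate that maximises adjusted R²; the step
   with the overall highest adjusted R² defines the selected subset.
   Exact ties keep the earlier variable in the fixed order
   `T,H,Cc,Sd,Ws,Wd,Wg,Rf`.  An exhaustive best-subset mode
   (`forward_stepwise(..., exhaustive = TRUE)`) exists for comparison;
   the two provably coincide on orthogonal designs, which the tests
   exploit.
2. **Leave-one-out cross-validation.**  One fold per training year; the
   final coefficients are the arithmetic means of the per-fold
   coefficients, and the model's score is the mean out-of-fold absolute
   error.  Selection is performed once per window, not per fold —
   re-selecting inside folds would make coefficient averaging ill-defined
   across differing variable sets.
3. **Gate and search.**  Models whose overall F-test p-value exceeds 0.05
   are discarded; among survivors the window with the smallest LOOCV MAE
   wins.  Start models search all 616 windows (starts 1 Jan–25 Feb ×
   ends 1–11 Mar); peak models search 56 windows whose end is each
   year's observed season start, with that start day joining the
   candidate features (observed in training, *predicted* at prediction
   time — the only causally consistent choice).

Predictions are `a + Σ bᵢxᵢ` rounded to the nearest whole day; MAEs are
computed on rounded predictions (the rounding rule changes MAE by less
than half a day but is stated because it is part of the contract).
All eight variables are aggregated by plain arithmetic means, including
rainfall and wind direction: a published linear coefficient on `Wd`
implies linear treatment, so circular averaging was rejected for
consistency of coefficient semantics.

## Phenological models

The start model accumulates a sigmoid daily forcing from a calendar onset
`F1`:

$$sf = \sum_{F_1}^{F} \frac{1}{1 + e^{d\,(t_{avg} - c)}}$$

with steepness `d < 0` and threshold `c` (°C): a day near `c` contributes
½ unit, far below `c` almost nothing, far above almost one.  The sigmoid
itself realises the "heat only counts above the threshold" behaviour, so
no extra hard cutoff is applied — a cutoff would contradict the printed
formula.  The season starts when the running sum reaches the plant's
requirement `M`.

The peak model accumulates growing-degree heat `max(T_avg − T_h, 0)` from
the trigger day — the first day strictly after the season start with
`T_avg ≥ T_D` — and fires at its own requirement (°C·day).  Contributions
are clamped at zero so cold days cannot erase accumulated heat.

All parameters are unknown for paper mulberry, so calibration is a grid
search: onsets 1 Oct–28 Feb (151 dates, autumn onsets accumulate across
the year boundary), `d` from −10 to −0.25 in steps of 0.25 (40 values;
zero is excluded because `d` is strictly negative), and 0–40 °C in 1 °C
steps for `c`, `T_D`, `T_h` — 247,640 start combinations and 1,681 peak
combinations.  For every combination the per-training-year units are
accumulated to the observed start (or observed start → observed peak),
and combinations are discarded when the mean is "zero" (≤ ε = 10⁻⁶ — the
operational reading of non-zero forcing) or the relative SD exceeds 50%.
Survivors are ranked by training MAE (predict each year as the first
crossing of the mean units `M`); ties break by smaller RSD, then grid
order.  Units are accumulated *through* the observed start day
(inclusive); the exclusive alternative is one flag away
(`include_start_day = FALSE`).  Candidate evaluation is internally
vectorised but pure per candidate, so results are identical to scanning
combinations one at a time — a property the tests enforce against a
scalar brute-force oracle.

## Issue-date hindcast

Operationally a forecast issued on 25 February cannot see March weather.
The evaluation therefore replaces every post-issue day's value with
`0.8 × eventual observation + 0.2 × training-years mean` for that
calendar day — a stand-in for a short-term weather forecast, applied to
all eight variables (the blend weights and issue date are configurable;
daily updating is re-running with the issue date advanced).  This is an
evaluation device, not an operational forecast.  With observation weight
1 the entire blended pipeline collapses exactly onto the
pure-observation pipeline, which the tests verify end to end.

## The synthetic study record

`make_dataset()` generates the record the analyses run on; its defaults
*are* the study conditions.

* **Weather.**  Daily mean temperature
  `20.3 − 11·cos(2π·doy/365)` °C (Islamabad's annual mean is ~20.3 °C)
  plus AR(1) noise (ρ = 0.65, innovation SD 2.4 °C) and a per-season
  (July–June) offset with SD 1.2 °C.  The offset gives the
  warm-spring/cold-spring contrast real records show — observed seasons
  spread over roughly three weeks — and is what makes the forcing
  threshold identifiable at all: with day-to-day noise alone, `c` and `M`
  trade off along a ridge that twelve training years cannot resolve.
  The other seven variables follow simple bounded seasonal models; 15
  calendar years (2004–2018) are generated, with weather reaching back to
  1 October 2003 so autumn onsets are always covered (the pollen span is
  therefore a strict subset of the weather span).
* **Pollen.**  Release is driven by the forcing equations themselves with
  truth parameters inside the search grids: onset 31 Jan, `d = −1`,
  `c = 15 °C`, start requirement 12 units; trigger 15 °C, base 8 °C, peak
  requirement 25 °C·day; peak magnitude 40,000 grains/m³.  A steep truth
  sigmoid was chosen deliberately: a near-threshold response is both
  biologically plausible for an abrupt spring bloomer and statistically
  identifiable, whereas a very shallow sigmoid leaves the threshold
  ill-determined in any twelve-year record.  Each year's ground-truth
  start/peak are the first threshold crossings; concentrations follow a
  skewed unimodal bell over 45 days with an *abrupt onset*: release jumps
  to 55% of the peak level on the trigger day and holds that plateau
  until the rising limb overtakes it (catkins open quickly once the
  requirement is met).  The plateau keeps the cumulative 2.5%/5%
  criteria within 0–2 days of the mechanistic trigger, which is what
  makes calibration on the output a clean parameter-recovery problem.
  Multiplicative lognormal noise (CV 0.15 by default, mean-one) perturbs
  in-season days; an optional late-summer bump (off by default) mimics
  the secondary flowering.
* **What it does not emulate.**  Real records have missing days and
  counting error structure, pollen transport from outside the city,
  bimodal seasons, and weather whose correlation structure is richer than
  AR(1) + seasonal offset.  Passing tests therefore demonstrate that the
  *procedures* are implemented correctly and can recover a known
  mechanism — not that either model family attains any particular
  accuracy on real Islamabad data.  Notably, on this record the
  phenological models beat the regressions (the generator *is* the
  forcing mechanism); on the real record the ordering was the reverse.

## Numerical and calendar conventions

* Day-of-year is 1-based; 8 March = 67 in non-leap years.  Cross-year
  alignment uses month-day keys, and 29 February is dropped from
  climatologies and window means so window lengths stay comparable; the
  forcing sums use the actual daily series.
* Missing weather values are a hard error at ingest; an optional linear
  interpolation repair exists (`repair_missing = TRUE`, off by default)
  because real station feeds are gappy.  Absent pollen dates are
  missing data; zeros are true zeros.
* Threshold crossings use ≥ with `findInterval` on running sums, so a
  crossing lands on the first day the requirement *has accumulated*.
* The train/test split is chronological: first 80% of years train
  (2004–2015), last 20% test (2016–2018).  Fitting functions only ever
  receive training-year slices; a tamper test perturbs test years and
  asserts fitted models are bit-identical.

## Problem sizes used by the tests

The unit and acceptance suites run the full 616-window regression search
and full grids where the check needs them, and reduced-but-truth-
containing grids (onsets 15 Jan–15 Feb, `d` −2…−0.25, `c` 10–20 °C) plus
an 8-year record for the fast end-to-end pipeline checks; the mini-grid
oracle comparison uses a 3-year toy record with a 3×2×2 grid.  The
`analysis/` scripts and `scripts/acceptance.R` run the full 15-year
record, all 616 windows and all 247,640 start-grid combinations
(a few seconds each thanks to the vectorised accumulation).

## Known limitations

* The phenological selection criterion (training MAE at whole-day
  resolution over twelve years) separates nearby grid candidates only
  weakly; the recovered `(d, c, M)` can land on an adjacent ridge point
  for some records even at zero concentration noise.  The package
  reports the RSD precisely so users can see how flat the optimum is.
* Linear-model coefficients are unit-dependent; the shipped example
  coefficient sets assume the units fixed in `DailyWeatherRecord` and
  the package's window conventions.
* The hindcast blend assumes the training-years climatology is an
  unbiased stand-in for a forecast; under systematic warming this biases
  post-issue temperatures cold and start-day predictions late.
* Season end days (95%/97.5%), summer seasons, and regularised or
  nonlinear regression variants are out of scope.
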