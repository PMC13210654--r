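---
title: "Plant-centric irrigation timing from stem-diameter dynamics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plant-centric irrigation timing from stem-diameter dynamics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemcast)
```

## The sensing problem

A linear-displacement dendrometer sampled every 30 minutes resolves the
diurnal rhythm of a plant stem at micrometre resolution: transpiration
dehydrates elastic stem tissues during the day (contraction beginning
mid-morning, minimum in the late afternoon), and nocturnal root uptake
rehydrates them, normally restoring and then exceeding the previous maximum
as the stem grows. Three indicators summarise each 24-h cycle:

* **MXSD / MNSD** — the cycle maximum and minimum diameter (micrometres);
* **MDS** (maximum daily shrinkage) — `MXSD - MNSD`; rises with both
  evaporative demand and soil-water deficit;
* **DI** (daily increment) — today's MXSD minus yesterday's; `DI <= 0` means
  overnight rehydration failed to restore the previous maximum;
* **RT** (recovery time) — hours from the minimum until the signal first
  re-attains the same cycle's maximum, capped at 24 h when recovery is
  incomplete.

MDS alone is an ambiguous trigger: a hot, bright day inflates MDS with the
soil still wet (an *atmospheric false positive*), and an overcast day can
flatten MDS while the root zone is dry (a *masked deficit*). The decision
engine therefore triggers irrigation only when the physiological signal
(`MDS >= 70` um by default) and the soil constraint (volumetric water
content `VWC <= 17 %`) hold simultaneously; the other three quadrants are
named for why they do not trigger.

## Threshold calibration

Two estimates are computed side by side from progressive-drought
experiments, deliberately kept independent:

1. **Growth-arrest criterion.** Per replicate, the first complete cycle with
   `RT = 24 h` and `DI <= 0` is the physiological tipping point; the
   arrest-day MDS values are averaged across replicates. Both conditions are
   required: `RT = 24` with a positive increment is pre-arrest stress, and a
   transiently negative increment with full recovery is noise.
2. **Statistical process control.** Normal-growth-phase MDS values give a
   baseline mean and sample standard deviation (n-1 denominator); the
   1-sigma upper control limit `UCL = mean + sd` bounds normal physiological
   fluctuation (capturing about `pnorm(1) = 84.1 %` of Gaussian baseline
   observations). The recommended trigger is the UCL rounded *down* to the
   nearest 5 um, so intervention precedes the statistical boundary; with the
   bundled worked-example baseline (51.5 ± 21.7 um) this yields
   73.2 → 70 um.

The *normal growth phase* used for the baseline is every cycle strictly
before the earliest replicate arrest in drought treatments plus all control
cycles. Soil status is reported both as VWC (%) and as the fraction of field
capacity `PPV = SWC / FC` (FC = 26.0 % volumetric for the reference sandy
loam), rounded to two decimals.

## The hybrid forecaster

Decisions are proactive: the engine evaluates a 24-h-ahead forecast of the
stem signal rather than waiting for the shrinkage to materialise. The
forecaster decomposes the cleaned single-sensor series by seasonal-trend
decomposition using Loess (`stats::stl`) into `Y = T + S + R` with a
48-step seasonal period and a 337-step trend window (the 7-day window of
336 steps adjusted to the next odd integer that Loess requires), seasonal
sub-series smoothing set to periodic and robustness iterations off — the
strict-periodicity assumption is precisely what the seasonal persistence
forecast exploits. The remainder is stored as `Y - T - S`, so additivity is
exact by construction. Each component is then forecast by the method suited
to its character:

* **Trend**: least-squares quadratic in the time index over the last 7 days
  (336 points), evaluated at the horizon indices. The centred design matrix
  keeps the normal equations well conditioned.
* **Seasonal**: persistence, `S(t+h) = S(t+h-48)`, recursing on its own
  output beyond one period.
* **Remainder**: a gated recurrent unit (GRU) network with a linear head of
  width 48 (direct multi-output; chosen over recursive multi-step for
  stability and single-pass prediction). Features per lookback step (24
  steps = 12 h): the three decomposition components, the four environment
  covariates (air temperature, relative humidity, light, soil VWC), and a
  sine-cosine encoding of clock time with period 48. All features are
  observed history — no future covariates are consumed, so the forecast
  needs no weather forecast; where a soil stream must extend across the
  horizon (decision stage), the last observation is persisted and drying is
  never extrapolated, which can delay but never fabricate a trigger.

The network is implemented directly on base-R matrix algebra (batched
forward pass, backpropagation through time, Adam, inverted dropout between
layers with masks held constant across time, early stopping on validation
loss with best-weight restore). Gradients are verified against central
differences in the test suite. Everything is driven by one integer seed, so
a rerun reproduces the training log bit for bit.

Training uses a chronological 60/20/20 split of the timeline; a window
whose span crosses a split boundary is excluded, and normalization
parameters (z-score, population sd for features; separate scaling for the
residual targets) are fitted on training windows only. The default
architecture (2 layers x 64 units, learning rate 0.001, batch 32) is the
optimum of the 81-point grid `layers {1,2,3} x units {32,64,128} x lr
{1e-3,1e-4,1e-5} x batch {16,32,64}`, which `hyperparameter_search()`
evaluates exhaustively at a reduced epoch budget, ranking by validation
RMSE with ties to the smaller model; a 128+64-unit variant is available
through the configuration. The forecast horizon defaults to 48 steps
(24 h) and is configurable down to the 12-h warning window some operations
prefer.

One caveat is stated openly: model *training* decomposes the full series
once, as is usual for decomposition-hybrid pipelines, so the Loess trend at
training time has seen a smoothed version of later data. *Evaluation* is
stricter: every backtest origin re-decomposes only the history before it,
and metrics pool only test-block forecasts, so the reported test RMSE /
R-squared / MAPE contain no look-ahead. The MAPE here follows the
stabilised form `mean(|y - yhat| / (y + 0.01)) * 100` — the denominator is
`y + 0.01`, not `|y|`; this is not the textbook MAPE and is asymmetric in
its arguments, which the tests assert. The comparison baseline is the
seasonal-naive forecast `Y(t+h) = Y(t+h-48)`, a hard target on strongly
diurnal signals.

## Data preparation

Raw tables carry replicate dendrometer columns plus the four covariates on
a strict 30-min grid; reading validates the grid, inserts missing slots as
flagged gaps, and rejects duplicate timestamps. Cleaning is tiered:

* **Outliers**: Tukey fences (1.5 x IQR) in a centred rolling 2-day window.
  Two days is long enough for stable quartiles and short enough to track
  growth drift; removed samples become gaps.
* **Sparse gaps** (<= 4 steps = 2 h by default): linear interpolation
  between observed neighbours.
* **Long gaps**: analog-day transfer — the donor day minimises the
  z-scored Euclidean distance of daily-mean temperature, humidity and
  light; its same-clock-time segment is level-shifted by a linear blend of
  the endpoint offsets. Boundary gaps use a constant shift from the single
  available endpoint and are never linearly extrapolated.
* **Aggregation**: per-timestep arithmetic mean over available replicates;
  a step with no replicate propagates a gap.

Min-max normalization (training min to 0, max to 1) is provided alongside
z-score; the forecaster uses z-score internally. The z-score convention is
the population standard deviation (divide by n), fixed and documented here
because round-tripping depends on it.

## The synthetic scenario generator

No public dendrometer corpus accompanies this problem, so the generator is
first-class, tested code that encodes the study conditions every other
module is validated against. Per day it draws a weather regime (sunny, or
cloudy with probability 0.3 and amplitude multiplier 0.55), a soil state,
and builds the stem signal from a clock-anchored template: growth (20
um/day healthy) accrues linearly up to the contraction onset (09:30) and
holds; a smooth contraction dip (half-cosine down to the minimum at 16:30,
half-cosine recovery complete by 22:00) is subtracted from the accrued
level. By construction the cycle maximum falls at 09:30, the minimum at
16:30, MDS equals the day's configured amplitude exactly, and healthy
recovery completes within the cycle (RT = 5.5 h at these defaults) — the
properties the indicator tests assert.

Water stress couples through the soil: the amplitude is multiplied by
`1 + 2.5 d^2 / (d^2 + 14^2)` with `d = max(0, FC - swc)`, a saturating
curve that yields a realistic 5-7 um/day MDS rise near the arrest
threshold and crosses 90 um around 18 % VWC under the default progressive
depletion (0.8 %/day from 24 %). As the amplitude approaches the
configured true arrest MDS, daily growth collapses sharply
(`1 - (amp/theta)^40`, decline capped at 1.5x the healthy rate) and a
nocturnal recovery deficit ramps up smoothly
(`0.3 / (1 + exp(-(amp - theta)/3))` of the amplitude): the day before
arrest already shows incomplete recovery with a still-rising dawn maximum,
and on the arrest day the dawn maximum stops rising — so `RT = 24` and
`DI <= 0` first coincide exactly where the internal MDS crosses the truth,
which the generator records in its bookkeeping along with the noise-free
signal, components and per-day indicator values.

Environment covariates share one standardized diurnal driver with loadings
calibrated analytically so the temperature-humidity correlation lands on
its -0.79 target regardless of regime sequence; light follows a clear-sky
half-sine scaled by the regime; soil VWC interpolates the daily trajectory
with small autocorrelated noise, clamped to `[0, FC]`. The learnable
remainder is `8 tanh((T-20)/6) * L / max(L)` plus AR(1) noise — a smooth
nonlinear function of observables, which is what the residual network is
for. Replicate sensor noise is AR(1) with coefficient 0.95 at the 30-min
step: dendrometer error is slow drift, not white noise, and a white model
would bias every cycle maximum upward by the extreme-value pull of 48
independent draws.

What the generator does *not* emulate — sensor dropouts correlated with
weather, hysteresis and temperature sensitivity of the gauge itself,
phenology-driven drift of the diurnal phase, irrigation-event step
responses — bounds what green tests mean: they certify the algorithms
against signals with the assumed structure, not field performance.

## Problem sizes, numerics, degenerate inputs

The test and acceptance workloads run at desk scale, chosen as the smallest
sizes at which every claim is meaningfully exercised: 60-day scenarios
(2880 steps) for forecasting with a compact residual network (1 layer x 32
units, batch 256, up to 12 epochs — on these strongly structured signals
the validation loss plateaus within a handful of epochs), 16-day
progressive-drought scenarios for calibration, five generator seeds per
stochastic claim. Fixed numerical conventions: quartiles use R's default
type-7; ties for cycle extremes resolve to the earliest occurrence; RT is
measured at the 30-min sample resolution without sub-sample interpolation,
reading "recovery within the cycle" in its simplest defensible form
(against the same cycle's maximum, from the minimum forward); cycles with
under 90 % valid samples report indicators as unavailable rather than
guessing; a constant feature is an error for a user-fitted normalizer but
is neutralised (unit scale, zero signal) inside the forecaster, where a
constant covariate is legitimate; degenerate grids, duplicate timestamps,
gapped decomposition inputs and empty calibration sets all fail loudly with
named errors.

## Known limitations

* Thresholds are static; growth-stage-adaptive thresholds and irrigation
  *volume* are out of scope by design.
* The dual-threshold rule is evaluated on forecast-cycle extremes of the
  reconstructed signal only; blending observed morning values into a
  partially elapsed cycle is not attempted.
* The SPC baseline assumes approximately Gaussian normal-phase MDS; heavy
  tails would make the 1-sigma capture optimistic.
* Training-time decomposition sees the full series (see above); fully
  online decomposition would remove the caveat at some cost in component
  stability.
* Synthetic validation transfers to field data only to the extent the
  generator's assumptions hold; the list of un-emulated effects above is
  the honest boundary.
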