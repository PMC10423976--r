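---
title: "Process-based phenology modelling for enclosure warming experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Process-based phenology modelling for enclosure warming experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenopeat)
```

`phenopeat` models spring green-up and autumn green-down transition dates
observed in whole-ecosystem warming experiments: open-top enclosures on a
boreal *Picea*–*Sphagnum* bog warmed year-round at five nominal levels (0,
+2.25, +4.5, +6.75, +9 °C; two enclosures per level), half of them
fumigated with ~+500 ppm CO2 during the growing season, monitored with
canopy cameras and a dense environmental sensor network. This vignette
documents the models, the estimation machinery, the synthetic experiment
generator, and the design decisions a maintainer should know about.

## From greenness to transition dates

Canopy cameras yield a daily green chromatic coordinate (G~cc~ = G/(R+G+B)
over a region of interest), one series per enclosure and plant functional
type (DN = deciduous needleleaf larch, EN = evergreen needleleaf spruce,
SH = mixed shrub). Snow depresses the greenness signal, so flagged snow
days are removed (`exclude_snow_days()`); the remaining days are composited
with a moving 3-day 90th percentile (`composite_90th()`), using the
linear-interpolation percentile definition (R's default type 7) — the rule
is stated here because percentile conventions differ. No further smoothing
is applied: the 3-day 90th-percentile composite *is* the smoothed series.

The transition date is where the composite crosses 25% of its seasonal
amplitude above the seasonal minimum: the first upward crossing on the
rising limb in spring (crossings before the seasonal minimum are ignored),
and the last downward crossing on the falling limb in autumn; ties from
noisy shoulders therefore resolve to the earliest spring and latest autumn
crossing. The crossing day is interpolated linearly between the bracketing
days. Because the threshold is amplitude-relative, the extracted dates are
exactly invariant to adding a constant to, or positively rescaling, the
greenness series — both invariances are under test.

A 90% interval is attached by re-crossing the threshold with the curve
shifted by ±1.645 residual standard deviations (raw minus composite). This
is a labelled heuristic: it propagates observation noise through the
crossing geometry but has no formal coverage guarantee.

## The model registry

All 29 models share one evaluation contract: from a driver window running
from 1 September of the previous year (day-of-year −121) to 31 December of
the focal year, accumulate a daily rate from a start day and report the
first day the accumulated state reaches a requirement; if it never does,
return the no-transition sentinel (`NA`), which is a value, not an error.
Accumulation begins the day *after* the start parameter `t0`, so a
constant unit rate with requirement `F` crosses on day `t0 + F`. Spring
crossings are only valid within day-of-year 1–243; a crossing outside that
window (e.g. a marginal chilling requirement met only the following
autumn) is ecologically meaningless for budburst and is returned as the
sentinel. The negative-day window exists because chilling accumulation
starts in the previous autumn; `t0` and `t0_chill` may be negative, and
the 1 September window start is a documented convention.

Spring families:

* **LIN** — `DOY = a + b · mean(T)` over days 1–120 (window configurable).
* **TT / TTs** — thermal time: growing-degree-day forcing
  `max(T − T_base, 0)` or its sigmoid variant `1/(1+exp(−b_f(T − c_f)))`,
  accumulated from `t0` until `F*`.
* **PTT / PTTs** — as TT(s) with daily forcing weighted by `L/24`
  (daylength fraction).
* **M1 / M1s** — as TT(s) with weight `(L/10)^k`; `k = 0` recovers the
  photoperiod-free model exactly, which the nesting tests exploit.
* **AT** — alternating: chill days (`T < T_base`) counted from `t0` lower
  the forcing requirement `F*(t) = a + b·exp(c·C(t))` (`b ≥ 0, c ≤ 0`).
* **SQ / SQb, SM1 / SM1b** — sequential: chilling (triangular over
  `T_min < T_opt < T_max`, or the bell
  `1/(1+exp(a_c(T−c_c)² + b_c(T−c_c)))`) accumulates from `t0_chill`;
  forcing begins the day the chilling requirement `C*` is met (inclusive)
  and not before `t0`; forcing accumulated before release is discarded.
  The M1 variants multiply forcing by `(L/10)^k`.
* **PA / PAb, PM1 / PM1b** — parallel: chilling and forcing accumulate
  simultaneously; daily forcing is weighted by
  `K(t) = K_min + (1 − K_min)·min(1, C(t)/C*)`. The `K_min` floor is what
  brings the parameter count to the conventional nine; with `K_min = 0` it
  reduces to the plain `min(1, C/C*)` weight, and `C* = 0` forces `K ≡ 1`.
* **UM1** — unified: bell chilling and sigmoid forcing share a single
  start day `t0_chill` (keeping nine parameters), with the requirement
  relaxing in accumulated chill, `F*(t) = w·exp(−z·C(t))`, `z ≥ 0`.
* **SGSI / AGSI** — growing-season index: daily index =
  `ramp(T) · (1 − ramp(VPD)) · ramp(L)^k`, each ramp
  `(x − x_lo)/(x_hi − x_lo)` clamped to [0, 1]; the VPD ramp enters in the
  decreasing direction (dry air suppresses the index) and the photoperiod
  exponent `k` is the ninth parameter. SGSI triggers on a trailing 21-day
  moving average of the index crossing a threshold; AGSI accumulates the
  index from `t0` against a requirement.

Autumn families accumulate *cold*: CDD uses `max(T_base − T, 0)`, CDDs the
decreasing sigmoid `1/(1+exp(b_s(T − c_s)))`; CDDP multiplies the cold rate
by the photoperiod weight `1 − L/24` (shorter days increase senescence
pressure; an internal switch keeps the alternative `L/24` reading
available); CDDM by the
water-table weight `1 + m·W` clamped at zero, with the sign of `m` left to
the optimizer because the direction linking water table to senescence is
not settled; PPM accumulates the daylength deficit `max(L_crit − L, 0)`
times the water weight, starting at the summer solstice rather than
consuming a start-day parameter — that interpretation preserves its
three-parameter count `{L_crit, m, F*}`. Autumn start days are bounded
below at midsummer (day 180) so spring cold spells cannot trigger
accumulation.

Each autumn model has a CO2 variant: the requirement becomes
`F_eff = max(F* − c_co2 · max(co2 − 400, 0), 0.05·F*)`, using the
enclosure-year's growing-season (days 120–280) mean CO2 as a single
scalar, with a fixed 400 ppm reference. CO2 thus lets senescence occur
with less accumulated cold — earlier under enrichment — and `c_co2 = 0`
makes the variant prediction-identical to its base model (a tested
invariant). Subtraction from, rather than multiplication of, the
requirement is a documented choice.

## Estimation and model selection

`pheno_fit()` minimizes the RMSE between observed and predicted dates,
with sentinel predictions replaced by a 9999-day penalty so parameter
vectors that fail to predict a transition are dominated. Parameters are
searched within uniform bounds shipped with the registry (user-overridable
via `fit_config(bounds = ...)`); a triangular chilling shape with
disordered `T_min, T_opt, T_max` yields all-sentinel predictions and hence
the penalty, which is how parameter-domain violations are handled inside
the unconstrained sampler.

The optimizer is a bounded simulated annealer in the generalized style:
single-coordinate (occasionally full-vector) Cauchy visiting moves
reflected into the box, Boltzmann acceptance at a temperature calibrated
to the cost spread of 20 initial probes, hyperbolic temperature and step
decay, and a deterministic pattern-search (coordinate-descent) refinement
of the incumbent at periodic restarts and at the end — the local-search
component conventional in generalized annealing engines, which matters on
these cost surfaces because integer-day predictions make the RMSE
piecewise constant. The decay schedules depend only on the iteration
counter, never on the total budget, so with `polish = FALSE` the best cost
for a fixed seed is exactly monotone in the iteration budget (a tested
property). The full protocol runs 25 chains × 40,000 iterations; the test
suite and examples use 3–5 chains × 500–2,000 iterations, which recover
noise-free thermal-time truths to ≤ 0.5 day RMSE. Chain sub-seeds are
drawn once from the master seed, making fits bit-reproducible and
independent of execution order.

Model selection uses `AIC = 2k + n·log(SSE/n)` (natural log, `k` the
parameter count, SSE floored at 1e-8 with a warning when a fit is exact)
and ΔAIC support classes: < 2 essentially equivalent, 2–10 little support,
≥ 10 no support. For a fixed model the lowest-AIC chain is the
lowest-RMSE chain, and that is how the best of the parallel chains is
selected. `compare_driver_depths()` refits one model per temperature
channel (air, or soil at 0–200 cm) under identical seeds;
`apply_fitted()` forward-evaluates fitted parameters at another site
without refitting, skipping (with a notice) models whose driver channels
the site lacks.

## The synthetic experiment generator

The generator reproduces the statistical structure the analysis assumes,
not bog physics (no microtopography, *Sphagnum* dynamics, or enclosure
engineering). Defaults encode the study conditions: latitude 47.5° N, mean
annual temperature 3.4 °C with a 16 °C seasonal half-amplitude (a
mid-continental boreal annual cycle), AR(1) daily weather noise
(coefficient 0.7, innovation SD 3 °C — realistic day-to-day variability
with ~week-scale persistence), ten enclosures at the five nominal warming
levels, and +500 ppm CO2 on days 120–280 in the elevated half. Weather
noise is shared across enclosures, so the realized temperature
differential equals the warming offset essentially exactly — convenient
for testing, though real enclosures differ slightly. Soil temperature at
each depth is the enclosure air series passed through a first-order
low-pass filter with depth-decreasing weight, giving the damping and lag
of a conductive profile; the water table follows a seasonal drawdown
(about +8 cm after snowmelt to −22 cm in midsummer) plus noise.

Transition dates are generated two ways. The mixed-effects mechanism draws
`DOY = intercept + slope·ΔT + co2·flag + interaction·ΔT·flag + year effect
+ residual`, with a year effect shared across enclosures (SD 3 days by
default; the year-effect SD is not reported with the coefficient sets, so
3 days is the package's choice, exposed in the arguments). The default
coefficient sets (`sensitivity_defaults()`) mirror the final fitted
structures from the enclosure experiment this package emulates — spring:
temperature only (−1.59, −1.94, −1.0 d/°C for DN/EN/SH); autumn DN:
temperature +1.86 d/°C, CO2 −16.94 d and interaction +1.38 d/°C; autumn
EN: +1.77 d/°C and −4.22 d; autumn SH: +3.06 d/°C — so simulated
experiments reproduce that effect structure. Residual SDs are not reported
either; they are back-calculated from the reported slope standard errors
under this design (slope SE ≈ σ/√Σ(ΔT−mean ΔT)², giving ≈ 4.3/6.5/3.6 d in
spring and 6.5/5.9/8.6 d in autumn), fixed once and documented here.

The process mechanism forward-runs any registry model plus Gaussian noise.
The sequential truth used in the structure-identifiability tests
(`t0_chill = −60, T_min = −30, T_opt = −12, T_max = 20, C* = 92`, fast
forcing with `F* = 15` above 5 °C) was calibrated once so that the chilling requirement binds
across the warming gradient in every weather realization — chilling
release is progressively delayed with warming until, in the warmest
enclosures, it overtakes the forcing advance and the spring response turns
non-monotone, a signature a pure forcing model cannot absorb — while
every enclosure-year still transitions. The greenness mechanism places
double-logistic 25%-amplitude crossings exactly at the supplied dates (the
logistic midpoints sit `log(3)/rate` inside the transition), so the
extraction chain can be validated against a closed form.

## Numerical choices and edge cases

* Day axis: day 0 is 31 December of the previous year; leap focal years
  carry day 366 in the driver series, but model evaluation aligns all
  enclosure-years on the common −121..365 axis and drops day 366.
* Daylength uses the CBM photoperiod model (revolution-angle declination)
  with the −0.8333° civil threshold; the threshold angle is an argument so
  other conventions can be swapped in.
* VPD uses the Tetens saturation formula; zero at 100% humidity.
* Driver gaps up to 3 consecutive days are linearly interpolated; longer
  gaps are an error naming the date range, because accumulation models
  cannot skip days silently. Fully absent optional drivers are flagged
  absent, never zero-filled.
* Mixed-effects fits use `nlme::lme` (maximum likelihood during backward
  elimination of the interaction and then the CO2 main effect at Wald
  p ≥ 0.05; REML for the final model). When the mixed model is not
  estimable — noise-free data with zero residual variance — fixed effects
  fall back to ordinary least squares with the year variance reported as
  zero, which in balanced designs leaves the slope estimates unchanged.
* CO2 is coded as a binary treatment indicator (ambient 0, elevated 1),
  so CO2 effects are in days.

## Problem sizes and what the tests do (and do not) show

The packaged test suite and acceptance checks run the full design at
reduced estimation budgets: coefficient recovery uses 20–40 Monte-Carlo
replicates of the 10-enclosure × 5-year experiment; identifiability checks
use 10 replicate datasets fitted at 5 chains × 2,000 iterations; the
depth scan uses a 5-channel subset at 3 chains × 1,000. These sizes were
chosen as the smallest at which the checked properties are stable across
seeds. Passing them shows the machinery is correct and the experimental
design identifies the simulated mechanisms; it does not show that any
particular mechanism drives a real bog, because the generator omits real
features — observation gaps, camera changes, snow misclassification,
drought events, and between-enclosure microclimate — that real data carry.

## Known limitations

* The confidence intervals on extracted transition dates are heuristic.
* The annealing schedule is fixed by defaults rather than adapted; very
  high-dimensional models (10 parameters) may need more chains or
  iterations than the test presets.
* The CO2 offset uses a single growing-season mean per enclosure-year; a
  daily CO2 pathway is not modelled.
* `run_pipeline()` orchestrates single-machine runs; chain-level
  parallelism is left to the caller since results are seed-derived and
  order-independent.
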