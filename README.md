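# phenopeat

Process-based modelling of spring green-up and autumn green-down for
whole-ecosystem warming experiments on boreal peatlands.

Enclosure-scale experiments that warm intact ecosystems across a gradient
(here nominally 0, +2.25, +4.5, +6.75 and +9 °C, with half the enclosures
receiving ~+500 ppm CO2 during the growing season) let phenology models be
confronted with temperatures far outside historical variability. `phenopeat`
is for ecologists who want to ask, with such data: which mechanism —
thermal forcing, winter chilling, photoperiod, vapour pressure deficit,
water table, CO2 — best explains the observed shifts in canopy transition
dates?

The package provides, end to end:

* **Transition-date extraction** from daily canopy greenness (green
  chromatic coordinate, G~cc~): snow-day exclusion, 3-day 90th-percentile
  compositing, and the 25%-of-seasonal-amplitude threshold crossing
  (`composite_90th()`, `extract_transitions()`).
* **A registry of 29 process-based models** (`pheno_models()`): 19 spring
  models — linear regression (LIN), thermal time (TT/TTs), photo-thermal
  time (PTT/PTTs), M1 photoperiod-exponent variants (M1/M1s), alternating
  (AT), sequential (SQ/SQb/SM1/SM1b), parallel (PA/PAb/PM1/PM1b), unified
  (UM1) and growing-season-index (SGSI/AGSI) — and 10 autumn models built
  on chilling-degree-day accumulation with photoperiod (CDDP), water-table
  (CDDM, PPM) and CO2-offset variants of each (CDDCO2, ...). A spring model
  accumulates a daily forcing rate (optionally gated or weighted by
  chilling state and multiplied by a photoperiod factor) and predicts the
  first day the accumulated state reaches its requirement; autumn models
  accumulate cold (or daylength deficit) until a senescence requirement,
  which elevated CO2 lowers linearly, is met.
* **Parameter estimation and model selection**: bounded simulated annealing
  over independent parallel chains with RMSE cost and sentinel penalty
  (`pheno_fit()`), AIC computed as `2k + n log(SSE/n)`, and ΔAIC ranking
  with the conventional support classes at 2 and 10 (`rank_models()`).
  Temperature-depth scans (`compare_driver_depths()`) and cross-site
  application of fitted parameters (`apply_fitted()`) reuse the same
  machinery.
* **Sensitivity statistics**: linear mixed-effects models of transition DOY
  on the measured warming differential and CO2 treatment with a random year
  intercept (`fit_sensitivity_lme()`, via `nlme`), per-year ordinary
  regressions (`per_year_sensitivity()`), and growing-season extension
  (`season_extension()`).
* **A synthetic enclosure-experiment generator** (`simulate_drivers()`,
  `simulate_transitions_lme()`, `simulate_transitions_process()`,
  `simulate_gcc()`) reproducing the design above, so every stage is testable
  without any external download.
* **A pipeline orchestrator** (`run_pipeline()`) driven by a YAML
  configuration, writing per-stage outputs and a manifest of content hashes.

## Worked example

```r
library(phenopeat)

# a 2-year synthetic experiment: 10 enclosures, 5 warming levels
sim <- simulate_drivers(n_years = 2, seed = 1)

# spring transition dates generated from a thermal-time truth
truth <- c(t0 = 30, T_base = 5, F_star = 120)
obs <- simulate_transitions_process(sim$drivers, "TT", truth,
                                    noise_sd = 2, seed = 2)

fits <- lapply(c("TT", "PTT", "LIN"), function(m)
  pheno_fit(m, obs, sim$drivers,
            config = fit_config(n_chains = 3, n_iter = 1500, seed = 7)))
rank_models(fits)
#> Model ranking (ascending AIC; support classes at delta 2 and 10):
#>  model k  rmse   aic delta_aic    support
#>     TT 3 2.000 33.73      0.00 equivalent
#>    PTT 3 2.000 33.73      0.00 equivalent
#>    LIN 2 3.163 50.07     16.34       none
```

The thermal-time model (and its photo-thermal variant, which differs only
by a daylength weight the optimizer can absorb) rank as equivalent
(ΔAIC < 2) with an RMSE equal to the 2-day observation noise, while the
two-parameter linear regression loses all support (ΔAIC ≥ 10) — the
ranking recovers the generating mechanism.

Temperature/CO2 sensitivity of the same kind of data:

```r
tr <- simulate_transitions_lme(sim$metadata, 2016:2017, "DN", "autumn", seed = 3)
fit_sensitivity_lme(tr, sim$metadata, "autumn", "DN")
#> Sensitivity of DN autumn transition dates (doy ~ dtemp+co2, n = 20)
#>         term estimate     se       t         p
#>  (Intercept)  280.750 2.7131 103.480 4.825e-24
#>        dtemp    2.411 0.4263   5.656 3.579e-05
#>          co2  -10.100 2.7131  -3.723 1.852e-03
#> Random year SD 0.00 d; residual SD 6.07 d [lme]
```

Warming delays green-down (+2.4 d/°C here) and elevated CO2 advances it
(−10 d); with only two simulated years the temperature-by-CO2 interaction
is not significant and backward elimination drops it from the final model.

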