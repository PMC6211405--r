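# denclim

Bayesian models of hibernation (denning) phenology and daily climate.

Long-term monitoring of protected areas records, per park and year, the day
of the last den entry in autumn and of the first den exit in spring.
`denclim` asks two questions of such records together with daily station
climate series:

1. **What do conditions look like around the event?**  Event-aligned
   temperature windows (`[-30, +30]` days) are modelled with a three-level
   hierarchical Gaussian-process regression

   ```
   v_iy(t) ~ GP(u_i(t),  k3_i)     observations, rough OU kernel per park
   u_i(t)  ~ GP(w(t)+h_i, k2)      park trajectories, smooth SE kernel
   w(t)    ~ GP(mu,       k1)      population trajectory, smooth SE kernel
   ```

   yielding the population trajectory `w(t)` with credible bands, the value
   and local slope of climate at the event day, and a partition of the
   observed variation into shared / park-specific / idiosyncratic
   components.  Snow depth, whose dynamics defeat smooth GPs, gets a
   parallel loess-based exploratory summary.

2. **Which days of the season drive the event date?**  A
   time-varying-coefficient (distributed-lag) mixed model

   ```
   z_iy = mu + r_i + sum_t a_i(t) u_iy(t) + sum_t b_i(t) v_iy(t) + eps_iy
   ```

   with GP priors on the daily coefficient curves, reported as posterior
   coefficient curves, window-sum credibility surfaces
   `P(sum_{t1..t2} alpha(t) >= 0)`, maximal runs of days with credibly
   negative effects, variance explained, and predicted event-date shifts
   for sustained climate anomalies.  The flexible model is benchmarked
   against every 7-day-lattice windowed-average linear mixed model by
   exact-refit leave-one-out cross-validated log predictive density.

Because the underlying monitoring data are not public, the package ships a
fully specified synthetic world (multi-park daily temperature and snow,
event dates from the model equation) so that every stage is testable
end-to-end; see the methods vignette
(`vignettes/denning-climate-models.Rmd`) for the model details, priors,
and the design arguments behind the generator defaults.

## Worked example

```r
library(denclim)

## a synthetic world: 6 parks, 15 years of spring den-exit records, and a
## known truth -- warm days around day 65 bring den exit forward
## (a negative temperature-coefficient bump, peak -0.15 days/degC, sd 4 d)
grid <- 41:100
sc   <- den_scenario("first_exit", n_parks = 6, years = 2000:2014, seed = 42,
                     event_params = list(t0 = 41, T = 100, mu = 80,
                                         residual_sd_mean = 2,
                                         residual_sd_spread = 0.3),
                     coef_params = list(
                       alpha = -0.15 * exp(-(grid - 65)^2 / (2 * 4^2)),
                       beta  = rep(0, 60)))
clim <- simulate_climate(sc)
ev   <- simulate_event_dates(clim, simulate_coefficient_functions(sc), sc)

## Model 1: event-aligned temperature trajectories
win <- align_event_windows(ev, clim, "temperature")
tf  <- fit_temperature_trajectory(win,
         sampler = list(chains = 1, iter = 800, warmup = 350, seed = 1))
tf
#> <trajectory_fit> 6 parks | lags -30..30 | 300 function draws
#>   w(0) = -2.93 (+/- 1.32) | slope at lag 0 = 0.232 per day
round(variance_partition(win, tf), 1)
#>          shared park_additional   idiosyncratic
#>            47.6             0.2            52.2

## Model 2: which days shift the exit date?
ef <- fit_event_model(ev, clim, t0 = 41, T = 100,
        sampler = list(chains = 1, iter = 800, warmup = 350, seed = 1))
pointwise_sign_credibility(ef, "alpha")$runs
#> # A tibble: 1 x 2
#>   start   end
#> 1    54    76
predict_event_shift(ef, c(55, 75), delta = 1)[c("mean", "sd")]
#> $mean
#> [1] -1.319
#> $sd
#> [1] 0.183
```

Reading the output: spring exits happen while temperatures climb through
about −3 °C at roughly +0.23 °C/day (`w(0)` is the population-mean
temperature on the event day itself); about half the aligned temperature
variation is a shared pattern and half is day-to-day weather.  The event
model flags days 54–76 as having a credibly negative temperature effect —
bracketing the true bump at day 65 — and a +1 °C anomaly sustained over
days 55–75 is expected to bring den exit forward by 1.3 ± 0.2 days (the
true value implied by the generating curve over that window is −1.2).
Numbers are what these exact calls print at seed 42.

## Pipeline and acceptance script

`run_pipeline(run_config(...))` chains the stages — simulate (or ingest
CSVs with nearest-station assignment and gap filling), trajectory fit, event
fit, window scan, report — into a run directory whose every table carries
the seed and a config hash; see `?run_config`.

`scripts/acceptance.R` re-runs the package's full analysis from scratch on
the synthetic world (all five pipeline stages, including the complete
7-day-window scan on a 60-day season) and writes its results JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
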