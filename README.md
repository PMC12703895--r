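# heatburden

Heatwave detection, distributed-lag mortality models, and attributable
burden estimation for daily environmental-epidemiology time series.

`heatburden` is aimed at environmental epidemiologists and public-health
analysts quantifying how much mortality multi-day heat events cause. It
implements the standard two-stage design for multi-location studies:

1. **Exposure** — heatwaves are runs of ≥ `min_duration` consecutive
   warm-season days whose daily maximum temperature strictly exceeds a
   location-specific percentile threshold (default: 92.5th percentile of
   the warm-season distribution, ≥ 2 days). Exposure is summarised by the
   cumulative excessive degree-day, CEDD = Σ max(0, T<sub>max</sub> −
   threshold), and by person-days (heatwave days × exposed population).
2. **First stage** — per location, a distributed-lag quasi-Poisson
   regression of daily deaths on the cross-basis of the heatwave
   indicator with a natural-cubic-spline lag structure over lags 0–3
   (intercept + 2 log-spaced internal knots), adjusted for a 4 df/year
   time spline, a 3 df humidity spline, linear PM2.5 and O3, and
   day-of-week. The estimand is the cumulative log relative risk
   β = Σ<sub>l</sub> θ<sub>l</sub>, reported as excess risk
   ER = (e<sup>β</sup> − 1) × 100%.
3. **Second stage** — DerSimonian–Laird random-effects meta-analysis of
   location β̂s, with Cochran's Q, τ², and I², overall and by stratum.
4. **Burden** — attributable deaths
   AN = Σ<sub>i</sub> pop · Mort<sub>i</sub> · HW<sub>i</sub> · (1 − e<sup>−β</sup>),
   attributable fraction AF = AN / (pop · Mort<sub>s</sub>) in ‰ of
   warm-season deaths, percentage changes of a target year against a
   baseline-period mean, and Monte-Carlo 95% CIs (1000 draws of β and
   rates, empirical 2.5/97.5 percentiles).

A synthetic-data generator (`sim_config()`, `generate_study()`) produces
multi-location daily datasets with known true effects, so every stage is
tested by parameter recovery; `run_pipeline()` drives
simulate → detect → fit → pool → burden from one (YAML-able) config.

## Worked example

```r
library(heatburden)

cfg <- sim_config(n_locations = 8, years = 2010:2016, seed = 42)
st  <- generate_study(cfg)

s   <- st$series[["loc001"]]
def <- heatwave_definition()                      # tmax > 92.5th pct, >= 2 days
thr <- compute_threshold(s$date, s$tmax, def)
ev  <- detect_heatwaves(s$date, s$tmax, thr, 2, location_id = "loc001")
round(thr, 2)          # 29.19  (deg C threshold for this location)
nrow(ev)               # 17     heatwave events over 7 warm seasons
sum(ev$duration)       # 52     heatwave days
round(compute_cedd(ev), 1)  # 88.4 degree-days of cumulative excess heat

fits <- lapply(seq_len(8), function(i) {
  si <- st$series[[i]]
  m  <- as.integer(format(si$date, "%m")) %in% 5:9
  fit_location(si[m, ], st$indicators[[i]][m], model_spec(),
               location_id = names(st$series)[i])
})
pool_fits(fits, "national")
#> national (k = 8): beta = 0.0824 (se 0.0432); ER 8.59% (-0.23 to 18.19)
#>   Q = 15.66 on 7 df, I2 = 55.3%, tau2 = 0.00825
```

The pooled ER of 8.59% means mortality on heatwave (and lagged) days is
about 8.6% above comparable non-heatwave days — close to the true
simulated pooled effect of 8.41% injected by `sim_config()`'s default
`beta_mean = log(1.0841)`; the interval is wide because only 8 locations
were fitted. I² = 55% says roughly half the between-location variation
in β̂ exceeds what sampling error alone explains.

Burden conversion (with a population, rate table and pooled β) runs
through `monte_carlo_burden()` or the end-to-end `run_pipeline()`; see
the methods vignette (`vignettes/heatwave-burden-methods.Rmd`).

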