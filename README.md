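# popfert

Estimation of population and fertility by single year of age, sex, and
calendar year, built around the demographic balancing equation

```
N(T) = N(0) + B(0,T) - D(0,T) + G(0,T)
```

where `B`, `D`, and `G` are births, deaths, and net migration over the
interval. The package provides a full, tested pipeline from raw demographic
inputs to internally consistent population series with uncertainty:

- **Fertility** — two-stage estimation of age-specific fertility rates
  (ASFR) from vital registration, complete birth histories, and summary
  birth histories: a covariate prior (schooling; a spline on the 20-24 rate
  for other age groups), source-bias adjustment to a reference source, and
  Gaussian-process regression of residuals over time (`fit_stage1`);
  splitting of aggregate children-ever-born and total-births records into
  pseudo-ASFR points (`split_aggregates`), and re-estimation
  (`fit_final`). Fertility at ages 10-14 and 50-54 is modelled from the
  adjacent groups (`fit_extreme_age_model`, `apply_extreme_ages`), and the
  sex ratio at birth by a GP around a time-invariant 1.05 prior
  (`estimate_srb`).
- **Census preparation** — a census completeness model fitted to
  post-enumeration surveys on a logit scale against the Socio-demographic
  Index, with a penalized-spline age pattern of enumeration
  (`fit_completeness_model`, `adjust_census`); the UN age-sex accuracy
  joint score (`age_sex_joint_score`); and age-heaping corrections:
  iterative Feeney-type redistribution for single-year counts and the
  Arriaga / Arriaga-strong 10-to-5-year splits for grouped counts
  (`correct_heaping`, `whipple_index`).
- **Life tables** — graduation of abridged period life tables (<1, 1-4,
  5-year groups to 110+) to single-year ages: a per-age regression
  `log(1qx) = b0 + b1 log(5qx)` fitted on a library of paired tables for
  ages under 15 and over 99, and a shape-preserving monotone cubic
  graduation of the 5-year cumulative-hazard increments in between, with
  the group identity `prod(1 - 1qx) = 1 - 5qx` enforced exactly
  (`fit_qx_regression`, `expand_lifetable`); fatal-discontinuity shock
  rates (`add_shock_rates`) and projection survivorship ratios
  (`survivorship_ratios`).
- **Projection** — deterministic single-year cohort-component projection
  with an open 95+ interval, exact vital-flow bookkeeping
  (`ccmpp_project`, `balance_residual`), and backward projection to a 1950
  baseline (`back_project`).
- **Demographic balancing** — a Bayesian model that infers the baseline
  population and an age-time-correlated net-migration surface (AR1 x AR1
  prior on rate knots) consistent with adjusted census counts, by MAP
  optimization with analytic gradients over an exactly linear
  cohort-component model (`fit_map`, `variance_schedule`,
  `select_version`, `insample_fit`).
- **Uncertainty** — out-of-sample predictive validity: hold-out census
  errors modelled as an isotonic function of years to the nearest census,
  combined with completeness-model coefficient uncertainty, and 1000 draws
  of percentage error per location-year (`oos_holdout_errors`,
  `fit_oos_error_model`, `population_draws`).
- **Indicators** — TFR, TFU25 (under age 25), TFO30 (ages 30-54), span
  aggregates, livebirths, net reproductive rate, growth rates, working-age
  share, mean age, and the Socio-demographic Index
  (`fertility_summaries`, `nrr`, `population_summaries`, `sdi`).
- **Synthetic data** — a generator of whole "countries" with known truth
  and realistically corrupted observations (undercount varying with
  development, terminal-digit age heaping, old-age exaggeration, biased
  registration, birth-history surveys), so every stage has a
  parameter-recovery test without external data (`make_true_country`,
  `observe_census`, `observe_fertility_sources`,
  `make_lifetable_library`).

## Worked example

```r
library(popfert)

truth <- make_true_country(list(years = 1950:2000), seed = 1)
truth
#> Synthetic truth: 51 years 1950 - 2000 ; final population 16,467,100

obs <- obs_config(census_years = c(1960, 1975, 1990),
                  heaping_strength = 0.25, age_grouping = "single")
census <- observe_census(truth, 1975, obs)
census
#> Census 1975 ( single ages ) total 9,416,355

round(whipple_index(census$counts), 1)                          # heaped
#> [1] 172.6
round(whipple_index(correct_heaping(census$counts, "feeney")), 1)
#> [1] 99.7

fs <- fertility_summaries(true_group_asfr(truth, 2000))
round(unlist(fs), 2)
#>   tfr tfu25 tfo30
#>  2.21  1.01  0.60

round(nrr(true_group_asfr(truth, 2000), truth$srb[50],
          truth$lifetables[[51]]$female), 2)
#> [1] 0.99

round(unlist(population_summaries(truth$pop, 1950, 2000)), 3)
#>       growth_rate    percent_change working_age_share          mean_age
#>             0.024           229.342             0.642            30.664
#>       prop_female
#>             0.494
```

The Whipple index of 172.6 says a quarter of the census counts near each
multiple of five have been piled onto it; the Feeney-type correction
restores it to 99.7 (100 = no digit preference) while preserving totals
exactly. A total fertility rate of 2.21 with a net reproductive rate of
0.99 means the synthetic country in 2000 is almost exactly at replacement;
the population still grew 229% since 1950 (momentum plus migration), with
64.2% of people at working ages.

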