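---
title: "Methods: demographic balancing, fertility estimation, and uncertainty"
author: "popfert"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: demographic balancing, fertility estimation, and uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models it implements, the
parameters that matter, the numerical choices made where the design was
genuinely open, and what the synthetic-data tests do and do not demonstrate
about real data.

## The balancing equation and the projection engine

Everything rests on the demographic balancing identity
`N(T) = N(0) + B - D + G`. The cohort-component projection
(`ccmpp_project`) operates on single ages 0–94 plus an open 95+ interval,
two sexes, and annual intervals between mid-year time points. Within each
interval:

1. half of the net migrants are added to the starting population;
2. each cohort is survived one age step using person-year ratios
   `S(a) = L(a+1)/L(a)` from a complete life table (the open interval
   absorbs age 94 via `L95/L94` and retains its stayers via `T96/T95`);
3. the remaining half of the migrants are added;
4. births are the age-specific fertility rates (single ages 10–54, per
   woman-year) applied to the mean of the start- and end-of-interval female
   population, split by the sex ratio at birth, and survived with newborn
   survivorship `L0/l0`.

Deaths are recorded per origin age as the survival complement, newborn
deaths at age 0, so the balancing identity holds to floating-point
precision by construction; `balance_residual` audits it and every
projection in the test suite asserts a relative residual below 1e-9.
Migration timing (half at each end) and the birth-exposure convention
(start/end average) are declared conventions: the estimation framework is
agnostic about within-year timing, and these are the standard textbook
choices. Negative populations (possible under extreme emigration) are
clipped to zero with the clipped mass absorbed into deaths and a count
reported, so the audit identity survives clipping.

Backward projection (`back_project`) reverse-survives an anchor
enumeration under zero net migration. The open interval is disaggregated
with the anchor's own age shape, chosen so that a forward projection
reproduces the anchor exactly; the pre-survival birth counts implied by the
reconstructed age-0 populations are returned, making
back-projection/projection an exact inverse pair (an acceptance property).
Back-projected baselines are flagged low-confidence: the balancing model
treats the baseline as measured with substantial error (prior sd 0.1 on
the relative scale) precisely because of this construction.

## Life-table graduation

Abridged period tables (<1, 1–4, then 5-year groups to 110+) are expanded
to single ages 0–110 (`expand_lifetable`). Two regimes:

- **Ages 0–14 and 100–110.** A per-single-age regression
  `log(1qx) = b0 + b1 log(5qx)` is fitted across a library of paired
  complete/abridged tables (`fit_qx_regression`), because childhood
  mortality has a sharply structured single-year pattern and old-age `lx`
  values are too small for stable interpolation. Predictions are rescaled
  *within each abridged group* by a single multiplier `k` solving
  `prod(1 - k qhat) = 1 - 5qx` (bisection seed, Newton-polished to 1e-15),
  so the group identity is exact. A group with `5qx = 0` expands to zeros;
  a terminal group expands to probability 1.
- **Ages 15–99.** The default graduation interpolates the *log of the
  5-year cumulative-hazard increments* `log(ΔH/5)`, `H = -log lx`, at group
  midpoints with a shape-preserving monotone cubic Hermite interpolant
  (pchip), converts back to single-year probabilities, and rescales within
  each group so the group survival ratio is exact. The more common
  alternative — a Hyman-filtered monotone cubic spline on `lx` itself — is
  available as `method = "hyman-lx"`, but it is not the default: where
  decrements are tiny (young adults in low-mortality tables) the spline's
  derivative error exceeds the decrement itself, producing single-year
  `qx` errors near 100%, while the hazard-scale graduation is nearly exact
  for Gompertz-type mortality (worst-case 20–90 error on the synthetic
  library ~0.3%, against a 2% acceptance band). Because both extremes of
  the seam (14/15 and 99/100) switch estimator, the `qx` slope may be
  discontinuous there; this is accepted.

Conventions: `1ax = 0.5` at ages 1–109; ages <1 and 110+ keep the abridged
values. Rate/probability conversion is `q = m / (1 + (1 - a) m)`. Fatal
discontinuities are added as group-constant death *rates* on the converted
scale (`add_shock_rates`), capping at probability 1 with a warning. A
zero-mortality table yields survivorship ratios of exactly 1, including
the open interval (handled as the limit of infinite terminal person-years).

## Census preparation

Completeness is modelled from post-enumeration surveys on a scaled-logit
scale, `logit(c / 1.05) ~ SDI`, so mild overcounts (up to the 1.05
ceiling) are representable and predictions are capped at 1.02 — whether
published models admit predicted overcounts is not documented, so a small
allowance is made. The coefficient variance-covariance matrix is stored
for uncertainty propagation. The age pattern of enumeration is a
penalized cubic-spline meta-regression (`mgcv::gam`) of age-specific
completeness ratios with inverse-variance weights, normalised to mean 1 —
a desk-scale stand-in for a full Bayesian meta-regression tool, playing
the same role (one smooth global age pattern). Adjusted counts are
`raw / (completeness x age multiplier)`; high-SDI censuses with their own
survey use the nationally reported value; low/middle-SDI censuses have
their under-5 counts flagged out of the balancing likelihood, since young
children are systematically underenumerated there.

Age heaping is scored with the Whipple index and the UN age-sex accuracy
joint score (3 x sex-ratio score + both age-ratio scores). Thresholds for
choosing a correction — none below 20, Arriaga to 40, Arriaga-strong
above, Feeney for single-year data with Whipple over 105 — follow UN
accuracy-index conventions, since the scoring rule itself does not come
with cutoffs. The Feeney-type correction iteratively removes the excess at
each multiple of five measured against a 4-point Lagrange interpolation of
the non-heaped neighbours (exact for cubics, so smooth inputs are fixed
points to better than 1e-6), redistributing with double weight to
immediate neighbours, damped by 0.5 per sweep, converged when the maximum
excess falls below 1e-8 of the total; totals are conserved exactly and
moves are capped to keep counts nonnegative. The Arriaga split re-derives
5-year groups from 10-year totals with the standard interior weights
`(2 younger + 11 this - older)/24` and two-point linear-density endpoint
splits; the strong variant first smooths the 10-year totals with a centred
moving average, rescaled to preserve the overall total.

## Fertility

Rates are births per woman-year internally; the factor 1000 appears only
at I/O — this removes an entire class of unit bugs.

**Stage 1** (`fit_stage1`). The 20-24 group gets a log-linear prior on
mean schooling (intercept-only without a covariate); every other group's
prior is a natural cubic spline of the *estimated* 20-24 rate plus the
schooling term (dropped in the high-income super-region). The spline knot
marking the 30+ fertility upturn defaults to a 20-24 rate of 0.1 per
woman; if the observed 20-24 range does not straddle it, the knot falls
back to the in-sample median (an ill-placed exterior knot makes the basis
ill-conditioned). Source bias is estimated as fixed effects on cells
(group x year) observed by more than one source, with the reference source
as baseline (reference cascade: flagged source, else vital registration,
else complete birth histories; unresolvable references are an error
listing candidates), and all data are shifted to the reference level.
Residuals from the prior are smoothed with a tricube local mean and
refined by Gaussian-process regression over time with a Matern-5/2 kernel.
Data variance is the sampling variance (relative scale, floored at 1e-8)
plus a non-sampling variance estimated by a second-difference noise
estimator on the year-mean residual series — insensitive to the smooth
signal, so dense exact data are interpolated (to ~0.2%) while noisy data
are shrunk. The GP amplitude is the median-absolute-deviation scale of
the residual signal; hyperparameters follow a three-tier data-density
rule (30+ data years: window 3, length-scale 4; 10–29: 10/12; fewer:
20/20) standing in for unavailable density scores. With one location the
spatial dimension degenerates and smoothing is time-only. Draws come from
the GP posterior covariance (eigendecomposition, negative eigenvalues
floored at zero) and are multiplicatively recentred so the draw mean
equals the point estimate.

**Stage 2** (`split_aggregates`, `fit_final`). For each summary-birth-
history cohort the ratio of observed children ever born to the stage-1
implied cohort cumulative fertility (integrated along the cohort diagonal
from age 10 to the survey date, single ages, group-constant expansion)
scales the stage-1 rates into period pseudo-points at every 5-year lag
where the cohort occupies one group. Splitting is exactly linear in the
observed value, and a truth differing from stage 1 by a constant factor is
recovered exactly. Total-births records are split by stage-1 age shares
(requiring female population to convert to rates). The final fit re-runs
the stage-1 machinery on the augmented data; with no aggregate data it is
bit-identical to stage 1.

**Extreme ages.** `log(ASFR[10-14]/ASFR[15-19])` is regressed on
`ASFR[15-19]`; the 50-54 to 45-49 ratio is a constant — no covariate
predicts its variation. **Sex ratio at birth** is a GP over time on the
proportion male around a time-invariant prior of 1.05 males per female
(0.5122 as a proportion); the GP amplitude comes from the data's deviation
scale with a 0.005 floor, so a late ramp (e.g. to 1.17) is tracked while
no data returns exactly the prior.

## The balancing model

`fit_map` maximises a log posterior with three parts: a Gaussian
likelihood of log adjusted census counts around log model counts,
aggregated to the census age groups, with the age-dependent variance
schedule (inflated x2 below age 5, flat to 44, log-sd growing at 0.03 per
year of age after 45 — age misreporting grows with age); a Gaussian prior
(sd 0.1) on relative baseline deviations; and a mean-zero AR1(age) x
AR1(time) prior on migration-rate knots.

Two deliberate reformulations keep this exactly solvable at desk scale.
First, migration is parameterized as *rates at knots* (default spacing 2
years of age x 2 calendar years, bilinear interpolation) but converted to
counts against a fixed zero-migration reference projection of the initial
baseline — so model counts are *exactly linear* in all parameters, the
design matrix is assembled from unit-perturbation runs of the projection
engine itself (guaranteeing the fitted trajectory is bit-identical to a
fresh `ccmpp_project` of the fitted baseline and migration), and BFGS with
analytic gradients converges in seconds. The prior remains a prior on
rates. Second, posterior spread is *not* taken from this fit: uncertainty
comes from the out-of-sample module, so a Laplace approximation around the
MAP is unnecessary. The fit errors if the optimizer fails to improve on
the initialization; with no censuses it returns the prior mode (baseline
unchanged, zero migration).

Prior defaults were chosen by the package's own synthetic sensitivity
runs: `rho_age = 0.9`, `rho_time = 0.95`, `sigma_mig = 0.05` per
capita-year. Weak time correlation (0.7) leaves the between-census
migration path under-regularized; 0.95 recovers smooth migration surfaces
nearly exactly (RMSE ~4% of the true signal sd) while still tracking a
decade-long episode (pointwise correlation ~0.95). A structural limit is
acknowledged: with censuses 15 years apart, the *within-period timing* of
migration is weakly identified and is resolved by the prior; pointwise
errors concentrate at sharp onsets/offsets of migration shocks, while
cumulative and age-profile recovery remain accurate. The known
deaths-versus-emigration trade-off is resolved by the mean-zero migration
prior, not by data.

Age misreporting at old ages is handled by model versions: each candidate
excludes census counts above a maximum age, and `select_version` picks the
highest maximum age among versions within 0.005 of the best in-sample
log-space R-squared whose mean absolute migration rate above age 55 stays
under 0.01 per year, falling back to the best R-squared.

## Uncertainty

`oos_holdout_errors` drops one census at a time, refits, and records the
relative error of the predicted total against the held-out adjusted total
plus the gap to the nearest remaining census. Pooled absolute errors
(scaled by sqrt(pi/2) to a normal sd) are fitted by isotonic regression in
the gap — monotone nondecreasing by construction, with no parametric
form imposed. The completeness-model contribution is a delta-method
propagation of the coefficient variance-covariance. `population_draws`
draws one relative error per location-year (normal, truncated at -0.9 to
keep counts positive, mean zero — symmetric because no bias correction is
attempted), fully correlated across ages within the year, 1000 draws by
default, with 95% intervals from the 2.5th/97.5th percentiles; in
registry years only the completeness term applies.

## The synthetic generator: what it does and does not emulate

`make_true_country` produces truth satisfying the balancing identity
exactly: a Hadwiger-type fertility schedule (default width 1.7,
calibrated so the group shares match published high-fertility schedules;
a width of 3+ concentrates fertility unrealistically), Siler mortality
(childhood exponential + Makeham + Gompertz; defaults give e0 in the
high-60s, library spread e0 ~ 49–87 and m(90) ~ 0.08–0.35, matching the
range of empirical full-period tables), an age-peaked migration surface
with optional box shocks and smooth raised-cosine episodes, constant sex
ratio at birth 1.05, and a linear development-index path. Observation
operators add: completeness logistic in the development index floored at
0.85 with a U-shaped age deficit (under 5 and over 65); total-preserving
terminal-digit heaping (immediate neighbours send a fraction h, second
neighbours h/2); old-age exaggeration (a share of counts at 60+ reported
five years older); multiplicative source bias and lognormal noise on
fertility sources (defaults: vital registration 3%, complete birth
histories 7%, summary birth histories 10% — the noise law for
birth-history data is not documented anywhere, so these are the package's
own choices, lognormal to keep rates positive).

What passing tests therefore show: the estimators recover truth generated
*under the model family they assume* (smooth hazards, smooth migration,
unbiased-in-aggregate completeness). What they do not show: robustness to
de-jure/de-facto mismatches, conflict-driven disruptions, correlated
multi-country structure, or misspecified noise laws in real surveys.
Problem sizes in the tests (30–50 year spans, 3x3 or coarser knot grids,
single synthetic locations, 50 coverage replicates) were chosen as the
smallest sizes at which the statistical claims are meaningful.

## Degenerate inputs and tie-breaks

Zero-mortality tables give unit survivorship (infinite terminal
person-years handled as a limit); zero-fertility scenarios give pure age
shifts; empty likelihoods return prior modes; all-identical PES SDI,
outliered censuses, zero age-ratio denominators, proportions male outside
(0,1), and positive children-ever-born with zero implied fertility are
errors, not silent results. Censuses at non-integer dates are assigned to
the nearest mid-year. De-jure counts are treated as de-facto (the standard
assumption), with the flag carried for provenance.

## Limitations

- Single-location estimation: the spatial dimension of the fertility
  smoother degenerates to time-only smoothing unless a hierarchy is
  supplied; borrowing strength across countries is out of scope.
- No global zero-net-migration constraint: the net global migration sum is
  a diagnostic only.
- Within-period migration timing between censuses is prior-driven (see
  above); pointwise migration error bands should be read accordingly.
- The uncertainty model assumes complete correlation of errors across ages
  within a location-year and independence across locations.
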