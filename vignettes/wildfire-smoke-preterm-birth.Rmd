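---
title: "Wildfire smoke PM2.5 and preterm birth: models, metrics and the synthetic test bed"
author: "smokeptb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wildfire smoke PM2.5 and preterm birth: models, metrics and the synthetic test bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smokeptb)
```

## The problem

Wildfire-derived PM2.5 is episodic: long stretches of zero exposure broken
by multi-day smoke events whose daily concentrations can be an order of
magnitude above background. Studying its association with preterm birth
(delivery before 37 completed weeks, i.e. gestational age < 259 days from
conception) therefore requires exposure summaries that capture intensity
(threshold-exceedance *smoke days*), duration (consecutive-day *smoke
waves*) and timing (weekly and cumulative windows over gestation), and a
survival framework that compares each delivering pregnancy only against
pregnancies still at risk at the same gestational week.

The individual-level cohort data used in such studies are restricted, so
this package ships a synthetic cohort generator with a *known*
discrete-time hazard. Everything downstream of raw data — exposure
windowing, cohort rules, person-period expansion, mixed-model fitting,
imputation, pooling — is validated against that known truth.

## Exposure metrics and their conventions

A pregnancy's daily exposure vector is built by linking each gestational
day (day 0 = conception; week $w$ covers days $7w..7w+6$) to the wildfire
PM2.5 value of the census tract of residence on that date, through the
half-open residential-history intervals. Two conventions matter:

* **Threshold rules.** "Any smoke" is strict (`> 0` on the stored value,
  no epsilon; the generator emits exact zeros on non-smoke days), while
  the intensity thresholds 2.5, 5.0 and 10.0 µg/m³ are inclusive (`>=`).
* **Wave counting.** A wave of duration $d$ is a *maximal run* of
  consecutive qualifying days with length $\ge d$; one 5-day run counts
  once at each of $d = 2, 3, 4$. This at-least-$d$ convention makes wave
  prevalence monotone non-increasing in duration, matching how published
  prevalence tables behave; the alternative (mutually exclusive
  run-length bins) would not be monotone. Both the chosen rule and the
  enumeration it must match are unit-tested against a brute-force oracle,
  so switching convention would be a one-line change with an immediate
  test signal.
* **Residential gaps.** Gaps in the address history up to `max_gap = 7`
  days carry the last tract forward; longer or leading gaps are linkage
  errors naming the first uncovered date. Trimesters are weeks 0–12,
  13–26, 27–delivery; both choices are conventions the data do not
  dictate, fixed here and documented.
* **Partial weeks.** Week-specific counts exist only for fully covered
  weeks, and cumulative metrics at week $w$ use days $0..7w-1$ — exposure
  *before* the week at risk — so an event week's own exposure can never
  leak into its row.

## The discrete-time outcome model

The person-period table has one row per pregnancy and at-risk gestational
week 22–36 (births below 22 completed weeks are excluded with an explicit
ledger reason; term births are censored at week 36). Pooled logistic
regression then fits

$$\mathrm{logit}\, P(\text{delivery in } w \mid \text{at risk}) =
\alpha_w + \beta X_w + \gamma' Z + b_{\text{site}},$$

with week indicators $\alpha_w$, time-updated cumulative exposure $X_w$,
covariate set $Z$, and site random intercepts $b \sim N(0, \sigma^2)$.
The primary covariate set is infant sex, maternal age (natural cubic
spline, 3 df), race, Hispanic ethnicity, neighbourhood poverty rate,
season of conception, birth year (spline, 4 df) and a 2-d thin-plate
spatial smooth (10 df); the extended set adds parity, prepregnancy BMI,
tobacco, alcohol, gestational-age determination method and an
education-by-collection-stage interaction.

Numerical choices:

* Random intercepts use adaptive Gauss–Hermite quadrature (7 nodes) when
  the fixed-effect design is lean; for wide designs (more than 10
  columns) the fit switches to the Laplace approximation, because lme4
  cannot profile fixed effects out of the quadrature objective and joint
  optimisation over 30+ dimensions is both slow and fragile. The
  `nloptwrap` optimizer is used throughout; random slopes (site-level
  slope on exposure) always use Laplace.
* Generated design columns (spline bases) are standardised before
  fitting; this leaves the fitted smooths and the exposure coefficient
  unchanged but keeps mixed-model optimisation well-scaled.
* Confidence intervals are Wald on the link scale
  ($\hat\beta \pm 1.96\,\mathrm{SE}$, exponentiated for ORs).
* A fit is *flagged* rather than silently reported when the optimizer
  signals failure or the exposure standard errors are unstable. A
  zero-event week indicator drifting to $-\infty$ (benign
  quasi-separation in small samples) does not flag the fit, because it
  does not affect the reported exposure estimate.
* Reference levels: race = White, season = Winter, region = West; the
  exposure estimate is invariant to this parameterisation (tested).
* Week-window models (weeks 0–35, birth-level logistic, one model per
  week) include only births whose window closed before delivery
  (`ga_days > 7(w+1)`); weeks with zero exposure variance are skipped
  with a flag. No multiplicity correction is applied across the 36
  models — interpretation rests on the pattern across weeks, not on any
  single test.
* The gestational-age linear model fixes the exposure window at
  conception–32 weeks and excludes deliveries before 32 weeks, so every
  analysed birth has a complete window.
* Poverty tertiles for effect modification are computed within the
  analysis sample. Binary modifiers use the Wald p of the product term;
  categorical modifiers a multi-df Wald $\chi^2$ over all interaction
  coefficients.

## The synthetic generator

**Exposure process.** Each tract's daily series follows a two-state
(smoke/no-smoke) Markov chain with seasonally modulated entry probability
(sinusoid peaking mid-August) and lognormal concentrations on smoke days.
All days of one smoke run share an episode-level random effect carrying
`episode_share` of the log-scale variance; this is what lets 4-day runs
above 10 µg/m³ occur at realistic rates, as real multi-day fire episodes
have a shared severity. The closed-form stationary smoke fraction
$p_{enter}/(p_{enter} + 1 - p_{stay})$ anchors a Monte-Carlo test.
Regional multipliers reproduce the published geography (Midwest: most
smoke days; West: most intense days). Default parameters were calibrated
once against the published cohort marginals — mean 22.2 smoke days (SD
16.6), mean daily wildfire PM2.5 0.36 µg/m³, 1.8 days ≥ 10 µg/m³, 99.2%
any exposure, wave prevalence from 80.6% (2-day, ≥ 2.5) to 6.0% (≥ 4-day,
≥ 10) — and then frozen; the acceptance tests verify them at ±15%
relative tolerance on a 20 000-pregnancy cohort.

**Cohort.** Pregnancies are allocated to 30 sites of unequal (lognormal)
size across the four census regions (shares 29/18/32/21%), conceptions
uniform over Jan 2006–Mar 2020, covariates drawn to match published
published demographic marginals (age 30.6 ± 5.6, 51.2% male, 8.4%-scale preterm
mix, BMI 26.8 ± 6.6, etc.). 10% of pregnancies move once, uniformly over
pregnancy days, to another tract of the same site — the data sources
report history availability, not move rates, so this is a documented
default, not an inference.

**Hazard.** Weekly Bernoulli delivery trials at weeks 22–36 with a
piecewise-constant baseline over the severity bands (22–31, 32–33,
34–36 weeks) calibrated to split preterm incidence ≈ 1.0/0.9/6.4%;
default exposure effect OR 1.01 per cumulative smoke day; covariate
effects on centred covariates (e.g. log-OR 0.45 for Black race, 0.25 for
tobacco) chosen to reproduce the published outcome gradients; site
intercepts $N(0, 0.3^2)$, with the realised draws centred over the cohort
so the marginal preterm rate reflects the calibration rather than the
luck of 30 site draws. Survivors of week 36 draw a term week from a
documented categorical distribution over 37–42 weeks
(0.07/0.17/0.35/0.27/0.12/0.02) — the real-world term distribution is not
published in this context, so these are defaults, not estimates. Preterm
severity follows from the hazard, not from a separate severity draw.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: exposure measurement error from the upstream
spatiotemporal model, within-tract heterogeneity, informative residential
mobility, correlated covariates (draws are independent across
covariates), within-person correlation across repeated births, and any
non-proportional or lagged exposure effects beyond the injected window
effect. Parameter recovery here demonstrates the *pipeline* is correct,
not that any particular real-data estimate is.

## Imputation

Site-specific chained equations: within each site (sites under 50 records
fall back to the pooled sample with a site indicator, with a warning),
incomplete covariates are initialised from observed draws and updated by
sweeps of predictive mean matching (continuous), logistic draws (binary)
or multinomial draws (categorical), with all other analysis covariates
plus the exposure summary and the outcome as predictors — the standard
congeniality practice. Defaults `m = 10`, `max_iter = 10` are
configurable; published analyses of this design rarely report their
values. Rubin's rules combine the per-imputation fits: pooled estimate =
mean, total variance = within + (1 + 1/m) between, small-sample df, t
intervals. Observed cells are never modified, and a variable entirely
missing within a site is an error naming both.

## Problem sizes used in validation

The test suite validates at sizes chosen to give stable Monte-Carlo
behaviour while staying desk-scale: calibration on one 20 000-pregnancy
default cohort; oracle equivalence on 1 000 random vectors; IRLS
equivalence at n = 5 000; parameter recovery (true OR 1.02 per cumulative
smoke day) over 200 replicates of n = 5 000 with a 10% relative-bias
bound and coverage in [0.91, 0.98]; type-I error over 200 null replicates
of n = 2 000 (±2 Monte-Carlo SE around 0.05); critical-window
localisation over 100 replicates of n = 4 000 with an effect confined to
weeks 18–24; and MI consistency over 100 replicates of n = 1 500 with 20%
MCAR missingness. The lean replicate generator
(`simulate_replicate_cohort()`) gives each pregnancy an independent
exposure series — geography and mobility are exercised separately by the
linked-cohort tests.

## Known limitations

* The interface to real data expects gap-free tract series; upstream
  model uncertainty is not propagated.
* The week-window risk-set convention (window fully observed before
  delivery) is one of several defensible choices; it slightly conditions
  late-window risk sets on longer gestations.
* `glmmTMB`-style fast quadrature alternatives are not wired in; very
  wide random-slope models can be slow.
* The generator's covariates are mutually independent, so it cannot be
  used to study confounding *strength* — only estimator correctness under
  known effects.
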