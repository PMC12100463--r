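---
title: "Estimating lifetime SVAC prevalence: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating lifetime SVAC prevalence: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind `svacprev`, the
assumptions it relies on, the tunable parameters and their defaults,
what the synthetic-data generator does and does not emulate, and the
design decisions taken where the methodology was genuinely open.

## The estimation problem

The target is the lifetime prevalence of sexual violence against
children (SVAC) — contact sexual violence experienced before age
18 — by country, calendar year, five-year age group, and sex. The
available data are source-level survey estimates that differ in case
definition, interview mode, age grouping, and coverage, and are absent
entirely for many countries. Two structural facts make estimation
tractable:

* **Boundedness.** A lifetime proportion lives in (0, 1), so every
  adjustment and regression stage operates on `logit(p)`. Observed
  proportions of exactly 0 or 1 are offset to `0.5/n` and `1 - 0.5/n`
  (`n` = sample size, 100 when unknown) so the logit stays finite with
  minimal distortion.
* **Cohort stability.** Exposure accrues only before age 18, so
  within a birth cohort the lifetime prevalence is fixed once the
  cohort is past the childhood window. This licenses the cohort
  extrapolation step and is built into the synthetic truth surface
  exactly.

## Pipeline stages

### Case-definition crosswalk

Sources reporting an alternative definition (non-contact forms
included; intercourse only; childhood window closed at 16 or 12) are
mapped onto the reference definition with a logit-scale offset per
definition tag. Offsets are estimated from within-study pairs — the
same source reporting the same (location, year, sex, age) cell under
two definitions — as the inverse-variance-weighted mean of the paired
logit differences, after iterative trimming: fit, drop the largest
absolute standardised residual, refit, until a `trim_fraction`
(default 0.1) of pairs is removed. Trimming makes the estimate robust
to aberrant pairs without modelling them. Tags with fewer than 5 pairs
fall back to configured prior offsets (and error if none are given);
uncertainty is propagated by adding `se(beta)^2` to the observation's
logit variance, so adjustment can only widen uncertainty. The full
Bayesian spline meta-regression machinery used in large-scale practice
is intentionally out of scope: only scalar offsets are identified by
paired data of this kind.

### Disclosure correction

Face-to-face interviews under-elicit disclosure relative to
confidential self-reports. From studies observing both modes in the
same population, the confidential logit prevalence is regressed
(ordinary least squares) on the face-to-face logit prevalence, and the
fitted line transforms face-to-face observations onto the confidential
scale, with the residual variance added to the observation's logit
variance. The scale of this transform and whether its uncertainty is
propagated are not settled questions; logit-scale OLS with
residual-variance inflation is this package's choice, made so that the
stage's output stays in point + variance form.

### Age splitting and cohort extrapolation

Observations spanning several canonical five-year groups are split
using a relative age pattern estimated from single-group observations
(inverse-variance-weighted group means divided by the grand mean,
renormalised to mean 1, data-free groups imputed at 1). The split is
constructed so the population-weighted mean of the children equals the
parent exactly; child SEs are `se * sqrt(rel_g / sum(w rel))`, floored
at `se / sqrt(|G|)`, which roughly conserves the parent's information.
The SE rule is this package's choice — nothing in the data identifies
it — and it is deliberately simple.

Each single-group adult observation (ages 20-24 and older) is then
copied along its birth-cohort diagonal in 5-year steps, both
directions, while the shifted year stays in the estimation window and
the shifted group within ages 20 to 95+. Copies keep the observed mean;
their standard error is multiplied by `extrapolation_se_factor`
(default 2). We read the published "uncertainty inflated by a factor
of 2" as doubling the standard error — the conservative reading — and
expose the factor as configuration rather than reproducing the
sensitivity analysis that selected it. The youngest modelled group
(15-19) is modelled but never extrapolated: its childhood window is
incomplete, so its prevalence is not yet a cohort constant.

### Three-stage ST-GPR

1. **Linear prior.** A weighted linear model on the logit scale,
   pooling both sexes: fixed effects for sex, age group, and a linear
   year trend, with nested region and super-region random intercepts
   shrunk by `lme4::lmer`. Pooling lets the global female:male ratio
   inform the prior for data-sparse strata; countries without data
   inherit their region and super-region effects. Degenerate inputs
   fall back to a weighted fixed-effects model (aliased terms dropped
   with a warning) and ultimately to a constant surface.
2. **Spatiotemporal residual smoothing.** Each grid cell adds a
   weighted mean of observation residuals, with separable weights:
   space `zeta` / `zeta(1-zeta)` / `zeta(1-zeta)^2` for own country /
   region / super-region, age `exp(-omega |dindex|)`, and time
   `(1 - (|dt|/(1+max_dt))^lambda)^3` with `max_dt` the window span.
   Sexes are smoothed separately; cells with zero total weight keep
   the prior.
3. **Gaussian process.** Per (country, age group, sex) series over
   time, an exact GP posterior with prior mean equal to the stage-2
   surface, Matern nu = 3/2 kernel with length-scale `gpr_scale`
   years, conditioned on the series' observations with noise variance
   equal to the delta-method logit variance times the squared
   extrapolation inflation — extrapolated copies are thereby
   down-weighted exactly as intended. `n_draws` (default 1000) joint
   posterior draws per series are generated by Cholesky factorisation
   and mapped through the inverse logit, so all draws stay in (0, 1).

**Amplitude calibration.** The GP amplitude is
`amplitude_mad_mult * 1.4826 * MAD(residuals)`, floored at
`amplitude_floor`. Two residual pools are used, and the distinction
matters. In-sample stage-2 residuals are shrunk toward zero by the
smoothing itself and badly understate prior uncertainty, so the
amplitude for series whose country has data uses *leave-one-source-out*
residuals: each observation against the stage-2 value computed without
any row of its own source (the row itself, its extrapolated copies,
split siblings, and within-study twins share noise or provenance).
Series in countries that contributed no same-sex data face an
additional error component — the between-country spread that no
within-country residual can reveal — so their amplitude is estimated
from *leave-one-country-out* residuals instead. This is the estimator
matching its prior variance to the prediction geometry; the test suite
checks the resulting 95% intervals cover the synthetic truth at close
to nominal rates in both strata.

### Holt damped-trend smoothing

In (location, sex) series with no direct observations the GP reverts
to its prior, and residual smoothing can still transmit implausible
short-term wiggles for what is, within a cohort, a constant. Flagged
series (default: zero non-extrapolated observations; threshold
configurable) have every draw trajectory replaced by its damped-trend
smoothed version on the logit scale: the standard recursions
`level_t = alpha y_t + (1-alpha)(level_{t-1} + phi b_{t-1})`,
`b_t = beta(level_t - level_{t-1}) + (1-beta) phi b_{t-1}` are run
forward and on the reversed series, and the two level sequences
averaged — forecasting and backcasting follow
`level + (phi + ... + phi^h) b`, which converges to
`level + phi/(1-phi) b`. Defaults `alpha = 0.3`, `beta = 0.1`,
`phi = 0.9` are conventional smoothing values; whether such smoothing
should apply to all locations or only data-free ones is exposed
through the flagging threshold.

### Post-processing

Age-standardisation is the weighted sum of age-specific prevalence
draws over groups 20 and older, with standard-population weights
renormalised over the groups present; the packaged weight file is a
synthetic stand-in and users should substitute their preferred
standard. Aggregation up the hierarchy is the population-weighted mean
of child draws, draw-index aligned so correlation survives;
associativity (country to region to global versus country to global
directly) holds to machine precision. Summaries are the draw mean and
the 2.5th/97.5th percentiles under the type-7 (linear interpolation)
quantile definition, fixed for reproducibility. Changes over time are
computed per draw and then summarised, preserving between-year
correlation.

### Age at first experience

Survey microdata (DHS: female respondents; VACS: both sexes) are
filtered to respondents who ever experienced sexual violence and
reported a plausible age at first experience: present, non-negative,
and not greater than the respondent's age — equality is plausible and
kept, and all thresholds are strict ("before age 18" means
`age_first < 18`). The analysis windows are ages 15-24 (DHS) and 13-24
(VACS). DHS modules with strictly more than 50% missingness in the
age-at-first variable among ever-exposed respondents are dropped
whole; missingness of exactly 50% retains the module, and VACS modules
are never dropped by this rule. Distributions are unweighted counts of
first experiences before ages 12, 16, and 18 by sex, series (plus a
pooled aggregate), and region (plus all data). Diagnostics report the
Pearson correlation between respondent age and reported age at first
experience and the missing-versus-non-missing contrasts in age,
education, urbanicity, and sex, with standard errors and no decision
rule; missing values are never imputed.

## The synthetic-data generator

The generator is first-class, tested code: it defines the conditions
under which every recovery test operates.

* **Truth surface.** `eta` = global intercept + sex offset + nested
  super-region/region/country Gaussian intercepts + a smooth cohort
  trend (linear plus sinusoid in birth cohort) + a negative offset for
  the incomplete 15-19 group. Because `eta` depends on time only
  through the cohort, cohort stability holds exactly by construction.
  Default grid: 12 countries in 3 regions and 2 super-regions, years
  1990-2023, age groups 15-19 through 65-69 — desk-scale sizes chosen
  so the full pipeline and its tests run in minutes; the full
  204-country grid is available through configuration.
* **Observations.** Each source draws a cell and reports
  `expit(eta + definition offset + mode offset + noise)`; the
  published definition offsets (+0.434, -0.426, -0.455, -1.279) are
  used as the generator's true values, the face-to-face gap is -0.3,
  and the logit noise SD is 0.12 with the reported SE consistent with
  it via the delta method. Around half of alternative-definition
  sources also report a reference-definition twin of the same cell
  (and face-to-face sources a confidential twin), providing the
  within-study pairs the crosswalk and disclosure fits need; three
  countries receive no data at all. A ledger records the true `eta`
  and every applied offset per observation.
* **Microdata.** Age at first experience follows a Beta distribution
  (per sex) discretised over ages 5-23 and truncated at the
  respondent's age; respondent ages are uniform in the series window.
  Missingness is 0.15 with a +0.10 male excess; 2% of non-missing
  values are corrupted to implausible ones. `aafe_design_cdf()`
  computes the exact marginal CDF implied by this design (averaging
  the truncated distributions over the respondent-age mixture), which
  is what recovery tests compare against. The ledger keeps the
  uncorrupted values.

What the generator does **not** emulate: non-sampling error that is
correlated within survey series, informative missingness, survey
design weights, differential mortality by exposure, subnational
heterogeneity, and real-world definition drift within a source.
Passing recovery tests therefore demonstrates that the pipeline undoes
the biases it models, on data satisfying its assumptions — not that
real-world estimates carry no residual bias.

## Numerical choices

* GP linear algebra uses dense `solve`/`chol` per series (at most a
  34 x 34 system), with escalating diagonal jitter (1e-8 to 1e-4)
  before failing on non-positive-definite covariance.
* Draw generation uses one seed substream per series, ordered by
  (location, age, sex), so results are independent of iteration order
  and reproducible bit-for-bit from a single root seed.
* The Holt recursions initialise `level_1 = y_1`,
  `b_1 = y_2 - y_1`, which makes constant and exactly-linear series
  fixed points of the filter.
* The trimming loop removes `floor(trim_fraction * n)` pairs one at a
  time, refitting between removals; ties are broken by first maximum.
* Inclusion-filter reasons are reported in the fixed priority order
  population-based, representative, self-report when several fail.

## Problem sizes in the test suite

The suite and the acceptance script use the default shrunk grid (8976
cells, roughly 150 source observations growing to about 650 rows after
splitting and extrapolation, 264 GP series, 1000 draws), 500 crosswalk
pairs per definition tag, 50 paired-mode studies, and 5000 microdata
records per survey series — sizes at which every stage's recovery
target is statistically identifiable while the whole suite runs in a
few minutes on one CPU.

## Known limitations

* The crosswalk assumes one tag per observation; combined-definition
  sources are out of scope.
* Stage-1 effects for age and region enter as unpenalised fixed and
  shrunk random intercepts respectively; no spline in age or year.
* The smoothing hyperparameters (`zeta = 0.9`, `lambda = 0.5`,
  `omega = 0.5`, `gpr_scale = 10`, `amplitude_mad_mult = 1`) are
  conventional defaults, exposed in `stgpr_config()`; no out-of-sample
  selection machinery is provided.
* Aggregated (regional and global) intervals on synthetic data are
  narrow because country draws are independent; real applications with
  correlated country errors would be wider.
* No survey-design weighting anywhere; the age-at-first distributions
  are unweighted by design.
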