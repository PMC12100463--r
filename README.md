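# svacprev

Estimation of the lifetime prevalence of sexual violence against
children (SVAC) — contact sexual violence experienced before age 18 —
by country, year, five-year age group, and sex, from heterogeneous
survey data.

Population surveys measure SVAC under incompatible case definitions
(some include non-contact violence, some count intercourse only, some
close the childhood window at 16 or 12 rather than 18), under
interview modes with different disclosure (face-to-face interviews
elicit fewer disclosures than confidential self-reports), over wide
age bins, and only in some countries and years. `svacprev` implements
a full harmonisation and estimation pipeline for this setting, plus an
analysis of the reported age at first experience. It is aimed at
epidemiologists and global-health modellers who need a transparent,
testable implementation of every step.

## The model

All modelling is on the logit scale, `eta = logit(p)`, which respects
the (0, 1) bound of a lifetime proportion. The stages are:

1. **Inclusion filter** — keep observations that are population-based,
   representative, and self-reported.
2. **Case-definition crosswalk** — from within-study pairs reporting
   the same population under the reference and an alternative
   definition, estimate a logit offset `beta_d` per definition `d` by
   inverse-variance-weighted meta-regression with iterative trimming
   of the largest standardised residuals; adjust
   `logit(p') = logit(p) - beta_d`, adding `se(beta_d)^2` to the logit
   variance.
3. **Disclosure correction** — regress confidential logit prevalence
   on face-to-face logit prevalence across paired-mode studies and
   linearly transform face-to-face observations onto the confidential
   scale.
4. **Age processing** — observations spanning several five-year groups
   are split by the observed age pattern (conserving the
   population-weighted mean exactly); because lifetime exposure is
   fixed after age 18, each adult observation is carried along its
   birth-cohort diagonal in 5-year steps (ages 20–24 and up), with the
   standard error of each carried copy doubled.
5. **ST-GPR** — a three-stage spatiotemporal Gaussian process
   regression: (i) a pooled weighted linear prior (sex, age group,
   year, nested region/super-region intercepts), (ii) residual
   smoothing with separable space x age x time weights,
   (iii) per-series exact GP conditioning (Matern 3/2 kernel) on the
   observations with their full logit variance, producing 1000
   posterior draws per cell.
6. **Holt damped-trend smoothing** — draw trajectories of data-free
   (location, sex) series are smoothed with damped-trend exponential
   smoothing to remove implausible time trends.
7. **Post-processing** — direct age-standardisation over ages 20+ with
   standard-population weights, population-weighted aggregation up the
   location hierarchy (draw-index aligned), and summaries as the draw
   mean with a 95% uncertainty interval (2.5th/97.5th percentiles).

A synthetic-data module generates a known truth surface with the full
bias structure (definition offsets, disclosure gap, wide bins, sparse
countries) and survey microdata with sex-differential missingness, so
every stage is validated by parameter recovery against a ledger of
applied corruptions.

## Worked example

```r
library(svacprev)

sim <- svac_simulate(truth_config(), seed = 7, out_dir = tempfile())
res <- svac_run(sim$observations$obs, sim$truth$hierarchy,
                sim$truth$population,
                microdata = sim$microdata$records,
                crosswalk_prior = c(noncontact_included = 0.434,
                                    intercourse_only = -0.426,
                                    before_16 = -0.455,
                                    before_12 = -1.279),
                seed = 7)
print(res)
```

```
SVAC prevalence estimation results
              stage rows
              input  146
   inclusion_filter  146
          crosswalk  146
         disclosure  146
          age_split  180
 cohort_extrapolate  659
          gpr_draws 8976
     holt_smoothing    6
   age_standardised 1224
       aafe_records  846

Global age-standardised prevalence (ages 20+), 2023 :
  female 20.7% (95% UI 19.9-21.4)
  male   15.1% (95% UI 14.5-15.7)
```

The manifest lists each stage with its output row count: 146 simulated
source observations survive the inclusion filter, age-splitting takes
the table to 180 single-group rows, cohort extrapolation to 659 rows
(the extra rows are carried copies with doubled SE), and the GP stage
produces draws for all 8976 grid cells; 6 (country, sex) series had no
direct data and were Holt-smoothed. The headline block is the
population-weighted global aggregate of the age-standardised draws —
on synthetic data these numbers reflect the simulated truth surface,
not any real population.

The fitted adjustment models and the 1990-to-2023 change are in the
result object:

```r
print(res$crosswalk)
```

```
Case-definition crosswalk (trimmed IVW, trim = 0.1 )
                       beta     se pairs estimated
noncontact_included  0.5556 0.0566     9      TRUE
intercourse_only    -0.3454 0.0693     6      TRUE
before_16           -0.4759 0.0693     6      TRUE
before_12           -1.2790 0.0000     0     FALSE
```

With only 146 sources the simulation yields few within-study pairs, so
the recovered betas are noisy and `before_12` (under 5 pairs) falls
back to its configured prior offset — exactly the behaviour intended
for sparse real data. `res$change_20_24` holds the per-draw
1990-to-2023 difference for ages 20-24, and `res$aafe$distribution`
the percentage of first experiences before ages 12/16/18 by sex,
survey series, and region.

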