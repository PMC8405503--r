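# ft4pop

Population modelling of free thyroxine (FT4) dynamics in newborns and
infants with congenital hypothyroidism (CH) under levothyroxine (LT4)
replacement therapy.

## Who this is for

Pharmacometricians and clinical researchers analysing longitudinal FT4 /
TSH / weight / dose records from treated CH infants — in particular
retrospective multi-center cohorts in which every FT4 measurement carries
its own assay-specific laboratory reference range, so that raw values from
different centers and assay generations are not directly comparable.

## What it does

**1. Time-dependent reference-range normalization.** Each measurement
`x_meas` with assay range `(r_low, r_up)` is mapped onto a postnatal-age
dependent target range `(r_low^Std, r_up^Std)` by blending two classical
normalizers over time since treatment start:

```
scale:           x_norm = x_meas * r_up^Std / r_up
location-scale:  x_norm = (x_meas - r_low) * (r_up^Std - r_low^Std) / (r_up - r_low) + r_low^Std

blended(t) = (t/ts) * location_scale + (1 - t/ts) * scale   for t <= ts
           = location_scale                                  for t >  ts
```

with `ts = 150` days: FT4 is right-skewed at diagnosis (the scale formula's
regime) and moves towards normality under substitution (the location-scale
regime).

**2. A population pharmacokinetic model of FT4.** One-compartment oral
absorption with residual endogenous T4 production and weight-dependent
volume:

```
dA_B/dt = In(t_j, dose_j, F) - ka * A_B          A_B(0) = 0
dA_C/dt = ka * A_B + kendo - kel * A_C           A_C(0) = kendo / kel
C_FT4   = 0.3 * A_C / V(W)                       V(W) = fV * (W / W_Ref)^betaW
```

(`ka = 20`/day, `kel = 0.1`/day and `F = 0.6` fixed; doses converted to
nmol/day with factor 1.29). `fit_ft4()` estimates `kendo`, `fV`, `betaW`,
their log-normal inter-individual variabilities and the proportional
residual error by maximum marginal likelihood (vectorized Laplace inner
solver, adaptive Gauss–Hermite reported likelihood), with covariate and
TSH-feedback machinery, likelihood-ratio model comparison, empirical Bayes
estimates, goodness-of-fit tables and visual predictive checks.

**3. A synthetic multi-center cohort generator** with known ground truth
(severity classes, titrated tablet dosing, infant growth curves, TSH
normalization, a pool of 34 assay reference ranges over 4 centers), used by
the test suite for parameter-recovery and calibration experiments.

## Worked example

```r
library(ft4pop)

cohort <- generate_cohort(cohort_config(), seed = 42)
cohort$data
#> Longitudinal FT4 dataset
#>   61 subjects, 499 observation rows (494 FT4 measurements)
#>   follow-up: 0 to 764 days since treatment start
#>   severity: severe 18, moderate 17, mild 21, unknown 5

dn <- normalize_ft4(cohort$data)
#> Warning: 13 FT4 measurement(s) lack an assay reference range and were not normalized
summarize_comparison(dn)
#>           window  n median_raw q25_raw q75_raw median_norm q25_norm q75_norm  p_value
#> 1          t = 0 54       3.73     1.8    6.91        3.35     1.88     6.66 0.015179
#> 2     0 < t < 50 80      25.69    20.5   35.08       24.25    18.22    33.03 0.005947
#> 3 100 <= t < 150 40      16.97    13.5   22.36       15.71    12.86    20.11 0.000193
#> 4     last visit 59      17.15    13.5   20.81       16.64    12.38    21.39 0.714308
```

Each row compares the median [IQR] of the raw and normalized FT4 values in
a time window (days since treatment start); normalization pulls values down
because several synthetic assay ranges have inflated upper limits, the
pattern the method is built to correct. `skewness_diagnostic(dn)` shows the
distributional transition that motivates the time blend: sample skewness
1.29 at `t = 0` falling to 0.71 at the last visit, with the Shapiro–Wilk
p-value rising from 4e-07 to 0.08.

Fitting the population model to a cohort generated with identity assay
ranges (so the response is the simulated measurement itself):

```r
cohort <- generate_cohort(cohort_config(identity_ranges = TRUE), seed = 42)
fit <- fit_ft4(cohort$data, start = ft4_model())
summary(fit)
#> Population estimates (fixed effects), IIV and residual error
#>    parameter estimate       se rse_pct
#>        kendo   3.6775 0.481552  13.095
#>           fV   4.9826 0.173014   3.472
#>        betaW   0.7400 0.057101   7.716
#>  omega_kendo   0.9046 0.099030  10.948
#>     omega_fV   0.2253 0.028155  12.495
#>  omega_betaW   0.4145 0.065654  15.840
#>   sigma_prop   0.2417 0.009788   4.050
#> fixed constants: ka = 20 /day, kel = 0.1 /day, F = 0.6
#> -2LL = 3065.78; shrinkage (%): kendo 4.7, fV 11.6, betaW 21.0
#> 61 subjects, 494 observations; converged: TRUE
```

The generating truth was `kendo = 3.66` nmol/day, `fV = 4.96` l,
`betaW = 0.753`, `omega = (1.12, 0.249, 0.404)`, `sigma_prop = 0.228`:
the typical values are recovered within a few percent, the variability
components within their sampling error. `vpc(fit)` and
`goodness_of_fit(fit)` provide the model diagnostics;
`compare_models(reduced, full)` runs the likelihood-ratio test used for
covariate and TSH-feedback selection.

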