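# ipwbin

Causal dose–response estimation for continuous environmental exposures and
mortality counts, by decile-binned stabilized inverse probability
weighting.

## The problem

Large administrative cohorts (think tens of millions of elderly enrollees
followed as person-years, with deaths counted per stratum of sex, race,
age group, Medicaid eligibility, residential area and calendar year) are
the main evidence base linking chronic air pollution — PM2.5, ozone,
NO2 — to mortality. Classical inverse probability weighting for a
*continuous* exposure requires a correctly specified conditional density
of the exposure, struggles with heteroscedastic, long-tailed
concentration distributions, and produces unstable weights for outliers.

`ipwbin` implements the binned alternative:

1. **Aggregate** person-year records into strata `j` with cumulated
   deaths and person-years `n_ij`.
2. **Bin** each exposure `X` into `K` equal-person-year groups at
   weighted quantiles (deciles for `K = 10`), the lowest bin being the
   reference. The marginal probability of any bin is `1/K` by
   construction.
3. **Model the propensity** of the observed bin `i` given confounders
   `C` (the other concurrent exposures, calendar year, demographic
   variables, area-level covariates) with a gradient-boosted classifier
   (logistic loss), each stratum weighted by `n_ij`. Predictions are
   cross-fitted and the boosting size is chosen by covariate balance.
4. **Weight** each stratum by the stabilized inverse probability

   `sw_ij = P(X in i) / p_hat(i | C) = (1/K) / p_hat(i | C)`,

   constructing a pseudo-population in which bin membership is
   independent of the measured confounders.
5. **Estimate** the marginal dose–response by weighted quasi-Poisson
   regression with a person-years offset:

   `log E[deaths_j] = log n_j + beta_i 1{bin_j = i}`,

   reporting `RR_i = exp(beta_i)` versus the reference bin with Wald 95%
   intervals scaled by the estimated dispersion.
6. **Translate** a contrast of two bins into expected annual early deaths
   avoided: `N * alpha0 * ((RR_high - 1)/RR_high - (RR_low - 1)/RR_low)`.

Because real enrollment data of this kind are access-restricted, the
package ships a first-class synthetic-cohort generator
(`sim_config()` / `generate_cohort()`) with known confounding structure
and a known step-function dose–response, so every estimator property is
testable by parameter recovery.

## Worked example

```r
library(ipwbin)

cfg    <- validation_config(seed = 7, n_person_years = 2e5)
cohort <- generate_cohort(cfg)

fit <- run_pipeline(
  cohort, "pm25",
  co_exposures = c("o3", "no2"),
  confounders  = c("year", "summer_tmean", "winter_tmean",
                   "pct_poverty", "log_median_income"),
  K = 10, key_fields = c("area_id", "year"),
  control = propensity_control(nrounds = 200, eta = 0.15, seed = 7)
)
fit
```

```
<ipw_fit> exposure 'pm25'
<dose_response_curve> pm25, K = 10 bins (reference: bin 1), dispersion 1.01
 bin bin_mean_exposure    rr ci_low ci_high
   1             2.896 1.000     NA      NA
   2             4.939 0.983  0.900   1.073
   3             6.011 1.043  0.957   1.137
   4             6.884 1.111  1.021   1.210
   5             7.710 0.984  0.902   1.075
   6             8.483 1.050  0.963   1.144
   7             9.308 1.141  1.048   1.242
   8            10.210 1.162  1.069   1.265
   9            11.360 1.204  1.108   1.309
  10            13.650 1.145  1.052   1.246
balance: max |SMD| 0.548 (before) -> 0.067 (after); mean sw 1.0000
```

Reading the output: each row is one exposure decile, plotted at its
person-year-weighted mean concentration; `rr` is the mortality rate
ratio versus the lowest decile. The generating truth of this single
2×10⁵-person-year cohort rises monotonically to RR 1.2 in the top
decile; the weighted fit tracks it within its intervals (single-cohort
estimates carry per-bin standard errors of about 0.04 on the log scale —
the replicated study run by the acceptance script shows the estimator's
mean bias per bin is an order of magnitude smaller). The balance line
shows the standardized mean differences of the confounders collapsing
from 0.55 to 0.07 after weighting, with the person-year-weighted mean
stabilized weight equal to 1.

Downstream:

```r
deaths_avoided(n_person_years = 1e6, baseline_rate = 0.05,
               rr_high = 1.2, rr_low = 1.1)   # 3787.879 deaths/year
plot_dose_response(fit$curve, reference_lines = 12)  # needs ggplot2
```

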