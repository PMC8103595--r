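---
title: "Methods: decile-binned stabilized IPW for causal dose-response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decile-binned stabilized IPW for causal dose-response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ipwbin` estimates marginal dose–response relations between continuous
environmental exposures and mortality counts in open cohorts followed as
person-years. This vignette is the package's account of the method: the
model and its assumptions, the parameters that matter, what the
synthetic-cohort generator does and does not emulate, and the numerical
and design choices behind the implementation.

## 1. The estimation problem

The data are person-year follow-up records: every individual contributes
one record per calendar year of follow-up, carrying categorical
demographics (sex, race, 5-year age group, Medicaid eligibility), a
residential area identifier, the calendar year, continuous area-year
exposures (e.g. annual PM2.5 in µg·m⁻³, warm-season O3 and annual NO2 in
ppb), continuous area-year confounders (seasonal temperatures, humidity,
socioeconomic, behavioral and medical-access covariates), and a death
indicator. Records sharing all of these values are interchangeable, so
the unit of estimation is the *stratum*: the unique combination of
demographic cell × area × year, with deaths and person-years `n_ij`
cumulated (`aggregate_person_years()`).

The estimand is the marginal relative risk of death in each exposure
group versus the least-exposed group — the effect in a hypothetical
population in which exposure group membership has been made independent
of the measured confounders. Weighting by the inverse probability of the
*observed* exposure constructs exactly that pseudo-population, provided
the propensity model is correctly specified and positivity holds.

For a continuous exposure, inverse probability weighting requires the
conditional *density* of the exposure — a strong parametric commitment
that fails quietly under heteroscedasticity and produces explosive
weights in long tails, both typical of ambient pollutant concentrations.
The binned formulation trades resolution for robustness:

* the exposure is cut into `K` groups of equal person-year mass at
  weighted quantiles (`assign_exposure_bins()`, `K = 10` by default), so
  the marginal probability of every group is `1/K` by construction;
* the propensity is now a `K`-class classification problem,
  `p(i | C)`, needing no distributional form for the exposure;
* the stabilized weight of stratum `j` observed in bin `i` is
  `sw_ij = (1/K) / p_hat(i | C_j)` — the `1/K` numerator keeps the
  weight distribution centered near 1 (`stabilized_weights()`);
* the outcome stage fits, on the weighted strata, the saturated
  log-linear rate model
  `log E[deaths_j] = log n_j + beta_i 1{bin_j = i}` with a quasi-Poisson
  family and reports `RR_i = exp(beta_i)` with Wald intervals scaled by
  the estimated dispersion (`fit_outcome_model()`).

Key assumptions, none testable from the data alone: all confounders are
measured (exchangeability given `C`), every stratum has non-negligible
probability of every bin (positivity), and the propensity model is
flexible enough to capture `p(i | C)`.

## 2. Tunable parameters

| parameter | where | default | why |
|---|---|---|---|
| `K` | `run_pipeline()` | 10 (deciles) | resolution vs per-bin stability; 14 used as a robustness check |
| bin weighting | `assign_exposure_bins(weight=)` | `"person_years"` | "equal-sized groups" read as equal shares of the *population at risk*; `"strata"` (equal stratum counts) available for sensitivity |
| `nrounds`, `max_depth`, `eta`, `subsample` | `propensity_control()` | 300, 3, 0.05, 0.8 | conventional boosted-tree defaults; the *effective* size is selected, see §4 |
| `method` | `propensity_control()` | `"multinomial"` | one softmax model is internally consistent; `"one_vs_rest"` (K binary logistic GBMs, renormalized) provided as the closer reading of a per-class inverse-logit formulation |
| `nfold` | `propensity_control()` | 5 | cross-fitted propensities; `1` = in-sample fit (see §4) |
| `selection`, `balance_metric` | `propensity_control()` | `"balance"`, `"es.mean"` | boosting size chosen by covariate balance of the resulting weights |
| `floor` | `stabilized_weights()` | 1e-6 | guards against numerically zero probabilities; occurrences flagged |
| `truncate` | `stabilized_weights()` | `NULL` | no truncation by default — binning itself bounds outlier influence; optional symmetric percentile truncation is flagged when active |
| `normalize` | `stabilized_weights()` | `TRUE` | per-bin Hajek normalization, see §4 |
| `weight_mode` | `fit_outcome_model()` | `"sw"` | the stratum's population mass already enters through the offset and the `n_ij`-weighted propensity fit; `"sw_py"` multiplies by `n_ij` for frequency-style weighting |
| `baseline_rate` (α0) | `deaths_avoided()` | user-supplied | `baseline_rate_from()` offers reference-bin deaths per person-year as one defensible reading of "baseline annual mortality rate" |

## 3. The synthetic cohort generator

Real enrollment data of this kind are restricted, so estimator
correctness is established by parameter recovery on simulated cohorts
with known truth (`sim_config()`, `generate_cohort()`).

What it emulates:

* stratum-structured person-year tables (demographic cells × area ×
  year), with person-years allocated multinomially so the configured
  total is conserved exactly;
* continuous area-year confounders from configurable families (normal,
  lognormal, gamma, uniform);
* three mutually correlated exposures, each linear in confounders plus
  noise drawn through a Gaussian copula with configurable cross-exposure
  correlation; noise families include lognormal (long tails), and the
  noise scale can be a linear function of a confounder floored at a
  positive constant (heteroscedasticity);
* Poisson death counts at stratum level with
  `rate = baseline_rate * exp(true_log_rr[bin(X)] + centered confounder
  and demographic log-rate effects)`, where `bin(X)` uses the same
  person-year-weighted K-quantiles as the analysis. The confounder terms
  make the covariates true confounders (they drive both exposure and
  death rate); because they are centered and balanced by weighting, the
  marginal IPW estimand still equals `exp(true_log_rr)`.

Death counts are Poisson at stratum level rather than Bernoulli per
person: this matches the quasi-Poisson outcome model and keeps
simulation cheap. Keep `baseline_rate` at or below 0.2 per person-year;
draws exceeding a stratum's person-years are clipped with a warning.
The default baseline rate is 0.05/year, the order of magnitude of an
elderly cohort. One random stream per cohort is split into named
substreams (confounders, exposures, allocation, deaths, split), so
adding a confounder does not perturb the death draws, and generation is
bit-reproducible given the seed.

What it does **not** emulate — and what passing tests therefore do not
show about real data: spatial autocorrelation of exposures and
confounders (areas are exchangeable draws), exposure measurement error,
within-area individual heterogeneity beyond the demographic cells,
informative censoring or cohort entry/exit dynamics, and cause-specific
mortality. The exposure/covariate joint distribution is a stand-in with
realistic first and second moments, not a calibration to any particular
cohort.

`validation_config()` fixes the canonical recovery scenario:
2×10⁵ person-years over 12,000 area-years, a monotone truth rising to
RR 1.2 in the top decile, and moderate confounding (the crude top-decile
estimate is biased upward by roughly a third of the true effect). Two
choices deserve explanation. The number of area-years is what controls
the attainable post-weighting balance: the sampling noise of a
person-year-weighted SMD is roughly `1/sqrt(area-years/K)` per
confounder-bin cell, so demonstrating max |SMD| < 0.1 requires on the
order of 10⁴ independent area-year units regardless of how many
person-years they carry. And the *effect* exposure uses normal noise in
this scenario: a lognormal noise floor makes some observed bins
structurally near-impossible given the co-exposures (true weights in the
tens), a positivity violation under which even oracle weights cannot
balance a finite sample; the package's default cohort keeps the
long-tailed, heteroscedastic form.

## 4. Numerical and design choices

**Binning convention.** Strata are sorted by exposure; each distinct
value receives bin `ceiling(K × cumulative person-year fraction)`
evaluated at its last occurrence, so ties always share a bin and a value
whose cumulative mass lands exactly on a cut closes the lower bin. The
reported boundaries are the smallest value of each upper bin, so binning
new data with left-closed `[boundary, …)` intervals (values on a cut go
up) reproduces the in-sample labels (`bin_lookup()`). Bins can deviate
from `1/K` mass only by the mass of an indivisible tie block; a warning
is raised beyond `max(tie block, 1%)`. If fewer than `K` non-empty bins
are possible the operation fails with a degenerate-bin error rather than
silently merging.

**Cross-fitted propensities.** The classifier's predictions enter the
weights for the same strata it was trained on. A boosted model given a
few thousand distinct covariate patterns will memorize each pattern's
observed bin, sending every predicted probability toward 1 and every
weight toward a constant — weights that adjust nothing. Predictions for
the training strata therefore come from 5-fold cross-fitting, with folds
assigned to whole distinct patterns of the *continuous* confounders (the
exposure-assignment unit, e.g. an area-year), so demographic cells of
one area-year can never straddle the train/predict split. `nfold = 1`
restores the in-sample fit for very large data, where memorization is
not attainable.

**Boosting size by balance.** Stopping on held-out log-loss optimizes
prediction, which is dominated by the strongest signals (the
co-exposures) and can stop before the weaker confounder signal — the
part the weights exist to remove — is learned. The default instead
evaluates out-of-fold weights on a geometric grid of boosting sizes
(including size 0 = marginal shares, i.e. no weighting) and keeps the
smallest size whose confounder SMD summary (`es.mean` by default) is
within 5% of the best. The parsimony margin means an unconfounded
cohort keeps near-unit weights instead of chasing noise. This is the
balance-based stopping rule familiar from propensity-boosting practice,
applied to cross-fitted weights.

**Weight normalization.** Noisy predicted probabilities inflate
`E[1/p_hat]` above `1/E[p_hat]` (Jensen), drifting the mean raw weight a
few percent above 1. Weights are therefore normalized to
person-year-weighted mean 1 *within each bin* (Hajek). Because the
outcome model is saturated in bin, a per-bin constant cancels from every
within-bin weighted mean: point estimates are unchanged; only the weight
summaries and the dispersion bookkeeping improve. The raw mean is kept
in the weight table (`sw_raw`) and reported by the diagnostics.

**Outcome stage.** Quasi-Poisson with `offset(log person_years)` and
regression weights `sw` (default) — the stratum's mass already enters
through the offset and the `n_ij`-weighted propensity stage; `sw × n_ij`
is available as an alternative. With unit weights the factored model is
saturated, so fitted RRs equal crude per-bin rate ratios exactly (this
identity is tested to 10⁻⁸). The dispersion is Pearson χ²/df floored at
1 — underdispersion is never allowed to shrink the intervals. A bin with
zero deaths stops the fit with advice to use fewer bins. Model-based
Wald intervals ignore weight-estimation uncertainty; `bootstrap_curve()`
(resampling strata and rerunning both stages) is provided where that
matters. The replicated validation study measures the practical
consequence as empirical CI coverage rather than claiming nominal
coverage.

**Impact formula.** `deaths_avoided()` evaluates
`N·α0·((RR_high−1)/RR_high − (RR_low−1)/RR_low)` exactly as written; it
is antisymmetric in its two risks, zero at equality, and linear in `N`.
Multi-pollutant totals are plain sums — overlap between pollutants is
deliberately not modeled. α0 is an explicit input because its
operational definition (which population, which year) belongs to the
analyst; `baseline_rate_from()` implements the reference-bin rate as one
documented choice.

**Problem sizes in the test suite.** The replicated validation study
runs 50 cohorts of 2×10⁵ person-years (12,000 strata each) with a
200-round, learning-rate-0.15 boosting control — at this problem size
its selected models are indistinguishable from the slower defaults. The
binning mass check runs at 10⁵ strata; all other unit tests use cohorts
of 10³–10⁴ strata. All seeds are fixed; the whole suite is
deterministic on a single thread.

## 5. Known limitations

* Causal interpretation rests on no unmeasured confounding, which no
  diagnostic in this package can verify; balance tables only certify
  adjustment for what was measured.
* Bin-level estimates are step functions; within-bin dose gradients are
  not resolved, and the contrast of extreme bins depends on the bin
  means, which the curve reports for that reason.
* Model-based intervals understate uncertainty when weights are highly
  variable; use the bootstrap option in that regime.
* The one-vs-rest propensity variant renormalizes K separately
  calibrated probabilities; its probabilities are not jointly calibrated
  the way the softmax model's are.
* `summarize_cohort()` reports demographic composition as person-year
  shares; converting them to person counts assumes follow-up length is
  unrelated to the demographic cell, and the person count itself must be
  supplied (person identity is not recoverable from aggregated
  person-years).
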