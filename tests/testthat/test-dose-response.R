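test_that("with unit weights the factored fit is the crude rate ratio, exactly", {
  # closed-form two-bin example: 10/1000 vs 20/1000 -> RR = 2
  strata <- data.frame(pm25 = c(5, 10), deaths = c(10, 20),
                       person_years = c(1000, 1000), pm25_bin = c(1L, 2L))
  curve <- fit_outcome_model(strata, NULL, exposure = "pm25")
  expect_equal(curve$rr[2], 2, tolerance = 1e-8)
  expect_equal(curve$rr[1], 1)
  expect_true(curve$reference[1])

  # random multi-stratum fixture vs the independent summation oracle
  strata <- toy_binned_strata(K = 5, strata_per_bin = 6, seed = 7)
  curve <- fit_outcome_model(strata, NULL, exposure = "pm25")
  expect_equal(curve$rr, crude_rr_oracle(strata), tolerance = 1e-8)
})

test_that("weighted fits equal the weighted rate-ratio oracle (saturated model)", {
  strata <- toy_binned_strata(K = 4, strata_per_bin = 5, seed = 15)
  set.seed(15)
  sw <- exp(rnorm(nrow(strata), 0, 0.4))
  w <- manual_weights(strata$pm25_bin, sw, K = 4)
  curve <- fit_outcome_model(strata, w, exposure = "pm25")
  expect_equal(curve$rr, crude_rr_oracle(strata, w = sw), tolerance = 1e-8)
  # frequency-style weighting mode agrees with its own oracle
  curve2 <- fit_outcome_model(strata, w, exposure = "pm25", weight_mode = "sw_py")
  expect_equal(curve2$rr, crude_rr_oracle(strata, w = sw * strata$person_years),
               tolerance = 1e-8)
})

test_that("relative risks are invariant to rescaling deaths and person-years", {
  strata <- toy_binned_strata(K = 4, strata_per_bin = 5, seed = 31)
  c1 <- fit_outcome_model(strata, NULL, exposure = "pm25")
  strata2 <- strata
  strata2$deaths <- strata2$deaths * 7
  strata2$person_years <- strata2$person_years * 7
  c2 <- fit_outcome_model(strata2, NULL, exposure = "pm25")
  expect_equal(c2$rr, c1$rr, tolerance = 1e-9)
})

test_that("null cohorts give rate ratios within Monte-Carlo error of 1", {
  set.seed(44)
  n <- 600
  strata <- data.frame(pm25 = runif(n), person_years = round(runif(n, 500, 1500)))
  strata$deaths <- rpois(n, strata$person_years * 0.02)
  strata <- assign_exposure_bins(strata, "pm25", 5)$strata
  curve <- fit_outcome_model(strata, NULL, exposure = "pm25")
  expect_true(all(abs(curve$log_rr[-1]) < 3 * curve$se[-1]))
  expect_true(all(curve$ci_low[-1] <= curve$rr[-1] &
                  curve$rr[-1] <= curve$ci_high[-1]))
  expect_gte(attr(curve, "dispersion"), 1)
})

test_that("a bin without deaths is a clear error", {
  strata <- data.frame(pm25 = c(1, 2, 3), deaths = c(5, 0, 4),
                       person_years = 100, pm25_bin = 1:3)
  expect_error(fit_outcome_model(strata, NULL, exposure = "pm25"),
               "zero deaths.*fewer bins")
})

test_that("curves serialize losslessly to JSON and CSV", {
  strata <- toy_binned_strata(K = 4, strata_per_bin = 5, seed = 3)
  curve <- fit_outcome_model(strata, NULL, exposure = "pm25")
  jp <- withr::local_tempfile(fileext = ".json")
  write_curve_json(curve, jp)
  back <- read_curve_json(jp)
  expect_equal(back$rr, curve$rr)
  expect_equal(back$se, curve$se)
  expect_equal(attr(back, "K"), attr(curve, "K"))
  cp <- withr::local_tempfile(fileext = ".csv")
  write_curve_csv(curve, cp)
  expect_equal(read.csv(cp)$rr, curve$rr, tolerance = 1e-12)
})

test_that("the full pipeline is deterministic given the configuration seed", {
  coh <- generate_cohort(small_config(seed = 55, n_person_years = 4e4))
  run <- function() {
    run_pipeline(coh, "pm25", co_exposures = c("o3", "no2"),
                 confounders = c("summer_tmean", "pct_poverty", "year"),
                 K = 5, key_fields = c("sex", "medicaid", "area_id", "year"),
                 control = propensity_control(nrounds = 40, eta = 0.2,
                                              nfold = 2, seed = 5))
  }
  f1 <- run()
  f2 <- run()
  expect_identical(f1$curve$rr, f2$curve$rr)
  expect_identical(f1$weights$sw, f2$weights$sw)
  # and the serialized curve is bit-identical
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_curve_json(f1$curve, p1)
  write_curve_json(f2$curve, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("pipeline on an unconfounded null cohort yields a flat curve", {
  # true no-confounding null: neither the exposures nor the outcome depend
  # on the covariates, so the true weights are identically 1
  spec <- default_exposure_spec()
  for (nm in names(spec)) spec[[nm]]$coef <- spec[[nm]]$coef * 0
  spec$pm25$hetero <- NULL
  cfg <- sim_config(
    n_person_years = 1e5, n_areas = 300, n_years = 3,
    demographic_spec = list(), demographic_log_rate = list(),
    exposure_spec = spec,
    cross_exposure_correlation = diag(3), # nothing predicts the bin
    confounder_log_rate = c(summer_tmean = 0, winter_tmean = 0,
                            pct_poverty = 0, log_median_income = 0),
    true_log_rr = rep(0, 5), seed = 66
  )
  coh <- generate_cohort(cfg)
  fit <- run_pipeline(coh, "pm25", co_exposures = c("o3", "no2"),
                      confounders = c("summer_tmean", "winter_tmean",
                                      "pct_poverty", "log_median_income"),
                      K = 5, key_fields = c("area_id", "year"),
                      control = propensity_control(nrounds = 80, eta = 0.2, seed = 2))
  expect_true(all(abs(fit$curve$log_rr[-1]) < 3 * fit$curve$se[-1]))
  # under log-loss regularization the boosting shrinks toward the marginal
  # rate, so the weights concentrate near 1 when there is nothing to learn
  m <- fit_propensity(fit$strata, "pm25",
                      c("o3", "no2", "summer_tmean", "winter_tmean",
                        "pct_poverty", "log_median_income"),
                      control = propensity_control(nrounds = 80, eta = 0.2,
                                                   seed = 2, selection = "logloss"))
  w <- stabilized_weights(m, fit$strata)
  expect_lt(weighted.mean((w$sw - 1)^2, fit$strata$person_years), 0.05)
})

test_that("stage failures carry their stage label", {
  coh <- generate_cohort(small_config(seed = 3))
  expect_error(
    run_pipeline(coh, "pm25", confounders = "nope", K = 5,
                 key_fields = c("sex", "medicaid", "area_id", "year")),
    "\\[propensity\\]"
  )
})

test_that("bootstrap intervals bracket the point estimates", {
  strata <- generate_cohort(small_config(seed = 91, n_person_years = 3e4))
  binned <- assign_exposure_bins(strata, "pm25", 3)$strata
  ctl <- propensity_control(nrounds = 20, eta = 0.3, nfold = 2, seed = 9)
  bs <- bootstrap_curve(binned, "pm25", c("summer_tmean", "pct_poverty"),
                        n_boot = 8, control = ctl)
  expect_equal(nrow(bs), 3L)
  expect_true(all(bs$ci_low <= bs$ci_high))
  expect_equal(bs$ci_low[1], 1) # reference bin degenerate at 1
})
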