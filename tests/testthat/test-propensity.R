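# fast boosting settings for unit tests
fast_ctl <- function(...) {
  propensity_control(nrounds = 60, eta = 0.3, nfold = 1, ...)
}

test_that("uninformative confounders give near-marginal bin probabilities", {
  set.seed(2)
  n <- 400
  strata <- data.frame(
    pm25 = runif(n), z = 1, # constant confounder
    deaths = 0, person_years = rep(10, n)
  )
  strata <- assign_exposure_bins(strata, "pm25", 4)$strata
  m <- fit_propensity(strata, "pm25", "z", control = fast_ctl())
  P <- predict(m, strata)
  expect_equal(dim(P), c(n, 4L))
  expect_true(all(abs(P - 0.25) < 0.02)) # no splits possible on a constant
  expect_equal(rowSums(P), rep(1, n), tolerance = 1e-6)
})

test_that("a deterministic threshold assignment rule is recovered", {
  set.seed(3)
  n <- 1200
  z <- runif(n, 0, 10)
  strata <- data.frame(
    pm25 = z, # exposure IS the confounder: bins are exact z-intervals
    z = z, deaths = 0, person_years = rep(5, n)
  )
  strata <- assign_exposure_bins(strata, "pm25", 4)$strata
  m <- fit_propensity(strata, "pm25", "z",
                      control = propensity_control(nrounds = 150, eta = 0.3, nfold = 1))
  pred_bin <- max.col(predict(m, strata))
  expect_gt(mean(pred_bin == strata$pm25_bin), 0.97)
})

test_that("halving weights while duplicating strata leaves predictions unchanged", {
  set.seed(4)
  n <- 300
  strata <- data.frame(pm25 = rnorm(n), z = rnorm(n), deaths = 0,
                       person_years = runif(n, 10, 40))
  strata <- assign_exposure_bins(strata, "pm25", 3)$strata
  doubled <- rbind(strata, strata)
  doubled$person_years <- doubled$person_years / 2
  ctl <- propensity_control(nrounds = 40, eta = 0.3, nfold = 1, subsample = 1)
  m1 <- fit_propensity(strata, "pm25", "z", control = ctl)
  m2 <- fit_propensity(doubled, "pm25", "z", control = ctl)
  expect_equal(predict(m1, strata), predict(m2, strata), tolerance = 1e-6)
})

test_that("the target exposure is rejected as its own confounder", {
  strata <- toy_binned_strata()
  expect_error(fit_propensity(strata, "pm25", c("pm25", "year")),
               "cannot be one of its own confounders")
})

test_that("stabilized weights are the marginal share over the predicted probability", {
  # hand-constructed model: known probabilities, no fitting
  fake_model <- function(p_obs, bin, K) {
    P <- matrix((1 - p_obs) / (K - 1), length(bin), K)
    P[cbind(seq_along(bin), bin)] <- p_obs
    structure(list(K = K, exposure = "pm25", training_bin = bin,
                   training_prob = P, method = "multinomial"),
              class = "propensity_model")
  }
  strata <- data.frame(pm25_bin = c(1L, 2L, 1L, 2L), person_years = c(5, 5, 5, 5))
  # K = 10: p = 0.1 -> sw = 1; p = 0.05 -> sw = 2
  m10 <- fake_model(c(0.1, 0.05, 0.1, 0.05), strata$pm25_bin, 10)
  w10 <- stabilized_weights(m10, strata, normalize = FALSE)
  expect_equal(w10$sw, c(1, 2, 1, 2))
  # K = 4: uniform p = 0.25 -> sw = 1
  m4 <- fake_model(rep(0.25, 4), strata$pm25_bin, 4)
  expect_equal(stabilized_weights(m4, strata, normalize = FALSE)$sw, rep(1, 4))
})

test_that("probability floor and truncation are applied and flagged", {
  strata <- data.frame(pm25_bin = c(1L, 1L, 2L, 2L), person_years = rep(1, 4))
  P <- rbind(c(1e-9, 1 - 1e-9), c(0.5, 0.5), c(0.6, 0.4), c(0.5, 0.5))
  m <- structure(list(K = 2L, exposure = "pm25", training_bin = strata$pm25_bin,
                      training_prob = P, method = "multinomial"),
                 class = "propensity_model")
  expect_warning(w <- stabilized_weights(m, strata, floor = 1e-6, normalize = FALSE),
                 "floor")
  expect_true(w$floored[1])
  expect_equal(w$sw[1], 0.5 / 1e-6)

  wt <- suppressWarnings(
    stabilized_weights(m, strata, floor = 1e-6, truncate = c(0.25, 0.75),
                       normalize = FALSE)
  )
  expect_true(any(wt$truncated))
  expect_lt(max(wt$sw), max(w$sw))
})

test_that("normalized weights have person-year-weighted mean 1 within each bin", {
  coh <- generate_cohort(small_config(seed = 17))
  binned <- assign_exposure_bins(coh, "pm25", 5)$strata
  m <- fit_propensity(binned, "pm25", c("summer_tmean", "pct_poverty"),
                      control = propensity_control(nrounds = 40, eta = 0.2, nfold = 2))
  w <- stabilized_weights(m, binned)
  for (b in 1:5) {
    sel <- w$bin == b
    expect_equal(weighted.mean(w$sw[sel], binned$person_years[sel]), 1,
                 tolerance = 1e-10)
  }
  expect_true(all(w$sw > 0))
})

test_that("balance diagnostics match a hand-computed standardized difference", {
  strata <- data.frame(pm25_bin = c(1L, 2L), z = c(0, 1), deaths = 0,
                       person_years = c(1, 1))
  w <- manual_weights(strata$pm25_bin, c(1, 1), K = 2)
  bal <- balance_diagnostics(strata, w, "z")
  # pooled mean 0.5, pooled sd 0.5 -> each bin is (x - 0.5)/0.5 away
  expect_equal(bal$smd_before[bal$bin == 1], -1)
  expect_equal(bal$smd_before[bal$bin == 2], 1)
  # identity weights: after == before
  expect_equal(bal$smd_after, bal$smd_before)
  expect_lte(attr(bal, "ess"), sum(strata$person_years))
})

test_that("constant confounders get SMD zero with a flag", {
  strata <- data.frame(pm25_bin = rep(1:2, each = 3), z = 7, deaths = 0,
                       person_years = 1)
  bal <- balance_diagnostics(strata, manual_weights(strata$pm25_bin, rep(1, 6), 2), "z")
  expect_true(all(bal$smd_before == 0))
  expect_true(all(bal$zero_variance))
})

test_that("weighting shifts the 'after' column toward balance on a confounded cohort", {
  coh <- generate_cohort(small_config(seed = 23, n_person_years = 5e4))
  binned <- assign_exposure_bins(coh, "pm25", 5)$strata
  conf <- c("o3", "no2", "summer_tmean", "winter_tmean", "pct_poverty")
  m <- fit_propensity(binned, "pm25", conf,
                      control = propensity_control(nrounds = 150, eta = 0.2, nfold = 3))
  w <- stabilized_weights(m, binned)
  bal <- balance_diagnostics(binned, w, conf)
  expect_lt(mean(abs(bal$smd_after)), mean(abs(bal$smd_before)))
})

test_that("one-vs-rest boosted models give valid renormalized probabilities", {
  coh <- generate_cohort(small_config(seed = 29))
  binned <- assign_exposure_bins(coh, "pm25", 4)$strata
  m <- fit_propensity(binned, "pm25", c("summer_tmean", "o3"),
                      control = propensity_control(nrounds = 30, eta = 0.3,
                                                   nfold = 1, method = "one_vs_rest"))
  P <- predict(m, binned)
  expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-8)
  expect_true(all(P > 0 & P < 1))
  w <- stabilized_weights(m, binned, normalize = FALSE)
  expect_equal(w$sw, (1 / 4) / w$p_hat)
})
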