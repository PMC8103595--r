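test_that("aggregation collapses keys additively and carries covariates", {
  df <- data.frame(
    sex = c("f", "f"), area_id = c("A1", "A1"), year = c(2000L, 2000L),
    pm25 = c(8.1, 8.1), deaths = c(1, 2), person_years = c(3, 4)
  )
  # single row: identity
  one <- aggregate_person_years(df[1, ], key_fields = c("sex", "area_id", "year"))
  expect_equal(one$deaths, 1)
  expect_equal(one$person_years, 3)

  # two rows with identical keys sum
  agg <- aggregate_person_years(df, key_fields = c("sex", "area_id", "year"))
  expect_equal(nrow(agg), 1L)
  expect_equal(agg$deaths, 3)
  expect_equal(agg$person_years, 7)
  expect_equal(agg$pm25, 8.1)
})

test_that("aggregation matches a brute-force sort-and-scan tally", {
  df <- data.frame(
    sex = c("f", "m", "f", "f", "m", "f"),
    area_id = c("A1", "A1", "A2", "A1", "A2", "A2"),
    year = 2000L,
    deaths = c(1, 0, 2, 3, 1, 1),
    person_years = c(10, 20, 30, 40, 50, 60)
  )
  agg <- aggregate_person_years(df, key_fields = c("sex", "area_id", "year"))
  expect_equal(nrow(agg), 4L) # 4 unique keys
  # oracle: independent tally via tapply
  key <- paste(df$sex, df$area_id, df$year)
  akey <- paste(agg$sex, agg$area_id, agg$year)
  for (k in unique(key)) {
    expect_equal(agg$deaths[akey == k], sum(df$deaths[key == k]))
    expect_equal(agg$person_years[akey == k], sum(df$person_years[key == k]))
  }
  expect_equal(sum(agg$deaths), sum(df$deaths))
})

test_that("aggregating a split cohort restores the unsplit table", {
  cfg <- small_config(seed = 8)
  whole <- generate_cohort(cfg)
  split <- generate_cohort(cfg, rows_per_stratum = 4)
  keys <- c("sex", "medicaid", "area_id", "year")
  agg <- aggregate_person_years(split, key_fields = keys)
  o1 <- do.call(order, whole[keys])
  o2 <- do.call(order, agg[keys])
  expect_equal(agg$deaths[o2], whole$deaths[o1])
  expect_equal(agg$person_years[o2], whole$person_years[o1])
})

test_that("non-constant covariates within a key raise a named error", {
  df <- data.frame(
    sex = c("f", "f"), area_id = "A1", year = 2000L,
    pm25 = c(8.1, 9.9), deaths = 1, person_years = 2
  )
  expect_error(aggregate_person_years(df, c("sex", "area_id", "year")),
               "pm25.*not constant")
})

test_that("equal-mass binning splits four equal strata at the weighted median", {
  strata <- data.frame(pm25 = c(1, 2, 3, 4), deaths = 1,
                       person_years = c(10, 10, 10, 10))
  out <- assign_exposure_bins(strata, "pm25", K = 2)
  expect_equal(out$strata$pm25_bin, c(1L, 1L, 2L, 2L))
  expect_equal(out$bins$boundaries, 3) # cut between 2 and 3
})

test_that("binning matches the exhaustive cumulative-mass oracle", {
  set.seed(99)
  for (K in c(2, 7, 10)) {
    n <- 800
    x <- round(rlnorm(n, 2, 0.6), 2) # rounding forces ties
    w <- sample(1:50, n, replace = TRUE)
    strata <- data.frame(pm25 = x, deaths = 0, person_years = w)
    got <- assign_exposure_bins(strata, "pm25", K = K)
    expect_equal(got$strata$pm25_bin, scan_bins_oracle(x, w, K))
    expect_equal(sum(got$bins$bin_person_years), sum(w))
  }
})

test_that("bin labels are invariant to adding a constant to all exposures", {
  set.seed(5)
  strata <- data.frame(pm25 = rnorm(300, 10, 3), deaths = 0,
                       person_years = sample(1:30, 300, TRUE))
  a <- assign_exposure_bins(strata, "pm25", 10)$strata$pm25_bin
  strata$pm25 <- strata$pm25 + 100
  b <- assign_exposure_bins(strata, "pm25", 10)$strata$pm25_bin
  expect_identical(a, b)
})

test_that("degenerate exposures cannot be binned", {
  strata <- data.frame(pm25 = rep(7, 20), deaths = 0, person_years = 5)
  expect_error(assign_exposure_bins(strata, "pm25", 2), "distinct exposure")
  strata$pm25[1] <- NaN
  expect_error(assign_exposure_bins(strata, "pm25", 2), "non-finite")
})

test_that("boundary lookup sends on-cut values to the upper bin", {
  # decile boundaries in the shape of a national PM2.5 distribution:
  # 10% quantile 5.80 ... 90% quantile 13.95
  bd <- bin_definition(
    exposure = "pm25", K = 10,
    boundaries = c(5.80, 7.28, 8.23, 9.00, 9.75, 10.53, 11.41, 12.46, 13.95),
    bin_person_years = rep(1, 10), bin_mean_exposure = seq(5, 16, length.out = 10)
  )
  expect_equal(bin_lookup(bd, 5.0), 1L)   # below the 10% cut
  expect_equal(bin_lookup(bd, 14.5), 10L) # above the 90% cut
  expect_equal(bin_lookup(bd, 5.80), 2L)  # exactly on a cut: upper bin
  expect_equal(bin_lookup(bd, c(6.0, 9.0, 13.94)), c(2L, 5L, 9L))
})

test_that("bin mean exposures are person-year-weighted means", {
  strata <- data.frame(pm25 = c(8, 10, 20, 30), deaths = 0,
                       person_years = c(1, 3, 2, 2))
  strata$pm25_bin <- c(1L, 1L, 2L, 2L)
  bd <- bin_summaries(strata, "pm25", K = 2)
  expect_equal(bd$bin_mean_exposure[1], (8 * 1 + 10 * 3) / 4) # = 9.5 by hand
  expect_equal(bd$bin_mean_exposure[2], 25)

  # uniform person-years: weighted mean equals the plain mean
  strata$person_years <- 2
  bd2 <- bin_summaries(strata, "pm25", K = 2)
  expect_equal(bd2$bin_mean_exposure, c(mean(c(8, 10)), mean(c(20, 30))))

  # one stratum per bin: the mean is that stratum's exposure
  solo <- data.frame(pm25 = c(3, 9), deaths = 0, person_years = c(5, 1),
                     pm25_bin = c(1L, 2L))
  expect_equal(bin_summaries(solo, "pm25", 2)$bin_mean_exposure, c(3, 9))

  # empty bin errors
  strata$pm25_bin <- c(1L, 1L, 1L, 3L)
  expect_error(bin_summaries(strata, "pm25", K = 3), "empty bin")
})

test_that("bin definitions round-trip through JSON", {
  strata <- generate_cohort(small_config(seed = 4))
  bd <- assign_exposure_bins(strata, "o3", 10)$bins
  path <- withr::local_tempfile(fileext = ".json")
  write_bin_definition(bd, path)
  back <- read_bin_definition(path)
  expect_equal(back$boundaries, bd$boundaries)
  expect_equal(back$bin_mean_exposure, bd$bin_mean_exposure)
  expect_equal(back$K, bd$K)
})

test_that("mass is conserved and bins are near-equal under person-year weighting", {
  coh <- generate_cohort(small_config(seed = 13, n_person_years = 6e4))
  out <- assign_exposure_bins(coh, "pm25", 10)
  expect_equal(sum(out$bins$bin_person_years), sum(coh$person_years))
  shares <- out$bins$bin_person_years / sum(out$bins$bin_person_years)
  tie_block <- max(rowsum(coh$person_years, coh$pm25)) / sum(coh$person_years)
  expect_true(all(abs(shares - 0.1) <= tie_block + 1e-12))
})
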