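# Shared fixtures, built in code.

# A tiny deterministic stratum table with K bins already assigned:
# bin b holds `strata_per_bin` strata with deaths/person-years giving a
# known crude rate ratio pattern.
toy_binned_strata <- function(K = 5, strata_per_bin = 4, seed = 42) {
  set.seed(seed)
  n <- K * strata_per_bin
  bin <- rep(seq_len(K), each = strata_per_bin)
  py <- round(runif(n, 200, 1500))
  rate <- 0.01 * (1 + 0.15 * (bin - 1))
  deaths <- rpois(n, py * rate)
  deaths[deaths == 0] <- 1 # keep every stratum informative
  df <- data.frame(
    area_id = sprintf("A%03d", seq_len(n)),
    year = 2000L,
    pm25 = 5 + bin + runif(n), # exposures consistent with bin order
    deaths = deaths,
    person_years = py
  )
  df$pm25_bin <- bin
  df
}

# Weight table wrapper for hand-constructed weights.
manual_weights <- function(bin, sw, K = max(bin), exposure = "pm25") {
  structure(
    data.frame(bin = bin, p_hat = (1 / K) / sw, sw = sw, sw_raw = sw,
               floored = FALSE, truncated = FALSE),
    K = as.integer(K), exposure = exposure,
    class = c("weight_table", "data.frame")
  )
}

# Independent crude rate-ratio oracle: per-bin weighted death rate over the
# reference bin, computed by direct summation.
crude_rr_oracle <- function(strata, bin_col = "pm25_bin", w = NULL) {
  if (is.null(w)) w <- rep(1, nrow(strata))
  bins <- sort(unique(strata[[bin_col]]))
  rate <- vapply(bins, function(b) {
    sel <- strata[[bin_col]] == b
    sum(w[sel] * strata$deaths[sel]) / sum(w[sel] * strata$person_years[sel])
  }, numeric(1))
  rate / rate[1]
}

# Independent weighted-quantile / binning oracle: exhaustive scan of the
# sorted cumulative mass, assigning bin = ceiling(K * cumulative fraction)
# at the last occurrence of each tied value.
scan_bins_oracle <- function(x, w, K) {
  o <- order(x)
  xs <- x[o]
  ws <- w[o]
  cf <- cumsum(ws) / sum(ws)
  bin_sorted <- integer(length(xs))
  i <- 1L
  while (i <= length(xs)) {
    j <- i
    while (j < length(xs) && xs[j + 1L] == xs[i]) j <- j + 1L
    bin_sorted[i:j] <- min(K, max(1L, ceiling(cf[j] * K - 1e-9)))
    i <- j + 1L
  }
  out <- integer(length(x))
  out[o] <- bin_sorted
  out
}

# A small cohort configuration that keeps unit tests fast.
small_config <- function(seed = 1, n_person_years = 3e4, ...) {
  sim_config(
    n_person_years = n_person_years, n_areas = 25, n_years = 3,
    demographic_spec = list(
      sex = c(male = 0.45, female = 0.55),
      medicaid = c(no = 0.8, yes = 0.2)
    ),
    demographic_log_rate = list(sex = c(male = 0, female = -0.2)),
    seed = seed, ...
  )
}
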