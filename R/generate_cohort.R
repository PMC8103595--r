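# Distribution-family helpers for the generator: draws go through the
# quantile function so exposures can share a Gaussian copula.

family_quantile <- function(spec, u) {
  switch(spec$family,
    normal    = qnorm(u, spec$mean %||% 0, spec$sd %||% 1),
    lognormal = qlnorm(u, spec$meanlog %||% 0, spec$sdlog %||% 1),
    gamma     = qgamma(u, shape = spec$shape, scale = spec$scale %||% 1),
    uniform   = qunif(u, spec$min %||% 0, spec$max %||% 1),
    stop(sprintf("unknown distribution family '%s'", spec$family), call. = FALSE)
  )
}

family_mean <- function(spec) {
  switch(spec$family,
    normal    = spec$mean %||% 0,
    lognormal = exp((spec$meanlog %||% 0) + (spec$sdlog %||% 1)^2 / 2),
    gamma     = spec$shape * (spec$scale %||% 1),
    uniform   = ((spec$min %||% 0) + (spec$max %||% 1)) / 2
  )
}

family_draw <- function(spec, n) family_quantile(spec, stats::runif(n))

# Symmetric matrix square root; tolerates semi-definite correlation matrices
# (chol() would not).
matrix_sqrt <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Generate a synthetic person-year cohort
#'
#' Simulates an open-cohort person-year table at the stratum level: each row
#' is a unique combination of demographic cell, area and calendar year,
#' carrying cumulated person-years and Poisson death counts. Continuous
#' confounders and exposures live at the area-year level; exposures are
#' linear in the confounders plus correlated, optionally heteroscedastic
#' noise. The death rate of a stratum is
#' `baseline_rate * exp(true_log_rr[bin] + centered confounder and
#' demographic effects)`, where `bin` is the person-year-weighted K-quantile
#' bin of the effect exposure over the generated cohort — so the ground
#' truth is a step-function dose-response curve known exactly.
#'
#' Randomness is split into named substreams (confounders, exposures,
#' allocation, deaths, split), each seeded deterministically from
#' `config$seed`, so e.g. adding a confounder does not perturb the death
#' draws. The caller's RNG state is left untouched.
#'
#' @param config a [sim_config()] object.
#' @param rows_per_stratum if greater than 1, each stratum's person-years
#'   and deaths are split uniformly at random across that many rows sharing
#'   the same key, producing a table on which [aggregate_person_years()] has
#'   real work to do. Defaults to 1 (one row per stratum).
#' @return a `data.frame` with one row per stratum (times
#'   `rows_per_stratum`): the demographic key columns, `area_id`, `year`,
#'   one column per exposure, one per confounder, `deaths` and
#'   `person_years`. Total person-years equal `config$n_person_years`
#'   exactly; strata allocated zero person-years are dropped.
#' @export
generate_cohort <- function(config, rows_per_stratum = 1L) {
  cfg <- validate_sim_config(config)
  K <- length(cfg$true_log_rr)
  seed <- cfg$seed

  # area-year grid with continuous confounders
  ay <- expand.grid(
    area_id = sprintf("A%04d", seq_len(cfg$n_areas)),
    year = cfg$start_year + seq_len(cfg$n_years) - 1L,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  nay <- nrow(ay)
  conf <- with_substream(seed, "confounders", {
    as.data.frame(lapply(cfg$confounder_spec, family_draw, n = nay))
  })

  # exposures: linear in confounders + copula-correlated centered noise
  expo <- with_substream(seed, "exposures", {
    nE <- length(cfg$exposure_spec)
    Z <- matrix(rnorm(nay * nE), nay, nE) %*% matrix_sqrt(cfg$cross_exposure_correlation)
    U <- pnorm(Z)
    out <- matrix(NA_real_, nay, nE,
                  dimnames = list(NULL, names(cfg$exposure_spec)))
    for (j in seq_len(nE)) {
      sp <- cfg$exposure_spec[[j]]
      noise <- family_quantile(sp$noise, U[, j]) - family_mean(sp$noise)
      if (!is.null(sp$hetero)) {
        cc <- conf[[sp$hetero$confounder]]
        mult <- pmax(sp$hetero$floor %||% 0.1,
                     1 + sp$hetero$slope * (cc - mean(cc)))
        noise <- noise * mult
      }
      mu <- rep(sp$intercept %||% 0, nay)
      for (cn in names(sp$coef)) mu <- mu + sp$coef[[cn]] * conf[[cn]]
      out[, j] <- mu + noise
    }
    out
  })

  # demographic cells and person-year allocation over strata = area-year x cell
  if (length(cfg$demographic_spec)) {
    cells <- expand.grid(lapply(cfg$demographic_spec, names),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    cell_prob <- Reduce(`*`, Map(function(margin, lev) unname(margin[lev]),
                                 cfg$demographic_spec, cells))
  } else {
    cells <- data.frame(matrix(nrow = 1L, ncol = 0L)) # one cell per area-year
    cell_prob <- 1
  }
  n_cells <- nrow(cells)
  p_stratum <- rep(cell_prob / nay, times = nay) # cell fast, area-year slow
  py <- with_substream(seed, "allocation", {
    as.vector(rmultinom(1L, size = round(cfg$n_person_years), prob = p_stratum))
  })

  ay_idx <- rep(seq_len(nay), each = n_cells)
  cell_idx <- rep(seq_len(n_cells), times = nay)
  keep <- py > 0
  ay_idx <- ay_idx[keep]; cell_idx <- cell_idx[keep]; py <- py[keep]

  tab <- cbind(
    cells[cell_idx, , drop = FALSE],
    ay[ay_idx, , drop = FALSE],
    as.data.frame(expo[ay_idx, , drop = FALSE]),
    conf[ay_idx, , drop = FALSE]
  )
  rownames(tab) <- NULL

  # ground-truth bin of the effect exposure: person-year-weighted K-quantiles
  x_eff <- tab[[cfg$effect_exposure]]
  bin <- scan_bins(x_eff, py, K)$bin

  # death rates: step function of bin + centered confounder/demographic effects
  eta <- cfg$true_log_rr[bin]
  if (length(cfg$confounder_log_rate)) {
    ec <- rep(0, length(py))
    for (cn in names(cfg$confounder_log_rate)) {
      ec <- ec + cfg$confounder_log_rate[[cn]] * tab[[cn]]
    }
    eta <- eta + ec - wtd_mean(ec, py)
  }
  for (dn in names(cfg$demographic_log_rate)) {
    ed <- unname(cfg$demographic_log_rate[[dn]][tab[[dn]]])
    eta <- eta + ed - wtd_mean(ed, py)
  }

  lambda <- py * cfg$baseline_rate * exp(eta)
  deaths <- with_substream(seed, "deaths", rpois(length(lambda), lambda))
  over <- deaths > py
  if (any(over)) {
    warning(sprintf("%d strata had simulated deaths exceeding person-years; clipped (consider baseline_rate <= 0.2)",
                    sum(over)))
    deaths[over] <- py[over]
  }
  tab$deaths <- deaths
  tab$person_years <- as.numeric(py)

  if (rows_per_stratum > 1L) {
    tab <- split_stratum_rows(tab, as.integer(rows_per_stratum), seed)
  }
  tab
}

# Split each stratum row into m rows with the same key, partitioning
# person-years (multinomially) and deaths (hypergeometric-free binomial
# thinning proportional to person-years). Rows receiving zero person-years
# are dropped.
split_stratum_rows <- function(tab, m, seed) {
  with_substream(seed, "split", {
    n <- nrow(tab)
    py_split <- vapply(seq_len(n), function(i) {
      as.vector(rmultinom(1L, size = tab$person_years[i], prob = rep(1 / m, m)))
    }, numeric(m))             # m x n
    idx <- rep(seq_len(n), each = m)
    out <- tab[idx, , drop = FALSE]
    out$person_years <- as.vector(py_split)
    d_split <- vapply(seq_len(n), function(i) {
      d <- tab$deaths[i]
      p <- py_split[, i]
      if (d == 0 || sum(p) == 0) return(rep(0, m))
      as.vector(rmultinom(1L, size = d, prob = pmax(p, 1e-12)))
    }, numeric(m))
    out$deaths <- as.vector(d_split)
    out <- out[out$person_years > 0, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Write or read a person-year cohort table as CSV
#'
#' Columns are written in the canonical order: demographic keys, `area_id`,
#' `year`, exposures, confounders, `deaths`, `person_years` (i.e. the order
#' produced by [generate_cohort()]).
#'
#' @param cohort a person-year `data.frame`.
#' @param path file path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns a `data.frame`.
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
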