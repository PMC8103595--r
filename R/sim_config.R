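#' Configuration for the synthetic cohort generator
#'
#' Describes a simulated open cohort of elderly person-years: demographic
#' cell structure, area-year level continuous confounders, continuous
#' exposures that depend linearly on those confounders with correlated
#' (optionally heteroscedastic, long-tailed) noise, and Poisson death counts
#' whose log rate is a known step function of the quantile bin of one
#' exposure. Because the bin-level log relative risks are set by the user,
#' the generated cohorts have a known ground-truth dose-response curve and
#' can be used to test estimator recovery.
#'
#' @param n_person_years total person-years of follow-up to distribute over
#'   strata (exactly conserved).
#' @param n_areas,n_years number of areas (ZIP-like units) and calendar
#'   years; confounders and exposures vary at the area-year level.
#' @param start_year first calendar year.
#' @param demographic_spec named list of categorical demographic margins;
#'   each element is a named probability vector over its levels. Strata are
#'   the full cross of these levels within each area-year.
#' @param confounder_spec named list of continuous area-year confounders;
#'   each element is `list(family =, ...)` with `family` one of
#'   `"normal"` (`mean`, `sd`), `"lognormal"` (`meanlog`, `sdlog`),
#'   `"gamma"` (`shape`, `scale`), `"uniform"` (`min`, `max`).
#' @param exposure_spec named list of exposures; each element has
#'   `intercept`, `coef` (named coefficients on confounders), `noise`
#'   (a distribution spec as in `confounder_spec`, centered at its
#'   theoretical mean before use), and optionally `hetero =
#'   list(confounder =, slope =, floor =)` multiplying the noise scale by
#'   `pmax(floor, 1 + slope * (C - mean(C)))`.
#' @param cross_exposure_correlation correlation matrix of the exposure
#'   noise terms (Gaussian copula); must be symmetric positive
#'   semi-definite.
#' @param true_log_rr numeric vector of length K: true log relative risk of
#'   each exposure bin versus bin 1; first element must be 0. K (the number
#'   of bins) is its length.
#' @param effect_exposure name of the exposure whose bin drives mortality;
#'   defaults to the first exposure in `exposure_spec`.
#' @param confounder_log_rate named numeric: log-rate coefficients of the
#'   continuous confounders on mortality (centered at their person-year
#'   mean when applied, so `baseline_rate` stays the approximate
#'   reference-bin rate). Non-zero values make the confounders true
#'   confounders: they then affect both exposure and outcome.
#' @param demographic_log_rate named list matching `demographic_spec`
#'   entries; each element a named numeric of per-level log-rate effects
#'   (centered when applied). Demographics are independent of exposure by
#'   construction, so they add rate heterogeneity without confounding.
#' @param baseline_rate reference-bin death rate per person-year, in (0, 1).
#'   Keep at or below 0.2 so that `deaths <= person_years` holds in
#'   practice; draws above a stratum's person-years are clipped with a
#'   warning.
#' @param seed integer seed; the generator is bit-reproducible given the
#'   full configuration.
#'
#' @return an object of class `sim_config`.
#' @seealso [generate_cohort()], [true_dose_response()]
#' @export
sim_config <- function(n_person_years = 1e5,
                       n_areas = 40,
                       n_years = 4,
                       start_year = 2000,
                       demographic_spec = default_demographic_spec(),
                       confounder_spec = default_confounder_spec(),
                       exposure_spec = default_exposure_spec(),
                       cross_exposure_correlation = default_exposure_correlation(),
                       true_log_rr = log(seq(1, 1.2, length.out = 10)),
                       effect_exposure = NULL,
                       confounder_log_rate = default_confounder_log_rate(),
                       demographic_log_rate = default_demographic_log_rate(),
                       baseline_rate = 0.05,
                       seed = 1L) {
  cfg <- structure(
    list(
      n_person_years = n_person_years,
      n_areas = as.integer(n_areas),
      n_years = as.integer(n_years),
      start_year = as.integer(start_year),
      demographic_spec = demographic_spec,
      confounder_spec = confounder_spec,
      exposure_spec = exposure_spec,
      cross_exposure_correlation = cross_exposure_correlation,
      true_log_rr = as.numeric(true_log_rr),
      effect_exposure = effect_exposure %||% names(exposure_spec)[1L],
      confounder_log_rate = confounder_log_rate,
      demographic_log_rate = demographic_log_rate,
      baseline_rate = baseline_rate,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
  validate_sim_config(cfg)
}

.sim_families <- c("normal", "lognormal", "gamma", "uniform")

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.numeric(cfg$n_person_years) || cfg$n_person_years < 1) {
    stop("n_person_years must be a positive number", call. = FALSE)
  }
  if (cfg$n_areas < 1 || cfg$n_years < 1) {
    stop("n_areas and n_years must be positive integers", call. = FALSE)
  }
  for (nm in names(cfg$demographic_spec)) {
    p <- cfg$demographic_spec[[nm]]
    if (is.null(names(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop(sprintf("demographic margin '%s' must be a named probability vector summing to 1", nm),
           call. = FALSE)
    }
  }
  for (nm in names(cfg$confounder_spec)) {
    fam <- cfg$confounder_spec[[nm]]$family
    if (is.null(fam) || !fam %in% .sim_families) {
      stop(sprintf("unknown distribution family '%s' for confounder '%s'",
                   fam %||% "<missing>", nm), call. = FALSE)
    }
  }
  if (length(cfg$exposure_spec) < 1) stop("at least one exposure required", call. = FALSE)
  for (nm in names(cfg$exposure_spec)) {
    sp <- cfg$exposure_spec[[nm]]
    fam <- sp$noise$family
    if (is.null(fam) || !fam %in% .sim_families) {
      stop(sprintf("unknown noise family '%s' for exposure '%s'",
                   fam %||% "<missing>", nm), call. = FALSE)
    }
    bad <- setdiff(names(sp$coef), names(cfg$confounder_spec))
    if (length(bad)) {
      stop(sprintf("exposure '%s' references unknown confounder(s): %s",
                   nm, paste(bad, collapse = ", ")), call. = FALSE)
    }
    if (!is.null(sp$hetero) &&
        !sp$hetero$confounder %in% names(cfg$confounder_spec)) {
      stop(sprintf("heteroscedasticity confounder '%s' not in confounder_spec",
                   sp$hetero$confounder), call. = FALSE)
    }
  }
  R <- cfg$cross_exposure_correlation
  nE <- length(cfg$exposure_spec)
  if (!is.matrix(R) || nrow(R) != nE || ncol(R) != nE) {
    stop("cross_exposure_correlation must be a square matrix matching the number of exposures",
         call. = FALSE)
  }
  if (max(abs(R - t(R))) > 1e-8 || any(abs(diag(R) - 1) > 1e-8) || any(abs(R) > 1 + 1e-8)) {
    stop("cross_exposure_correlation must be symmetric with unit diagonal and entries in [-1, 1]",
         call. = FALSE)
  }
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("cross_exposure_correlation must be positive semi-definite", call. = FALSE)
  }
  if (length(cfg$true_log_rr) < 2) stop("true_log_rr must have length K >= 2", call. = FALSE)
  if (cfg$true_log_rr[1L] != 0) {
    stop("true_log_rr[1] must be 0 (bin 1 is the reference)", call. = FALSE)
  }
  if (!(cfg$baseline_rate > 0 && cfg$baseline_rate < 1)) {
    stop("baseline_rate must lie in (0, 1)", call. = FALSE)
  }
  if (!cfg$effect_exposure %in% names(cfg$exposure_spec)) {
    stop(sprintf("effect_exposure '%s' not in exposure_spec", cfg$effect_exposure),
         call. = FALSE)
  }
  bad <- setdiff(names(cfg$confounder_log_rate), names(cfg$confounder_spec))
  if (length(bad)) {
    stop(sprintf("confounder_log_rate references unknown confounder(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  cfg
}

# -- default study conditions -------------------------------------------------

#' @rdname sim_config
#' @export
default_demographic_spec <- function() {
  list(
    sex = c(male = 0.446, female = 0.554),
    race = c(white = 0.840, black = 0.089, other = 0.071),
    age_group = c(`65-69` = 0.34, `70-74` = 0.26, `75-79` = 0.18,
                  `80-84` = 0.12, `85+` = 0.10),
    medicaid = c(no = 0.815, yes = 0.185)
  )
}

#' @rdname sim_config
#' @export
default_confounder_spec <- function() {
  list(
    summer_tmean = list(family = "normal", mean = 22, sd = 4),
    winter_tmean = list(family = "normal", mean = 4, sd = 5),
    pct_poverty = list(family = "gamma", shape = 4, scale = 2.5),
    log_median_income = list(family = "normal", mean = 10.8, sd = 0.3)
  )
}

#' @rdname sim_config
#' @export
default_exposure_spec <- function() {
  list(
    pm25 = list(
      intercept = 4.7,
      coef = c(summer_tmean = 0.18, pct_poverty = 0.12),
      noise = list(family = "lognormal", meanlog = 1.337, sdlog = 0.6),
      hetero = list(confounder = "summer_tmean", slope = 0.04, floor = 0.2)
    ),
    o3 = list(
      intercept = 28.3,
      coef = c(summer_tmean = 0.5),
      noise = list(family = "normal", mean = 0, sd = 3.46)
    ),
    no2 = list(
      intercept = 12.2,
      coef = c(winter_tmean = 0.4, pct_poverty = 0.35),
      noise = list(family = "lognormal", meanlog = 1.964, sdlog = 0.8)
    )
  )
}

#' @rdname sim_config
#' @export
default_exposure_correlation <- function() {
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- 0.3
  R[1, 3] <- R[3, 1] <- 0.5
  R[2, 3] <- R[3, 2] <- 0.2
  dimnames(R) <- list(c("pm25", "o3", "no2"), c("pm25", "o3", "no2"))
  R
}

#' @rdname sim_config
#' @export
default_confounder_log_rate <- function() {
  c(summer_tmean = 0.015, winter_tmean = -0.008,
    pct_poverty = 0.02, log_median_income = -0.15)
}

#' @rdname sim_config
#' @export
default_demographic_log_rate <- function() {
  list(
    age_group = c(`65-69` = 0, `70-74` = 0.35, `75-79` = 0.7,
                  `80-84` = 1.0, `85+` = 1.4),
    sex = c(male = 0, female = -0.25)
  )
}

#' @export
print.sim_config <- function(x, ...) {
  K <- length(x$true_log_rr)
  cat("<sim_config>\n")
  cat(sprintf("  person-years: %s over %d areas x %d years (%d demographic cells)\n",
              format(x$n_person_years, big.mark = ","), x$n_areas, x$n_years,
              prod(vapply(x$demographic_spec, length, integer(1)))))
  cat(sprintf("  exposures: %s (effect on '%s', K = %d bins)\n",
              paste(names(x$exposure_spec), collapse = ", "),
              x$effect_exposure, K))
  cat(sprintf("  true RR range: %.3f..%.3f; baseline rate %.3g/person-year; seed %d\n",
              exp(min(x$true_log_rr)), exp(max(x$true_log_rr)),
              x$baseline_rate, x$seed))
  invisible(x)
}

# -- serialization ------------------------------------------------------------

#' Read and write simulation configurations as JSON
#'
#' @param config a [sim_config()] object.
#' @param path file path.
#' @return `read_sim_config` returns a validated `sim_config`;
#'   `write_sim_config` returns `path` invisibly.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  # named numeric vectors must become JSON objects, not nameless arrays
  named_to_list <- function(x) {
    if (is.list(x)) {
      lapply(x, named_to_list)
    } else if (is.numeric(x) && !is.null(names(x))) {
      as.list(x)
    } else {
      x
    }
  }
  x <- unclass(config)
  x$cross_exposure_correlation <- unname(x$cross_exposure_correlation)
  x[] <- lapply(x, named_to_list)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$cross_exposure_correlation <- as.matrix(x$cross_exposure_correlation)
  x$demographic_spec <- lapply(x$demographic_spec, unlist)
  x$confounder_log_rate <- unlist(x$confounder_log_rate)
  x$demographic_log_rate <- lapply(x$demographic_log_rate, unlist)
  x$exposure_spec <- lapply(x$exposure_spec, function(sp) {
    sp$coef <- unlist(sp$coef)
    sp
  })
  do.call(sim_config, x)
}

#' Ground-truth dose-response curve of a simulation configuration
#'
#' Returns the curve the generator embeds in the death rates: the relative
#' risk of bin i versus bin 1 is `exp(true_log_rr[i])`, with degenerate
#' (zero-width) confidence intervals. This is the recovery target for
#' estimators run on cohorts from the same configuration.
#'
#' @param config a [sim_config()] object.
#' @return a [dose_response_curve] with `K` rows; `bin_mean_exposure` is `NA`
#'   (it depends on the realized cohort, not the configuration).
#' @export
true_dose_response <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  K <- length(config$true_log_rr)
  new_dose_response_curve(
    data.frame(
      bin = seq_len(K),
      bin_mean_exposure = NA_real_,
      rr = exp(config$true_log_rr),
      ci_low = exp(config$true_log_rr),
      ci_high = exp(config$true_log_rr),
      log_rr = config$true_log_rr,
      se = 0,
      reference = seq_len(K) == 1L
    ),
    exposure = config$effect_exposure,
    K = K,
    dispersion = NA_real_,
    weight_mode = "truth"
  )
}
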