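#' Run the full dose-response pipeline for one exposure
#'
#' Composes the whole analysis: aggregate person-year records into strata;
#' cut the exposure into `K` equal-person-year bins; fit the gradient-
#' boosted propensity model of bin membership given the confounders
#' (including the concurrent co-exposures); form stabilized inverse
#' probability weights; diagnose covariate balance; and fit the weighted
#' quasi-Poisson outcome model. The design stage (binning + weighting)
#' constructs the pseudo-population; the analysis stage estimates the
#' marginal relative risk of each bin versus the lowest-exposure reference
#' bin.
#'
#' @param records person-year `data.frame`.
#' @param exposure exposure column to analyse.
#' @param co_exposures names of the concurrent exposures entered as
#'   confounders (mutual adjustment).
#' @param confounders further confounder columns (calendar year,
#'   demographic keys, area-level covariates).
#' @param K number of bins (10 = deciles).
#' @param key_fields stratum key for aggregation.
#' @param control [propensity_control()] hyperparameters (includes the
#'   seed; the pipeline is deterministic given it).
#' @param bin_weight quantile weighting for the bins, see
#'   [assign_exposure_bins()].
#' @param weight_mode outcome-stage weighting, see [fit_outcome_model()].
#' @param floor,truncate weight guards, see [stabilized_weights()].
#' @param verbose log each stage via `message()`.
#' @return a list of class `ipw_fit`: `curve` (the IPW
#'   [dose_response_curve][fit_outcome_model]), `crude_curve` (unit-weight
#'   fit, for comparison), `bins` ([bin_definition]), `weights`
#'   ([stabilized_weights()] table), `balance` ([balance_diagnostics()]),
#'   `model` (the propensity model) and `strata` (the binned stratum
#'   table).
#' @export
run_pipeline <- function(records, exposure, co_exposures = character(),
                         confounders, K = 10L,
                         key_fields = c("sex", "race", "age_group",
                                        "medicaid", "area_id", "year"),
                         control = propensity_control(),
                         bin_weight = "person_years",
                         weight_mode = "sw",
                         floor = 1e-6, truncate = NULL,
                         verbose = FALSE) {
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  stage <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", label, conditionMessage(e)), call. = FALSE)
    })
  }

  say("aggregating %d person-year rows by {%s}", nrow(records),
      paste(key_fields, collapse = ", "))
  strata <- stage("aggregate", aggregate_person_years(records, key_fields))
  say("-> %d strata, %.0f person-years", nrow(strata), sum(strata$person_years))

  say("binning '%s' into %d equal-person-year groups", exposure, K)
  binned <- stage("bin", assign_exposure_bins(strata, exposure, K, weight = bin_weight))

  conf_all <- c(co_exposures, confounders)
  say("fitting %s propensity GBM on %d confounders", control$method, length(conf_all))
  model <- stage("propensity",
                 fit_propensity(binned$strata, exposure, conf_all, control = control))

  say("computing stabilized weights")
  weights <- stage("weights",
                   stabilized_weights(model, binned$strata, floor = floor,
                                      truncate = truncate))

  balance <- stage("balance",
                   balance_diagnostics(binned$strata, weights, conf_all))
  say("balance: max |SMD| %.3f -> %.3f; mean sw %.4f",
      max(abs(balance$smd_before)), max(abs(balance$smd_after)),
      attr(balance, "mean_sw"))

  say("fitting weighted quasi-Poisson outcome model")
  curve <- stage("outcome",
                 fit_outcome_model(binned$strata, weights, exposure = exposure,
                                   weight_mode = weight_mode))
  crude <- stage("outcome-crude",
                 fit_outcome_model(binned$strata, NULL, exposure = exposure))

  structure(
    list(curve = curve, crude_curve = crude, bins = binned$bins,
         weights = weights, balance = balance, model = model,
         strata = binned$strata),
    class = "ipw_fit"
  )
}

#' @export
print.ipw_fit <- function(x, ...) {
  cat(sprintf("<ipw_fit> exposure '%s'\n", attr(x$curve, "exposure")))
  print(x$curve)
  cat(sprintf("balance: max |SMD| %.3f (before) -> %.3f (after); mean sw %.4f\n",
              max(abs(x$balance$smd_before)), max(abs(x$balance$smd_after)),
              attr(x$balance, "mean_sw")))
  invisible(x)
}

#' Bootstrap confidence intervals for the dose-response curve
#'
#' Resamples strata with replacement and reruns both stages (propensity
#' fit, weighting, outcome fit) on each resample, giving percentile
#' intervals that propagate weight-estimation uncertainty, which the
#' model-based Wald intervals ignore.
#'
#' @param strata_binned binned stratum table (e.g. `fit$strata`).
#' @param exposure exposure name.
#' @param confounders confounders for the propensity refit (include the
#'   co-exposures).
#' @param n_boot number of bootstrap resamples.
#' @param control [propensity_control()]; resample r uses `seed + r`.
#' @param conf_level interval level.
#' @return a `data.frame` with `bin`, `ci_low`, `ci_high` (percentile
#'   bootstrap, reference bin fixed at 1).
#' @export
bootstrap_curve <- function(strata_binned, exposure, confounders,
                            n_boot = 50L, control = propensity_control(),
                            conf_level = 0.95) {
  bin_col <- paste0(exposure, "_bin")
  assert_cols(strata_binned, bin_col)
  K <- max(strata_binned[[bin_col]])
  reps <- matrix(NA_real_, n_boot, K)
  for (r in seq_len(n_boot)) {
    set.seed(substream_seed(control$seed + r, "bootstrap"))
    idx <- sample.int(nrow(strata_binned), replace = TRUE)
    bs <- strata_binned[idx, , drop = FALSE]
    ctl <- control
    ctl$seed <- control$seed + r
    fit <- tryCatch({
      m <- fit_propensity(bs, exposure, confounders, control = ctl)
      w <- stabilized_weights(m, bs)
      fit_outcome_model(bs, w, exposure = exposure)
    }, error = function(e) NULL)
    if (!is.null(fit)) reps[r, ] <- fit$rr
  }
  alpha <- (1 - conf_level) / 2
  data.frame(
    bin = seq_len(K),
    ci_low = apply(reps, 2, stats::quantile, probs = alpha, na.rm = TRUE),
    ci_high = apply(reps, 2, stats::quantile, probs = 1 - alpha, na.rm = TRUE)
  )
}
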