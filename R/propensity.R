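# -- propensity model ---------------------------------------------------------

#' Gradient-boosting hyperparameters for the propensity stage
#'
#' Defaults: 300 trees of depth 3, learning rate 0.05, 80% row subsampling,
#' single thread, fixed seed — all exposed here and recorded in the fitted
#' model.
#'
#' @param nrounds maximum number of boosting rounds (trees per class); the
#'   size actually used is chosen by `selection` under cross-fitting,
#'   while `nfold = 1` uses all `nrounds`.
#' @param early_stopping_rounds for `selection = "logloss"`: stop a fold
#'   model after this many rounds without held-out improvement.
#' @param max_depth maximum tree depth.
#' @param eta learning rate.
#' @param subsample row subsampling fraction per round.
#' @param method `"multinomial"` fits one K-class softmax boosted model
#'   (the internally consistent default); `"one_vs_rest"` fits K binary
#'   logistic boosted models — each class probability is its own
#'   inverse-logit score — and renormalizes the K probabilities to sum
#'   to 1.
#' @param selection how the boosting size (number of rounds actually used)
#'   is chosen under cross-fitting. `"balance"` (default) evaluates the
#'   cross-fitted weights on a geometric grid of sizes (including size 0,
#'   i.e. no effective weighting) and keeps the smallest size whose
#'   person-year-weighted confounder SMD summary is within 5% of the best
#'   — the balance-based stopping rule of the propensity-boosting
#'   literature, targeting what the weights are for. `"logloss"` stops
#'   each fold early at its best held-out logistic loss (best predictive
#'   calibration).
#' @param balance_metric summary of the SMD table minimized by
#'   `selection = "balance"`: `"es.mean"` (default; mean absolute SMD over
#'   all confounder-bin cells, weighting every bin's balance equally) or
#'   `"es.max"` (worst cell).
#' @param nfold cross-fitting folds for the propensity predictions used in
#'   the weights. With `nfold > 1` (default 5) each stratum's probability
#'   comes from a model trained without its fold, folds being assigned to
#'   whole distinct covariate patterns — strata sharing identical
#'   confounder values (e.g. demographic cells of one area-year) stay
#'   together, so a flexible learner cannot simply memorize each pattern's
#'   observed bin and collapse every weight toward `1/K * K`-confident
#'   predictions. `nfold = 1` uses in-sample predictions.
#' @param seed RNG seed for the boosting subsampling and fold assignment.
#' @param nthread number of threads (1 keeps fits bit-reproducible).
#' @return a list of class `propensity_control`.
#' @export
propensity_control <- function(nrounds = 300L, max_depth = 3L, eta = 0.05,
                               subsample = 0.8,
                               method = c("multinomial", "one_vs_rest"),
                               selection = c("balance", "logloss"),
                               balance_metric = c("es.mean", "es.max"),
                               nfold = 5L, early_stopping_rounds = 25L,
                               seed = 1L, nthread = 1L) {
  structure(
    list(nrounds = as.integer(nrounds), max_depth = as.integer(max_depth),
         eta = eta, subsample = subsample, method = match.arg(method),
         selection = match.arg(selection),
         balance_metric = match.arg(balance_metric),
         nfold = as.integer(nfold),
         early_stopping_rounds = as.integer(early_stopping_rounds),
         seed = as.integer(seed), nthread = as.integer(nthread)),
    class = "propensity_control"
  )
}

# One-hot design matrix for the boosted trees; character/factor confounders
# are expanded to full dummies (no reference level dropped — trees are
# invariant to that, and full dummies keep balance tables readable).
propensity_design <- function(strata, confounders) {
  assert_cols(strata, confounders, "confounder")
  df <- strata[confounders]
  is_cat <- vapply(df, function(v) is.character(v) || is.factor(v) || is.logical(v),
                   logical(1))
  for (cl in names(df)[is_cat]) df[[cl]] <- factor(df[[cl]])
  mm <- model.matrix(
    ~ . - 1, data = df,
    contrasts.arg = lapply(df[names(df)[is_cat]], stats::contrasts, contrasts = FALSE)
  )
  attr(mm, "assign") <- NULL
  mm
}

#' Fit the bin-propensity model
#'
#' Estimates each stratum's probability of its observed exposure bin given
#' the confounders with a gradient-boosted classifier (logistic loss),
#' weighting every stratum by its person-years. The confounder set should
#' contain the other concurrent exposures, calendar year, the demographic
#' key variables and the area-level continuous covariates — and must not
#' contain the binned exposure itself.
#'
#' @param strata_binned stratum `data.frame` carrying `<exposure>_bin` (see
#'   [assign_exposure_bins()]).
#' @param exposure name of the binned exposure.
#' @param confounders character vector of confounder column names.
#' @param control a [propensity_control()].
#' @param weight_col column of training weights; default `"person_years"`.
#' @return an object of class `propensity_model`.
#' @export
fit_propensity <- function(strata_binned, exposure, confounders,
                           control = propensity_control(),
                           weight_col = "person_years") {
  bin_col <- paste0(exposure, "_bin")
  assert_cols(strata_binned, c(bin_col, weight_col))
  if (exposure %in% confounders) {
    stop(sprintf("the binned exposure '%s' cannot be one of its own confounders", exposure),
         call. = FALSE)
  }
  bin <- strata_binned[[bin_col]]
  K <- max(bin)
  if (!setequal(unique(bin), seq_len(K))) {
    stop("every bin 1..K must be present in the training data", call. = FALSE)
  }
  X <- propensity_design(strata_binned, confounders)
  w <- strata_binned[[weight_col]]

  # cross-fitted probabilities for the training strata: folds are assigned
  # to whole distinct patterns of the *continuous* confounders (the
  # exposure-assignment unit, e.g. an area-year), so rows that share those
  # values — demographic cells of one area-year — never straddle the
  # train/predict split and cannot be memorized from their twins
  if (control$nfold > 1L) {
    is_cat <- vapply(strata_binned[confounders],
                     function(v) is.character(v) || is.factor(v) || is.logical(v),
                     logical(1))
    group_cols <- if (any(!is_cat)) confounders[!is_cat] else confounders
    pattern <- key_id(strata_binned, group_cols)
    upat <- unique(pattern)
    fold_of_pattern <- with_substream(control$seed, "folds", {
      sample(rep_len(seq_len(control$nfold), length(upat)))
    })
    fold <- fold_of_pattern[match(pattern, upat)]

    if (control$selection == "balance") {
      fit <- cross_fit_balance_selected(X, bin, w, K, fold, control)
    } else {
      fit <- cross_fit_logloss_stopped(X, bin, w, K, fold, control)
    }
    training_prob <- fit$training_prob
    boosters <- fit_gbm_classifier(X, bin, w, K, control,
                                   nrounds = max(1L, fit$nrounds))
    nrounds_used <- fit$nrounds
  } else {
    boosters <- fit_gbm_classifier(X, bin, w, K, control)
    training_prob <- predict_gbm_classifier(boosters, X, control, K)
    nrounds_used <- control$nrounds
  }

  structure(
    list(boosters = boosters, method = control$method, K = K,
         exposure = exposure, confounders = confounders,
         feature_names = colnames(X), control = control,
         nrounds_used = nrounds_used,
         training_bin = bin, training_prob = training_prob),
    class = "propensity_model"
  )
}

check_fold_classes <- function(bin, hold, K) {
  if (!setequal(unique(bin[!hold]), seq_len(K))) {
    stop("a cross-fitting fold lost an exposure bin entirely; use fewer folds or more strata",
         call. = FALSE)
  }
}

# Cross-fit with per-fold early stopping on held-out logistic loss; the
# final-model size is the median of the folds' best iterations.
cross_fit_logloss_stopped <- function(X, bin, w, K, fold, control) {
  training_prob <- matrix(NA_real_, nrow(X), K)
  fold_best_iter <- numeric(0)
  for (f in sort(unique(fold))) {
    hold <- fold == f
    check_fold_classes(bin, hold, K)
    bf <- fit_gbm_classifier(X[!hold, , drop = FALSE], bin[!hold], w[!hold], K,
                             control,
                             eval = list(X = X[hold, , drop = FALSE],
                                         bin = bin[hold], w = w[hold]))
    fold_best_iter <- c(fold_best_iter, best_iterations(bf))
    training_prob[hold, ] <- predict_gbm_classifier(bf, X[hold, , drop = FALSE],
                                                    control, K)
  }
  list(training_prob = training_prob,
       nrounds = max(10L, as.integer(round(stats::median(fold_best_iter)))))
}

# Cross-fit with the boosting size chosen by the person-year-weighted
# confounder SMDs (es.mean or es.max summary) of the resulting
# bin-normalized stabilized weights -- the balance stopping rule of the
# propensity-boosting literature. All folds are trained to
# control$nrounds, out-of-fold probabilities are evaluated on a geometric
# iteration grid, and the selected size is kept for both the stored
# cross-fitted probabilities and the final model.
cross_fit_balance_selected <- function(X, bin, w, K, fold, control) {
  boosters_by_fold <- list()
  for (f in sort(unique(fold))) {
    hold <- fold == f
    check_fold_classes(bin, hold, K)
    boosters_by_fold[[f]] <- fit_gbm_classifier(X[!hold, , drop = FALSE],
                                                bin[!hold], w[!hold], K, control)
  }
  # candidate sizes: 0 boosting rounds = marginal bin shares (no effective
  # weighting), then a geometric grid up to control$nrounds
  grid <- c(0L, unique(pmin(control$nrounds, c(
    5L, ceiling(5 * 1.35^seq_len(ceiling(log(control$nrounds / 5) / log(1.35))))
  ))))
  marginal_share <- as.vector(rowsum(w, factor(bin, levels = seq_len(K)))) / sum(w)
  prob_at <- function(it) {
    if (it == 0L) {
      return(matrix(marginal_share, nrow(X), K, byrow = TRUE))
    }
    P <- matrix(NA_real_, nrow(X), K)
    for (f in sort(unique(fold))) {
      hold <- fold == f
      P[hold, ] <- predict_gbm_classifier(boosters_by_fold[[f]],
                                          X[hold, , drop = FALSE], control, K,
                                          iterationrange = c(1L, as.integer(it)))
    }
    P
  }
  agg <- if (control$balance_metric == "es.max") max else mean
  crit <- vapply(grid, function(it) {
    P <- prob_at(it)
    p_obs <- pmax(P[cbind(seq_len(nrow(P)), bin)], 1e-6)
    sw <- normalize_by_bin((1 / K) / p_obs, bin, w, K)
    agg(abs(smd_matrix(X, w, sw * w, bin, K)))
  }, numeric(1))
  # parsimony: the smallest size whose balance is within 5% of the best, so
  # an unconfounded cohort keeps (near-)unit weights instead of noise-chasing
  best <- grid[which(crit <= 1.05 * min(crit))[1L]]
  list(training_prob = prob_at(best), nrounds = as.integer(best))
}

# person-year-weighted SMD of every column of X, each bin vs the pooled
# population; pooled SD from the unweighted (n_ij) stage is the fixed
# denominator. Columns with zero variance get SMD 0.
smd_matrix <- function(X, w_base, w_stage, bin, K) {
  sd_pool <- vapply(seq_len(ncol(X)), function(j) wtd_sd(X[, j], w_base), numeric(1))
  mean_pool <- vapply(seq_len(ncol(X)), function(j) wtd_mean(X[, j], w_stage), numeric(1))
  out <- matrix(0, ncol(X), K, dimnames = list(colnames(X), NULL))
  for (b in seq_len(K)) {
    sel <- bin == b
    mb <- vapply(seq_len(ncol(X)), function(j) wtd_mean(X[sel, j], w_stage[sel]),
                 numeric(1))
    ok <- sd_pool > 0
    out[ok, b] <- (mb[ok] - mean_pool[ok]) / sd_pool[ok]
  }
  out
}

normalize_by_bin <- function(sw, bin, w, K) {
  for (b in seq_len(K)) {
    sel <- bin == b
    sw[sel] <- sw[sel] / wtd_mean(sw[sel], w[sel])
  }
  sw
}

# Fit boosted classifier(s): one softmax model or K one-vs-rest models.
# When `eval` (a held-out X/bin/w triple) is supplied, training stops early
# once held-out logistic loss stops improving; predictions from such a
# booster automatically use its best iteration.
fit_gbm_classifier <- function(X, bin, w, K, control, eval = NULL,
                               nrounds = control$nrounds) {
  params_common <- list(max_depth = control$max_depth, eta = control$eta,
                        subsample = control$subsample,
                        nthread = control$nthread, seed = control$seed)
  esr <- if (!is.null(eval)) control$early_stopping_rounds else NULL
  if (control$method == "multinomial") {
    dtrain <- xgboost::xgb.DMatrix(X, label = bin - 1L, weight = w,
                                   nthread = control$nthread)
    evals <- if (!is.null(eval)) {
      list(val = xgboost::xgb.DMatrix(eval$X, label = eval$bin - 1L,
                                      weight = eval$w, nthread = control$nthread))
    }
    list(xgboost::xgb.train(
      params = c(list(objective = "multi:softprob", num_class = K), params_common),
      data = dtrain, nrounds = nrounds, verbose = 0,
      evals = evals %||% list(), early_stopping_rounds = esr
    ))
  } else {
    lapply(seq_len(K), function(k) {
      dtrain <- xgboost::xgb.DMatrix(X, label = as.numeric(bin == k), weight = w,
                                     nthread = control$nthread)
      evals <- if (!is.null(eval)) {
        list(val = xgboost::xgb.DMatrix(eval$X, label = as.numeric(eval$bin == k),
                                        weight = eval$w, nthread = control$nthread))
      }
      xgboost::xgb.train(
        params = c(list(objective = "binary:logistic"), params_common),
        data = dtrain, nrounds = nrounds, verbose = 0,
        evals = evals %||% list(), early_stopping_rounds = esr
      )
    })
  }
}

best_iterations <- function(boosters) {
  vapply(boosters, function(b) {
    es <- attributes(b)$early_stop
    as.numeric(es$best_iteration %||% xgboost::xgb.get.num.boosted.rounds(b))
  }, numeric(1))
}

predict_gbm_classifier <- function(boosters, X, control, K, iterationrange = NULL) {
  dm <- xgboost::xgb.DMatrix(X, nthread = control$nthread)
  if (length(boosters) == 1L && control$method == "multinomial") {
    P <- predict(boosters[[1L]], dm, iterationrange = iterationrange)
    matrix(P, ncol = K, byrow = is.null(dim(P)))
  } else {
    P <- vapply(boosters,
                function(b) predict(b, dm, iterationrange = iterationrange),
                numeric(nrow(X)))
    P <- matrix(P, ncol = K)
    P / rowSums(P)
  }
}

#' Predicted bin probabilities
#'
#' @param object a [fit_propensity()] model.
#' @param newdata stratum `data.frame` with the model's confounder columns.
#' @param ... unused.
#' @return an `n x K` matrix of probabilities; rows sum to 1 and entries
#'   lie in (0, 1).
#' @export
predict.propensity_model <- function(object, newdata, ...) {
  X <- propensity_design(newdata, object$confounders)
  missing <- setdiff(object$feature_names, colnames(X))
  if (length(missing)) {
    add <- matrix(0, nrow(X), length(missing), dimnames = list(NULL, missing))
    X <- cbind(X, add)
  }
  X <- X[, object$feature_names, drop = FALSE]
  predict_gbm_classifier(object$boosters, X, object$control, object$K)
}

#' @export
print.propensity_model <- function(x, ...) {
  cat(sprintf("<propensity_model> %s, K = %d classes, %s GBM (%d rounds, depth %d, eta %.3g, %s)\n",
              x$exposure, x$K, x$method, x$control$nrounds,
              x$control$max_depth, x$control$eta,
              if (x$control$nfold > 1L) sprintf("%d-fold cross-fit", x$control$nfold)
              else "in-sample"))
  cat(sprintf("  %d features from %d confounders\n",
              length(x$feature_names), length(x$confounders)))
  invisible(x)
}

# -- stabilized weights -------------------------------------------------------

#' Stabilized inverse probability weights
#'
#' For stratum j observed in bin i, the stabilized weight is
#' `sw = P(X in i) / p_hat(i | C)`, where the numerator — the marginal
#' probability of any observation falling in bin i — equals `1/K` by
#' construction of the equal-mass bins, and the denominator is the
#' propensity model's predicted probability of the observed bin. A
#' well-calibrated model gives person-year-weighted mean weights near 1
#' within every bin.
#'
#' @param model a [fit_propensity()] model.
#' @param strata_binned the stratum table the weights are for.
#' @param floor lower bound applied to predicted probabilities to prevent
#'   infinite weights from numerically zero predictions; occurrences are
#'   flagged and reported. Default `1e-6`.
#' @param truncate optional length-2 percentile pair (e.g. `c(0.01, 0.99)`)
#'   for symmetric weight truncation; `NULL` (default) leaves weights
#'   untruncated — the binning itself already guards against outlier
#'   weights. Truncated rows are flagged.
#' @param normalize divide the weights within each observed bin by their
#'   person-year-weighted mean (Hajek normalization), so the weighted mean
#'   weight is exactly 1 in every bin. This leaves the saturated outcome
#'   model's rate-ratio point estimates unchanged (a per-bin constant
#'   cancels from a within-bin weighted mean) while removing the upward
#'   drift of raw inverse-probability weights under noisy predicted
#'   probabilities. Default `TRUE`.
#' @return a `data.frame` of class `weight_table` aligned row-for-row with
#'   `strata_binned`: `bin`, `p_hat`, `sw`, `floored`, `truncated`.
#' @export
stabilized_weights <- function(model, strata_binned, floor = 1e-6,
                               truncate = NULL, normalize = TRUE) {
  stopifnot(inherits(model, "propensity_model"))
  bin_col <- paste0(model$exposure, "_bin")
  assert_cols(strata_binned, bin_col)
  bin <- strata_binned[[bin_col]]
  if (nrow(strata_binned) == length(model$training_bin) &&
      all(bin == model$training_bin)) {
    # the training table itself: use the stored (cross-fitted) probabilities
    P <- model$training_prob
  } else {
    P <- predict(model, strata_binned)
  }
  p_hat <- P[cbind(seq_along(bin), bin)]
  floored <- p_hat < floor
  if (any(floored)) {
    warning(sprintf("%d predicted probabilities below floor %.1g; floored",
                    sum(floored), floor))
    p_hat <- pmax(p_hat, floor)
  }
  sw <- (1 / model$K) / p_hat
  truncated <- rep(FALSE, length(sw))
  if (!is.null(truncate)) {
    stopifnot(length(truncate) == 2L, truncate[1] < truncate[2])
    bounds <- stats::quantile(sw, truncate, names = FALSE)
    truncated <- sw < bounds[1] | sw > bounds[2]
    if (any(truncated)) {
      message(sprintf("truncated %d weights to [%.3g, %.3g]",
                      sum(truncated), bounds[1], bounds[2]))
    }
    sw <- pmin(pmax(sw, bounds[1]), bounds[2])
  }
  sw_raw <- sw
  if (normalize) {
    sw <- normalize_by_bin(sw, bin, strata_binned$person_years, model$K)
  }
  structure(
    data.frame(bin = bin, p_hat = p_hat, sw = sw, sw_raw = sw_raw,
               floored = floored, truncated = truncated),
    K = model$K, exposure = model$exposure,
    class = c("weight_table", "data.frame")
  )
}

# -- balance diagnostics ------------------------------------------------------

#' Covariate balance before and after weighting
#'
#' For each confounder and each exposure bin, computes the person-year-
#' weighted standardized mean difference (SMD) between the bin and the
#' pooled population — before weighting (weights `n_ij`) and after
#' (weights `sw x n_ij`). The denominator is the pooled person-year-
#' weighted SD of the confounder, held fixed across bins and stages so the
#' two stages are comparable. Categorical confounders are expanded to
#' level indicators. `|SMD| < 0.1` for every confounder in every bin is
#' the conventional evidence that the pseudo-population is exchangeable.
#'
#' @param strata_binned stratum table with bins assigned.
#' @param weights a [stabilized_weights()] table aligned to it.
#' @param confounders confounder column names to diagnose.
#' @return a `data.frame` of class `balance_report`: one row per confounder
#'   component x bin with `smd_before`, `smd_after` and a `zero_variance`
#'   flag (constant confounders get SMD 0). Attributes carry the effective
#'   sample size `ess = (sum w)^2 / sum(w^2)` with `w = sw * n`, the
#'   n-weighted mean stabilized weight, and weight quantiles.
#' @export
balance_diagnostics <- function(strata_binned, weights, confounders) {
  stopifnot(inherits(weights, "weight_table"),
            nrow(weights) == nrow(strata_binned))
  X <- propensity_design(strata_binned, confounders)
  n <- strata_binned$person_years
  w_before <- n
  w_after <- weights$sw * n
  bin <- weights$bin
  K <- attr(weights, "K")

  S_before <- smd_matrix(X, w_before, w_before, bin, K)
  S_after <- smd_matrix(X, w_before, w_after, bin, K)
  zv <- vapply(seq_len(ncol(X)), function(j) wtd_sd(X[, j], w_before) == 0,
               logical(1))
  out <- data.frame(
    confounder = rep(colnames(X), each = K),
    bin = rep(seq_len(K), times = ncol(X)),
    smd_before = as.vector(t(S_before)),
    smd_after = as.vector(t(S_after)),
    zero_variance = rep(zv, each = K)
  )
  structure(
    out,
    ess = sum(w_after)^2 / sum(w_after^2),
    total_person_years = sum(n),
    mean_sw = wtd_mean(weights$sw, n),
    mean_sw_raw = wtd_mean(weights$sw_raw %||% weights$sw, n),
    sw_quantiles = stats::quantile(weights$sw, c(0, 0.01, 0.25, 0.5, 0.75, 0.99, 1)),
    class = c("balance_report", "data.frame")
  )
}

#' @export
print.balance_report <- function(x, ...) {
  cat("<balance_report>\n")
  cat(sprintf("  max |SMD| before: %.3f   after: %.3f  (threshold 0.1)\n",
              max(abs(x$smd_before)), max(abs(x$smd_after))))
  cat(sprintf("  n-weighted mean sw: %.4f   ESS: %.0f of %.0f person-years\n",
              attr(x, "mean_sw"), attr(x, "ess"), attr(x, "total_person_years")))
  invisible(x)
}
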