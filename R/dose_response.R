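# -- dose-response curve object -----------------------------------------------

new_dose_response_curve <- function(df, exposure, K, dispersion, weight_mode) {
  stopifnot(is.data.frame(df))
  structure(df, exposure = exposure, K = as.integer(K),
            dispersion = dispersion, weight_mode = weight_mode,
            class = c("dose_response_curve", "data.frame"))
}

#' @export
print.dose_response_curve <- function(x, digits = 3, ...) {
  cat(sprintf("<dose_response_curve> %s, K = %d bins (reference: bin 1)",
              attr(x, "exposure") %||% "?", attr(x, "K")))
  if (is.finite(attr(x, "dispersion") %||% NA_real_)) {
    cat(sprintf(", dispersion %.2f", attr(x, "dispersion")))
  }
  cat("\n")
  df <- as.data.frame(x)
  df$rr <- round(df$rr, digits)
  df$ci_low <- round(df$ci_low, digits)
  df$ci_high <- round(df$ci_high, digits)
  df$bin_mean_exposure <- signif(df$bin_mean_exposure, 4)
  print.data.frame(df[c("bin", "bin_mean_exposure", "rr", "ci_low", "ci_high")],
                   row.names = FALSE)
  invisible(x)
}

#' Serialize a dose-response curve
#'
#' @param curve a [dose_response_curve][fit_outcome_model].
#' @param path file path.
#' @return `path`, invisibly (writers); a curve (reader).
#' @export
write_curve_json <- function(curve, path) {
  stopifnot(inherits(curve, "dose_response_curve"))
  jsonlite::write_json(
    list(exposure = attr(curve, "exposure"), K = attr(curve, "K"),
         dispersion = attr(curve, "dispersion"),
         weight_mode = attr(curve, "weight_mode"),
         curve = as.data.frame(curve)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
  )
  invisible(path)
}

#' @rdname write_curve_json
#' @export
read_curve_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_dose_response_curve(as.data.frame(x$curve), exposure = x$exposure,
                          K = x$K, dispersion = x$dispersion %||% NA_real_,
                          weight_mode = x$weight_mode)
}

#' @rdname write_curve_json
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "dose_response_curve"))
  write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

# -- outcome model ------------------------------------------------------------

#' Fit the weighted quasi-Poisson outcome model
#'
#' Analysis stage of the pipeline: on the pseudo-population defined by the
#' stabilized weights, fits the log-linear rate model
#' `log E[deaths] = log(person_years) + beta_i 1{bin = i}` with bin 1 as
#' reference, using a quasi-Poisson family so overdispersion inflates the
#' standard errors. Relative risks are `RR_i = exp(beta_i)` with Wald 95%
#' intervals `exp(beta_i +/- 1.96 se_i)`; the dispersion (Pearson chi-square
#' over residual df, floored at 1 — underdispersion never shrinks the
#' intervals) scales the `se_i`.
#'
#' @param strata_binned stratum table with `<exposure>_bin` assigned.
#' @param weights a [stabilized_weights()] table aligned to it, or `NULL`
#'   for unit weights (the crude, confounded curve). With unit weights the
#'   factored model is saturated, so each fitted RR equals the crude
#'   per-bin rate ratio `(deaths_i / py_i) / (deaths_1 / py_1)` exactly.
#' @param exposure exposure name (used to locate the bin column and label
#'   the curve); if `NULL`, taken from the weight table.
#' @param weight_mode `"sw"` (default) uses the stabilized weight itself as
#'   the regression weight — the stratum's population mass already enters
#'   through the person-years offset; `"sw_py"` uses `sw * person_years`
#'   as frequency-style weights instead.
#' @param conf_level confidence level for the Wald intervals.
#' @return a `dose_response_curve`: one row per bin (`bin`,
#'   `bin_mean_exposure`, `rr`, `ci_low`, `ci_high`, `log_rr`, `se`,
#'   `reference`), including the reference row with RR fixed at 1.
#' @export
fit_outcome_model <- function(strata_binned, weights = NULL, exposure = NULL,
                              weight_mode = c("sw", "sw_py"),
                              conf_level = 0.95) {
  weight_mode <- match.arg(weight_mode)
  exposure <- exposure %||% attr(weights, "exposure")
  if (is.null(exposure)) stop("exposure name required", call. = FALSE)
  bin_col <- paste0(exposure, "_bin")
  assert_cols(strata_binned, c(bin_col, exposure, "deaths", "person_years"))

  bin <- strata_binned[[bin_col]]
  K <- max(bin)
  deaths_by_bin <- as.vector(rowsum(strata_binned$deaths,
                                    factor(bin, levels = seq_len(K))))
  if (any(deaths_by_bin == 0)) {
    stop(sprintf("bin(s) %s contain zero deaths; the rate ratio is undefined - consider fewer bins",
                 paste(which(deaths_by_bin == 0), collapse = ", ")), call. = FALSE)
  }

  sw <- if (is.null(weights)) rep(1, nrow(strata_binned)) else weights$sw
  if (!is.null(weights) && nrow(weights) != nrow(strata_binned)) {
    stop("weight table is not aligned with the stratum table", call. = FALSE)
  }
  w <- if (weight_mode == "sw") sw else sw * strata_binned$person_years

  dat <- data.frame(
    deaths = strata_binned$deaths,
    bin = factor(bin, levels = seq_len(K)),
    off = log(strata_binned$person_years),
    w = w
  )
  fit <- glm(deaths ~ bin + offset(off), family = quasipoisson(link = "log"),
             data = dat, weights = w)
  if (!fit$converged) {
    stop(sprintf("outcome model did not converge (weight range %.3g..%.3g)",
                 min(w), max(w)), call. = FALSE)
  }

  disp_hat <- sum(residuals(fit, type = "pearson")^2) / fit$df.residual
  dispersion <- max(1, disp_hat)
  sm <- summary(fit, dispersion = dispersion)
  est <- sm$coefficients[-1L, "Estimate"]
  se <- sm$coefficients[-1L, "Std. Error"]
  z <- qnorm(1 - (1 - conf_level) / 2)

  log_rr <- c(0, est)
  se_all <- c(NA_real_, se)
  curve <- data.frame(
    bin = seq_len(K),
    bin_mean_exposure = bin_means(strata_binned[[exposure]],
                                  strata_binned$person_years, bin, K),
    rr = exp(log_rr),
    ci_low = exp(log_rr - z * se_all),
    ci_high = exp(log_rr + z * se_all),
    log_rr = log_rr,
    se = se_all,
    reference = seq_len(K) == 1L
  )
  new_dose_response_curve(curve, exposure = exposure, K = K,
                          dispersion = dispersion, weight_mode = weight_mode)
}

#' Plot a dose-response curve
#'
#' Relative risk (with CI bars) against the mean exposure of each bin, in
#' the usual presentation for binned dose-response analyses. Requires
#' ggplot2.
#'
#' @param curve a `dose_response_curve`.
#' @param reference_lines optional numeric vector of exposure values drawn
#'   as dashed vertical lines (e.g. an air quality standard).
#' @return a ggplot object.
#' @export
plot_dose_response <- function(curve, reference_lines = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  df <- as.data.frame(curve)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_mean_exposure, y = .data$rr)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 3, colour = "grey50") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      width = 0, na.rm = TRUE
    ) +
    ggplot2::geom_point() +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = attr(curve, "exposure"), y = "relative risk of death") +
    ggplot2::theme_minimal()
  if (!is.null(reference_lines)) {
    p <- p + ggplot2::geom_vline(xintercept = reference_lines, linetype = 2)
  }
  p
}
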