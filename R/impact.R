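# -- attributable deaths ------------------------------------------------------

#' Expected annual early deaths avoided by lowering an exposure
#'
#' For a population of `n_person_years` annual averaged person-years with
#' baseline annual mortality rate `baseline_rate`, moving from the exposure
#' bin with relative risk `rr_high` down to the bin with `rr_low` avoids
#'
#' `n_person_years * baseline_rate * ((rr_high - 1)/rr_high - (rr_low - 1)/rr_low)`
#'
#' expected deaths per year: the difference in attributable fractions,
#' scaled by the baseline death toll. The result is 0 when the two relative
#' risks are equal, and negative (excess deaths, with a warning) when
#' `rr_low > rr_high`. Totals across several pollutants are the plain sum
#' of the per-pollutant values; interactions between pollutants are not
#' modeled.
#'
#' @param n_person_years annual averaged person-years at risk (N > 0).
#' @param baseline_rate baseline annual mortality rate, deaths per
#'   person-year, in (0, 1).
#' @param rr_high,rr_low relative risks of the higher- and lower-exposure
#'   bins being compared (both > 0). Vectors are recycled elementwise.
#' @return expected annual deaths avoided (numeric).
#' @export
deaths_avoided <- function(n_person_years, baseline_rate, rr_high, rr_low) {
  if (any(n_person_years <= 0)) stop("n_person_years must be positive", call. = FALSE)
  if (any(baseline_rate <= 0 | baseline_rate >= 1)) {
    stop("baseline_rate must lie in (0, 1)", call. = FALSE)
  }
  if (any(rr_high <= 0) || any(rr_low <= 0)) {
    stop("relative risks must be positive", call. = FALSE)
  }
  out <- n_person_years * baseline_rate *
    ((rr_high - 1) / rr_high - (rr_low - 1) / rr_low)
  if (any(out < 0)) {
    warning("negative deaths avoided: rr_low exceeds rr_high (excess deaths)")
  }
  out
}

#' Baseline mortality rate from a binned stratum table
#'
#' One plausible reading of the baseline annual mortality rate: deaths per
#' person-year in the reference (lowest-exposure) bin.
#'
#' @param strata_binned stratum table with `<exposure>_bin` assigned.
#' @param exposure exposure name.
#' @param reference_bin reference bin index (default 1).
#' @return deaths per person-year in the reference bin.
#' @export
baseline_rate_from <- function(strata_binned, exposure, reference_bin = 1L) {
  bin_col <- paste0(exposure, "_bin")
  assert_cols(strata_binned, c(bin_col, "deaths", "person_years"))
  sel <- strata_binned[[bin_col]] == reference_bin
  if (!any(sel)) stop("reference bin is empty", call. = FALSE)
  sum(strata_binned$deaths[sel]) / sum(strata_binned$person_years[sel])
}

# -- cohort summary -----------------------------------------------------------

#' Cohort summary arithmetic
#'
#' Builds the standard demographic summary of an open cohort from
#' person-level counts: average follow-up (total person-years divided by
#' the number of people, one decimal) and the percentage of the population
#' in each category (count over population, one decimal).
#'
#' @param population number of people in the cohort (> 0).
#' @param total_person_years total person-years of follow-up.
#' @param counts named numeric vector of person-level category counts
#'   (deaths, sex, race, age-at-entry bands, Medicaid enrollment, ...).
#' @return an object of class `cohort_summary`: `population`,
#'   `total_person_years`, `avg_followup_years` (1 decimal), and a
#'   `data.frame` `categories` with `count` and `pct` (1 decimal).
#' @export
cohort_summary <- function(population, total_person_years, counts = numeric()) {
  if (!is.numeric(population) || population <= 0) {
    stop("population must be positive", call. = FALSE)
  }
  structure(
    list(
      population = population,
      total_person_years = total_person_years,
      avg_followup_years = round(total_person_years / population, 1),
      categories = data.frame(
        category = names(counts) %||% character(),
        count = as.numeric(counts),
        pct = round(100 * as.numeric(counts) / population, 1)
      )
    ),
    class = "cohort_summary"
  )
}

#' Summarize a person-year cohort table
#'
#' Open-cohort person-year tables do not identify individuals, so the
#' person count cannot be derived from them and must be supplied (for
#' simulated cohorts, choose it to match the intended follow-up length).
#' Deaths are person-level events and are counted from the table; the
#' demographic composition is reported as person-year shares, which equal
#' person shares only when follow-up length does not depend on the
#' demographic cell.
#'
#' @param records person-year `data.frame` with `deaths`, `person_years`
#'   and categorical demographic columns.
#' @param population number of distinct people in the cohort.
#' @param categorical names of categorical columns to tabulate by
#'   person-years; defaults to the character columns other than `area_id`.
#' @return a `cohort_summary`; category counts for demographics are
#'   person-year-proportional person counts (`population * share`), while
#'   `death` is the exact death count.
#' @export
summarize_cohort <- function(records, population,
                             categorical = NULL) {
  if (missing(population) || is.null(population) || population <= 0) {
    stop("population must be a positive person count", call. = FALSE)
  }
  assert_cols(records, c("deaths", "person_years"))
  total_py <- sum(records$person_years)
  if (is.null(categorical)) {
    is_chr <- vapply(records, is.character, logical(1))
    categorical <- setdiff(names(records)[is_chr], "area_id")
  }
  counts <- c(death = sum(records$deaths))
  for (cl in categorical) {
    shares <- rowsum(records$person_years, records[[cl]]) / total_py
    v <- setNames(round(population * as.vector(shares)), rownames(shares))
    names(v) <- paste(cl, names(v), sep = ":")
    counts <- c(counts, v)
  }
  cohort_summary(population, total_py, counts)
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n")
  cat(sprintf("  population: %s   person-years: %s   avg follow-up: %.1f years\n",
              format(x$population, big.mark = ","),
              format(x$total_person_years, big.mark = ","),
              x$avg_followup_years))
  if (nrow(x$categories)) {
    df <- x$categories
    df$count <- format(df$count, big.mark = ",")
    print.data.frame(df, row.names = FALSE)
  }
  invisible(x)
}
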