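# -- stratum aggregation ------------------------------------------------------

#' Aggregate person-year records into estimation strata
#'
#' Collapses a person-year table to one row per unique combination of the
#' key fields, summing `deaths` and `person_years` and carrying every other
#' column through unchanged. Carried columns must be constant within a key
#' (true by construction when exposures and confounders are area-year
#' attributes and the key includes area and year); a non-constant column
#' raises an error naming the offending key and column.
#'
#' @param records person-year `data.frame` with `deaths` and `person_years`
#'   columns.
#' @param key_fields character vector of stratum key column names (e.g.
#'   sex, race, 5-year age group, Medicaid eligibility, area, year).
#' @return a `data.frame` with one row per unique key; total deaths and
#'   person-years are conserved.
#' @export
aggregate_person_years <- function(records,
                                   key_fields = c("sex", "race", "age_group",
                                                  "medicaid", "area_id", "year")) {
  assert_cols(records, c(key_fields, "deaths", "person_years"))
  if (any(!complete.cases(records[key_fields]))) {
    stop("missing values in key fields", call. = FALSE)
  }
  id <- key_id(records, key_fields)
  first <- !duplicated(id)
  ref_row <- match(id, id[first]) # index into the first occurrence of each key

  carry <- setdiff(names(records), c(key_fields, "deaths", "person_years"))
  for (cl in carry) {
    v <- records[[cl]]
    same <- v == v[first][ref_row]
    same[is.na(v) & is.na(v[first][ref_row])] <- TRUE
    if (!all(same, na.rm = FALSE)) {
      bad <- which(!same)[1L]
      stop(sprintf("column '%s' is not constant within stratum key '%s'",
                   cl, gsub("\r", "/", id[bad])), call. = FALSE)
    }
  }

  out <- records[first, c(key_fields, carry), drop = FALSE]
  f <- factor(id, levels = id[first])
  out$deaths <- as.vector(rowsum(records$deaths, f))
  out$person_years <- as.vector(rowsum(records$person_years, f))
  rownames(out) <- NULL
  out
}

# -- exposure binning ---------------------------------------------------------

# Core equal-mass binning scan. Sorts by exposure, computes the cumulative
# weight fraction at the *last* occurrence of each distinct value (so ties
# always share a bin), and assigns bin = ceiling(K * fraction). A value whose
# cumulative fraction lands exactly on i/K therefore closes bin i; the next
# distinct value opens bin i+1. Returns per-observation bins and the K-1
# boundaries (each the smallest value of the bin above, so binning new data
# with left-closed [boundary, ...) intervals reproduces the in-sample labels).
scan_bins <- function(x, w, K) {
  if (any(!is.finite(x))) stop("non-finite exposure values", call. = FALSE)
  if (K < 2) stop("K must be at least 2", call. = FALSE)
  o <- order(x)
  cw <- cumsum(as.numeric(w[o])) / sum(w)
  xo <- x[o]
  last <- !duplicated(xo, fromLast = TRUE)
  vals <- xo[last]
  vfrac <- cw[last]
  vbin <- pmin(K, pmax(1L, as.integer(ceiling(vfrac * K - 1e-9))))
  present <- unique(vbin)
  if (length(present) < K) {
    stop(sprintf("cannot form %d non-empty equal-mass bins from %d distinct exposure values; use fewer bins",
                 K, length(vals)), call. = FALSE)
  }
  boundaries <- vals[match(2:K, vbin)]
  list(bin = vbin[match(x, vals)], boundaries = boundaries)
}

#' Assign equal-person-year exposure bins
#'
#' Cuts a continuous exposure into `K` groups of (as near as granularity
#' allows) equal person-year mass at weighted quantiles — deciles when
#' `K = 10`. Bin 1 holds the lowest exposures and is the reference group.
#' Intervals are left-closed/right-open: a stratum exactly on a cut point
#' belongs to the upper bin, and ties in the exposure always share a bin.
#'
#' @param strata stratum `data.frame` (see [aggregate_person_years()]).
#' @param exposure name of the exposure column to bin.
#' @param K number of bins (default 10; the robustness analysis uses 14).
#' @param weight `"person_years"` (default) weights the quantiles by each
#'   stratum's person-years, so each bin holds ~1/K of the study
#'   population's follow-up time; `"strata"` gives every stratum unit
#'   weight (equal stratum counts), provided for sensitivity analyses.
#' @param mass_tol warn when any bin's weight share deviates from `1/K` by
#'   more than `max(largest single stratum share, mass_tol)`; default 0.01.
#' @return a list with `strata` (the input plus an integer column
#'   `<exposure>_bin`) and `bins` (a [bin_definition]).
#' @export
assign_exposure_bins <- function(strata, exposure, K = 10L,
                                 weight = c("person_years", "strata"),
                                 mass_tol = 0.01) {
  weight <- match.arg(weight)
  assert_cols(strata, c(exposure, "person_years"))
  w <- if (weight == "person_years") strata$person_years else rep(1, nrow(strata))
  sb <- scan_bins(strata[[exposure]], w, as.integer(K))
  bin_col <- paste0(exposure, "_bin")
  strata[[bin_col]] <- sb$bin

  mass <- as.vector(rowsum(strata$person_years, factor(sb$bin, levels = seq_len(K))))
  if (weight == "person_years") {
    # granularity: a block of strata tied on the exposure is indivisible
    tie_mass <- max(rowsum(strata$person_years, strata[[exposure]]))
    tol <- max(tie_mass / sum(strata$person_years), mass_tol)
    dev <- abs(mass / sum(mass) - 1 / K)
    if (any(dev > tol)) {
      warning(sprintf("bin person-year shares deviate from 1/K by up to %.3g (tolerance %.3g); exposure ties may prevent equal-mass bins",
                      max(dev), tol))
    }
  }

  bins <- bin_definition(
    exposure = exposure, K = as.integer(K), boundaries = sb$boundaries,
    bin_person_years = mass,
    bin_mean_exposure = bin_means(strata[[exposure]], strata$person_years, sb$bin, K),
    reference_bin = 1L, weight = weight
  )
  list(strata = strata, bins = bins)
}

bin_means <- function(x, w, bin, K) {
  f <- factor(bin, levels = seq_len(K))
  as.vector(rowsum(x * w, f) / rowsum(w, f))
}

#' Bin a new exposure value with an existing bin definition
#'
#' @param bins a [bin_definition].
#' @param x numeric exposure values.
#' @return integer bin labels in `1..K`; values on a boundary go to the
#'   upper bin.
#' @export
bin_lookup <- function(bins, x) {
  stopifnot(inherits(bins, "bin_definition"))
  1L + findInterval(x, bins$boundaries)
}

#' Per-bin exposure summaries
#'
#' Completes a [bin_definition] from binned strata: the person-year-weighted
#' mean exposure within each bin (the concentration at which each relative
#' risk is plotted on a dose-response curve) and the person-year mass per
#' bin. Errors if any bin is empty; warns if bin means are not strictly
#' increasing (possible only under heavy ties).
#'
#' @param strata_binned stratum `data.frame` carrying `<exposure>_bin`.
#' @param exposure exposure column name.
#' @param K number of bins; defaults to the maximum observed label.
#' @return a [bin_definition].
#' @export
bin_summaries <- function(strata_binned, exposure, K = NULL) {
  bin_col <- paste0(exposure, "_bin")
  assert_cols(strata_binned, c(exposure, bin_col, "person_years"))
  bin <- strata_binned[[bin_col]]
  K <- as.integer(K %||% max(bin))
  counts <- tabulate(bin, nbins = K)
  if (any(counts == 0)) {
    stop(sprintf("empty bin(s): %s", paste(which(counts == 0), collapse = ", ")),
         call. = FALSE)
  }
  m <- bin_means(strata_binned[[exposure]], strata_binned$person_years, bin, K)
  if (any(diff(m) <= 0)) {
    warning("bin mean exposures are not strictly increasing")
  }
  o <- order(strata_binned[[exposure]])
  first_of_bin <- o[!duplicated(bin[o])]
  boundaries <- sort(strata_binned[[exposure]][first_of_bin])[-1L]
  bin_definition(
    exposure = exposure, K = K, boundaries = boundaries,
    bin_person_years = as.vector(rowsum(strata_binned$person_years,
                                        factor(bin, levels = seq_len(K)))),
    bin_mean_exposure = m, reference_bin = 1L, weight = "person_years"
  )
}

# -- bin definition object ----------------------------------------------------

#' Bin definition
#'
#' Describes an equal-mass binning of one exposure: the `K - 1` ascending
#' cut points, the person-year mass and mean exposure of each bin, and the
#' reference bin (always the lowest-exposure bin). The marginal probability
#' of any observation falling in a given bin — the numerator of the
#' stabilized weight — is `1/K`.
#'
#' @param exposure exposure name.
#' @param K number of bins.
#' @param boundaries `K - 1` strictly ascending cut points, in exposure units.
#' @param bin_person_years person-year mass per bin.
#' @param bin_mean_exposure person-year-weighted mean exposure per bin.
#' @param reference_bin index of the reference bin.
#' @param weight which weighting produced the bins.
#' @return an object of class `bin_definition`.
#' @export
bin_definition <- function(exposure, K, boundaries, bin_person_years,
                           bin_mean_exposure, reference_bin = 1L,
                           weight = "person_years") {
  stopifnot(length(boundaries) == K - 1L,
            length(bin_person_years) == K,
            length(bin_mean_exposure) == K)
  if (any(diff(boundaries) <= 0)) {
    stop("bin boundaries must be strictly ascending", call. = FALSE)
  }
  structure(
    list(exposure = exposure, K = as.integer(K),
         boundaries = as.numeric(boundaries),
         bin_person_years = as.numeric(bin_person_years),
         bin_mean_exposure = as.numeric(bin_mean_exposure),
         reference_bin = as.integer(reference_bin),
         weight = weight),
    class = "bin_definition"
  )
}

#' @export
print.bin_definition <- function(x, ...) {
  cat(sprintf("<bin_definition> %s, K = %d (%s-weighted)\n",
              x$exposure, x$K, x$weight))
  cat("  boundaries:", paste(signif(x$boundaries, 4), collapse = ", "), "\n")
  cat(sprintf("  bin mass share: %.3f..%.3f (target %.3f)\n",
              min(x$bin_person_years) / sum(x$bin_person_years),
              max(x$bin_person_years) / sum(x$bin_person_years), 1 / x$K))
  invisible(x)
}

#' @rdname bin_definition
#' @param bins a `bin_definition`.
#' @param path file path.
#' @export
write_bin_definition <- function(bins, path) {
  stopifnot(inherits(bins, "bin_definition"))
  jsonlite::write_json(unclass(bins), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname bin_definition
#' @export
read_bin_definition <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(bin_definition, x)
}
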