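# Internal helpers shared across modules.

# Deterministic sub-seed for a named random substream. Each draw block in the
# cohort generator seeds its own stream, so adding a confounder does not
# perturb the death draws. Result is kept well below 2^31.
substream_seed <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes)) %% 39989L
  as.integer((as.numeric(seed) %% 49999) * 39989 + h) %% 2147483647L
}

with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, name))
  force(expr)
}

# Weighted mean/sd with fixed denominators; sd uses the weighted population
# formula (no small-sample correction), the convention used for standardized
# mean differences.
wtd_mean <- function(x, w) sum(x * w) / sum(w)

wtd_sd <- function(x, w) {
  m <- wtd_mean(x, w)
  sqrt(sum(w * (x - m)^2) / sum(w))
}

# Weighted quantile, left-continuous inverse CDF: smallest x whose cumulative
# weight fraction reaches p. Used as the reporting convention for bin
# boundaries; bin assignment itself uses the cumulative-mass scan in
# assign_exposure_bins (see that function for the tie convention).
wtd_quantile <- function(x, w, probs) {
  stopifnot(length(x) == length(w), all(w >= 0), sum(w) > 0)
  o <- order(x)
  x <- x[o]
  w <- w[o]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p - 1e-12)[1L]], numeric(1))
}

# Collapse a set of key columns to a single id vector.
key_id <- function(df, key_fields) {
  do.call(paste, c(unname(as.list(df[key_fields])), sep = "\r"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_cols <- function(df, cols, what = "column") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("missing %s(s): %s", what, paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}
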