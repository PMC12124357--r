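#' Hartigan dip statistic
#'
#' Computes the dip statistic of a univariate sample: the smallest sup-norm
#' distance between the empirical distribution function and any unimodal
#' distribution function (convex below the mode, concave above it, with an
#' atom permitted only at the mode).  The value is computed exactly by
#' enumerating candidate mode placements over the distinct sample values.
#'
#' A constant sample has dip 0 (a point mass is unimodal).  Two equal point
#' masses attain the maximal dip of 0.25.  For a sample of `n` distinct
#' values the dip is at least `1/(2n)`.  The statistic is invariant under
#' increasing affine transformations of the data.
#'
#' @param x Numeric vector, non-empty; `NA` values are not accepted.
#' @return The dip statistic, a single number in `[0, 0.25]`.
#' @seealso [dip_pvalue()] for Monte-Carlo calibration against the uniform
#'   null.
#' @examples
#' dip_statistic(c(3, 3, 3, 3, 3))          # 0
#' dip_statistic(rep(c(0, 1), each = 10))   # 0.25, maximally bimodal
#' @export
dip_statistic <- function(x) {
  if (length(x) == 0) stop("empty sample")
  if (anyNA(x)) stop("sample contains NA values")
  dip_stat_cpp(as.numeric(x))
}

#' Monte-Carlo p-value for the dip statistic
#'
#' Calibrates an observed dip against samples of the same size drawn from
#' the uniform distribution on (0, 1), the canonical unimodal null.  The
#' p-value uses the add-one correction `(1 + k) / (1 + n_boot)` where `k`
#' counts null dips at least as large as the observed one, so a dip of 0
#' always yields p = 1.
#'
#' Samples with fewer than `min_distinct` distinct values are reported as
#' unimodal by convention (p = 1): the dip has essentially no resolution
#' there and heavily tied copy-number data would otherwise be flagged
#' spuriously.
#'
#' @param dip Observed dip statistic (from [dip_statistic()]).
#' @param n Sample size the dip was computed from.
#' @param n_boot Number of null samples (default 10000).
#' @param seed Integer seed for the null draws (mandatory).
#' @param n_distinct Number of distinct values in the observed sample; when
#'   supplied and smaller than `min_distinct` the p-value is 1.
#' @param min_distinct Convention threshold (default 4).
#' @return A p-value in (0, 1].
#' @export
dip_pvalue <- function(dip, n, n_boot = 10000, seed, n_distinct = NULL,
                       min_distinct = 4) {
  if (n_boot < 1) stop("n_boot must be at least 1")
  if (!is.null(n_distinct) && n_distinct < min_distinct) return(1)
  if (n < min_distinct) return(1)
  null <- dip_null_distribution(n, n_boot = n_boot, seed = seed)
  (1 + sum(null >= dip)) / (1 + n_boot)
}

#' Null distribution of the dip for uniform samples
#'
#' Draws `n_boot` uniform(0, 1) samples of size `n` and returns their dip
#' statistics.  Used internally by [dip_pvalue()] and cached per sample
#' size by [classify_strs()].
#'
#' @inheritParams dip_pvalue
#' @return Numeric vector of `n_boot` null dip values.
#' @export
dip_null_distribution <- function(n, n_boot = 10000, seed) {
  key <- paste(n, n_boot, seed, sep = "_")
  hit <- .dip_null_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- with_seed(seed, dip_null_cpp(as.integer(n), as.integer(n_boot)))
  .dip_null_cache[[key]] <- out
  out
}

# session cache for simulated dip null tables (keyed by n, n_boot, seed)
.dip_null_cache <- new.env(hash = TRUE, parent = emptyenv())
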