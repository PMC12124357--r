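#' Two-sample Kolmogorov-Smirnov test
#'
#' Computes `D`, the supremum distance between the empirical distribution
#' functions of `x` and `y`, with a two-sided p-value from the asymptotic
#' Kolmogorov distribution evaluated at `sqrt(n_eff) * D`, where
#' `n_eff = n_x * n_y / (n_x + n_y)`.  Ties are handled exactly in `D`
#' (the ECDFs are compared at all jump points).
#'
#' @param x,y Non-empty numeric vectors.
#' @return List with elements `statistic` (D) and `p_value`.
#' @examples
#' ks_two_sample(c(1, 2, 3), c(4, 5, 6))$statistic  # 1: disjoint supports
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("empty sample")
  if (anyNA(x) || anyNA(y)) stop("samples contain NA values")
  nx <- length(x)
  ny <- length(y)
  pts <- sort(unique(c(x, y)))
  fx <- vapply(pts, function(p) sum(x <= p), numeric(1)) / nx
  fy <- vapply(pts, function(p) sum(y <= p), numeric(1)) / ny
  d <- max(abs(fx - fy))
  neff <- nx * ny / (nx + ny)
  list(statistic = d, p_value = kolmogorov_sf(sqrt(neff) * d))
}

# Survival function of the Kolmogorov distribution:
# P(K >= lambda) = 2 * sum_{k>=1} (-1)^{k-1} exp(-2 k^2 lambda^2).
kolmogorov_sf <- function(lambda) {
  if (lambda <= 0) return(1)
  k <- seq_len(101)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(1, max(0, p))
}

#' One-sided Wilcoxon rank-sum test
#'
#' Rank-sum test with midranks for ties and the normal approximation with
#' tie-corrected variance (no continuity correction).  With
#' `alternative = "greater"` the p-value is for `x` tending to exceed `y`.
#'
#' @param x,y Non-empty numeric vectors.
#' @param alternative `"greater"` (default) or `"less"`.
#' @param correct Apply the 0.5 continuity correction (default `TRUE`),
#'   which brings the normal approximation closer to the exact permutation
#'   p-value at small sample sizes.
#' @return List with elements `statistic` (the z score) and `p_value`.
#' @export
rank_sum_one_sided <- function(x, y, alternative = c("greater", "less"),
                               correct = TRUE) {
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0) stop("empty sample")
  if (anyNA(x) || anyNA(y)) stop("samples contain NA values")
  nx <- length(x)
  ny <- length(y)
  n <- nx + ny
  r <- rank(c(x, y))
  rx <- sum(r[seq_len(nx)])
  mu <- nx * (n + 1) / 2
  ties <- table(r)
  tiecor <- sum(ties^3 - ties) / (n * (n - 1))
  v <- nx * ny / 12 * ((n + 1) - tiecor)
  if (v <= 0) {
    # all observations identical: no evidence of a shift
    return(list(statistic = 0, p_value = 1))
  }
  dev <- rx - mu
  cc <- if (correct) 0.5 else 0
  z <- if (alternative == "greater") (dev - cc) / sqrt(v) else
    (dev + cc) / sqrt(v)
  p <- if (alternative == "greater") pnorm(z, lower.tail = FALSE) else pnorm(z)
  list(statistic = z, p_value = p)
}

#' Multiple-testing adjustment
#'
#' Adjusts p-values by Bonferroni (`min(1, m * p)`) or Benjamini-Hochberg
#' step-up q-values, preserving input order.
#'
#' @param ps Numeric vector of p-values in `[0, 1]`.
#' @param method `"bh"` or `"bonferroni"`.
#' @return Adjusted p-values in the input order.
#' @export
adjust_pvalues <- function(ps, method = c("bh", "bonferroni")) {
  method <- match.arg(method)
  if (length(ps) == 0) return(numeric(0))
  if (any(ps < 0 | ps > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(ps, method = if (method == "bh") "BH" else "bonferroni")
}

#' Two-proportion test
#'
#' Two-sided chi-square test (no continuity correction) on the pooled
#' z statistic for comparing `k1/n1` against `k2/n2`.
#'
#' @param k1,n1 Successes and trials in group 1.
#' @param k2,n2 Successes and trials in group 2.
#' @return List with `statistic` (z), `p_value`.
#' @export
two_proportion_test <- function(k1, n1, k2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("zero denominator")
  if (k1 > n1 || k2 > n2 || k1 < 0 || k2 < 0) stop("counts out of range")
  p1 <- k1 / n1
  p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  v <- pp * (1 - pp) * (1 / n1 + 1 / n2)
  if (v == 0) return(list(statistic = 0, p_value = 1))
  z <- (p1 - p2) / sqrt(v)
  list(statistic = z, p_value = pchisq(z^2, df = 1, lower.tail = FALSE))
}

#' DerSimonian-Laird random-effects pooling of log odds ratios
#'
#' Pools per-study log odds ratios with inverse-variance weights, a
#' method-of-moments between-study variance `tau2 = max(0, (Q - df) / C)`,
#' and re-weighted pooled estimate with its 95% confidence interval on the
#' odds-ratio scale.  A single study is returned as-is with `tau2 = 0`.
#'
#' @param log_or Numeric vector of study log odds ratios.
#' @param se Positive standard errors, same length.
#' @return List with `pooled_or`, `ci_low`, `ci_high`, `tau2`,
#'   `pooled_log_or`, `pooled_se`, `Q`.
#' @export
random_effects_pool <- function(log_or, se) {
  if (length(log_or) == 0) stop("at least one study required")
  if (length(se) != length(log_or)) stop("log_or and se lengths differ")
  if (any(se <= 0)) stop("standard errors must be positive")
  k <- length(log_or)
  w <- 1 / se^2
  fixed <- sum(w * log_or) / sum(w)
  Q <- sum(w * (log_or - fixed)^2)
  tau2 <- 0
  if (k > 1) {
    C <- sum(w) - sum(w^2) / sum(w)
    tau2 <- max(0, (Q - (k - 1)) / C)
  }
  wstar <- 1 / (se^2 + tau2)
  est <- sum(wstar * log_or) / sum(wstar)
  se_p <- sqrt(1 / sum(wstar))
  z <- qnorm(0.975)
  list(
    pooled_or = exp(est),
    ci_low = exp(est - z * se_p),
    ci_high = exp(est + z * se_p),
    tau2 = tau2,
    pooled_log_or = est,
    pooled_se = se_p,
    Q = Q
  )
}
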