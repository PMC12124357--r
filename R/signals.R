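#' Per-gene log2 fold change between species
#'
#' Scales each condition to counts per million, averages over the matched
#' conditions, and returns
#' `log2((cpm_human + pseudocount) / (cpm_other + pseudocount))` per gene.
#'
#' @param expr_human,expr_other Genes x conditions matrices over an
#'   identical gene universe (same rownames, same order).
#' @param pseudocount Pseudocount on the CPM scale (default 1).
#' @return Named numeric vector of per-gene log2 fold changes.
#' @export
log_fold_change <- function(expr_human, expr_other, pseudocount = 1) {
  if (!identical(rownames(expr_human), rownames(expr_other))) {
    stop("gene universe mismatch between the two tables")
  }
  cpm <- function(m) {
    sweep(m, 2, colSums(m), "/") * 1e6
  }
  h <- rowMeans(cpm(expr_human))
  o <- rowMeans(cpm(expr_other))
  setNames(log2((h + pseudocount) / (o + pseudocount)), rownames(expr_human))
}

#' One-sided gene-set shift test on fold changes
#'
#' Rank-sum test of the set genes' log fold changes against the background
#' genes' (default direction: set shifted upward).  [gene_set_shift_batch()]
#' applies it across conditions with BH adjustment at the conventional
#' q < 0.1 significance level.
#'
#' @param lfc Named numeric vector of per-gene log fold changes.
#' @param set_genes,background_genes Disjoint, non-empty gene id vectors.
#' @param alternative `"greater"` (default) or `"less"`.
#' @return List with `p_value` and `statistic`.
#' @export
gene_set_shift_test <- function(lfc, set_genes, background_genes,
                                alternative = "greater") {
  if (length(set_genes) == 0 || length(background_genes) == 0) {
    stop("empty gene set")
  }
  if (length(intersect(set_genes, background_genes)) > 0) {
    stop("set and background must be disjoint")
  }
  x <- lfc[names(lfc) %in% set_genes]
  y <- lfc[names(lfc) %in% background_genes]
  if (length(x) == 0 || length(y) == 0) stop("no fold changes for a group")
  rank_sum_one_sided(x, y, alternative)
}

#' Batch gene-set shift tests across conditions
#'
#' @param lfc_list Named list of per-condition log-fold-change vectors.
#' @param set_genes,background_genes As in [gene_set_shift_test()].
#' @param alternative Test direction.
#' @param q_threshold Significance level on BH-adjusted p (default 0.1).
#' @return Data frame with `condition`, `p`, `q`, `significant`.
#' @export
gene_set_shift_batch <- function(lfc_list, set_genes, background_genes,
                                 alternative = "greater",
                                 q_threshold = 0.1) {
  ps <- vapply(lfc_list, function(lfc) {
    gene_set_shift_test(lfc, set_genes, background_genes,
                        alternative)$p_value
  }, numeric(1))
  qs <- adjust_pvalues(ps, "bh")
  data.frame(condition = names(lfc_list), p = unname(ps), q = unname(qs),
             significant = unname(qs) < q_threshold,
             stringsAsFactors = FALSE)
}

#' Average expression in equal-count pseudotime bins
#'
#' Divides cells into `n_bins` equal-count bins along their pseudotime
#' ordering (quantile binning, so no bin is empty) and returns the per-bin
#' mean expression of each gene.
#'
#' @param cell_expr Genes x cells expression matrix.
#' @param pseudotime Numeric vector of finite pseudotimes along the cells.
#' @param n_bins Number of bins (default 100).
#' @return Genes x bins matrix of mean expression.
#' @export
pseudotime_bin_means <- function(cell_expr, pseudotime, n_bins = 100) {
  nc <- ncol(cell_expr)
  if (length(pseudotime) != nc) stop("pseudotime length must match cells")
  if (!all(is.finite(pseudotime))) stop("pseudotime must be finite")
  if (nc < n_bins) {
    stop("fewer cells than bins: reduce n_bins to at most ", nc)
  }
  ord <- rank(pseudotime, ties.method = "first")
  bin <- ceiling(ord * n_bins / nc)
  out <- matrix(NA_real_, nrow = nrow(cell_expr), ncol = n_bins,
                dimnames = list(rownames(cell_expr),
                                sprintf("bin%03d", seq_len(n_bins))))
  for (b in seq_len(n_bins)) {
    out[, b] <- rowMeans(cell_expr[, bin == b, drop = FALSE])
  }
  out
}

#' Fisher enrichment of a gene set within expression modules
#'
#' Tests each module for enrichment of `set_genes` against the rest of the
#' universe via the exact 2x2 test, with BH adjustment across modules.
#'
#' @param module_assignment Named character/integer vector: module label
#'   per gene (a subset of the universe may be unassigned).
#' @param set_genes Genes of interest.
#' @param universe All genes under consideration.
#' @return Data frame per module: counts, odds ratio, p, q.
#' @export
module_enrichment <- function(module_assignment, set_genes, universe) {
  if (!all(names(module_assignment) %in% universe)) {
    stop("module genes outside the universe")
  }
  set_genes <- intersect(set_genes, universe)
  mods <- sort(unique(module_assignment))
  res <- lapply(mods, function(m) {
    in_mod <- names(module_assignment)[module_assignment == m]
    set_in <- universe %in% set_genes
    mod_in <- universe %in% in_mod
    fe <- fisher_enrichment(mod_in[set_in], mod_in[!set_in])
    data.frame(module = m, n_set_in_module = fe$table[["a"]],
               n_module = sum(mod_in), odds_ratio = fe$odds_ratio,
               p = fe$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- adjust_pvalues(out$p, "bh")
  out
}

#' Ranked (GSEA-style) set enrichment with permutation p-value
#'
#' Sorts items by score in descending order and forms the running sum that
#' adds `|score|^w / sum_members |score|^w` at members and subtracts
#' `1/(N - N_members)` at non-members; the enrichment score is the signed
#' maximal deviation.  At `weight_exponent = 0` the absolute score equals
#' the two-sample Kolmogorov-Smirnov statistic between member and
#' non-member rank distributions.  The p-value permutes the member labels
#' (one-sided toward the observed sign).
#'
#' @param item_scores Numeric vector of finite scores (e.g. per-peak fold
#'   changes, ranked in descending order internally).
#' @param member_flags Logical vector marking the set members.
#' @param weight_exponent Score weighting exponent (default 1).
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Integer seed.
#' @return List with `es`, `p_value`, `leading_edge` (indices into the
#'   original vector), `n_perm`.
#' @export
ranked_set_enrichment <- function(item_scores, member_flags,
                                  weight_exponent = 1, n_perm = 1000,
                                  seed) {
  if (!all(is.finite(item_scores))) stop("scores must be finite")
  if (all(member_flags) || !any(member_flags)) {
    stop("need at least one member and one non-member")
  }
  es_fun <- function(flags) {
    ord <- order(item_scores, decreasing = TRUE)
    f <- flags[ord]
    s <- abs(item_scores[ord])^weight_exponent
    inc <- ifelse(f, s / sum(s[f]), -1 / sum(!f))
    run <- cumsum(inc)
    run[which.max(abs(run))]
  }
  es <- es_fun(member_flags)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      es_fun(sample(member_flags))
    }, numeric(1))
  })
  k <- if (es >= 0) sum(perm >= es) else sum(perm <= es)
  ord <- order(item_scores, decreasing = TRUE)
  f <- member_flags[ord]
  s <- abs(item_scores[ord])^weight_exponent
  run <- cumsum(ifelse(f, s / sum(s[f]), -1 / sum(!f)))
  peak <- which.max(abs(run))
  lead <- if (es >= 0) ord[seq_len(peak)][f[seq_len(peak)]] else
    ord[peak:length(run)][f[peak:length(run)]]
  list(es = es, p_value = (1 + k) / (1 + n_perm), leading_edge = lead,
       n_perm = n_perm)
}
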