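gene_body_granges <- function(genes) {
  GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(start = genes$start + 1, end = genes$end),
    gene_id = genes$gene_id)
}

gene_promoter_granges <- function(genes, promoter_halfwidth = 3000) {
  GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(start = pmax(1, genes$tss - promoter_halfwidth + 1),
                     end = genes$tss + promoter_halfwidth),
    gene_id = genes$gene_id)
}

str_ids <- function(strs) {
  if (!is.null(strs$name)) return(as.character(strs$name))
  if (!is.null(names(strs))) return(names(strs))
  as.character(seq_along(strs))
}

support_by_gene <- function(hits, gene_ids, hestr_names) {
  sup <- split(hestr_names[S4Vectors::queryHits(hits)],
               gene_ids[S4Vectors::subjectHits(hits)])
  lapply(sup, unique)
}

#' Regulation-by-colocalization (RBC) genes
#'
#' A gene qualifies when at least one expanded STR overlaps its promoter
#' (TSS +/- 3 kb) or gene body.
#'
#' @param hestrs [GenomicRanges::GRanges] of expanded STRs (named, or with
#'   a `name` column).
#' @param genes Gene-model data frame (`gene_id`, `chrom`, `strand`,
#'   `tss`, `start`, `end`; 0-based).
#' @param promoter_halfwidth Promoter half-width in bp (default 3000).
#' @return List with `genes` (character vector) and `support` (named list
#'   of supporting STR ids per gene).
#' @export
rbc_genes <- function(hestrs, genes, promoter_halfwidth = 3000) {
  ids <- str_ids(hestrs)
  targets <- c(gene_promoter_granges(genes, promoter_halfwidth),
               gene_body_granges(genes))
  hits <- GenomicRanges::findOverlaps(hestrs, targets, ignore.strand = TRUE)
  sup <- support_by_gene(hits, targets$gene_id, ids)
  list(genes = sort(unique(names(sup))), support = sup)
}

#' Regulation-by-looping (RBL) genes
#'
#' A gene qualifies when at least `min_hestrs` distinct expanded STRs
#' overlap the union of its promoter-centered loop anchors (either anchor,
#' pooled across tissues).
#'
#' @param hestrs [GenomicRanges::GRanges] of expanded STRs.
#' @param loops Data frame with columns `gene_id`, `chrom1`, `start1`,
#'   `end1`, `chrom2`, `start2`, `end2` (0-based half-open anchors) and
#'   optionally `tissue`.
#' @param min_hestrs Minimum distinct supporting STRs (default 2).
#' @return List with `genes` and `support` as in [rbc_genes()].
#' @export
rbl_genes <- function(hestrs, loops, min_hestrs = 2) {
  if (nrow(loops) == 0) return(list(genes = character(0), support = list()))
  trans <- loops$chrom1 != loops$chrom2
  if (any(trans)) {
    warning(sum(trans), " trans-chromosomal loop(s) rejected")
    loops <- loops[!trans, , drop = FALSE]
  }
  ids <- str_ids(hestrs)
  anchors <- GenomicRanges::GRanges(
    c(loops$chrom1, loops$chrom2),
    IRanges::IRanges(start = c(loops$start1, loops$start2) + 1,
                     end = c(loops$end1, loops$end2)),
    gene_id = rep(loops$gene_id, 2))
  hits <- GenomicRanges::findOverlaps(hestrs, anchors, ignore.strand = TRUE)
  sup <- support_by_gene(hits, anchors$gene_id, ids)
  sup <- sup[vapply(sup, length, integer(1)) >= min_hestrs]
  list(genes = sort(unique(names(sup))), support = sup)
}

#' Regulation-by-TAD (RBT) genes
#'
#' A gene qualifies when its body overlaps an innermost-TAD interval (any
#' tissue) that itself contains at least one expanded STR.
#'
#' @param hestrs [GenomicRanges::GRanges] of expanded STRs.
#' @param ihtads [GenomicRanges::GRanges] of innermost TADs (pooled over
#'   tissues).
#' @param genes Gene-model data frame as in [rbc_genes()].
#' @return List with `genes` and `support`.
#' @export
rbt_genes <- function(hestrs, ihtads, genes) {
  if (length(ihtads) == 0) {
    return(list(genes = character(0), support = list()))
  }
  ids <- str_ids(hestrs)
  tad_hits <- GenomicRanges::findOverlaps(hestrs, ihtads,
                                          ignore.strand = TRUE)
  with_str <- unique(S4Vectors::subjectHits(tad_hits))
  if (length(with_str) == 0) {
    return(list(genes = character(0), support = list()))
  }
  body <- gene_body_granges(genes)
  gene_hits <- GenomicRanges::findOverlaps(body, ihtads[with_str],
                                           ignore.strand = TRUE)
  sup <- list()
  for (i in seq_len(length(gene_hits))) {
    g <- body$gene_id[S4Vectors::queryHits(gene_hits)[i]]
    tad <- with_str[S4Vectors::subjectHits(gene_hits)[i]]
    inside <- ids[S4Vectors::queryHits(tad_hits)[
      S4Vectors::subjectHits(tad_hits) == tad]]
    sup[[g]] <- unique(c(sup[[g]], inside))
  }
  list(genes = sort(unique(names(sup))), support = sup)
}

#' Combine the three regulatory mechanisms into target-gene categories
#'
#' Genes supported by at least two of colocalization, looping and TAD
#' co-membership are "regulation by multiple mechanisms" (RBM); genes with
#' exactly one mechanism are RBC-only / RBL-only / RBT-only.
#'
#' @param rbc,rbl,rbt Outputs of [rbc_genes()], [rbl_genes()],
#'   [rbt_genes()] (or plain character vectors of gene ids).
#' @return Data frame with `gene_id`, logical `rbc`, `rbl`, `rbt`, and
#'   `category` in {RBC-only, RBL-only, RBT-only, RBM}.
#' @export
categorize_targets <- function(rbc, rbl, rbt) {
  as_set <- function(x) if (is.list(x)) x$genes else as.character(x)
  a <- as_set(rbc)
  b <- as_set(rbl)
  c <- as_set(rbt)
  uni <- sort(unique(c(a, b, c)))
  fa <- uni %in% a
  fb <- uni %in% b
  fc <- uni %in% c
  nmech <- fa + fb + fc
  category <- ifelse(nmech >= 2, "RBM",
                     ifelse(fa, "RBC-only",
                            ifelse(fb, "RBL-only", "RBT-only")))
  data.frame(gene_id = uni, rbc = fa, rbl = fb, rbt = fc,
             category = category, stringsAsFactors = FALSE)
}
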