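#' Read a BED-like track into a GRanges
#'
#' Reads a headerless tab-separated BED3+ file (0-based half-open) into a
#' 1-based closed [GenomicRanges::GRanges].  Column 4 is taken as `name`,
#' column 5 as a numeric `value` (e.g. a per-TAD interaction frequency),
#' column 6 as strand.
#'
#' @param path File path.
#' @return A [GenomicRanges::GRanges].
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  gr <- GenomicRanges::GRanges(
    df[[1]], IRanges::IRanges(start = df[[2]] + 1, end = df[[3]]))
  if (ncol(df) >= 4) gr$name <- as.character(df[[4]])
  if (ncol(df) >= 5) gr$value <- suppressWarnings(as.numeric(df[[5]]))
  if (ncol(df) >= 6) {
    st <- df[[6]]
    st[!st %in% c("+", "-")] <- "*"
    BiocGenerics::strand(gr) <- st
  }
  gr
}

#' Write a GRanges to a BED file
#'
#' Writes 0-based half-open coordinates, tab-separated, no header.  `name`
#' and `value` metadata columns are emitted when present.
#'
#' @param gr A [GenomicRanges::GRanges].
#' @param path Output file path.
#' @export
write_bed <- function(gr, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  if (!is.null(gr$name)) df$name <- gr$name
  if (!is.null(gr$value)) {
    if (is.null(df$name)) df$name <- "."
    df$value <- gr$value
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Overlap flags between two interval tracks
#'
#' Flags each interval of `a` that overlaps `b` after symmetric extension
#' of `b` by `slop` bp, requiring at least `min_overlap` overlapping bases.
#' Coordinates are half-open in BED terms: adjacent intervals do not
#' overlap.
#'
#' @param a,b [GenomicRanges::GRanges] tracks.
#' @param slop Symmetric extension of `b` in bp (default 0).
#' @param min_overlap Minimum overlap in bp (default 1).
#' @return Logical vector along `a`; the pair list is attached as
#'   attribute `"pairs"` (a data frame of query/subject indices).
#' @export
interval_overlaps <- function(a, b, slop = 0, min_overlap = 1) {
  if (slop < 0) stop("slop must be non-negative")
  bb <- if (slop > 0) {
    GenomicRanges::trim(suppressWarnings(GenomicRanges::resize(
      b, width = GenomicRanges::width(b) + 2 * slop, fix = "center")))
  } else {
    b
  }
  hits <- GenomicRanges::findOverlaps(a, bb, minoverlap = min_overlap,
                                      ignore.strand = TRUE)
  flag <- logical(length(a))
  flag[unique(S4Vectors::queryHits(hits))] <- TRUE
  attr(flag, "pairs") <- data.frame(
    query = S4Vectors::queryHits(hits),
    subject = S4Vectors::subjectHits(hits)
  )
  flag
}

#' Distance from each interval to the closest interval of another track
#'
#' Returns the minimal gap in bp between interval boundaries (0 when the
#' intervals overlap or are adjacent in 1-based closed coordinates of
#' width-positive BED intervals).  Intervals on chromosomes absent from
#' `b` get `Inf`.
#'
#' @param a,b [GenomicRanges::GRanges] tracks.
#' @return Numeric vector of distances along `a`.
#' @export
closest_distance <- function(a, b) {
  d <- rep(Inf, length(a))
  hits <- suppressWarnings(
    GenomicRanges::distanceToNearest(a, b, ignore.strand = TRUE))
  d[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  d
}

#' Categorize STRs by genomic region
#'
#' Assigns each STR exactly one label with precedence
#' promoter > exon > intron > intergenic.  The promoter is the 3-kb window
#' on each side of the transcription start site (TSS); STRs overlapping a
#' gene body outside exons are intronic; STRs touching neither promoters
#' nor gene bodies are intergenic.
#'
#' @param strs [GenomicRanges::GRanges] of STR loci.
#' @param genes Data frame of gene models: `gene_id`, `chrom`, `strand`,
#'   `tss` (0-based position), `start`, `end` (0-based half-open body).
#' @param exons Optional [GenomicRanges::GRanges] of exons; when absent no
#'   STR is labelled `exon`.
#' @param promoter_halfwidth Promoter half-width in bp (default 3000).
#' @return Character vector of categories along `strs`.
#' @export
annotate_region_category <- function(strs, genes, exons = NULL,
                                     promoter_halfwidth = 3000) {
  if (any(genes$end <= genes$start)) stop("gene with end <= start")
  prom <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(start = pmax(1, genes$tss - promoter_halfwidth + 1),
                     end = genes$tss + promoter_halfwidth))
  body <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(start = genes$start + 1, end = genes$end))
  cat <- rep("intergenic", length(strs))
  in_body <- interval_overlaps(strs, body)
  cat[in_body] <- "intron"
  if (!is.null(exons) && length(exons) > 0) {
    cat[interval_overlaps(strs, exons)] <- "exon"
  }
  cat[interval_overlaps(strs, prom)] <- "promoter"
  cat
}

#' Fisher enrichment of a feature between a set and its background
#'
#' Builds the 2x2 table {set, background} x {overlaps feature, not} and
#' computes the two-sided exact p-value by summing hypergeometric
#' probabilities no larger than the observed table's.  The odds ratio is
#' the sample estimate `ad/bc`, with the Haldane-Anscombe 0.5 correction
#' applied (and flagged) only when a zero cell occurs.
#'
#' @param set_flags Logical vector: feature overlap per set member.
#' @param background_flags Logical vector: feature overlap per background
#'   member (set and background must be disjoint collections; the usual
#'   background is the conserved-STR set minus the expanded set).
#' @return List with `table` (2x2 counts a, b, c, d), `odds_ratio`,
#'   `p_value`, `haldane` flag.
#' @export
fisher_enrichment <- function(set_flags, background_flags) {
  if (length(set_flags) == 0 || length(background_flags) == 0) {
    stop("empty set or background")
  }
  a <- sum(set_flags)
  b <- sum(!set_flags)
  c <- sum(background_flags)
  d <- sum(!background_flags)
  if ((a + c) == 0 || (b + d) == 0) {
    stop("degenerate margin: feature column all-zero or all-one")
  }
  hald <- any(c(a, b, c, d) == 0)
  or <- if (hald) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else {
    (a * d) / (b * c)
  }
  list(table = c(a = a, b = b, c = c, d = d),
       odds_ratio = or,
       p_value = hypergeom_two_sided(a, b, c, d),
       haldane = hald)
}

# two-sided exact p: sum of hypergeometric point probabilities <= observed
# (with the conventional 1e-7 relative slack against ties)
hypergeom_two_sided <- function(a, b, c, d) {
  m <- a + b          # set size
  n <- c + d          # background size
  k <- a + c          # feature successes
  lo <- max(0, k - n)
  hi <- min(k, m)
  xs <- lo:hi
  probs <- dhyper(xs, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Density profile of STRs around feature centers
#'
#' Bins STR midpoints by their offset from the nearest feature center
#' within `half_window` bp, and reports per-bin densities (loci per bp per
#' feature), the layout used to profile STR density around regulatory
#' element centers.
#'
#' @param strs [GenomicRanges::GRanges] of STR loci.
#' @param features [GenomicRanges::GRanges] of features (centers used).
#' @param half_window Window half-width in bp (default 2000).
#' @param n_bins Even number of bins (default 40).
#' @return List with `bin_mid` (offsets) and `density`.
#' @export
density_profile <- function(strs, features, half_window = 2000,
                            n_bins = 40) {
  if (length(features) == 0) stop("no features")
  if (n_bins %% 2 != 0) stop("n_bins must be even")
  centers <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(features),
    IRanges::IRanges(start = (GenomicRanges::start(features) +
                                GenomicRanges::end(features)) %/% 2,
                     width = 1))
  mids <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(strs),
    IRanges::IRanges(start = (GenomicRanges::start(strs) +
                                GenomicRanges::end(strs)) %/% 2,
                     width = 1))
  hits <- GenomicRanges::distanceToNearest(mids, centers,
                                           ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  off <- GenomicRanges::start(mids)[qi] - GenomicRanges::start(centers)[si]
  off <- off[abs(off) <= half_window]
  edges <- seq(-half_window, half_window, length.out = n_bins + 1)
  counts <- tabulate(findInterval(off, edges, rightmost.closed = TRUE),
                     nbins = n_bins)
  width <- diff(edges)[1]
  list(bin_mid = (edges[-1] + edges[-length(edges)]) / 2,
       density = counts / (width * length(features)))
}

#' Permutation resampling test against a background pool
#'
#' Draws size-matched subsets from `pool_ids`, recomputes the statistic,
#' and returns the add-one empirical p-value
#' `(1 + #{permuted >= observed}) / (1 + n_perm)` (direction
#' configurable).
#'
#' @param observed_stat Observed statistic of the focal set.
#' @param set_ids Focal identifiers (only their number is used).
#' @param pool_ids Pool to resample from (at least as large as the set).
#' @param stat_fn Function mapping a vector of ids to a statistic.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param direction `"greater"` (default) or `"less"`.
#' @return List with `p_value` and the permuted statistics `perm`.
#' @export
permutation_resample_test <- function(observed_stat, set_ids, pool_ids,
                                      stat_fn, n_perm = 1000, seed,
                                      direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (n_perm < 1) stop("n_perm must be positive")
  if (length(set_ids) > length(pool_ids)) stop("set larger than pool")
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      stat_fn(sample(pool_ids, length(set_ids)))
    }, numeric(1))
  })
  k <- if (direction == "greater") sum(perm >= observed_stat) else
    sum(perm <= observed_stat)
  list(p_value = (1 + k) / (1 + n_perm), perm = perm)
}
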