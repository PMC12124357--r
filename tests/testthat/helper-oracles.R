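# Independent brute-force oracles used across the test files.

# all-pairs interval overlap (GRanges semantics, ignore strand)
brute_overlaps <- function(a, b, slop = 0, min_overlap = 1) {
  ac <- as.character(GenomicRanges::seqnames(a))
  bc <- as.character(GenomicRanges::seqnames(b))
  as <- GenomicRanges::start(a); ae <- GenomicRanges::end(a)
  bs <- GenomicRanges::start(b) - slop; be <- GenomicRanges::end(b) + slop
  vapply(seq_along(a), function(i) {
    any(bc == ac[i] & pmin(ae[i], be) - pmax(as[i], bs) + 1 >= min_overlap)
  }, logical(1))
}

brute_closest <- function(a, b) {
  ac <- as.character(GenomicRanges::seqnames(a))
  bc <- as.character(GenomicRanges::seqnames(b))
  as <- GenomicRanges::start(a); ae <- GenomicRanges::end(a)
  bs <- GenomicRanges::start(b); be <- GenomicRanges::end(b)
  vapply(seq_along(a), function(i) {
    j <- bc == ac[i]
    if (!any(j)) return(Inf)
    gaps <- pmax(0, pmax(bs[j] - ae[i], as[i] - be[j]) - 1)
    min(gaps)
  }, numeric(1))
}

# exact one-sided rank-sum p by enumeration of all label assignments
enum_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  idx <- utils::combn(length(pooled), nx)
  r <- rank(pooled)
  obs <- sum(r[seq_len(nx)])
  stats <- apply(idx, 2, function(ii) sum(r[ii]))
  mean(stats >= obs)
}

# exact two-sided K-S p by enumeration of all label assignments
enum_ks <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  ks_d <- function(a, b) {
    pts <- sort(unique(c(a, b)))
    max(abs(vapply(pts, function(p) mean(a <= p) - mean(b <= p), numeric(1))))
  }
  obs <- ks_d(x, y)
  idx <- utils::combn(length(pooled), nx)
  stats <- apply(idx, 2, function(ii) ks_d(pooled[ii], pooled[-ii]))
  list(d = obs, p = mean(stats >= obs - 1e-12))
}

# maximal periodic runs by lookahead regex (independent of the
# sliding-comparison implementation); overlapping tracts allowed
regex_repeats <- function(segment, min_copies = 2, min_tract_bp = 4) {
  L <- nchar(segment)
  ch <- strsplit(segment, "", fixed = TRUE)[[1]]
  out <- list()
  for (m in 1:6) {
    pat <- sprintf("(?=(([ACGT]{%d})\\2+))", m)
    hits <- gregexpr(pat, segment, perl = TRUE)[[1]]
    if (hits[1] == -1) next
    cl <- attr(hits, "capture.length")[, 1]
    for (j in seq_along(hits)) {
      i <- hits[j]
      # keep only maximal starts: the run must not extend to the left
      if (i > 1 && i + m - 1 <= L && ch[i - 1] == ch[i - 1 + m]) next
      tract_len <- cl[j]
      # extend by a partial unit to the full maximal run
      while (i + tract_len <= L &&
             ch[i + tract_len] == ch[i + tract_len - m]) {
        tract_len <- tract_len + 1
      }
      motif <- substr(segment, i, i + m - 1)
      copies <- tract_len / m
      if (copies < min_copies || tract_len < min_tract_bp) next
      if (!strexpand:::is_primitive_motif(motif)) next
      out[[length(out) + 1]] <- data.frame(
        start = i - 1, end = i - 1 + tract_len,
        motif = motif, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      motif = character(0)))
  }
  tr <- do.call(rbind, out)
  tr <- tr[order(tr$start, nchar(tr$motif)), ]
  tr[!duplicated(tr[, c("start", "end")]), ]
}

# brute-force PWM window scoring over one strand
brute_scan_scores <- function(seq, lo) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  code <- match(ch, c("A", "C", "G", "T"))
  L <- ncol(lo)
  n <- length(code)
  if (n < L) return(numeric(0))
  vapply(seq_len(n - L + 1), function(i) {
    idx <- code[i:(i + L - 1)]
    if (anyNA(idx)) return(-Inf)
    sum(lo[cbind(idx, seq_len(L))])
  }, numeric(1))
}

random_granges <- function(n, genome_size = 1e5, width_max = 500,
                           chroms = c("chr1", "chr2")) {
  st <- sample.int(genome_size, n, replace = TRUE)
  w <- sample.int(width_max, n, replace = TRUE)
  GenomicRanges::GRanges(sample(chroms, n, replace = TRUE),
                         IRanges::IRanges(start = st, width = w))
}
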