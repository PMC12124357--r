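#' Read PWMs from a MEME minimal-format file
#'
#' Parses `MOTIF` blocks with their letter-probability matrices into a
#' named list of position weight matrices (4 x L, rows A, C, G, T; columns
#' sum to 1).
#'
#' @param path Path to a MEME minimal-format motif file.
#' @return Named list of 4 x L probability matrices.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (startsWith(ln, "MOTIF")) {
      parts <- strsplit(ln, "\\s+")[[1]]
      name <- if (length(parts) >= 3) parts[3] else parts[2]
      j <- i + 1
      while (j <= length(lines) &&
             !grepl("letter-probability matrix", lines[j])) {
        j <- j + 1
      }
      if (j > length(lines)) break
      rows <- list()
      j <- j + 1
      while (j <= length(lines)) {
        vals <- suppressWarnings(as.numeric(
          strsplit(trimws(lines[j]), "\\s+")[[1]]))
        if (length(vals) != 4 || anyNA(vals)) break
        rows[[length(rows) + 1]] <- vals
        j <- j + 1
      }
      if (length(rows) > 0) {
        m <- t(do.call(rbind, rows))
        rownames(m) <- c("A", "C", "G", "T")
        out[[name]] <- m
      }
      i <- j
    } else {
      i <- i + 1
    }
  }
  out
}

#' Log-odds scoring matrix from a PWM
#'
#' `log2((p + pseudocount) / (background + pseudocount))` per cell; the
#' score of a sequence window is the sum over positions.
#'
#' @param pwm 4 x L probability matrix (rows A, C, G, T).
#' @param background Background base frequencies (default uniform 0.25).
#' @param pseudocount Pseudocount (default 0.001) keeping entries finite.
#' @return 4 x L numeric log-odds matrix (bits).
#' @export
logodds_matrix <- function(pwm, background = rep(0.25, 4),
                           pseudocount = 0.001) {
  if (nrow(pwm) != 4) stop("pwm must have 4 rows (A, C, G, T)")
  if (any(abs(colSums(pwm) - 1) > 1e-6)) {
    stop("pwm columns must sum to 1")
  }
  if (any(background + pseudocount <= 0)) {
    stop("background frequency 0 with pseudocount 0")
  }
  log2((pwm + pseudocount) / (background + pseudocount))
}

#' Score threshold for a null tail probability
#'
#' Computes the smallest window score `s` with
#' `P_background(score >= s) <= alpha` by exact dynamic programming over
#' the discretized score distribution under the background model (the
#' conventional site-calling threshold is `alpha = 1e-4`).
#'
#' @param logodds 4 x L log-odds matrix.
#' @param background Background base frequencies.
#' @param alpha Null tail probability in (0, 1].
#' @param granularity Score discretization step in bits (default 0.001).
#' @return The threshold score (on the discretized scale).
#' @export
score_threshold <- function(logodds, background = rep(0.25, 4),
                            alpha = 1e-4, granularity = 0.001) {
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  q <- round(logodds / granularity)
  L <- ncol(q)
  offset <- sum(apply(q, 2, min))
  width <- sum(apply(q, 2, max)) - offset
  dist <- c(1, rep(0, width))            # index 1 == offset
  for (j in seq_len(L)) {
    nxt <- rep(0, width + 1)
    qj <- q[, j] - min(q[, j])
    for (b in 1:4) {
      sh <- qj[b]
      idx <- seq_len(width + 1 - sh)
      nxt[idx + sh] <- nxt[idx + sh] + dist[idx] * background[b]
    }
    dist <- nxt
  }
  tail <- rev(cumsum(rev(dist)))
  ok <- which(tail <= alpha)
  s_int <- if (length(ok) == 0) width + 1 else min(ok) - 1
  (s_int + offset) * granularity
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

scan_one <- function(seq, q, thr_int) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  code <- match(ch, c("A", "C", "G", "T"))
  L <- ncol(q)
  n <- length(code)
  if (n < L) return(integer(0))
  nw <- n - L + 1
  sc <- rep(0, nw)
  for (j in seq_len(L)) {
    v <- q[code[j:(j + nw - 1)], j]
    v[is.na(v)] <- -Inf               # N bases invalidate the window
    sc <- sc + v
  }
  which(sc >= thr_int)
}

#' Scan flank sequences for PWM hits
#'
#' Scores every window of every sequence (both strands by default) with
#' the log-odds matrix and reports windows at or above the threshold.
#' Windows containing non-ACGT characters are skipped; sequences shorter
#' than the motif yield no hits.
#'
#' @param sequences Named character vector (or `DNAStringSet`) of flank
#'   sequences.
#' @param pwm 4 x L probability matrix.
#' @param background Background frequencies (default uniform).
#' @param alpha Null tail probability for the threshold (default 1e-4).
#' @param both_strands Scan the reverse complement too (default TRUE).
#' @param granularity Score discretization (bits).
#' @return Data frame of hits: `sequence_id`, `offset` (0-based),
#'   `strand`, `score` (bits); per-sequence hit counts as attribute
#'   `"counts"`, binary occupancy as attribute `"occupied"`.
#' @export
scan_flanks <- function(sequences, pwm, background = rep(0.25, 4),
                        alpha = 1e-4, both_strands = TRUE,
                        granularity = 0.001) {
  if (methods::is(sequences, "DNAStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  if (is.null(names(sequences))) {
    names(sequences) <- sprintf("seq%05d", seq_along(sequences))
  }
  lo <- logodds_matrix(pwm, background)
  thr <- score_threshold(lo, background, alpha, granularity)
  q <- round(lo / granularity)
  thr_int <- round(thr / granularity)
  L <- ncol(q)
  hits <- list()
  counts <- setNames(integer(length(sequences)), names(sequences))
  for (id in names(sequences)) {
    fwd <- scan_one(sequences[[id]], q, thr_int)
    for (o in fwd) {
      hits[[length(hits) + 1]] <- data.frame(
        sequence_id = id, offset = o - 1, strand = "+",
        score = NA_real_, stringsAsFactors = FALSE)
    }
    nh <- length(fwd)
    if (both_strands) {
      n <- nchar(sequences[[id]])
      rev <- scan_one(revcomp(sequences[[id]]), q, thr_int)
      for (o in rev) {
        hits[[length(hits) + 1]] <- data.frame(
          sequence_id = id, offset = n - (o - 1) - L, strand = "-",
          score = NA_real_, stringsAsFactors = FALSE)
      }
      nh <- nh + length(rev)
    }
    counts[[id]] <- nh
  }
  out <- if (length(hits) == 0) {
    data.frame(sequence_id = character(0), offset = integer(0),
               strand = character(0), score = numeric(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, hits)
  }
  attr(out, "counts") <- counts
  attr(out, "occupied") <- counts > 0
  out
}

#' Per-TF binding-site bias between expanded and conserved STR flanks
#'
#' For each transcription factor, forms the 2x2 occupancy table
#' {at least one hit, no hit} x {expanded-STR flanks, conserved-STR
#' flanks}, tests it with the exact Fisher machinery, adjusts across TFs
#' by Benjamini-Hochberg, and flags TFs with `OR > 1` and `q < 0.05` as
#' preferentially binding the expanded flanks.  A raw-count odds ratio
#' (total hits over flank count) is reported alongside.
#'
#' @param occupancy_hestr,occupancy_ncstr Named list per TF of logical
#'   occupancy vectors (one element per flank), as produced by
#'   [scan_flanks()]'s `"occupied"` attribute.
#' @param counts_hestr,counts_ncstr Optional named lists of per-flank hit
#'   counts for the raw-count odds ratio.
#' @param or_threshold,q_threshold Selection rule (defaults 1 and 0.05).
#' @return Data frame per TF: occupancy counts, `odds_ratio`, `p`, `q`,
#'   `raw_count_or`, `biased`.
#' @export
tf_bias <- function(occupancy_hestr, occupancy_ncstr,
                    counts_hestr = NULL, counts_ncstr = NULL,
                    or_threshold = 1, q_threshold = 0.05) {
  tfs <- intersect(names(occupancy_hestr), names(occupancy_ncstr))
  if (length(tfs) == 0) stop("no shared TFs between the two groups")
  res <- lapply(tfs, function(tf) {
    he <- occupancy_hestr[[tf]]
    nc <- occupancy_ncstr[[tf]]
    if (length(he) == 0 || length(nc) == 0) stop("zero flanks in a group")
    fe <- fisher_enrichment(he, nc)
    rc <- NA_real_
    if (!is.null(counts_hestr) && !is.null(counts_ncstr)) {
      rc <- (sum(counts_hestr[[tf]]) / length(he)) /
        max(sum(counts_ncstr[[tf]]) / length(nc), .Machine$double.eps)
    }
    data.frame(tf_name = tf, hits_hestr = sum(he), flanks_hestr = length(he),
               hits_ncstr = sum(nc), flanks_ncstr = length(nc),
               odds_ratio = fe$odds_ratio, p = fe$p_value,
               raw_count_or = rc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- adjust_pvalues(out$p, "bh")
  out$biased <- out$odds_ratio > or_threshold & out$q < q_threshold
  out[order(out$tf_name), ]
}

#' Cross-species shift of TF odds ratios
#'
#' Per TF, computes `d = OR_human - mean over species(OR)` and applies a
#' one-sided Wilcoxon signed-rank test of the differences against zero
#' (zeros dropped, standard convention), asking whether the human odds
#' ratios are systematically larger.
#'
#' @param or_human Named numeric vector of per-TF odds ratios in human.
#' @param or_by_species Matrix (TFs x species) of per-TF odds ratios in
#'   each NHP species; rownames must cover `names(or_human)`.
#' @return List with `p_value`, `statistic` (V) and the differences `d`.
#' @export
cross_species_or_shift <- function(or_human, or_by_species) {
  tfs <- names(or_human)
  if (length(tfs) < 5) stop("need at least 5 TFs")
  if (!all(tfs %in% rownames(or_by_species))) {
    stop("or_by_species must cover every TF")
  }
  d <- or_human - rowMeans(or_by_species[tfs, , drop = FALSE])
  dz <- d[d != 0]
  if (length(dz) == 0) {
    warning("all differences are zero")
    return(list(p_value = 1, statistic = NA_real_, d = d))
  }
  wt <- suppressWarnings(stats::wilcox.test(dz, alternative = "greater"))
  list(p_value = wt$p.value, statistic = unname(wt$statistic), d = d)
}
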