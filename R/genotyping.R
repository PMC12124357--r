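#' Canonical form of an STR motif
#'
#' Returns the lexicographically smallest string among all cyclic rotations
#' of the motif and of its reverse complement, so that e.g. `"CA"`, `"AC"`,
#' `"TG"` and `"GT"` all map to `"AC"`.  Idempotent.
#'
#' @param motif Character vector of motifs matching `[ACGT]{1,6}`.
#' @return Character vector of canonical motifs.
#' @examples
#' canonicalize_motif(c("CA", "AG", "A"))  # "AC", "AG", "A"
#' @export
canonicalize_motif <- function(motif) {
  vapply(motif, function(m) {
    if (is.na(m) || !grepl("^[ACGT]+$", m)) {
      stop("motif must be a non-empty ACGT string")
    }
    L <- nchar(m)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(m)))
    rots <- function(s) {
      vapply(seq_len(L), function(i) {
        paste0(substr(s, i, L), substr(s, 1, i - 1))
      }, character(1))
    }
    min(c(rots(m), rots(rc)))
  }, character(1), USE.NAMES = FALSE)
}

#' Build an STR reference panel from repeat-annotation records
#'
#' Keeps records annotated as class `"Simple_repeat"` with motif lengths of
#' 1 to 6 bp, assigns stable locus identifiers `chrom:start-end:motif`, and
#' computes canonical motifs.  Records with malformed coordinates or
#' non-ACGT motifs are dropped with a warning.
#'
#' @param records Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `class`, `motif`.
#' @return A data frame panel with columns `locus_id`, `chrom`, `start`,
#'   `end`, `motif`, `canonical_motif`.
#' @export
build_reference_panel <- function(records) {
  need <- c("chrom", "start", "end", "class", "motif")
  if (!all(need %in% names(records))) {
    stop("records need columns: ", paste(need, collapse = ", "))
  }
  if (nrow(records) == 0) {
    return(data.frame(locus_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      motif = character(0), canonical_motif = character(0),
                      stringsAsFactors = FALSE))
  }
  bad_coord <- records$end <= records$start
  bad_motif <- !grepl("^[ACGT]+$", records$motif)
  if (any(bad_coord | bad_motif)) {
    warning(sum(bad_coord | bad_motif),
            " record(s) rejected (malformed coordinates or motif)")
  }
  keep <- !bad_coord & !bad_motif &
    records$class == "Simple_repeat" &
    nchar(records$motif) >= 1 & nchar(records$motif) <= 6
  out <- records[keep, c("chrom", "start", "end", "motif")]
  rownames(out) <- NULL
  out$locus_id <- sprintf("%s:%d-%d:%s", out$chrom, out$start, out$end,
                          out$motif)
  out$canonical_motif <- canonicalize_motif(out$motif)
  out[, c("locus_id", "chrom", "start", "end", "motif", "canonical_motif")]
}

#' Detect tandem repeat tracts in a sequence segment
#'
#' Scans for maximal runs with period `m` (positions where
#' `segment[i] == segment[i + m]`) for every motif length `m` in 1..6, and
#' reports perfect tracts with at least `min_copies` copies and
#' `min_tract_bp` bases.  Tracts whose motif is a repetition of a shorter
#' motif are collapsed onto the primitive motif, and duplicate reports of
#' one tract at multiple periods keep the smallest period.
#'
#' @param segment Character scalar (or `DNAString`) to scan.
#' @param min_copies Minimum copy number to report (default 2).
#' @param min_tract_bp Minimum tract length in bp (default 4).
#' @return Data frame with `start`, `end` (0-based half-open within the
#'   segment), `motif` (primitive, as spelled in the tract),
#'   `canonical_motif`, and `copy_number`.
#' @examples
#' detect_repeats("ACACACAC")  # one tract, canonical motif "AC", 4 copies
#' @export
detect_repeats <- function(segment, min_copies = 2, min_tract_bp = 4) {
  segment <- as.character(segment)
  if (length(segment) != 1 || nchar(segment) == 0) {
    stop("segment must be a single non-empty sequence")
  }
  ch <- strsplit(segment, "", fixed = TRUE)[[1]]
  L <- length(ch)
  out <- list()
  for (m in 1:6) {
    if (L < 2 * m) next
    eq <- ch[seq_len(L - m)] == ch[seq_len(L - m) + m]
    r <- rle(eq)
    pos <- cumsum(c(1, r$lengths))
    for (j in seq_along(r$lengths)) {
      if (!r$values[j]) next
      i0 <- pos[j]                # 1-based start of the run
      run <- r$lengths[j]
      tract_len <- run + m
      copies <- tract_len / m
      if (copies < min_copies || tract_len < min_tract_bp) next
      motif <- substr(segment, i0, i0 + m - 1)
      if (!is_primitive_motif(motif)) next
      out[[length(out) + 1]] <- data.frame(
        start = i0 - 1, end = i0 - 1 + tract_len, motif = motif,
        period = m, stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      motif = character(0), canonical_motif = character(0),
                      copy_number = numeric(0), stringsAsFactors = FALSE))
  }
  tr <- do.call(rbind, out)
  tr <- tr[order(tr$start, tr$period), ]
  # identical span reported at several periods: keep the smallest period
  tr <- tr[!duplicated(tr[, c("start", "end")]), ]
  tr$canonical_motif <- canonicalize_motif(tr$motif)
  tr$copy_number <- (tr$end - tr$start) / nchar(tr$motif)
  rownames(tr) <- NULL
  tr[, c("start", "end", "motif", "canonical_motif", "copy_number")]
}

# exact matches of `pattern` within each contig of a DNAStringSet;
# returns data.frame(target_id, start) with 1-based starts
seed_hits <- function(pattern, target) {
  hits <- list()
  for (nm in names(target)) {
    mi <- Biostrings::matchPattern(pattern, target[[nm]])
    st <- BiocGenerics::start(mi)
    if (length(st) > 0) {
      hits[[length(hits) + 1]] <- data.frame(
        target_id = nm, start = st, stringsAsFactors = FALSE
      )
    }
  }
  if (length(hits) == 0) {
    return(data.frame(target_id = character(0), start = integer(0)))
  }
  do.call(rbind, hits)
}

mismatch_fraction <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- min(length(ca), length(cb))
  if (n == 0) return(1)
  mean(ca[seq_len(n)] != cb[seq_len(n)])
}

#' Locate an STR query region in a target genome by flank anchoring
#'
#' Anchors the left and right 500-bp (by default) flanks of the query with
#' exact-seed k-mer matches, tries successive seed offsets within each
#' flank so isolated substitutions cannot hide the locus, verifies
#' candidate placements by bounded-mismatch comparison of the full flanks,
#' and returns the longest verified region.  Ties are resolved toward the
#' smaller start coordinate.
#'
#' @param query Character scalar or `DNAString`: STR plus flanks.
#' @param target Named [Biostrings::DNAStringSet] (the haploid genome).
#' @param flank_len Flank length within the query (default 500).
#' @param k Seed k-mer length (default 21).
#' @param max_mismatch_frac Maximum tolerated flank mismatch fraction when
#'   verifying a candidate (default 0.05).
#' @param max_candidates Abort with "not found" beyond this many candidate
#'   anchor pairs (ambiguous placement).
#' @return List with `target_id`, `start`, `end` (0-based half-open) and
#'   `identity`, or `NULL` when the locus cannot be anchored.
#' @export
locate_locus <- function(query, target, flank_len = 500, k = 21,
                         max_mismatch_frac = 0.05, max_candidates = 50) {
  query <- as.character(query)
  qlen <- nchar(query)
  if (qlen < 2 * k) stop("query too short for seed anchoring")
  if (!methods::is(target, "DNAStringSet")) {
    target <- Biostrings::DNAStringSet(target)
  }
  flank_len <- min(flank_len, (qlen - 1) %/% 2)
  lf <- substr(query, 1, flank_len)
  rf <- substr(query, qlen - flank_len + 1, qlen)

  seed_scan <- function(flank, from_end) {
    offs <- seq(1, max(1, flank_len - k + 1), by = k)
    for (o in offs) {
      off <- if (from_end) max(1, flank_len - k + 1 - (o - 1)) else o
      seed <- substr(flank, off, off + k - 1)
      if (nchar(seed) < k) next
      h <- seed_hits(seed, target)
      if (nrow(h) > 0) {
        h$offset <- off
        return(h)
      }
    }
    NULL
  }
  lh <- seed_scan(lf, FALSE)
  rh <- seed_scan(rf, TRUE)
  if (is.null(lh) || is.null(rh)) return(NULL)

  # pair each left anchor with its nearest right anchor downstream:
  # a contiguous locus placement never spans another locus copy
  cands <- list()
  for (i in seq_len(nrow(lh))) {
    st <- lh$start[i] - (lh$offset[i] - 1)            # 1-based region start
    ends <- rh$start + (k - 1) + (flank_len - (rh$offset + k - 1))
    ok <- which(rh$target_id == lh$target_id[i] & ends > st &
                  (ends - st + 1) <= 5 * qlen)
    if (length(ok) == 0) next
    j <- ok[which.min(ends[ok])]
    cands[[length(cands) + 1]] <- list(target_id = lh$target_id[i],
                                       start = st, end = ends[j])
  }
  if (length(cands) == 0) return(NULL)
  if (length(cands) > max_candidates) return(NULL)

  best <- NULL
  for (cand in cands) {
    seqlen <- length(target[[cand$target_id]])
    st <- max(1, cand$start)
    en <- min(seqlen, cand$end)
    if (en - st + 1 < 2 * k) next
    region <- as.character(Biostrings::subseq(target[[cand$target_id]],
                                              st, en))
    mml <- mismatch_fraction(substr(region, 1, flank_len), lf)
    rlen <- nchar(region)
    mmr <- mismatch_fraction(substr(region, rlen - flank_len + 1, rlen),
                             rf)
    if (mml > max_mismatch_frac || mmr > max_mismatch_frac) next
    cand_len <- en - st + 1
    cand_id <- 1 - (mml + mmr) / 2
    if (is.null(best) || cand_len > best$len ||
        (cand_len == best$len && st < best$start1)) {
      best <- list(target_id = cand$target_id, start1 = st, end1 = en,
                   len = cand_len, identity = cand_id)
    }
  }
  if (is.null(best)) return(NULL)
  list(target_id = best$target_id, start = best$start1 - 1, end = best$end1,
       identity = best$identity)
}

#' Select the genotype call among detected tracts
#'
#' Keeps tracts whose canonical motif matches the expected one; when
#' several remain, picks the tract minimising
#' `|left_gap - flank_len| + |right_gap - flank_len|` where the gaps are
#' the distances from the tract boundaries to the region boundaries
#' (deterministic ties go to the smaller start).  The copy number is the
#' tract length divided by the motif length.
#'
#' @param tracts Data frame from [detect_repeats()] on the mapped region.
#' @param expected_canonical_motif Canonical motif of the reference STR.
#' @param region_len Length of the mapped region in bp.
#' @param flank_len Expected flank distance (default 500).
#' @return List with `status` (`"called"` or `"missing"`) and, when
#'   called, `copy_number` and the selected `tract` row.
#' @export
call_str <- function(tracts, expected_canonical_motif, region_len,
                     flank_len = 500) {
  hit <- tracts[tracts$canonical_motif == expected_canonical_motif, ,
                drop = FALSE]
  if (nrow(hit) == 0) return(list(status = "missing"))
  score <- abs(hit$start - flank_len) +
    abs((region_len - hit$end) - flank_len)
  ord <- order(score, hit$start)
  sel <- hit[ord[1], ]
  list(status = "called", copy_number = sel$copy_number, tract = sel)
}

#' Genotype an STR panel across a set of haploid genomes
#'
#' For each panel locus, extracts the reference STR with its flanks,
#' locates the region in every target genome by flank anchoring
#' ([locate_locus()]), detects tandem tracts in the mapped region
#' ([detect_repeats()]) and selects the call ([call_str()]).  Loci that
#' cannot be anchored or yield no matching tract are recorded as missing.
#'
#' @param panel Panel data frame from [build_reference_panel()] or a
#'   fixture panel with columns `chrom`, `start`, `end`, `motif`.
#' @param genomes Named list of [Biostrings::DNAStringSet] haploid genomes.
#' @param reference [Biostrings::DNAStringSet] reference genome the panel
#'   coordinates refer to.
#' @param flank_len Flank length to extract and anchor (default 500).
#' @param min_copies,min_tract_bp Tract detection thresholds.
#' @return List with `matrix` (loci x haplotypes copy numbers, `NA` for
#'   missing) and `calls` (long-format call table).
#' @export
genotype_cohort <- function(panel, genomes, reference, flank_len = 500,
                            min_copies = 2, min_tract_bp = 4) {
  if (length(genomes) == 0) {
    mat <- matrix(numeric(0), nrow = nrow(panel), ncol = 0)
    rownames(mat) <- if ("locus_id" %in% names(panel)) panel$locus_id else
      sprintf("locus%04d", seq_len(nrow(panel)))
    return(list(matrix = mat,
                calls = data.frame(locus_id = character(0),
                                   haplotype_id = character(0),
                                   status = character(0),
                                   copy_number = numeric(0))))
  }
  if (anyDuplicated(names(genomes))) stop("duplicate haplotype ids")
  if (!"locus_id" %in% names(panel)) {
    panel$locus_id <- sprintf("locus%04d", seq_len(nrow(panel)))
  }
  if (!"canonical_motif" %in% names(panel)) {
    panel$canonical_motif <- canonicalize_motif(panel$motif)
  }
  haps <- names(genomes)
  mat <- matrix(NA_real_, nrow = nrow(panel), ncol = length(haps),
                dimnames = list(panel$locus_id, haps))
  calls <- vector("list", nrow(panel) * length(haps))
  ci <- 0
  for (i in seq_len(nrow(panel))) {
    chrom <- panel$chrom[i]
    if (!chrom %in% names(reference)) next
    seqlen <- length(reference[[chrom]])
    qs <- max(1, panel$start[i] + 1 - flank_len)     # 1-based inclusive
    qe <- min(seqlen, panel$end[i] + flank_len)
    query <- as.character(Biostrings::subseq(reference[[chrom]], qs, qe))
    left_flank <- panel$start[i] + 1 - qs            # realised left flank
    for (h in haps) {
      ci <- ci + 1
      rec <- list(locus_id = panel$locus_id[i], haplotype_id = h,
                  status = "missing", copy_number = NA_real_,
                  tract_start = NA_integer_, tract_end = NA_integer_,
                  motif = NA_character_)
      region <- locate_locus(query, genomes[[h]], flank_len = left_flank)
      if (!is.null(region)) {
        gseq <- genomes[[h]][[region$target_id]]
        rseq <- as.character(Biostrings::subseq(gseq, region$start + 1,
                                                region$end))
        tracts <- detect_repeats(rseq, min_copies = min_copies,
                                 min_tract_bp = min_tract_bp)
        call <- call_str(tracts, panel$canonical_motif[i],
                         region_len = nchar(rseq), flank_len = left_flank)
        if (call$status == "called") {
          rec$status <- "called"
          rec$copy_number <- call$copy_number
          rec$tract_start <- region$start + call$tract$start
          rec$tract_end <- region$start + call$tract$end
          rec$motif <- call$tract$motif
          mat[i, h] <- call$copy_number
        }
      }
      calls[[ci]] <- rec
    }
  }
  calls <- calls[!vapply(calls, is.null, logical(1))]
  calls <- do.call(rbind, lapply(calls, function(x) {
    as.data.frame(x, stringsAsFactors = FALSE)
  }))
  list(matrix = mat, calls = calls)
}
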