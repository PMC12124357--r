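test_that("motif canonicalization enumerates rotations and complements", {
  expect_equal(canonicalize_motif("A"), "A")
  # {CA, AC} U revcomp {TG, GT} -> AC
  expect_equal(canonicalize_motif("CA"), "AC")
  # {AG, GA} U {CT, TC} -> AG
  expect_equal(canonicalize_motif("AG"), "AG")
  # idempotent and rotation/revcomp invariant on random motifs
  set.seed(31)
  for (rep in 1:30) {
    L <- sample(1:6, 1)
    m <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
               collapse = "")
    can <- canonicalize_motif(m)
    expect_equal(canonicalize_motif(can), can)
    rot <- paste0(substr(m, 2, L), substr(m, 1, 1))
    expect_equal(canonicalize_motif(rot), can)
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(m)))
    expect_equal(canonicalize_motif(rc), can)
  }
  expect_error(canonicalize_motif("AXT"), "ACGT")
})

test_that("reference panel keeps only simple repeats with 1-6 bp motifs", {
  rec <- data.frame(
    chrom = "chr1",
    start = c(0, 100, 200, 300, 400, 500, 600, 700, 800, 900),
    end = c(50, 150, 250, 350, 450, 550, 650, 750, 850, 950),
    class = c("Simple_repeat", "Simple_repeat", "LINE", "Simple_repeat",
              "SINE", "Simple_repeat", "Simple_repeat", "Low_complexity",
              "Simple_repeat", "Simple_repeat"),
    motif = c("AC", "ACGACGA", "AC", "A", "AT", "ACGATC", "ACGATCA",
              "AC", "AGC", "ACNT"),
    stringsAsFactors = FALSE
  )
  # by hand: rows 1 (AC), 4 (A), 6 (ACGATC, 6 bp), 9 (AGC) pass;
  # row 2 has a 7-bp motif, rows 3/5/8 the wrong class, row 7 a 7-bp
  # motif, row 10 a non-ACGT motif
  panel <- suppressWarnings(build_reference_panel(rec))
  expect_equal(nrow(panel), 4)
  expect_setequal(panel$start, c(0, 300, 500, 800))
  expect_true(all(nchar(panel$motif) <= 6))
  # empty table gives an empty panel
  expect_equal(nrow(build_reference_panel(rec[0, ])), 0)
  # malformed coordinates are rejected with a warning
  bad <- rec[1, ]
  bad$end <- 0
  expect_warning(build_reference_panel(rbind(rec[1, ], bad)), "rejected")
})

test_that("repeat detection finds primitive tracts with exact copy counts", {
  tr <- detect_repeats("ACACACAC")
  expect_equal(nrow(tr), 1)
  expect_equal(tr$canonical_motif, "AC")
  expect_equal(tr$copy_number, 4)
  # homopolymer reported with the primitive single-base motif
  tr2 <- detect_repeats("AAAAAA")
  expect_equal(nrow(tr2), 1)
  expect_equal(tr2$motif, "A")
  expect_equal(tr2$copy_number, 6)
  # copy number times motif length equals tract length, exactly
  set.seed(32)
  for (rep in 1:10) {
    seg <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
    tr3 <- detect_repeats(seg, min_copies = 3)
    if (nrow(tr3) > 0) {
      expect_equal(tr3$copy_number * nchar(tr3$motif), tr3$end - tr3$start)
    }
  }
})

test_that("repeat detection agrees with the regex oracle on random data", {
  set.seed(33)
  for (rep in 1:25) {
    seg <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
    mine <- detect_repeats(seg, min_copies = 3, min_tract_bp = 6)
    oracle <- regex_repeats(seg, min_copies = 3, min_tract_bp = 6)
    key <- function(d) sort(sprintf("%d:%d", d$start, d$end))
    expect_equal(key(mine), key(oracle))
  }
  # long random sequence with a strict copy threshold: almost always empty
  set.seed(34)
  seg <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  expect_equal(nrow(detect_repeats(seg, min_copies = 6, min_tract_bp = 12)),
               nrow(regex_repeats(seg, min_copies = 6, min_tract_bp = 12)))
})

test_that("locus location returns the longest verified candidate", {
  set.seed(35)
  fx <- gen_genotyping_fixture(1, motif_length_range = c(2, 2),
                               copies_range = c(10, 10), flank_len = 120,
                               snv_rate = 0, seed = 36, n_haplotypes = 1,
                               spacer_len = 80)
  g <- fx$genomes[[1]]
  q <- as.character(Biostrings::subseq(
    fx$reference[["chr1"]], fx$panel$start[1] + 1 - 120,
    fx$panel$end[1] + 120))
  r <- locate_locus(q, g, flank_len = 120)
  expect_false(is.null(r))
  expect_equal(r$end - r$start, nchar(q))
  # identical target: full-length region from position 0
  self <- Biostrings::DNAStringSet(setNames(q, "t"))
  r2 <- locate_locus(q, self, flank_len = 120)
  expect_equal(c(r2$start, r2$end), c(0, nchar(q)))
  # unrelated target shares no seed k-mer: not found
  rand <- Biostrings::DNAStringSet(setNames(
    paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = ""), "t"))
  expect_null(locate_locus(q, rand, flank_len = 120))
})

test_that("locus location prefers the longer of two planted candidates", {
  set.seed(37)
  base <- c("A", "C", "G", "T")
  lf <- paste(sample(base, 150, TRUE), collapse = "")
  rf <- paste(sample(base, 150, TRUE), collapse = "")
  long_tract <- paste(rep("AC", 40), collapse = "")
  short_tract <- paste(rep("AC", 8), collapse = "")
  spacer <- paste(sample(base, 400, TRUE), collapse = "")
  target <- Biostrings::DNAStringSet(setNames(
    paste0(spacer, lf, short_tract, rf, spacer,
           lf, long_tract, rf, spacer), "t"))
  q <- paste0(lf, paste(rep("AC", 20), collapse = ""), rf)
  r <- locate_locus(q, target, flank_len = 150)
  # the region containing the 40-copy tract is longer and wins
  expect_equal(r$end - r$start, 150 + 80 + 150)
})

test_that("call selection applies the flank-distance tie-break", {
  tracts <- data.frame(
    start = c(500, 300), end = c(548, 340),
    motif = c("AC", "AC"), canonical_motif = c("AC", "AC"),
    copy_number = c(24, 20), stringsAsFactors = FALSE
  )
  # region of length 1048: gaps (500, 500) vs (300, 708) -> first wins
  call <- call_str(tracts, "AC", region_len = 1048, flank_len = 500)
  expect_equal(call$status, "called")
  expect_equal(call$copy_number, 24)
  # single matching tract: copy number is length over motif length
  one <- tracts[1, ]
  expect_equal(call_str(one, "AC", 1048)$copy_number, 48 / 2)
  # no tract with the expected canonical motif: missing
  expect_equal(call_str(tracts, "AG", 1048)$status, "missing")
})

test_that("cohort genotyping recovers planted copy numbers exactly", {
  fx <- gen_genotyping_fixture(12, motif_length_range = c(1, 6),
                               copies_range = c(6, 25), flank_len = 200,
                               snv_rate = 0, seed = 38, n_haplotypes = 2,
                               spacer_len = 150)
  gt <- genotype_cohort(fx$panel, fx$genomes, fx$reference,
                        flank_len = 200)
  for (i in seq_len(nrow(fx$truth))) {
    tr <- fx$truth[i, ]
    expect_equal(gt$matrix[tr$locus_id, tr$haplotype_id], tr$copy_number,
                 label = sprintf("locus %s hap %s", tr$locus_id,
                                 tr$haplotype_id))
  }
  # empty genome set: zero columns
  empty <- genotype_cohort(fx$panel, list(), fx$reference)
  expect_equal(ncol(empty$matrix), 0)
  expect_error(genotype_cohort(fx$panel,
                               setNames(fx$genomes, rep("h", 2)),
                               fx$reference),
               "duplicate")
})
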