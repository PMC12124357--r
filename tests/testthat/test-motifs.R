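meme_text <- c(
  "MEME version 4", "",
  "ALPHABET= ACGT", "",
  "strands: + -", "",
  "Background letter frequencies",
  "A 0.25 C 0.25 G 0.25 T 0.25", "",
  "MOTIF MA0001.1 TFA",
  "letter-probability matrix: alength= 4 w= 3 nsites= 20 E= 0",
  " 1.0 0.0 0.0 0.0",
  " 0.0 1.0 0.0 0.0",
  " 0.0 0.0 0.5 0.5",
  "",
  "MOTIF MA0002.1 TFB",
  "letter-probability matrix: alength= 4 w= 2 nsites= 10 E= 0",
  " 0.25 0.25 0.25 0.25",
  " 0.7 0.1 0.1 0.1"
)

write_meme_fixture <- function() {
  tmp <- tempfile(fileext = ".meme")
  writeLines(meme_text, tmp)
  tmp
}

test_that("MEME minimal format parsing recovers the matrices", {
  path <- write_meme_fixture()
  pwms <- read_meme(path)
  expect_setequal(names(pwms), c("TFA", "TFB"))
  expect_equal(dim(pwms$TFA), c(4, 3))
  expect_equal(unname(pwms$TFA["A", 1]), 1.0)
  expect_equal(unname(pwms$TFA["G", 3]), 0.5)
  expect_equal(unname(pwms$TFB["A", 2]), 0.7)
  expect_equal(colSums(pwms$TFA), rep(1, 3), ignore_attr = TRUE)
  unlink(path)
})

test_that("log-odds matrix follows the pseudocount arithmetic", {
  uni <- matrix(0.25, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL))
  # uniform PWM over uniform background: all-zero log-odds
  expect_equal(unname(logodds_matrix(uni, pseudocount = 0)),
               matrix(0, 4, 3))
  # a certain base scores log2(4) = 2 bits without pseudocount
  col <- matrix(c(1, 0, 0, 0), 4, 1,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  lo <- logodds_matrix(col, pseudocount = 0)
  expect_equal(unname(lo["A", 1]), 2)
  expect_equal(unname(lo["C", 1]), -Inf)
  # pseudocount keeps every entry finite
  expect_true(all(is.finite(logodds_matrix(col, pseudocount = 0.01))))
  expect_error(logodds_matrix(matrix(0.3, 4, 2)), "sum to 1")
})

test_that("score threshold equals brute force over all words", {
  set.seed(71)
  for (rep in 1:8) {
    L <- sample(2:5, 1)
    p <- matrix(stats::rgamma(4 * L, 1), 4, L,
                dimnames = list(c("A", "C", "G", "T"), NULL))
    p <- sweep(p, 2, colSums(p), "/")
    lo <- logodds_matrix(p)
    g <- 0.001
    q <- round(lo / g)
    words <- as.matrix(expand.grid(rep(list(1:4), L)))
    scores <- apply(words, 1, function(w) sum(q[cbind(w, seq_len(L))])) * g
    for (alpha in c(1, 0.05, 1e-3)) {
      thr <- score_threshold(lo, alpha = alpha, granularity = g)
      # smallest discretized score whose null tail is at most alpha
      tail_at <- function(s) mean(scores >= s - 1e-9)
      expect_lte(tail_at(thr), alpha)
      if (alpha < 1) expect_gt(tail_at(thr - g), alpha)
    }
  }
  # alpha = 1 admits every word
  uni <- matrix(0.25, 4, 2, dimnames = list(c("A", "C", "G", "T"), NULL))
  lo <- logodds_matrix(uni)
  expect_equal(score_threshold(lo, alpha = 1), 0)
  expect_error(score_threshold(lo, alpha = 0), "alpha")
})

test_that("flank scanning equals brute-force window scoring", {
  set.seed(72)
  p <- matrix(c(0.9, 0.03, 0.03, 0.04,
                0.03, 0.9, 0.03, 0.04,
                0.9, 0.03, 0.03, 0.04), 4, 3,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  seqs <- setNames(
    vapply(1:20, function(i) {
      paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
    }, character(1)),
    sprintf("f%02d", 1:20))
  hits <- scan_flanks(seqs, p, alpha = 1e-3, both_strands = FALSE)
  lo <- logodds_matrix(p)
  g <- 0.001
  q <- round(lo / g)
  thr_int <- round(score_threshold(lo, alpha = 1e-3, granularity = g) / g)
  for (id in names(seqs)) {
    # brute-force scoring on the same discretized matrix
    sc <- brute_scan_scores(seqs[[id]], q)
    expect_equal(sort(hits$offset[hits$sequence_id == id]),
                 sort(which(sc >= thr_int) - 1),
                 label = sprintf("hits in %s", id))
  }
  # sequences shorter than the motif yield no hits
  short <- scan_flanks(c(s = "AC"), p, alpha = 1)
  expect_equal(nrow(short), 0)
})

test_that("reverse-complementing inputs preserves per-sequence counts", {
  set.seed(73)
  p <- matrix(stats::rgamma(4 * 4, 1), 4, 4,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  p <- sweep(p, 2, colSums(p), "/")
  seqs <- setNames(
    vapply(1:10, function(i) {
      paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
    }, character(1)), sprintf("s%02d", 1:10))
  h1 <- scan_flanks(seqs, p, alpha = 0.01, both_strands = TRUE)
  rc <- vapply(seqs, strexpand:::revcomp, character(1))
  h2 <- scan_flanks(rc, p, alpha = 0.01, both_strands = TRUE)
  expect_equal(unname(attr(h1, "counts")), unname(attr(h2, "counts")))
})

test_that("TF bias selection applies OR > 1 and q < 0.05 exactly", {
  occ_he <- list(
    TF1 = rep(c(TRUE, FALSE), c(80, 20)),
    TF2 = rep(c(TRUE, FALSE), c(50, 50)),
    TF3 = rep(c(TRUE, FALSE), c(10, 90))
  )
  occ_nc <- list(
    TF1 = rep(c(TRUE, FALSE), c(20, 80)),
    TF2 = rep(c(TRUE, FALSE), c(50, 50)),
    TF3 = rep(c(TRUE, FALSE), c(30, 70))
  )
  r <- tf_bias(occ_he, occ_nc)
  # 80/100 vs 20/100: OR = 16, overwhelming evidence
  expect_equal(r$odds_ratio[r$tf_name == "TF1"], 16)
  ref <- stats::fisher.test(matrix(c(80, 20, 20, 80), 2, byrow = TRUE))
  expect_equal(r$p[r$tf_name == "TF1"], ref$p.value, tolerance = 1e-12)
  expect_true(r$biased[r$tf_name == "TF1"])
  # identical occupancy: OR 1, not biased
  expect_equal(r$odds_ratio[r$tf_name == "TF2"], 1)
  expect_false(r$biased[r$tf_name == "TF2"])
  # depleted TF: OR < 1 never selected however small its q
  expect_false(r$biased[r$tf_name == "TF3"])
  # selection is invariant to TF input order
  r2 <- tf_bias(rev(occ_he), rev(occ_nc))
  expect_equal(r$biased, r2$biased[match(r$tf_name, r2$tf_name)])
})

test_that("cross-species OR shift matches the signed-rank enumeration", {
  # six TFs all shifted upward: exact one-sided p = 1/2^6
  orh <- setNames(c(2.1, 1.8, 2.5, 1.9, 2.2, 2.0), paste0("T", 1:6))
  orsp <- matrix(1.5, 6, 3, dimnames = list(paste0("T", 1:6), NULL))
  r <- cross_species_or_shift(orh, orsp)
  expect_equal(r$p_value, 1 / 64, tolerance = 1e-9)
  # all differences zero: degenerate, p = 1 with a warning
  expect_warning(r0 <- cross_species_or_shift(
    setNames(rep(1.5, 6), paste0("T", 1:6)), orsp))
  expect_equal(r0$p_value, 1)
  # agreement with exhaustive sign-flip enumeration for n <= 10
  set.seed(74)
  for (rep in 1:5) {
    n <- sample(6:10, 1)
    d <- round(rnorm(n, 0.2, 0.5), 3)
    d[d == 0] <- 0.1
    orh2 <- setNames(1.5 + d, paste0("x", seq_len(n)))
    orsp2 <- matrix(1.5, n, 2, dimnames = list(names(orh2), NULL))
    p <- cross_species_or_shift(orh2, orsp2)$p_value
    # enumeration of all sign assignments of |d|
    w_obs <- sum(rank(abs(d))[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    ws <- signs %*% rank(abs(d))
    p_exact <- mean(ws >= w_obs)
    expect_equal(p, p_exact, tolerance = 1e-9)
  }
})
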