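test_that("cohort design defaults reproduce the study cohort shape", {
  des <- cohort_design()
  expect_equal(sum(des$meta$clade == "human"), 148)
  expect_equal(sum(des$meta$clade == "close_nhp"), 18)
  expect_equal(sum(des$meta$clade == "distant_nhp"), 8)
  expect_equal(length(unique(des$meta$species[des$meta$clade ==
                                                "close_nhp"])), 4)
  expect_equal(length(unique(des$meta$species[des$meta$clade ==
                                                "distant_nhp"])), 3)
  expect_error(cohort_design(close_species = c(a = 2, a = 3)), "unique")
})

test_that("cohort matrix generation is a pure function of its seed", {
  des <- cohort_design()
  sc <- list(locus_scenario("conserved", 20),
             locus_scenario("human_expanded", 10, effect = 4))
  a <- gen_cohort_matrix(des, sc, seed = 5)
  b <- gen_cohort_matrix(des, sc, seed = 5)
  expect_identical(a$matrix, b$matrix)
  c <- gen_cohort_matrix(des, sc, seed = 6)
  expect_false(identical(a$matrix, c$matrix))
  expect_error(gen_cohort_matrix(des, sc, seed = NULL), "seed")
})

test_that("truth labels cover exactly the generated loci", {
  des <- cohort_design()
  sc <- list(locus_scenario("conserved", 15, effect = 0),
             locus_scenario("distant_shifted", 5, effect = 3))
  g <- gen_cohort_matrix(des, sc, seed = 2)
  expect_identical(g$truth$locus_id, rownames(g$matrix))
  expect_equal(table(g$truth$scenario)[["conserved"]], 15)
  expect_equal(table(g$truth$scenario)[["distant_shifted"]], 5)
})

test_that("planted effects match their scenario moments", {
  des <- cohort_design()
  g <- gen_cohort_matrix(
    des, locus_scenario("human_expanded", 60, base_mean = 20, base_sd = 1,
                        effect = 5, missing_rate = 0),
    seed = 3)
  hum <- g$meta$clade == "human"
  diff <- mean(g$matrix[, hum]) - mean(g$matrix[, !hum])
  # sample mean difference within 3 standard errors of the planted effect
  se <- sqrt(1 / sum(hum) + 1 / sum(!hum)) / sqrt(60) * 3
  expect_lt(abs(diff - 5), max(3 * se, 0.1))
  # distant shift moves only the distant clade
  g2 <- gen_cohort_matrix(
    des, locus_scenario("distant_shifted", 60, effect = 4,
                        missing_rate = 0), seed = 4)
  dis <- g2$meta$clade == "distant_nhp"
  clo <- g2$meta$clade == "close_nhp"
  expect_lt(abs(mean(g2$matrix[, dis]) - mean(g2$matrix[, clo]) - 4), 0.25)
  # values truncated below at 1 and rounded to 0.1
  expect_true(all(g$matrix >= 1))
  expect_equal(g$matrix, round(g$matrix, 1))
})

test_that("full missingness in humans fails the coverage filter", {
  des <- cohort_design()
  g <- gen_cohort_matrix(des, locus_scenario("conserved", 8,
                                             missing_rate = 0), seed = 9)
  g$matrix[, g$meta$clade == "human"] <- NA_real_
  cov <- filter_homologous(g$matrix, g$meta)
  expect_true(all(!cov$kept))
})

test_that("genotyping fixture plants pure tracts at recorded coordinates", {
  fx <- gen_genotyping_fixture(5, motif_length_range = c(2, 3),
                               copies_range = c(6, 12), flank_len = 60,
                               snv_rate = 0, seed = 10, n_haplotypes = 2,
                               spacer_len = 50)
  for (i in seq_len(nrow(fx$truth))) {
    tr <- fx$truth[i, ]
    g <- fx$genomes[[tr$haplotype_id]][["chr1"]]
    tract <- as.character(Biostrings::subseq(g, tr$start + 1, tr$end))
    expect_equal(tract,
                 paste(rep(tr$motif, tr$copy_number), collapse = ""))
  }
  # determinism: identical seed gives byte-identical sequences
  fx2 <- gen_genotyping_fixture(5, motif_length_range = c(2, 3),
                                copies_range = c(6, 12), flank_len = 60,
                                snv_rate = 0, seed = 10, n_haplotypes = 2,
                                spacer_len = 50)
  expect_identical(as.character(fx$reference), as.character(fx2$reference))
  expect_identical(as.character(fx$genomes[[1]]),
                   as.character(fx2$genomes[[1]]))
  # flank length default matches the 500-bp convention
  expect_equal(formals(gen_genotyping_fixture)$flank_len, 500)
  expect_error(gen_genotyping_fixture(3, copies_range = c(1, 5), seed = 1),
               "copies_range")
})

test_that("annotation fixture saturates at infinite enrichment", {
  strs <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(start = seq(1000, 99000, by = 2000),
                             width = 50))
  enr <- seq_len(10)
  tr <- gen_annotation_fixture(1e5, strs, enr, n_features = 80,
                               enrichment_factor = Inf, seed = 3)
  expect_equal(length(tr), 80)
  flags <- interval_overlaps(tr, strs[enr])
  expect_true(all(flags))
  expect_error(gen_annotation_fixture(1e5, strs, enr, 0, 2, seed = 1),
               "positive")
})

test_that("annotation fixture with factor 1 gives odds ratios near 1", {
  strs <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(start = seq(500, 199500, by = 400), width = 40))
  enr <- seq_len(100)
  ors <- ps <- numeric(20)
  for (s in seq_len(20)) {
    tr <- gen_annotation_fixture(2e5, strs, enr, n_features = 400,
                                 enrichment_factor = 1, seed = 100 + s,
                                 feature_width = 100)
    fl <- interval_overlaps(strs, tr)
    fe <- fisher_enrichment(fl[enr], fl[-enr])
    ors[s] <- fe$odds_ratio
    ps[s] <- fe$p_value
  }
  # no planted signal: most seeds give a clearly non-significant table
  expect_gte(mean(ps > 0.01), 0.9)
  expect_lt(abs(median(log(ors))), 0.6)
})

test_that("annotation fixture recovers a planted enrichment factor", {
  # sparse loci and moderate overlap rates keep the odds ratio close to
  # the planted rate ratio
  strs <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(start = seq(500, 1599700, by = 400),
                             width = 40))
  enr <- seq_len(400)
  ors <- numeric(10)
  for (s in seq_len(10)) {
    tr <- gen_annotation_fixture(1.6e6, strs, enr, n_features = 500,
                                 enrichment_factor = 3, seed = 200 + s,
                                 feature_width = 100)
    fl <- interval_overlaps(strs, tr)
    ors[s] <- fisher_enrichment(fl[enr], fl[-enr])$odds_ratio
  }
  gm <- exp(mean(log(ors)))
  expect_gt(gm, 3 / 1.5)
  expect_lt(gm, 3 * 1.5)
})

test_that("expression fixture plants exact and noisy fold changes", {
  genes <- sprintf("g%03d", 1:200)
  tgt <- genes[1:40]
  fx <- gen_expression_fixture(genes, tgt, lfc_effect = 0, noise_sd = 0,
                               n_conditions = 3, seed = 6)
  expect_equal(fx$human, fx$nhp)
  fx1 <- gen_expression_fixture(genes, tgt, lfc_effect = 1, noise_sd = 0.2,
                                n_conditions = 3, seed = 6)
  expect_equal(fx1$human[tgt, ], 2 * fx1$nhp[tgt, ])
  # determinism
  fx1b <- gen_expression_fixture(genes, tgt, lfc_effect = 1,
                                 noise_sd = 0.2, n_conditions = 3, seed = 6)
  expect_identical(fx1$human, fx1b$human)
})

test_that("planted expression shift is detected by the set test", {
  genes <- sprintf("g%03d", 1:300)
  tgt <- genes[1:60]
  hits <- 0
  for (s in 1:20) {
    fx <- gen_expression_fixture(genes, tgt, lfc_effect = 1,
                                 noise_sd = 0.4, n_conditions = 4,
                                 seed = 500 + s)
    lfc <- log_fold_change(fx$human, fx$nhp)
    p <- gene_set_shift_test(lfc, tgt, setdiff(genes, tgt))$p_value
    if (p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 20, 0.9)
})
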