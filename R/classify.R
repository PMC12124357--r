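#' Configuration for the STR classification cascade
#'
#' Collects the thresholds of the cascade.  Defaults follow the study
#' design: loci must be called in at least 10 human haplotypes and in at
#' least 6 of the 7 non-human primate (NHP) species; the dip and K-S
#' screens use FDR 0.05; the human-expansion call uses a one-tailed
#' rank-sum test with Bonferroni-adjusted p < 0.05 (an 0.01 variant is
#' available via `hestr_alpha`).
#'
#' @param min_human_calls Minimum non-missing human calls (default 10).
#' @param min_nhp_species Minimum NHP species with at least one call
#'   (default 6).
#' @param dip_fdr_alpha FDR level of the unimodality screen (default 0.05).
#' @param ks_fdr_alpha FDR level of the cross-clade K-S screen
#'   (default 0.05).
#' @param hestr_alpha Adjusted-p threshold for the expansion call
#'   (default 0.05).
#' @param hestr_adjust `"bonferroni"` (default) or `"bh"`.
#' @param hestr_alternative Direction of the expansion test (default
#'   `"greater"`: human copy numbers exceed NHP).
#' @param dip_n_boot Bootstrap replicates for dip calibration
#'   (default 10000).
#' @param seed Integer seed for the dip null draws.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(min_human_calls = 10, min_nhp_species = 6,
                            dip_fdr_alpha = 0.05, ks_fdr_alpha = 0.05,
                            hestr_alpha = 0.05,
                            hestr_adjust = c("bonferroni", "bh"),
                            hestr_alternative = "greater",
                            dip_n_boot = 10000, seed = 1) {
  hestr_adjust <- match.arg(hestr_adjust)
  stopifnot(min_human_calls >= 1,
            dip_fdr_alpha > 0, dip_fdr_alpha < 1,
            ks_fdr_alpha > 0, ks_fdr_alpha < 1,
            hestr_alpha > 0, hestr_alpha < 1,
            dip_n_boot >= 100)
  structure(
    list(min_human_calls = min_human_calls,
         min_nhp_species = min_nhp_species,
         dip_fdr_alpha = dip_fdr_alpha, ks_fdr_alpha = ks_fdr_alpha,
         hestr_alpha = hestr_alpha, hestr_adjust = hestr_adjust,
         hestr_alternative = hestr_alternative,
         dip_n_boot = dip_n_boot, seed = seed),
    class = "pipeline_config"
  )
}

check_meta <- function(mat, meta) {
  need <- c("haplotype_id", "species", "clade")
  if (!all(need %in% names(meta))) {
    stop("meta needs columns: ", paste(need, collapse = ", "))
  }
  if (!all(colnames(mat) %in% meta$haplotype_id)) {
    stop("every matrix column needs exactly one metadata row")
  }
  meta[match(colnames(mat), meta$haplotype_id), ]
}

#' Homology coverage filter
#'
#' Keeps loci with at least `cfg$min_human_calls` non-missing human values
#' and non-missing values in at least `cfg$min_nhp_species` distinct NHP
#' species (a species is present when any of its haplotypes is called).
#'
#' @param mat Loci x haplotypes copy-number matrix (`NA` missing).
#' @param meta Haplotype metadata (haplotype_id, species, clade).
#' @param cfg A [pipeline_config()].
#' @return Data frame with `locus_id`, `n_human_calls`,
#'   `n_nhp_species_present`, `kept`.
#' @export
filter_homologous <- function(mat, meta, cfg = pipeline_config()) {
  meta <- check_meta(mat, meta)
  nhp_species <- unique(meta$species[meta$clade != "human"])
  if (cfg$min_nhp_species > length(nhp_species)) {
    stop("min_nhp_species exceeds the number of NHP species in meta")
  }
  hum <- meta$clade == "human"
  called <- !is.na(mat)
  n_human <- rowSums(called[, hum, drop = FALSE])
  sp_present <- vapply(nhp_species, function(s) {
    rowSums(called[, meta$species == s, drop = FALSE]) > 0
  }, logical(nrow(mat)))
  if (is.null(dim(sp_present))) sp_present <- matrix(sp_present, nrow = 1)
  n_species <- rowSums(sp_present)
  data.frame(
    locus_id = rownames(mat),
    n_human_calls = n_human,
    n_nhp_species_present = n_species,
    kept = n_human >= cfg$min_human_calls &
      n_species >= cfg$min_nhp_species,
    stringsAsFactors = FALSE
  )
}

#' Classify STR loci: coverage, unimodality, cross-clade consistency,
#' human expansion
#'
#' Runs the full cascade on a copy-number matrix:
#' \enumerate{
#'   \item coverage filter ([filter_homologous()]); failures are tier
#'     `excluded_low_coverage`;
#'   \item Hartigan dip test on each locus's pooled close-NHP values with
#'     seeded Monte-Carlo calibration and Benjamini-Hochberg adjustment
#'     across loci; `q < dip_fdr_alpha` is tier `excluded_multimodal`;
#'   \item two-sample Kolmogorov-Smirnov test of distant-NHP against
#'     close-NHP values, BH-adjusted; `q < ks_fdr_alpha` is tier
#'     `excluded_distant_shift`;
#'   \item survivors are `ncSTR`; a one-tailed rank-sum test of human
#'     against pooled NHP values, adjusted over the loci tested
#'     (Bonferroni by default), calls tier `heSTR` at
#'     `adjusted p < hestr_alpha`.
#' }
#' Downstream enrichment comparisons conventionally use the ncSTR set
#' excluding heSTRs as background.
#'
#' Dip null distributions are simulated once per distinct close-NHP sample
#' size (seeded from `cfg$seed`) and reused across loci.  Samples with
#' fewer than 4 distinct close-NHP values are treated as unimodal.
#'
#' @inheritParams filter_homologous
#' @return Data frame with one row per locus: coverage counts, dip, K-S
#'   and rank-sum statistics with adjusted values, and the final `tier`.
#'   The configuration is attached as attribute `"config"`.
#' @export
classify_strs <- function(mat, meta, cfg = pipeline_config()) {
  meta <- check_meta(mat, meta)
  cov <- filter_homologous(mat, meta, cfg)
  n_loci <- nrow(mat)
  rec <- data.frame(
    locus_id = cov$locus_id,
    n_human_calls = cov$n_human_calls,
    n_nhp_species_present = cov$n_nhp_species_present,
    dip_stat = NA_real_, dip_p = NA_real_, dip_q = NA_real_,
    ks_stat = NA_real_, ks_p = NA_real_, ks_q = NA_real_,
    rs_p = NA_real_, rs_p_adj = NA_real_,
    tier = ifelse(cov$kept, NA_character_, "excluded_low_coverage"),
    stringsAsFactors = FALSE
  )
  hum <- meta$clade == "human"
  clo <- meta$clade == "close_nhp"
  dis <- meta$clade == "distant_nhp"

  # Stage 1: unimodality of pooled close-NHP copy numbers
  stage1 <- which(cov$kept)
  if (length(stage1) > 0) {
    null_cache <- new.env(parent = emptyenv())
    dip_p_one <- function(x) {
      x <- x[!is.na(x)]
      nd <- length(unique(x))
      d <- if (length(x) > 0) dip_statistic(x) else 0
      if (nd < 4) return(c(d, 1))
      key <- as.character(length(x))
      if (!exists(key, envir = null_cache)) {
        assign(key, dip_null_distribution(length(x), cfg$dip_n_boot,
                                          seed = cfg$seed + length(x)),
               envir = null_cache)
      }
      null <- get(key, envir = null_cache)
      c(d, (1 + sum(null >= d)) / (1 + length(null)))
    }
    dp <- vapply(stage1, function(i) dip_p_one(mat[i, clo]), numeric(2))
    rec$dip_stat[stage1] <- dp[1, ]
    rec$dip_p[stage1] <- dp[2, ]
    rec$dip_q[stage1] <- adjust_pvalues(dp[2, ], "bh")
    multi <- stage1[rec$dip_q[stage1] < cfg$dip_fdr_alpha]
    rec$tier[multi] <- "excluded_multimodal"
  }

  # Stage 2: distant-NHP vs close-NHP distribution consistency
  stage2 <- which(cov$kept & is.na(rec$tier))
  if (length(stage2) > 0) {
    ks <- vapply(stage2, function(i) {
      x <- mat[i, dis]
      y <- mat[i, clo]
      x <- x[!is.na(x)]
      y <- y[!is.na(y)]
      if (length(x) == 0 || length(y) == 0) return(c(NA_real_, 1))
      r <- ks_two_sample(x, y)
      c(r$statistic, r$p_value)
    }, numeric(2))
    rec$ks_stat[stage2] <- ks[1, ]
    rec$ks_p[stage2] <- ks[2, ]
    rec$ks_q[stage2] <- adjust_pvalues(ks[2, ], "bh")
    shift <- stage2[rec$ks_q[stage2] < cfg$ks_fdr_alpha]
    rec$tier[shift] <- "excluded_distant_shift"
  }

  # Stage 3: human expansion among ncSTRs
  stage3 <- which(cov$kept & is.na(rec$tier))
  if (length(stage3) > 0) {
    rs <- vapply(stage3, function(i) {
      x <- mat[i, hum]
      y <- mat[i, clo | dis]
      x <- x[!is.na(x)]
      y <- y[!is.na(y)]
      if (length(x) == 0 || length(y) == 0) return(1)
      rank_sum_one_sided(x, y, cfg$hestr_alternative)$p_value
    }, numeric(1))
    rec$rs_p[stage3] <- rs
    rec$rs_p_adj[stage3] <- adjust_pvalues(rs, cfg$hestr_adjust)
    rec$tier[stage3] <- ifelse(rec$rs_p_adj[stage3] < cfg$hestr_alpha,
                               "heSTR", "ncSTR")
  }
  stopifnot(!anyNA(rec$tier), nrow(rec) == n_loci)
  attr(rec, "config") <- cfg
  rec
}

#' Summary counts per classification tier
#'
#' @param records Output of [classify_strs()].
#' @return Named list with per-tier counts and the configuration echo.
#' @export
classification_summary <- function(records) {
  tiers <- c("excluded_low_coverage", "excluded_multimodal",
             "excluded_distant_shift", "ncSTR", "heSTR")
  counts <- vapply(tiers, function(t) sum(records$tier == t), integer(1))
  cfg <- attr(records, "config")
  list(counts = as.list(counts), n_loci = nrow(records),
       config = if (is.null(cfg)) NULL else unclass(cfg))
}
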