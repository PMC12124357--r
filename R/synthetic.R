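#' Cohort design for synthetic copy-number matrices
#'
#' Describes the haplotype cohort to simulate.  The defaults reproduce the
#' study design the classifier targets: 148 human haplotypes, 18 haplotypes
#' from four closely related great-ape species, and 8 haplotypes from three
#' more distantly related primate species.
#'
#' @param n_human Number of human haplotypes.
#' @param close_species Named integer vector: haplotypes per close-NHP
#'   (great ape) species.
#' @param distant_species Named integer vector: haplotypes per distant-NHP
#'   species.
#' @param seed Optional default seed carried with the design.
#' @return A `cohort_design` list with a precomputed haplotype metadata
#'   table (`$meta`): haplotype_id, sample_id, species, clade.
#' @export
cohort_design <- function(n_human = 148,
                          close_species = c(chimpanzee = 5, bonobo = 5,
                                            gorilla = 4, orangutan = 4),
                          distant_species = c(gibbon = 3, rhesus_macaque = 3,
                                              crab_eating_macaque = 2),
                          seed = NULL) {
  stopifnot(n_human >= 0, all(close_species >= 0), all(distant_species >= 0))
  sp <- c(names(close_species), names(distant_species))
  if (anyDuplicated(sp)) stop("species names must be unique")
  if (is.null(names(close_species)) || is.null(names(distant_species))) {
    stop("species vectors must be named")
  }
  mk <- function(prefix, n) sprintf("%s%03d", prefix, seq_len(n))
  meta <- data.frame(
    haplotype_id = character(0), sample_id = character(0),
    species = character(0), clade = character(0),
    stringsAsFactors = FALSE
  )
  if (n_human > 0) {
    ids <- mk("HUM", n_human)
    meta <- rbind(meta, data.frame(
      haplotype_id = ids, sample_id = ids, species = "human",
      clade = "human", stringsAsFactors = FALSE
    ))
  }
  add_species <- function(meta, counts, clade) {
    for (s in names(counts)) {
      n <- counts[[s]]
      if (n == 0) next
      ids <- sprintf("%s_%02d", toupper(substr(gsub("_", "", s), 1, 3)),
                     seq_len(n))
      meta <- rbind(meta, data.frame(
        haplotype_id = ids, sample_id = ids, species = s, clade = clade,
        stringsAsFactors = FALSE
      ))
    }
    meta
  }
  meta <- add_species(meta, as.list(close_species), "close_nhp")
  meta <- add_species(meta, as.list(distant_species), "distant_nhp")
  structure(
    list(n_human = n_human, close_species = close_species,
         distant_species = distant_species, meta = meta, seed = seed),
    class = "cohort_design"
  )
}

#' Locus scenario for the cohort generator
#'
#' @param scenario One of `"conserved"`, `"human_expanded"`,
#'   `"close_multimodal"`, `"distant_shifted"`.
#' @param n_loci Number of loci to generate under this scenario.
#' @param base_mean Baseline copy-number mean.
#' @param base_sd Baseline copy-number standard deviation (> 0).
#' @param effect Scenario effect in copies: the human mean shift for
#'   `human_expanded`, the component separation for `close_multimodal`,
#'   the distant-clade mean shift for `distant_shifted`.
#' @param missing_rate Per-cell i.i.d. missingness fraction in `[0, 1]`.
#' @return A `locus_scenario` list.
#' @export
locus_scenario <- function(scenario = c("conserved", "human_expanded",
                                        "close_multimodal",
                                        "distant_shifted"),
                           n_loci, base_mean = 20, base_sd = 1,
                           effect = 0, missing_rate = 0.05) {
  scenario <- match.arg(scenario)
  stopifnot(n_loci >= 0, base_sd > 0, effect >= 0,
            missing_rate >= 0, missing_rate <= 1)
  structure(
    list(scenario = scenario, n_loci = n_loci, base_mean = base_mean,
         base_sd = base_sd, effect = effect, missing_rate = missing_rate),
    class = "locus_scenario"
  )
}

# normal truncated below at `lower`, via inverse-CDF sampling
rnorm_trunc <- function(n, mean, sd, lower = 1) {
  plo <- pnorm(lower, mean, sd)
  u <- runif(n, plo, 1)
  u <- pmin(u, 1 - 1e-12)
  qnorm(u, mean, sd)
}

#' Generate a synthetic cohort copy-number matrix with truth labels
#'
#' Simulates a loci x haplotypes copy-number matrix under the given cohort
#' design and locus scenarios.  Copy numbers are drawn from normal
#' distributions truncated below at 1 and rounded to 0.1 copies:
#' * `conserved`: one distribution for every haplotype;
#' * `human_expanded`: `effect` added to the human mean only;
#' * `close_multimodal`: close-NHP values from a symmetric two-component
#'   mixture with means `base_mean +/- effect/2`;
#' * `distant_shifted`: `effect` added to the distant-NHP mean only.
#' Missing entries are placed i.i.d. at each scenario's `missing_rate`.
#'
#' @param design A [cohort_design()].
#' @param scenarios A list of [locus_scenario()] objects with positive
#'   `n_loci`.
#' @param seed Integer seed (mandatory; defaults to `design$seed`).
#' @return List with `matrix` (numeric, loci x haplotypes, `NA` missing),
#'   `meta` (haplotype metadata), and `truth` (locus_id, scenario).
#' @export
gen_cohort_matrix <- function(design, scenarios, seed = design$seed) {
  if (!inherits(design, "cohort_design")) stop("design must be a cohort_design")
  if (is.null(seed)) stop("seed is mandatory")
  if (inherits(scenarios, "locus_scenario")) scenarios <- list(scenarios)
  if (length(scenarios) == 0) stop("empty scenario list")
  ok <- vapply(scenarios, inherits, logical(1), "locus_scenario")
  if (!all(ok)) stop("scenarios must be locus_scenario objects")
  if (sum(vapply(scenarios, `[[`, numeric(1), "n_loci")) == 0) {
    stop("at least one scenario needs n_loci > 0")
  }
  meta <- design$meta
  nh <- nrow(meta)
  is_human <- meta$clade == "human"
  is_close <- meta$clade == "close_nhp"
  is_distant <- meta$clade == "distant_nhp"

  with_seed(seed, {
    rows <- list()
    truth <- list()
    li <- 0
    for (sc in scenarios) {
      if (sc$n_loci == 0) next
      for (i in seq_len(sc$n_loci)) {
        li <- li + 1
        mu <- rep(sc$base_mean, nh)
        vals <- numeric(nh)
        if (sc$scenario == "human_expanded") {
          mu[is_human] <- mu[is_human] + sc$effect
        } else if (sc$scenario == "distant_shifted") {
          mu[is_distant] <- mu[is_distant] + sc$effect
        }
        vals <- rnorm_trunc(nh, mu, sc$base_sd)
        if (sc$scenario == "close_multimodal") {
          nc <- sum(is_close)
          comp <- rbinom(nc, 1, 0.5)
          cmu <- sc$base_mean + ifelse(comp == 1, sc$effect / 2,
                                       -sc$effect / 2)
          vals[is_close] <- rnorm_trunc(nc, cmu, sc$base_sd)
        }
        vals <- round(vals, 1)
        if (sc$missing_rate > 0) {
          vals[runif(nh) < sc$missing_rate] <- NA_real_
        }
        rows[[li]] <- vals
        truth[[li]] <- sc$scenario
      }
    }
    mat <- do.call(rbind, rows)
    rownames(mat) <- sprintf("locus%05d", seq_len(nrow(mat)))
    colnames(mat) <- meta$haplotype_id
    list(
      matrix = mat,
      meta = meta,
      truth = data.frame(locus_id = rownames(mat),
                         scenario = unlist(truth),
                         stringsAsFactors = FALSE)
    )
  })
}

# sample that never auto-expands a scalar into 1:x
resample <- function(x, n = 1, replace = FALSE) {
  x[sample.int(length(x), n, replace = replace)]
}

# random DNA of length n as a character scalar
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# TRUE when the motif is not a repetition of a shorter motif
is_primitive_motif <- function(motif) {
  L <- nchar(motif)
  if (L == 1) return(TRUE)
  for (p in seq_len(L - 1)) {
    if (L %% p == 0) {
      unit <- substr(motif, 1, p)
      if (paste(rep(unit, L / p), collapse = "") == motif) return(FALSE)
    }
  }
  TRUE
}

all_kmers <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  substring(seq, seq_len(L - k + 1), k:L)
}

#' Generate a genotyping fixture: toy genomes with planted STR tracts
#'
#' Builds a reference genome plus `n_haplotypes` haplotype genomes, each a
#' single contig where every locus is a pure tandem tract of a random
#' primitive motif embedded in unique random flanks (flank k-mer uniqueness
#' is enforced by rejection sampling so flank anchoring is unambiguous when
#' `snv_rate = 0`).  Copy numbers are drawn per haplotype; flank bases are
#' mutated i.i.d. at `snv_rate` in each haplotype; boundary bases adjacent
#' to each tract are chosen so they cannot extend the repeat run.
#'
#' @param n_loci Number of STR loci to plant.
#' @param motif_length_range Length-2 integer range within 1..6.
#' @param copies_range Length-2 integer range of planted copy numbers
#'   (minimum 2).
#' @param flank_len Flank length in bp (default 500).
#' @param snv_rate Per-base flank substitution rate per haplotype.
#' @param seed Integer seed.
#' @param n_haplotypes Number of haplotype genomes (default 3).
#' @param spacer_len Random spacer length between locus blocks.
#' @return List with `reference` and `genomes`
#'   ([Biostrings::DNAStringSet]; `genomes` is a named list), `panel`
#'   (chrom, start, end, motif, class; 0-based half-open reference
#'   coordinates), and per-haplotype `truth` (locus_id, haplotype_id,
#'   copy_number, start, end, motif).
#' @export
gen_genotyping_fixture <- function(n_loci, motif_length_range = c(1, 6),
                                   copies_range = c(8, 30), flank_len = 500,
                                   snv_rate = 0, seed, n_haplotypes = 3,
                                   spacer_len = 300) {
  stopifnot(n_loci >= 1, length(motif_length_range) == 2,
            motif_length_range[1] >= 1, motif_length_range[2] <= 6,
            copies_range[1] >= 2, flank_len >= motif_length_range[2],
            snv_rate >= 0, snv_rate < 1, n_haplotypes >= 1)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    k <- 21
    seen <- new.env(hash = TRUE, parent = emptyenv())
    fresh_flank <- function() {
      repeat {
        fl <- random_dna(flank_len)
        if (flank_len < k) return(fl)
        km <- all_kmers(fl, k)
        if (!any(vapply(km, function(x) exists(x, envir = seen),
                        logical(1))) && !anyDuplicated(km)) {
          for (x in km) assign(x, TRUE, envir = seen)
          return(fl)
        }
      }
    }
    loci <- vector("list", n_loci)
    for (i in seq_len(n_loci)) {
      repeat {
        L <- resample(seq(motif_length_range[1], motif_length_range[2]))
        motif <- random_dna(L)
        if (is_primitive_motif(motif)) break
      }
      lf <- fresh_flank()
      rf <- fresh_flank()
      # keep the flanks from extending the planted run
      last <- substr(motif, L, L)
      if (substr(lf, flank_len, flank_len) == last) {
        substr(lf, flank_len, flank_len) <- sample(setdiff(bases, last), 1)
      }
      first <- substr(motif, 1, 1)
      if (substr(rf, 1, 1) == first) {
        substr(rf, 1, 1) <- sample(setdiff(bases, first), 1)
      }
      copies <- resample(seq(copies_range[1], copies_range[2]),
                         n_haplotypes + 1, replace = TRUE)
      loci[[i]] <- list(motif = motif, lf = lf, rf = rf, copies = copies)
    }
    spacers <- replicate(n_loci + 1, random_dna(spacer_len))

    mutate <- function(seq, rate) {
      if (rate == 0) return(seq)
      L <- nchar(seq)
      hits <- which(runif(L) < rate)
      if (length(hits) == 0) return(seq)
      ch <- strsplit(seq, "", fixed = TRUE)[[1]]
      ch[hits] <- vapply(ch[hits],
                         function(b) sample(setdiff(bases, b), 1), character(1))
      paste(ch, collapse = "")
    }

    build <- function(hap_idx, rate) {
      parts <- character(0)
      pos <- 0
      recs <- vector("list", n_loci)
      for (i in seq_len(n_loci)) {
        lc <- loci[[i]]
        tract <- paste(rep(lc$motif, lc$copies[hap_idx]), collapse = "")
        lf <- mutate(lc$lf, rate)
        rf <- mutate(lc$rf, rate)
        parts <- c(parts, spacers[i], lf, tract, rf)
        start <- pos + spacer_len + flank_len
        end <- start + nchar(tract)
        pos <- end + flank_len
        recs[[i]] <- data.frame(
          locus_id = sprintf("locus%04d", i), start = start, end = end,
          motif = lc$motif, copy_number = lc$copies[hap_idx],
          stringsAsFactors = FALSE
        )
      }
      parts <- c(parts, spacers[n_loci + 1])
      list(seq = paste(parts, collapse = ""), recs = do.call(rbind, recs))
    }

    ref <- build(n_haplotypes + 1, 0)
    genomes <- list()
    truth <- list()
    for (h in seq_len(n_haplotypes)) {
      hap_id <- sprintf("hap%02d", h)
      g <- build(h, snv_rate)
      genomes[[hap_id]] <- Biostrings::DNAStringSet(setNames(g$seq, "chr1"))
      tr <- g$recs
      tr$haplotype_id <- hap_id
      truth[[hap_id]] <- tr
    }
    panel <- data.frame(
      chrom = "chr1",
      start = ref$recs$start,
      end = ref$recs$end,
      motif = ref$recs$motif,
      class = "Simple_repeat",
      stringsAsFactors = FALSE
    )
    list(
      reference = Biostrings::DNAStringSet(setNames(ref$seq, "chr1")),
      genomes = genomes,
      panel = panel,
      truth = do.call(rbind, truth)
    )
  })
}

#' Generate an annotation track with a planted enrichment
#'
#' Places `n_features` intervals on a toy genome so that the probability a
#' member of `enriched_subset` is overlapped equals `enrichment_factor`
#' times the rate for the remaining STRs: a fraction of the features are
#' anchored onto STRs chosen per-STR with Bernoulli probabilities in that
#' ratio, the rest are placed uniformly away from all STRs.
#' `enrichment_factor = Inf` anchors every feature on the enriched subset.
#'
#' @param genome_size Genome length in bp (single chromosome `"chr1"`).
#' @param strs [GenomicRanges::GRanges] of STR loci.
#' @param enriched_subset Logical or integer index into `strs`.
#' @param n_features Number of features to place (> 0).
#' @param enrichment_factor Target overlap-rate ratio (>= 1 or `Inf`).
#' @param seed Integer seed.
#' @param feature_width Feature width in bp.
#' @return A [GenomicRanges::GRanges] annotation track.
#' @export
gen_annotation_fixture <- function(genome_size, strs, enriched_subset,
                                   n_features, enrichment_factor, seed,
                                   feature_width = 200) {
  if (n_features <= 0) stop("n_features must be positive")
  if (!is.infinite(enrichment_factor) && enrichment_factor < 1) {
    stop("enrichment_factor must be >= 1 (or Inf)")
  }
  n_str <- length(strs)
  enr <- rep(FALSE, n_str)
  enr[enriched_subset] <- TRUE
  with_seed(seed, {
    if (is.infinite(enrichment_factor)) {
      idx <- resample(which(enr), n_features, replace = TRUE)
      centers <- (GenomicRanges::start(strs[idx]) +
                    GenomicRanges::end(strs[idx])) %/% 2
      st <- pmax(1, centers - feature_width %/% 2)
    } else {
      f <- enrichment_factor
      n_e <- sum(enr)
      n_b <- n_str - n_e
      p_bg <- min(0.5 * n_features / max(1, n_b + f * n_e),
                  0.9 / max(f, 1))
      p <- ifelse(enr, f * p_bg, p_bg)
      hit <- runif(n_str) < p
      if (sum(hit) > n_features) {
        stop("genome_size/n_features too small for the requested enrichment")
      }
      centers <- (GenomicRanges::start(strs[hit]) +
                    GenomicRanges::end(strs[hit])) %/% 2
      st <- pmax(1, centers - feature_width %/% 2)
      n_rand <- n_features - sum(hit)
      if (n_rand > 0) {
        rand_st <- integer(0)
        tries <- 0
        while (length(rand_st) < n_rand) {
          tries <- tries + 1
          if (tries > 200) {
            stop("genome_size too small to place features away from STRs")
          }
          cand <- sample.int(genome_size - feature_width,
                             n_rand - length(rand_st), replace = TRUE)
          gr <- GenomicRanges::GRanges(
            "chr1", IRanges::IRanges(cand, width = feature_width))
          keep <- !IRanges::overlapsAny(gr, strs)
          rand_st <- c(rand_st, cand[keep])
        }
        st <- c(st, rand_st)
      }
    }
    GenomicRanges::GRanges(
      "chr1",
      IRanges::IRanges(start = st, width = feature_width),
      name = sprintf("feat%05d", seq_along(st))
    )
  })
}

#' Generate paired cross-species expression tables
#'
#' Builds an "NHP" genes x conditions expression table from a log-normal
#' model and a "human" table equal to it times `2^lfc_effect` for genes in
#' the target set and times `2^e`, `e ~ N(0, noise_sd)` per gene and
#' condition, elsewhere.
#'
#' @param genes Character vector of gene identifiers (the universe).
#' @param target_genes Genes receiving the planted log2 fold change.
#' @param lfc_effect Planted log2 fold change.
#' @param noise_sd Standard deviation of the log2 noise on non-target
#'   genes (>= 0).
#' @param n_conditions Number of replicate conditions per species.
#' @param seed Integer seed.
#' @return List with matrices `human` and `nhp` and the `target_genes`.
#' @export
gen_expression_fixture <- function(genes, target_genes, lfc_effect = 1,
                                   noise_sd = 0.2, n_conditions = 4, seed) {
  stopifnot(noise_sd >= 0, n_conditions >= 1)
  if (!all(target_genes %in% genes)) stop("target_genes must be in genes")
  ng <- length(genes)
  with_seed(seed, {
    nhp <- matrix(stats::rlnorm(ng * n_conditions, log(100), 1),
                  nrow = ng,
                  dimnames = list(genes,
                                  sprintf("cond%02d", seq_len(n_conditions))))
    eps <- matrix(rnorm(ng * n_conditions, 0, noise_sd), nrow = ng)
    fold <- 2^eps
    fold[genes %in% target_genes, ] <- 2^lfc_effect
    human <- nhp * fold
    list(human = human, nhp = nhp, target_genes = target_genes)
  })
}
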