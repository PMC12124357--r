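---
title: "Detecting human-specific STR expansions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting human-specific STR expansions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strexpand)
```

## The problem

Short tandem repeats (STRs) are tracts of a 1-6 bp DNA motif repeated in
tandem. Their copy numbers mutate orders of magnitude faster than single
nucleotides, which makes them candidates for rapid, lineage-specific
regulatory evolution. Given haploid genome assemblies from a large human
cohort and a panel of non-human primate (NHP) species spanning both close
(great ape) and more distant lineages, the question is: which STR loci
have undergone a copy-number expansion specific to the human lineage,
against a background of loci whose copy numbers are conserved across the
primate panel?

`strexpand` implements the full chain: copy-number genotyping from
assemblies, a three-stage statistical cascade that first defines a
conserved background and then calls human-specific expansions, and the
downstream interpretation layer (regulatory-element enrichment,
target-gene assignment through promoters, chromatin loops and TADs,
cross-species expression shift tests, and transcription-factor motif bias
in STR flanks). A synthetic-cohort generator with known truth labels makes
every stage testable without any external data.

## Copy-number genotyping

The reference panel keeps repeat-annotation records of class
`Simple_repeat` with motif lengths 1-6 bp (`build_reference_panel()`).
For each locus the reference STR plus 500 bp of flanking sequence is
located in each haploid genome by exact-seed k-mer anchoring of the two
flanks (default k = 21), trying successive seed offsets so that isolated
substitutions cannot hide a locus, and verifying candidate placements by
bounded-mismatch comparison of the full flanks. Among verified candidate
regions the *longest* is retained; a locus that cannot be anchored is a
missing call.

Within the mapped region, `detect_repeats()` reports every maximal
perfect run of period $m \le 6$ (positions with
$s_i = s_{i+m}$), collapsing reports whose motif is a repetition of a
shorter motif onto the primitive motif. Motifs are compared in canonical
form: the lexicographic minimum over all cyclic rotations of the motif
and of its reverse complement (`canonicalize_motif()`), so `"CA"`,
`"AC"`, `"TG"` and `"GT"` are one family. When several tracts of the
expected canonical motif survive, the call minimises
$|d_\mathrm{left} - 500| + |d_\mathrm{right} - 500|$, the L1 distance of
the tract boundaries from the expected 500-bp flank geometry, with ties
resolved to the smaller coordinate. The copy number is tract length
divided by motif length, exactly.

Two deliberate simplifications, both documented limitations: only perfect
(purity-1) tracts are detected, and no general-purpose aligner is run —
flank anchoring assumes locally unique flanks, which holds for the
synthetic fixtures and for most of a real genome, and externally produced
alignments can be substituted where it does not.

## The classification cascade

The cascade takes a loci x haplotypes copy-number matrix with haplotype
metadata (species; clade `human`, `close_nhp`, `distant_nhp`) and assigns
each locus exactly one tier:

1. **Coverage** — a locus needs at least 10 non-missing human calls and
   calls in at least 6 of the 7 NHP species; otherwise
   `excluded_low_coverage`.
2. **Unimodality** — Hartigan's dip statistic of the pooled close-NHP
   copy numbers, calibrated by Monte-Carlo against uniform null samples
   of the same size (10,000 draws, seeded, cached per sample size), with
   Benjamini-Hochberg adjustment across loci; `q < 0.05` is
   `excluded_multimodal`. Samples with fewer than 4 distinct values are
   treated as unimodal by convention.
3. **Cross-clade consistency** — a two-sample Kolmogorov-Smirnov test of
   distant-NHP against close-NHP values (asymptotic p at effective size
   $n_x n_y/(n_x+n_y)$), BH-adjusted; `q < 0.05` is
   `excluded_distant_shift`. Survivors are the NHP-conserved set
   (**ncSTR**).
4. **Expansion** — a one-tailed Wilcoxon rank-sum test of human against
   pooled NHP values (midranks, tie-corrected variance, continuity
   correction), Bonferroni-adjusted over the loci tested; adjusted
   `p < 0.05` is **heSTR**.

Downstream comparisons use the ncSTR set *excluding* heSTRs as the
background, keeping the compared groups disjoint. The expansion threshold
has a stricter 0.01 variant (`pipeline_config(hestr_alpha = 0.01)`),
reflecting the two thresholds in circulation for this analysis; the
output records which was used.

### The dip statistic

No dip implementation is available in this environment, so the package
computes it from first principles, exactly. The dip of an empirical
distribution $F_n$ is the smallest sup-norm distance to any unimodal CDF
(convex up to the mode, concave after it, with an atom permitted only at
the mode). For a *fixed* mode position all constraints are linear: band
constraints at the distinct values, convex-hull deviation bounds on each
shoulder — including chords that extend across inter-point gaps to a
terminal at the mode position — and a monotone junction condition linking
the two shoulders. The implementation enumerates every distinct value as
a point mode and optimizes the mode position inside each gap (the gap
objective is quasiconvex: its left part is nondecreasing and its right
part nonincreasing in the mode position, so the crossing of the two
deviation curves locates the optimum; a bisection finds it, with a
golden-section fallback when the junction binds). The result was
validated to below $10^{-7}$ against two independent linear-programming
oracles on thousands of random samples, including heavy ties, atoms and
bimodal mixtures; 50 oracle values are frozen into the test suite.

The Monte-Carlo calibration uses the uniform distribution as the null,
the standard conservative choice (among unimodal distributions the
uniform produces the largest dips). A consequence worth knowing: at the
close-NHP sample size of 18 the test has limited resolution. Balanced
two-component mixtures are excluded reliably only when the component
separation is large relative to the within-component spread; at a
separation of five within-component standard deviations most mixture
samples produce dips inside the uniform null's own range, and the screen
excludes only a minority of them. The power curve can be reproduced with
the generator:

```{r dip-power, eval = FALSE}
des <- cohort_design()
for (sep in c(5, 8, 12, 16)) {
  g <- gen_cohort_matrix(des,
                         locus_scenario("close_multimodal", 200,
                                        effect = sep),
                         seed = 100 + sep)
  rec <- classify_strs(g$matrix, g$meta, pipeline_config(seed = 1))
  cat(sep, "sd separation:",
      mean(rec$tier == "excluded_multimodal"), "\n")
}
```

This is a property of the dip test at this sample size, not of the
implementation: the exact statistic and a calibrated p-value cannot be
made more sensitive without changing the test. Loci that slip through
stage 2 as multimodal mixtures are still protected against false
expansion calls by stage 4's rank-sum comparison, which is what the null
calibration below verifies.

### Multiple-testing conventions

Stage 2 and 3 adjust by Benjamini-Hochberg over the loci entering each
stage; stage 4 adjusts over the ncSTR loci actually tested (Bonferroni by
default). Under a fully conserved synthetic cohort of 2,000 loci this
keeps the expected number of false expansion calls per run well below
one, which the acceptance script measures directly.

## The synthetic cohort generator

`gen_cohort_matrix()` emulates the study design the cascade targets: 148
human haplotypes, 18 haplotypes from four close NHP species (5/5/4/4) and
8 from three distant species (3/3/2). Copy numbers are drawn from normal
distributions truncated below at 1 copy and rounded to 0.1 copies —
the simplest model whose unimodality the dip screen should accept.
Scenarios plant known structure: `human_expanded` shifts the human mean,
`close_multimodal` replaces close-NHP values with a symmetric
two-component mixture (components at $\pm$ half the separation, i.i.d.
fair assignment), `distant_shifted` shifts the distant clade.
Missingness is i.i.d. per cell (default 5%); real missingness from
mapping failure is locus-correlated, but the i.i.d. model is enough to
exercise the coverage filters. The default within-locus standard
deviation of 1 copy is a free parameter of the model — no empirical
per-locus variance is published to pin it — and stays configurable.

What passing tests on these fixtures do *not* show about real data:
assembly errors, locus-correlated dropout, impure or interrupted tracts,
and mutation processes with length-dependent rates are all outside the
generator's scope.

`gen_genotyping_fixture()` plants pure tandem tracts of random primitive
motifs in unique random flanks (21-mer uniqueness enforced by rejection
sampling, boundary bases chosen so flanks cannot extend a run), with
per-haplotype copy numbers and optional i.i.d. flank substitutions.
`gen_annotation_fixture()` and `gen_expression_fixture()` plant
enrichment factors and log2 fold changes for the interval and expression
layers.

## Interval enrichment and downstream statistics

All interval work is half-open BED semantics, strand-ignored, backed by
`GenomicRanges` and verified against brute-force scans in the tests.
Enrichment tables are tested exactly: the two-sided p sums hypergeometric
point probabilities no larger than the observed one; the reported odds
ratio is the sample estimate $ad/bc$ with the Haldane-Anscombe 0.5
correction only when a zero cell occurs (flagged). This differs slightly
from the conditional-MLE odds ratio some tools report; the p-values
agree exactly. Region categories use promoter = TSS $\pm$ 3 kb with
precedence promoter > exon > intron; enhancer-style "within 10 kb"
overlap is the `slop` argument. Per-TAD interaction-frequency
comparisons consume a numeric `value` column on the TAD track and reuse
the rank-sum test. Odds ratios from independent overlap studies are
pooled by DerSimonian-Laird random effects.

Target genes are assigned by three mechanisms — colocalization (promoter
or gene body), looping (at least two distinct expanded STRs in the union
of a gene's promoter-centered loop anchors, either anchor, pooled over
tissues) and TAD co-membership (gene body in an innermost TAD that
contains an expanded STR) — and genes supported by two or more mechanisms
form the "regulation by multiple mechanisms" class. The looping rule
counts *distinct* supporting loci; the TAD rule deliberately reads
"intersecting TAD intervals containing expanded STRs" as co-membership
of gene and STR in the same innermost TAD.

Cross-species expression comparisons reduce each table to counts per
million, average replicate conditions, and test *between-gene-set* shifts
of log2 fold changes with the one-sided rank-sum test, BH-adjusted across
conditions at the conventional q < 0.1. Per-gene differential calls are
out of scope — only the set-level shift feeds the conclusions, so no
count-model dispersion estimation is needed. Pseudotime profiles use 100
equal-count bins (quantile binning guarantees non-empty bins). Ranked
accessibility enrichment is the classical weighted running-sum score with
label-permutation p-values; at weight exponent 0 its absolute value
equals the two-sample Kolmogorov-Smirnov statistic between member and
non-member ranks, which the tests exploit as an analytic cross-check.

Motif scanning reads MEME minimal format, scores windows with log2
odds against a background model, and calls sites above the score
threshold whose null tail probability is at most $10^{-4}$, computed by
exact dynamic programming on a discretized score distribution (0.001-bit
granularity; for short motifs this equals brute-force enumeration of all
words on the same discretization). Per-TF bias between expanded-STR and
conserved-STR flanks uses flank *occupancy* (at least one hit) as the
2x2 unit — occupancy keeps the Fisher test's exchangeability assumption
honest where raw site counts would not — with the raw-count ratio
reported alongside; selection requires OR > 1 and BH q < 0.05. The
human-versus-NHP comparison of per-TF odds ratios uses a one-sided
Wilcoxon signed-rank test on the per-TF differences, zeros dropped.

## Numerical choices and degenerate inputs

* Rank-sum: normal approximation with midranks, tie-corrected variance
  and continuity correction; identical samples return p = 1. The
  continuity correction keeps the approximation within 0.02 of the exact
  permutation p on tie-free samples as small as 4 + 4.
* K-S: asymptotic Kolmogorov tail at effective sample size; at very
  small sizes the tail is conservative for extreme D values, which the
  tests document against full enumeration.
* Dip p-values: add-one Monte-Carlo `(1 + k)/(1 + B)`, so dip 0 gives
  exactly p = 1; null tables are memoized per (size, draws, seed).
* Empty samples, degenerate 2x2 margins, fewer cells than pseudotime
  bins, all-member GSEA inputs and trans-chromosomal loops raise
  immediate, specific errors.
* All generators are pure functions of (parameters, seed); the RNG state
  of the caller is restored afterwards.

## Problem sizes used in the test suite

The shipped tests run the cascade at the full cohort design with 2,000
null loci and 500 loci per planted scenario, genotype 200-locus fixtures
with 2 haplotypes, and verify the statistical kernels against
enumeration oracles at sizes where enumeration is exact (rank-sum and
K-S at 4 + 4, Fisher margins to 200, motifs to length 5, 50 frozen dip
oracle cases at n <= 12). These sizes exercise every code path at full
statistical fidelity while keeping a complete run on one CPU short.
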