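# strexpand

Genome-wide discovery of **human-specific expanded short tandem repeats
(heSTRs)** from haploid genome assemblies, with the interpretation layer
needed to connect them to regulatory biology.

Short tandem repeats (STRs) — tracts of a 1–6 bp motif repeated in tandem
— mutate in copy number orders of magnitude faster than single
nucleotides. Given copy-number calls for a large human cohort and a panel
of non-human primate (NHP) species spanning close (great ape) and distant
lineages, `strexpand` identifies loci whose copy numbers are conserved
across the primate panel (**ncSTRs**) and, among them, loci with a robust
human-specific expansion (**heSTRs**). The package is aimed at
comparative and population genomicists working with assembly-based STR
genotypes.

## The statistical core

For each STR locus with copy-number observations
$x^{\mathrm{hum}}, x^{\mathrm{close}}, x^{\mathrm{dist}}$ (human,
close-NHP and distant-NHP haplotypes), the cascade applies, in order:

1. **Coverage**: ≥ 10 human calls and calls in ≥ 6 of the 7 NHP species.
2. **Unimodality**: Hartigan's dip statistic
   $D = \min_{G\ \mathrm{unimodal}} \sup_x |F_n(x) - G(x)|$ of the pooled
   close-NHP values, with a seeded Monte-Carlo p-value against uniform
   null samples and Benjamini–Hochberg control across loci
   (q < 0.05 excludes the locus as multimodal). The dip is computed
   *exactly* by a mode-enumeration algorithm (see the methods vignette).
3. **Cross-clade consistency**: two-sample Kolmogorov–Smirnov test of
   distant-NHP against close-NHP values, BH-adjusted (q < 0.05 excludes
   the locus as distant-shifted). Survivors are ncSTRs.
4. **Expansion**: one-tailed Wilcoxon rank-sum test of human versus
   pooled NHP values, Bonferroni-adjusted over the loci tested; adjusted
   p < 0.05 calls an heSTR.

Around the core sit: assembly genotyping (flank-anchored locus location,
exact tandem-tract detection, canonical motifs, a 500-bp flank-distance
tie-break), genomic-interval enrichment (exact Fisher tables, density
profiles, permutation and proportion tests, DerSimonian–Laird pooling),
target-gene assignment (promoter/gene-body colocalization, promoter loop
anchors, innermost-TAD co-membership, and the multi-mechanism class),
cross-species expression shift tests, and PWM scanning of STR flanks for
transcription-factor binding bias. A synthetic-cohort generator with
truth labels makes the whole chain testable offline.

## Worked example

```r
library(strexpand)

design <- cohort_design()          # 148 human, 18 close-NHP, 8 distant-NHP
cohort <- gen_cohort_matrix(
  design,
  list(locus_scenario("conserved", 450),
       locus_scenario("human_expanded", 50, effect = 4)),
  seed = 42)

records <- classify_strs(cohort$matrix, cohort$meta,
                         pipeline_config(seed = 1))
table(records$tier)
#> heSTR ncSTR
#>    50   450
```

All 50 planted expansions are recovered and none of the 450 conserved
loci is miscalled. Each record carries the full audit trail:

```r
head(subset(records, tier == "heSTR"), 3)
#>       locus_id n_human_calls dip_q ks_q rs_p_adj  tier
#> 451 locus00451           143 0.985    1 3.70e-12 heSTR
#> 452 locus00452           143 0.985    1 1.62e-13 heSTR
#> 453 locus00453           144 0.985    1 1.49e-13 heSTR
```

`dip_q` and `ks_q` near 1 say the close-NHP values are unimodal and the
distant clade is consistent with them; `rs_p_adj` is the
Bonferroni-adjusted one-tailed rank-sum p for the human expansion — for
`locus00451` the human mean is 24.1 copies against 19.6 in NHPs, an
expansion of about 4 copies as planted.

A thin command-line entry point for the pipeline stages is installed
with the package (`inst/scripts/strexpand`):

```sh
Rscript inst/scripts/strexpand simulate-cohort --n-conserved 450 \
    --n-expanded 50 --effect 4 --seed 42 --out-dir sim/
Rscript inst/scripts/strexpand classify --matrix sim/matrix.tsv \
    --meta sim/meta.tsv --seed 1 --out sim/class.tsv
```

## Documentation

The methods vignette (`vignettes/strexpand-methods.Rmd`) describes the
genotyping rules, the cascade's tests and their calibration, the exact
dip computation and its power profile at small sample sizes, the
synthetic generator's assumptions, and the conventions of every
downstream module.
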