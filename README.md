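# csslqtl

Multi-method consensus QTL mapping for chromosome segment substitution line
(CSSL) populations.

## What it is for

CSSL panels — homozygous lines each carrying a few donor-genome segments in
a recurrent-parent background — are a workhorse for dissecting complex
stress syndromes such as rice salinity tolerance, where dozens of partially
redundant traits (visual salt-injury scores, dry weights and survival,
ion/chlorophyll/electrolyte physiology) are collected across experiments.
Different QTL scan statistics live on incomparable scales, so `csslqtl`
compares them by *rank*:

1. **Three scans per trait** — Haley–Knott interval mapping
   (LOD = (n/2)·log₁₀(RSS₀/RSS₁) on two-state Markov-chain donor
   probabilities with Haldane transitions), a per-marker Wilcoxon rank-sum
   test, and a Firth-penalized logistic regression of the donor-allele
   indicator on the trait (−log₁₀ p scores).
2. **Consensus** — markers with the donor allele in < 5 CSSLs are dropped;
   scores are percentile-rank (PR) normalized within each trait × method;
   markers with PR > 80 in ≥ 2 of 3 methods are *high-confidence*.
3. **Regions** — high-confidence markers chain into regions when within
   1 Mb or in strong LD (r² ≥ 0.8); regions merged across traits are
   classified *multi-trait* (≥ 2 linked traits) or *trait-specific*.
4. **Dual trait correlations** — Spearman matrices on phenotype scores
   (across lines) and on QTL-confidence scores (mean PR across markers),
   with Ward.D/Euclidean dendrograms, exposing traits that correlate
   phenotypically but map to different loci and vice versa.
5. **Expression refinement** — region candidate genes are intersected with
   genes passing p < 0.05 and a housekeeping-calibrated |log2FC| cutoff
   (≈ 0.2 microarray, 2 RNA-seq) in ≥ 3 independent experimental settings.

A bundled simulator generates CSSL populations, multi-trait phenotypes with
planted QTL architectures, and differential-expression tables with
housekeeping genes, plus full ground truth for benchmarking every stage.

## Worked example

```r
library(csslqtl)

pop <- simulate_population(seed = 7)                      # 120 lines, 5 x 100 markers
sim <- simulate_traits(pop,
  list(qtl_spec("chr1", 15e6, c(SIS1 = 1, SIS2 = 1, DW1 = 1, DW2 = 1))),
  n_null_traits = 2, seed = 7)
fit <- qtl_consensus(pop$geno, sim$traits)
fit
#> Consensus QTL fit (6 traits, 366 informative markers, 120 lines)
#>   high-confidence (PR > 80 in >= 2 methods): 445 trait-marker calls
#>   regions: 28 (15 multi-trait, 13 trait-specific)

evaluate_recovery(fit$regions, sim$truth, pop$geno$map)[c("recovery", "fdp")]
#> $recovery
#> [1] 1
#> $fdp
#> [1] 0.9642857
```

The planted locus at chr1:15 Mb, shared by the four real traits across two
trait groups, is recovered inside a multi-trait region
(`R002 chr1 9090910–20303031`, 36 passing SNPs, linked to SIS1/SIS2/DW1/DW2).
Note the high region-level false-discovery proportion: PR normalization
passes the top 20% of markers per method *by construction*, and two of the
three methods are single-marker tests of the same data, so a rank-based
consensus always carries a large spurious-call floor. The framework is a
prioritization scheme — recovery, multi-trait agreement and downstream
evidence do the narrowing — not an error-controlled discovery procedure
(see the methods vignette for the full analysis).

`summary(fit)` prints per-trait call counts and the region table;
`plot(fit, "SIS1")` draws the genome-wide mean-PR profile with region spans;
`sweep_cutoffs()`, `evaluate_against_benchmark()`, `map_regions_to_genes()`
and `refine_candidates()` cover benchmarking and expression refinement.
Readers/writers are provided for genotype/trait/benchmark TSVs, VCF (parent
recoded), GFF3, DE tables, and region TSV/BED6.

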