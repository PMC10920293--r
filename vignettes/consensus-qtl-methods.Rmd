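---
title: "Multi-method consensus QTL mapping in CSSL populations: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-method consensus QTL mapping in CSSL populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csslqtl)
```

## The problem

Chromosome segment substitution lines (CSSLs) are near-isogenic lines each
carrying one or a few donor-genome segments in a recurrent-parent background,
fixed by repeated backcrossing and selfing. Scanning such a panel for
marker-trait associations is attractive because every line is homozygous and
the genetic contrast at a marker is a clean two-group comparison; it is
awkward because different scan statistics (linkage-based LOD scores,
nonparametric rank tests, regression p-values) live on incomparable scales,
and because a stress syndrome such as salinity response is measured through
dozens of partially redundant traits collected by different experiments.

`csslqtl` implements a consensus framework for this setting: three scan
methods per trait, percentile-rank (PR) normalization of their scores so
that methods are compared by ranking rather than parametric scale, a
two-of-three vote for high-confidence markers, LD-informed grouping of those
markers into regions classified as multi-trait or trait-specific, dual
trait-trait correlation analyses (phenotype scores versus QTL-confidence
scores), and refinement of region candidate genes by aggregated
differential-expression evidence.

## The three scans

**Interval mapping (Haley-Knott).** Each line's genome along a chromosome is
modelled as a two-state (recurrent/donor) Markov chain with Haldane
transition probabilities, $r = (1 - e^{-2d/100})/2$ for genetic distance $d$
in cM. Conditional donor probabilities at grid positions between informative
flanking calls are
$P(\text{donor} \mid g_L, g_R) = P(g_L \to \text{donor}) P(\text{donor} \to g_R) / P(g_L \to g_R)$,
with one-sided conditioning at chromosome ends and across missing flanks,
and the prior (default 0.5) where a chromosome carries no informative call
for a line. The trait is regressed on these probabilities and
$\mathrm{LOD} = (n/2)\log_{10}(\mathrm{RSS}_0/\mathrm{RSS}_1)$. At a fully
observed marker this reduces to the two-group contrast LOD, which the tests
exploit as a closed-form oracle. Genome-wide significance thresholds come
from permuting trait values across lines (1,000 permutations, 95% quantile
of null genome-wide maxima); the thresholds are reported as metadata -- the
consensus ranks raw LOD scores and never thresholds them.

Physical positions are converted to map distance at a constant rate per
chromosome (default 250 kb/cM, the right order of magnitude for a rice
genome-wide average), with origin at the first marker; a user-supplied cM
column takes precedence.

**Rank-sum test.** A per-marker two-sample Wilcoxon rank-sum (Mann-Whitney)
comparison of donor-allele versus recurrent-allele lines. The method is
often loosely called a "signed-rank" test in the applied literature, but the
comparison is between two independent allele groups, so the rank-sum form is
the only applicable one and is what we implement (via `stats::wilcox.test`):
exact enumeration when the pooled size is at most 12 without ties, otherwise
the normal approximation with tie and continuity corrections. The score is
$-\log_{10} p$ (two-sided).

**Logistic regression.** The remaining single-marker method is written in
the field as a linear model $Y = mX + \epsilon$ yet fitted with a binomial
family. The only orientation consistent with a binomial likelihood when the
trait is continuous is to take the binary donor-allele indicator as the
response and the (standardized) trait as the predictor, and that is what we
fit. Because CSSL allele groups can be tiny, complete separation is common;
we therefore use a Firth-type penalty (iteratively reweighted least squares
on the hat-value-adjusted score, maximizing
$\ell(\beta) + \tfrac{1}{2}\log\det X^\top W X$), which keeps estimates
finite under separation. The score is $-\log_{10}$ of the two-sided Wald p
for the slope; the slope (SNP effect) and McFadden's $R^2$ are reported as
auxiliaries. The test suite checks the fit against an independent
`optim()`-based maximization of the same penalized likelihood.

## The consensus pipeline

1. *Informativeness filter.* Markers whose donor allele is carried by fewer
   than 5 lines are excluded (as are markers with fewer than 2
   recurrent-allele lines, where no contrast exists). Five carriers is the
   point where between-method agreement and benchmark sensitivity/
   selectivity curves intersect in the reference analysis; it is exposed as
   `min_lines`.
2. *PR normalization.* Within each trait x method score vector over the
   filtered markers, $PR(s_i) = 100 \cdot \mathrm{rank}(s_i)/N$ with average
   ranks for ties. PR is computed per trait x method (not pooled across
   traits) because score scales differ per trait; it is invariant under any
   strictly increasing transform of the scores, a property the tests assert
   byte-identically.
3. *Vote.* A marker passes a method when PR strictly exceeds 80 ("percentile
   over 80"), and is high-confidence when it passes in at least 2 of the 3
   methods; passing all three is recorded as a separate tier.
4. *Regions.* Per trait and chromosome, high-confidence markers chain into
   one region when adjacent markers are within 1 Mb of each other **or** in
   strong LD ($r^2 \ge 0.8$, computed from complete pairs of the binary
   calls). Per-trait regions overlapping on a chromosome are merged across
   traits, accumulating their linked traits. The underlying window
   estimation of the reference protocol is described only as "LD and SNP
   density"; this explicit chaining rule is our documented stand-in, with
   both thresholds configurable (`gap_bp`, `r2_min`). The 1 Mb default
   echoes the 1-Mb windows used to describe introgressed-segment SNP
   density.
5. *Classification.* A region linked to two or more distinct traits is a
   multi-trait locus, otherwise trait-specific. Multiplicity is decided at
   trait level; the set of trait groups hit (salt-injury scores, tolerant
   phenotypes, physiological traits) is reported separately.

Benchmark evaluation treats a marker as recovered when it is
high-confidence for at least one trait, over the filtered marker universe.
"Selectivity" is implemented as specificity $TN/(TN+FP)$; precision is also
emitted so either reading is recoverable. `sweep_cutoffs()` reproduces the
full factorial sensitivity/selectivity sweep over `min_lines` and
`pr_cutoff` and reports the crossing point.

## Dual trait correlations

Spearman correlations are computed twice: across lines on phenotype scores,
and across markers on each trait's QTL-confidence vector. As the reference
protocol does not name its per-marker aggregate, we use the across-method
mean PR, which is missing-aware and keeps all three methods on equal
footing. The two bases expose discordant pairs: traits correlated
phenotypically (for example through shared environment) yet mapping to
different loci, and vice versa. P-values use the t-approximation and are
flagged at p < 0.05 but never blanked. Trait dendrograms use Euclidean
distance between correlation-matrix rows with classical Ward linkage on
unsquared distances ("ward.D"; "ward.D2" by flag), missing cells imputed as
0 with a warning.

## Expression refinement

Differential-expression tables from independent experimental settings are
consumed precomputed. Per platform class, the |log2 fold-change| cutoff is
either supplied (0.2 for microarray, 2 for RNA-seq are the conventional
values) or derived as the mean |log2FC| of housekeeping genes across that
platform's settings -- stably expressed genes calibrate what "no meaningful
change" looks like. "Average fold-change" could also be read as the mean of
raw fold changes; the mean-|log2FC| reading is implemented because it
reproduces the conventional 0.2/2 scale ordering. A gene is a DEG in a
setting when p < 0.05 (strict) and |log2FC| at or above the cutoff
(inclusive), and robust when a DEG in at least 3 settings. Region candidates
are intersected with robust DEGs; candidates without any expression record
are reported separately, never silently dropped.

## The simulator

`simulate_population()` emulates the *endpoint* of the CSSL breeding design,
not the pedigree: each of 120 lines (default) draws 1-3 non-overlapping
donor segments of 1-8 Mb uniformly on five 30-Mb chromosomes with 100 evenly
spaced markers each, and a call is 1 exactly when the marker lies in a
segment. This reproduces the structural features that matter to the scans --
homozygous lines, few segments, low per-marker donor frequency (roughly
0-0.3), strong local LD within segments -- and is deterministic given the
seed; the genotype matrix is exactly recomputable from the ground-truth
segment list, which the tests assert.

`simulate_traits()` adds planted QTL effects (in units of residual SD, sign
per trait) at the marker nearest each causal locus, optional line-level
noise shared across traits (used to emulate common-environment correlation),
and Gaussian residuals; an optional ordinal transform bins values to the 1-9
salt-injury-score scale to stress-test the rank-based scan. Realized
heritability matches $e^2 p(1-p) / (e^2 p(1-p) + \sigma^2)$ within
Monte-Carlo error. The reference studies do not report their QTL effect
sizes; the benchmarking default of 1.0 residual SD is our choice of a
realistic moderate effect. `simulate_expression()` places genes on the same
coordinate system so region-to-gene-to-DEG refinement is closed under
simulation, with housekeeping genes at $\log_2FC \sim N(0, 0.1^2)$ (mean
|log2FC| $= 0.1\sqrt{2/\pi} \approx 0.08$) and responsive genes near causal
loci.

What the simulator does **not** emulate: recombination history and
linkage drag of the actual backcross pedigree, genotyping error, ordinal
measurement error structure of visual scores, trait-trait genetic
correlation beyond shared loci, and expression measurement models
(normalization, batch effects). Passing tests therefore show that the
machinery is correct and well calibrated under the stated generative
assumptions, not that the biological conclusions of any particular real
dataset would be reproduced.

## Numerical choices

- Grid spacing for interval mapping defaults to 1 cM; the consensus consumes
  scores at observed marker positions only, so all methods share one
  position set (pseudo-positions are retained in the scan result for
  profiles). PR is likewise computed over markers only.
- Degenerate inputs: constant traits give LOD 0 and rank-sum p 1 (not
  errors); monomorphic markers give undefined (missing) LD; all-tied score
  vectors rank degenerately with a warning; positions with fewer complete
  lines than `min_scan_lines` are flagged and skipped.
- p-values are floored at 1e-300 before the $-\log_{10}$ transform; RSS
  ratios are floored at a 1e-12 relative level so LOD stays finite.
- Ties in raw scores take average ranks; with all-distinct scores a strict
  cutoff $c$ passes exactly $N - \lfloor Nc/100 \rfloor$ of $N$ markers.
- The Firth IRLS damps steps at |5| per iteration and iterates to 1e-10;
  non-convergence is flagged per marker rather than raised.
- Coordinates are 1-based inclusive internally (GFF3 convention); BED export
  converts to 0-based half-open. Missing genotype and phenotype cells are
  `NA` in all TSV dialects. Genotype/trait line sets are intersected with a
  warning, since different experiments phenotype different CSSL subsets.
- Heterozygous VCF calls map to missing: the lines are modelled as fully
  homozygous after selfing, so a heterozygous call carries no usable signal.

## Study sizes used by the tests and acceptance script

Simulated checks use 120-line populations with 300-500 markers, 1,000
permutations per trait for calibration (200 null traits), and 20 simulation
seeds for recovery, classification and correlation summaries. These sizes
give Monte-Carlo standard errors comfortably inside the asserted bands while
keeping a full run in the minutes range on one core.

## Known limitations

- **Rank-based consensus has an intrinsic false-positive floor.** PR
  normalization passes a fixed top fraction of markers per method per trait
  (20% at the default cutoff) *whether or not the trait has any signal
  there*, and two of the three methods are single-marker analyses of the
  same data and hence strongly correlated, so their votes are far from
  independent. With only one or a few true loci per trait, most
  high-confidence calls are necessarily spurious, and they scatter into
  many small regions: in the simulated studies the acceptance script
  reports region-level false-discovery proportions around 0.9 even while
  planted-locus recovery is at or above 0.9 and the calibration of the
  permutation thresholds is nominal. The framework is a *prioritization*
  scheme -- its strength is ranking and cross-method, cross-trait
  agreement -- not an error-controlled discovery procedure; downstream
  filtering (benchmark agreement, multi-trait support, expression
  evidence) is what cuts the list down, exactly as in the reference
  workflow.
- The chaining rule for regions is a documented stand-in for an
  under-specified window procedure; region boundaries should not be
  over-interpreted.
- The logistic orientation (allele as response) answers "does the trait
  predict allele carriage", the mirror of the usual QTL question; it is
  used only as one voice of the vote.
- No multiple-QTL or composite interval mapping, no epistasis, no
  covariates; complete-case analysis per trait x marker with no imputation
  beyond the Haley-Knott conditional probabilities.

## A worked run

```{r example, eval = FALSE}
pop <- simulate_population(seed = 7)
sim <- simulate_traits(pop,
  list(qtl_spec("chr1", 15e6, c(SIS1 = 1, SIS2 = 1, DW1 = 1, DW2 = 1))),
  n_null_traits = 2, seed = 7)
fit <- qtl_consensus(pop$geno, sim$traits)
summary(fit)
plot(fit, "SIS1")
evaluate_recovery(fit$regions, sim$truth, pop$geno$map)
```
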