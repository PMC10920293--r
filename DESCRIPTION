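Package: csslqtl
Title: Multi-Method Consensus QTL Mapping for Chromosome Segment
    Substitution Line Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies quantitative trait loci (QTL) in chromosome
    segment substitution line (CSSL) populations by combining three scan
    methods -- Haley-Knott interval mapping, a single-marker rank-sum
    test, and Firth-penalized logistic regression -- through
    percentile-rank normalization of their heterogeneous confidence
    scores and a two-of-three-methods consensus vote. High-confidence
    markers are grouped into linkage-disequilibrium-informed regions,
    classified as multi-trait or trait-specific, cross-correlated
    between traits on both phenotype and QTL-confidence bases, and
    refined against aggregated differential-expression evidence with
    housekeeping-calibrated fold-change cutoffs. Includes a synthetic
    CSSL population simulator with planted QTL architectures for
    benchmarking the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    ape,
    vcfR,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
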