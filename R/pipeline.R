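#' Fit the multi-method consensus QTL model to a CSSL population
#'
#' The package's central fitting function. It aligns genotypes and
#' phenotypes on their shared lines, runs the three scan methods
#' (Haley-Knott interval mapping, rank-sum, Firth logistic) for every
#' scannable trait, percentile-rank normalizes the scores over the
#' informative markers, votes markers into high-confidence status, chains
#' high-confidence markers into LD-informed regions, classifies regions as
#' multi-trait or trait-specific, and computes the dual trait-trait
#' correlation matrices (phenotype basis and QTL-confidence basis).
#'
#' @param geno a [geno_matrix()].
#' @param traits a [trait_table()].
#' @param min_lines informativeness filter: minimum donor-allele carriers
#'   (default 5).
#' @param pr_cutoff strict percentile-rank cutoff (default 80).
#' @param min_methods methods that must agree for high confidence (default 2).
#' @param step_cM interval-mapping grid spacing.
#' @param prior donor prior for flankless genotype probabilities.
#' @param gap_bp,r2_min region-chaining thresholds (1 Mb / 0.8).
#' @param n_perm interval-mapping permutations per trait for the reported
#'   LOD thresholds; 0 (default) skips them -- the consensus itself ranks
#'   raw LOD scores and does not threshold them.
#' @param min_scan_lines minimum complete lines per scan position.
#' @param seed seed for the permutation thresholds.
#' @return object of class `"cssl_qtl"`: list with `scans`, `consensus`
#'   (a [consensus_table()]), `regions` (classified), `cor_phenotype`,
#'   `cor_qtl`, `thresholds`, `params`, `geno`, `traits`, `call`.
#' @seealso [summary.cssl_qtl()], [plot.cssl_qtl()], [evaluate_recovery()],
#'   [map_regions_to_genes()], [refine_candidates()]
#' @export
#' @examples
#' pop <- simulate_population(sim_config(n_lines = 60,
#'   chromosomes = data.frame(name = "chr1", length_bp = 30e6),
#'   markers_per_chromosome = 40), seed = 7)
#' sim <- simulate_traits(pop, list(qtl_spec("chr1", 15e6,
#'   c(T1 = 1.5, T2 = 1.5))), n_null_traits = 2, seed = 7)
#' fit <- qtl_consensus(pop$geno, sim$traits)
#' summary(fit)
qtl_consensus <- function(geno, traits, min_lines = 5L, pr_cutoff = 80,
                          min_methods = 2L, step_cM = 1, prior = 0.5,
                          gap_bp = 1e6, r2_min = 0.8, n_perm = 0L,
                          min_scan_lines = 10L, seed = 1L) {
  stopifnot(inherits(geno, "geno_matrix"), inherits(traits, "trait_table"))
  if (pr_cutoff <= 0 || pr_cutoff >= 100) stop("pr_cutoff must be in (0,100)")
  if (!min_methods %in% 1:3) stop("min_methods must be 1, 2 or 3")
  if (min_lines < 1L) stop("min_lines must be >= 1")
  if (gap_bp < 0 || r2_min < 0 || r2_min > 1) stop("invalid region-chaining thresholds")
  al <- align_lines(geno, traits)
  geno <- al$geno; traits <- al$traits
  scans <- scan_all(geno, traits, step_cM = step_cM, prior = prior,
                    min_lines = min_scan_lines)
  thresholds <- NULL
  if (n_perm > 0L) {
    probs <- compute_genotype_probabilities(geno, step_cM = step_cM, prior = prior)
    thresholds <- vapply(names(scans), function(tr)
      as.numeric(permutation_threshold(probs, traits$values[, tr],
                                       n_perm = n_perm, seed = seed)),
      numeric(1))
  }
  ctab <- consensus_table(scans, geno, min_lines = min_lines,
                          pr_cutoff = pr_cutoff, min_methods = min_methods)
  regions <- classify_regions(call_regions(ctab, geno, gap_bp = gap_bp,
                                           r2_min = r2_min), traits$meta)
  cor_ph <- if (sum(traits$scannable) >= 2L) trait_correlation_phenotype(traits) else NULL
  cor_qtl <- if (length(scans) >= 2L) trait_correlation_qtl(ctab) else NULL
  structure(list(scans = scans, consensus = ctab, regions = regions,
                 cor_phenotype = cor_ph, cor_qtl = cor_qtl,
                 thresholds = thresholds,
                 params = list(min_lines = min_lines, pr_cutoff = pr_cutoff,
                               min_methods = min_methods, step_cM = step_cM,
                               prior = prior, gap_bp = gap_bp, r2_min = r2_min,
                               n_perm = n_perm, seed = seed),
                 geno = geno, traits = traits, call = match.call()),
            class = "cssl_qtl")
}

#' @export
print.cssl_qtl <- function(x, ...) {
  cat("Consensus QTL fit (", length(x$scans), " traits, ",
      length(unique(x$consensus$marker_id)), " informative markers, ",
      nrow(x$geno$calls), " lines)\n", sep = "")
  cat("  high-confidence (PR > ", x$params$pr_cutoff, " in >= ",
      x$params$min_methods, " methods): ",
      sum(x$consensus$high_confidence), " trait-marker calls\n", sep = "")
  cat("  regions: ", nrow(x$regions), " (",
      sum(x$regions$specificity_class == "multi_trait"), " multi-trait, ",
      sum(x$regions$specificity_class == "trait_specific"), " trait-specific)\n",
      sep = "")
  invisible(x)
}

#' Summarize a consensus QTL fit
#'
#' @param object a `"cssl_qtl"` fit.
#' @param ... unused.
#' @return list of class `"summary.cssl_qtl"` with per-trait high-confidence
#'   counts, the region table, and parameters.
#' @export
summary.cssl_qtl <- function(object, ...) {
  hc <- object$consensus[object$consensus$high_confidence, ]
  per_trait <- as.data.frame(table(trait_id = factor(hc$trait_id,
                                                     levels = names(object$scans))),
                             responseName = "n_high_confidence")
  reg <- object$regions
  reg$traits <- vapply(reg$traits, paste, "", collapse = ",")
  reg$markers <- NULL
  reg$trait_groups_hit <- vapply(reg$trait_groups_hit, paste, "", collapse = ",")
  structure(list(per_trait = per_trait, regions = reg, params = object$params,
                 thresholds = object$thresholds),
            class = "summary.cssl_qtl")
}

#' @export
print.summary.cssl_qtl <- function(x, ...) {
  cat("High-confidence trait-marker calls per trait:\n")
  print(x$per_trait, row.names = FALSE)
  cat("\nSalt-responsive regions:\n")
  print(x$regions, row.names = FALSE)
  if (!is.null(x$thresholds)) {
    cat("\nInterval-mapping 95% permutation LOD thresholds:\n")
    print(round(x$thresholds, 3))
  }
  invisible(x)
}

#' Plot the consensus confidence landscape of one trait
#'
#' A genome-wide profile of the across-method mean percentile rank, with
#' chromosomes laid end to end, the PR cutoff as a horizontal line,
#' high-confidence markers highlighted, and called region spans for the
#' trait marked along the axis.
#'
#' @param x a `"cssl_qtl"` fit.
#' @param trait_id trait to plot; defaults to the first scanned trait.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cssl_qtl <- function(x, trait_id = names(x$scans)[1L], ...) {
  d <- x$consensus[x$consensus$trait_id == trait_id, ]
  d <- d[order(d$chrom, d$pos_bp), ]
  chroms <- unique(d$chrom)
  offs <- stats::setNames(cumsum(c(0, vapply(chroms[-length(chroms)], function(ch)
    max(d$pos_bp[d$chrom == ch]) + 1e6, 0))), chroms)
  xx <- d$pos_bp + offs[d$chrom]
  graphics::plot(xx, d$mean_pr, col = ifelse(d$high_confidence, "firebrick", "grey40"),
                 pch = 16, cex = 0.6, xlab = "genome position (chromosomes concatenated)",
                 ylab = "mean percentile rank", main = trait_id, ylim = c(0, 100), ...)
  graphics::abline(h = x$params$pr_cutoff, lty = 2)
  reg <- x$regions[vapply(x$regions$traits, function(tr) trait_id %in% tr, TRUE), ]
  if (nrow(reg))
    graphics::segments(reg$start_bp + offs[reg$chrom], 2,
                       reg$end_bp + offs[reg$chrom], 2, lwd = 4, col = "steelblue")
  invisible(x)
}
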