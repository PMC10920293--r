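#' Pairwise linkage disequilibrium r-squared
#'
#' `r^2 = D^2 / (p_A (1-p_A) p_B (1-p_B))` with `D = p_AB - p_A p_B`,
#' computed over complete pairs of the two binary marker vectors. Undefined
#' (missing, not zero) when either marker is monomorphic among the complete
#' pairs.
#'
#' @param a,b binary (0/1, NA allowed) genotype vectors of equal length.
#' @return r-squared in `[0, 1]`, or `NA` if undefined.
#' @export
ld_r2 <- function(a, b) {
  cc <- !is.na(a) & !is.na(b)
  if (sum(cc) < 2L) return(NA_real_)
  a <- a[cc]; b <- b[cc]
  pa <- mean(a); pb <- mean(b)
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) return(NA_real_)
  d <- mean(a * b) - pa * pb
  d^2 / (pa * (1 - pa) * pb * (1 - pb))
}

#' Group high-confidence SNPs into salt-responsive regions
#'
#' Per trait and chromosome, high-confidence markers are sorted by position
#' and chained into one region when adjacent markers are within `gap_bp` of
#' each other or in strong LD (`r^2 >= r2_min`); region bounds are the
#' min/max member positions. Per-trait regions are then merged across traits
#' whenever they overlap, accumulating the linked traits, so that merged
#' regions on one chromosome are disjoint.
#'
#' @param ctab a [consensus_table()].
#' @param geno the [geno_matrix()] (for LD).
#' @param gap_bp distance threshold for chaining (default 1 Mb, matching the
#'   1-Mb windows used to describe introgressed-segment SNP density).
#' @param r2_min LD threshold for chaining (default 0.8).
#' @return data.frame of regions: region_id, chrom, start_bp, end_bp,
#'   width_bp, n_passing, mean_pr, list columns `markers` and `traits`.
#' @export
call_regions <- function(ctab, geno, gap_bp = 1e6, r2_min = 0.8) {
  hc <- ctab[ctab$high_confidence, , drop = FALSE]
  if (!nrow(hc))
    return(data.frame(region_id = character(0), chrom = character(0),
                      start_bp = integer(0), end_bp = integer(0),
                      width_bp = integer(0), n_passing = integer(0),
                      mean_pr = numeric(0), markers = I(list()), traits = I(list())))
  per_trait <- list()
  for (tr in unique(hc$trait_id)) {
    d <- hc[hc$trait_id == tr, ]
    for (chr in unique(d$chrom)) {
      dc <- d[d$chrom == chr, ]
      dc <- dc[order(dc$pos_bp), ]
      grp <- cumsum(c(1L, vapply(seq_len(nrow(dc) - 1L), function(k) {
        near <- dc$pos_bp[k + 1L] - dc$pos_bp[k] <= gap_bp
        if (near) return(0L)
        r2 <- ld_r2(geno$calls[, dc$marker_id[k]], geno$calls[, dc$marker_id[k + 1L]])
        if (!is.na(r2) && r2 >= r2_min) 0L else 1L
      }, integer(1))))
      for (g in split(dc, grp)) {
        per_trait[[length(per_trait) + 1L]] <-
          list(chrom = chr, start_bp = min(g$pos_bp), end_bp = max(g$pos_bp),
               markers = g$marker_id, traits = tr, mean_pr = mean(g$mean_pr, na.rm = TRUE))
      }
    }
  }
  # merge per-trait regions across traits by overlap
  merged <- list()
  for (chr in unique(vapply(per_trait, `[[`, "", "chrom"))) {
    rs <- Filter(function(r) r$chrom == chr, per_trait)
    rs <- rs[order(vapply(rs, `[[`, 0, "start_bp"))]
    cur <- rs[[1L]]
    flush <- function(cur) merged[[length(merged) + 1L]] <<- cur
    for (r in rs[-1L]) {
      if (r$start_bp <= cur$end_bp) {     # >= 1 bp overlap
        cur$end_bp <- max(cur$end_bp, r$end_bp)
        cur$markers <- union(cur$markers, r$markers)
        cur$traits <- union(cur$traits, r$traits)
        cur$mean_pr <- c(cur$mean_pr, r$mean_pr)
      } else { flush(cur); cur <- r }
    }
    flush(cur)
  }
  out <- data.frame(
    chrom = vapply(merged, `[[`, "", "chrom"),
    start_bp = vapply(merged, `[[`, 0, "start_bp"),
    end_bp = vapply(merged, `[[`, 0, "end_bp"),
    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start_bp), ]
  ord <- order(vapply(merged, `[[`, "", "chrom"), vapply(merged, `[[`, 0, "start_bp"))
  merged <- merged[ord]
  out$region_id <- sprintf("R%03d", seq_len(nrow(out)))
  out$width_bp <- out$end_bp - out$start_bp + 1L
  out$n_passing <- vapply(merged, function(r) length(r$markers), 0L)
  out$mean_pr <- vapply(merged, function(r) mean(r$mean_pr), 0)
  out$markers <- I(lapply(merged, `[[`, "markers"))
  out$traits <- I(lapply(merged, `[[`, "traits"))
  rownames(out) <- NULL
  out[c("region_id", "chrom", "start_bp", "end_bp", "width_bp", "n_passing",
        "mean_pr", "markers", "traits")]
}

#' Classify regions as multi-trait or trait-specific
#'
#' A region linked to two or more distinct traits is a multi-trait locus;
#' one linked to exactly one trait is trait-specific. The set of trait
#' groups hit is recorded separately, since multiplicity is decided at trait
#' level even when all linked traits share a group.
#'
#' @param regions output of [call_regions()].
#' @param trait_meta trait metadata data.frame (`trait_id`, `group`).
#' @return `regions` with `specificity_class` and list column
#'   `trait_groups_hit` appended.
#' @export
classify_regions <- function(regions, trait_meta) {
  n_traits <- vapply(regions$traits, length, 0L)
  if (nrow(regions) && any(n_traits == 0L)) stop("region with zero linked traits")
  regions$specificity_class <- ifelse(n_traits >= 2L, "multi_trait", "trait_specific")
  regions$trait_groups_hit <- I(lapply(regions$traits, function(trs)
    sort(unique(trait_meta$group[match(trs, trait_meta$trait_id)]))))
  regions
}

#' Map regions to candidate genes
#'
#' A gene is a candidate for a region when its interval overlaps the region
#' by at least one base pair.
#'
#' @param regions output of [call_regions()].
#' @param annotation gene annotation data.frame from [read_gff3()].
#' @return named list (by region_id) of position-sorted gene-id vectors.
#' @export
map_regions_to_genes <- function(regions, annotation) {
  out <- stats::setNames(vector("list", nrow(regions)), regions$region_id)
  for (i in seq_len(nrow(regions))) {
    if (!regions$chrom[i] %in% annotation$chrom) {
      warning("chromosome '", regions$chrom[i], "' absent from annotation")
      out[[i]] <- character(0)
      next
    }
    hit <- annotation$chrom == regions$chrom[i] &
      annotation$start_bp <= regions$end_bp[i] &
      annotation$end_bp >= regions$start_bp[i]
    g <- annotation[hit, , drop = FALSE]
    out[[i]] <- g$gene_id[order(g$start_bp)]
  }
  out
}
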