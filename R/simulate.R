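#' Simulation configuration for a synthetic CSSL population
#'
#' Describes the endpoint of a CSSL breeding design (repeated backcrossing
#' followed by selfing): fully homozygous lines each carrying a small number
#' of donor-genome segments on an otherwise recurrent-parent background. The
#' defaults emulate a rice-scale population: 120 lines, five 30-Mb
#' chromosomes with 100 evenly spaced markers each, one to three donor
#' segments per line of 1-8 Mb.
#'
#' @param n_lines number of CSSLs (>= 10).
#' @param chromosomes data.frame with columns `name`, `length_bp`.
#' @param markers_per_chromosome markers per chromosome (>= 10), evenly spaced.
#' @param segments_per_line integer range `c(min, max)` of donor segments per line.
#' @param segment_length_bp numeric range `c(min, max)` of segment lengths,
#'   sampled uniformly.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(n_lines = 120L,
                       chromosomes = data.frame(name = paste0("chr", 1:5),
                                                length_bp = rep(30e6, 5)),
                       markers_per_chromosome = 100L,
                       segments_per_line = c(1L, 3L),
                       segment_length_bp = c(1e6, 8e6)) {
  stopifnot(n_lines >= 10L, markers_per_chromosome >= 10L,
            all(chromosomes$length_bp > 0), all(segment_length_bp > 0),
            length(segments_per_line) == 2L, segments_per_line[1] >= 0L)
  if (any(segment_length_bp[2] > chromosomes$length_bp))
    stop("maximum segment length exceeds a chromosome length")
  structure(list(n_lines = as.integer(n_lines), chromosomes = chromosomes,
                 markers_per_chromosome = as.integer(markers_per_chromosome),
                 segments_per_line = as.integer(segments_per_line),
                 segment_length_bp = segment_length_bp),
            class = "sim_config")
}

#' Simulate a CSSL population
#'
#' Each line draws its number of donor segments uniformly from the configured
#' range; each segment draws a chromosome (probability proportional to
#' length), a uniform length, and a uniform start, with rejection sampling to
#' keep segments within one line non-overlapping. A marker call is 1 exactly
#' when the marker position falls inside one of the line's donor segments, so
#' the genotype matrix is a deterministic function of the segment list.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; the generator is a pure function of
#'   (config, seed).
#' @return list with `geno` (a [geno_matrix()]) and `truth`, a list carrying
#'   the donor `segments` (line_id, chrom, start_bp, end_bp) and the
#'   chromosome table.
#' @export
simulate_population <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  chroms <- config$chromosomes
  map <- do.call(rbind, lapply(seq_len(nrow(chroms)), function(i) {
    pos <- round(seq(1, chroms$length_bp[i], length.out = config$markers_per_chromosome))
    data.frame(marker_id = sprintf("%s_m%03d", chroms$name[i], seq_along(pos)),
               chrom = chroms$name[i], pos_bp = as.integer(pos),
               stringsAsFactors = FALSE)
  }))
  line_ids <- sprintf("CSSL%03d", seq_len(config$n_lines))
  seg_list <- vector("list", config$n_lines)
  for (li in seq_len(config$n_lines)) {
    n_seg <- if (config$segments_per_line[1] == config$segments_per_line[2])
      config$segments_per_line[1] else
      sample(config$segments_per_line[1]:config$segments_per_line[2], 1L)
    segs <- data.frame(line_id = character(0), chrom = character(0),
                       start_bp = numeric(0), end_bp = numeric(0))
    tries <- 0L
    while (nrow(segs) < n_seg && tries < 200L) {
      tries <- tries + 1L
      ci <- sample.int(nrow(chroms), 1L, prob = chroms$length_bp)
      len <- stats::runif(1, config$segment_length_bp[1], config$segment_length_bp[2])
      start <- stats::runif(1, 1, chroms$length_bp[ci] - len)
      end <- start + len
      same <- segs[segs$chrom == chroms$name[ci], , drop = FALSE]
      if (nrow(same) && any(start <= same$end_bp & end >= same$start_bp)) next
      segs <- rbind(segs, data.frame(line_id = line_ids[li], chrom = chroms$name[ci],
                                     start_bp = start, end_bp = end))
    }
    seg_list[[li]] <- segs
  }
  segments <- do.call(rbind, seg_list)
  rownames(segments) <- NULL
  calls <- calls_from_segments(segments, map, line_ids)
  list(geno = geno_matrix(map, calls),
       truth = list(segments = segments, chromosomes = chroms))
}

#' Reconstruct the genotype matrix from donor segments
#'
#' Used both by the simulator and as its own cross-check: the genotype matrix
#' must be recomputable from the ground-truth segment list alone.
#'
#' @param segments data.frame(line_id, chrom, start_bp, end_bp).
#' @param map marker map data.frame.
#' @param line_ids ordered line ids (segments of lines with zero segments are
#'   absent from `segments`).
#' @return lines x markers 0/1 matrix.
#' @export
calls_from_segments <- function(segments, map, line_ids) {
  calls <- matrix(0, nrow = length(line_ids), ncol = nrow(map),
                  dimnames = list(line_ids, map$marker_id))
  for (k in seq_len(nrow(segments))) {
    hit <- map$chrom == segments$chrom[k] &
      map$pos_bp >= segments$start_bp[k] & map$pos_bp <= segments$end_bp[k]
    calls[segments$line_id[k], hit] <- 1
  }
  calls
}

#' Declare a planted QTL
#'
#' @param chrom,pos_bp causal locus position.
#' @param effects named numeric vector: per affected trait, the additive
#'   donor-allele effect in units of the residual standard deviation
#'   (sign per trait).
#' @return list of class `"qtl_spec"`.
#' @export
qtl_spec <- function(chrom, pos_bp, effects) {
  stopifnot(is.numeric(effects), !is.null(names(effects)), all(is.finite(effects)))
  structure(list(chrom = chrom, pos_bp = pos_bp, effects = effects), class = "qtl_spec")
}

#' Simulate multi-trait phenotypes with planted QTL architectures
#'
#' Trait values are additive on a Gaussian scale: for line i,
#' `y_i = sum_q effect_q * g(i, nearest marker of q) + u_i + e_i`, where
#' `u_i ~ N(0, shared_noise_sd^2)` is an environmental effect common to all
#' traits of the table (0 by default) and `e_i ~ N(0, residual_sd^2)` is
#' trait-private. Null traits are pure noise. An optional ordinal transform
#' bins values to a 1-9 salt-injury-score scale.
#'
#' @param population result of [simulate_population()].
#' @param qtl_specs list of [qtl_spec()] objects.
#' @param n_null_traits number of pure-noise traits to append.
#' @param group_assignment named character vector trait_id -> group; traits
#'   not listed are assigned round-robin across the three groups.
#' @param residual_sd trait-private residual standard deviation.
#' @param shared_noise_sd standard deviation of the line-level noise shared
#'   across traits.
#' @param ordinal if TRUE, bin trait values into the ordinal 1-9 scale.
#' @param seed integer seed.
#' @return list with `traits` (a [trait_table()]) and `truth` (data.frame of
#'   causal loci: trait_id, chrom, pos_bp, marker_id, effect).
#' @export
simulate_traits <- function(population, qtl_specs = list(), n_null_traits = 0L,
                            group_assignment = NULL, residual_sd = 1,
                            shared_noise_sd = 0, ordinal = FALSE, seed = 1L) {
  set.seed(seed + 1000L)
  map <- population$geno$map
  calls <- population$geno$calls
  n <- nrow(calls)
  trait_ids <- unique(c(unlist(lapply(qtl_specs, function(q) names(q$effects))),
                        if (n_null_traits > 0) sprintf("null%02d", seq_len(n_null_traits))))
  if (anyDuplicated(trait_ids)) stop("duplicate trait ids across null and QTL traits")
  causal <- list()
  genetic <- matrix(0, nrow = n, ncol = length(trait_ids),
                    dimnames = list(rownames(calls), trait_ids))
  for (q in qtl_specs) {
    on_chr <- which(map$chrom == q$chrom)
    if (!length(on_chr)) stop("QTL chromosome '", q$chrom, "' not in map")
    if (q$pos_bp < 1 || q$pos_bp > max(map$pos_bp[on_chr]))
      stop("QTL position outside chromosome bounds")
    mk <- on_chr[which.min(abs(map$pos_bp[on_chr] - q$pos_bp))]
    for (tr in names(q$effects)) {
      genetic[, tr] <- genetic[, tr] + q$effects[[tr]] * residual_sd * calls[, mk]
      causal[[length(causal) + 1L]] <-
        data.frame(trait_id = tr, chrom = q$chrom, pos_bp = q$pos_bp,
                   marker_id = map$marker_id[mk], effect = q$effects[[tr]],
                   stringsAsFactors = FALSE)
    }
  }
  shared <- stats::rnorm(n, 0, shared_noise_sd)
  values <- genetic + shared +
    matrix(stats::rnorm(n * length(trait_ids), 0, residual_sd), n)
  if (ordinal) {
    values <- apply(values, 2, function(v) {
      br <- stats::quantile(v, probs = seq(0, 1, length.out = 10), na.rm = TRUE)
      as.numeric(cut(v, breaks = unique(br), include.lowest = TRUE, labels = FALSE))
    })
    rownames(values) <- rownames(calls)
  }
  groups <- TRAIT_GROUPS[(seq_along(trait_ids) - 1L) %% 3L + 1L]
  names(groups) <- trait_ids
  if (!is.null(group_assignment)) {
    unknown <- setdiff(names(group_assignment), trait_ids)
    if (length(unknown)) stop("group assignment for unknown trait(s): ",
                              paste(unknown, collapse = ", "))
    groups[names(group_assignment)] <- group_assignment
  }
  meta <- data.frame(trait_id = trait_ids, group = unname(groups[trait_ids]),
                     experiment_id = "sim", tolerance_direction = "unknown",
                     stringsAsFactors = FALSE)
  list(traits = trait_table(values, meta),
       truth = if (length(causal)) do.call(rbind, causal) else
         data.frame(trait_id = character(0), chrom = character(0),
                    pos_bp = numeric(0), marker_id = character(0), effect = numeric(0)))
}

#' Simulate differential-expression tables with housekeeping genes
#'
#' Genes are synthesized on the simulated coordinate system. Genes within
#' `window_bp` of a planted causal locus are salt-responsive with probability
#' `prop_de_in_causal`; responsive genes receive a strong fold change of a
#' fixed per-gene sign in every setting (platform-scaled: around 1 log2 unit
#' for microarray settings, 3 for RNA-seq), background genes draw small fold
#' changes, and housekeeping genes draw `log2FC ~ N(0, 0.1^2)`. P-values are
#' generated consistently with the fold change (two-sided normal tail at the
#' platform's background scale), so large |log2FC| implies small p.
#'
#' @param truth population ground truth from [simulate_population()] (for the
#'   chromosome table) -- pass the `truth` element.
#' @param causal data.frame of causal loci from [simulate_traits()].
#' @param n_settings number of independent experimental settings (>= 3).
#' @param prop_de_in_causal probability that a causal-adjacent gene is
#'   salt-responsive.
#' @param housekeeping_n number of housekeeping genes.
#' @param n_genes total number of genes to synthesize.
#' @param window_bp distance from a causal locus within which genes may be
#'   responsive.
#' @param seed integer seed.
#' @return list: `tables` (data.frame in [read_de_tables()] layout), `genes`
#'   (annotation data.frame), `housekeeping_ids`, `responsive_ids`.
#' @export
simulate_expression <- function(truth, causal, n_settings = 5L,
                                prop_de_in_causal = 0.8, housekeeping_n = 50L,
                                n_genes = 500L, window_bp = 5e5, seed = 1L) {
  if (n_settings < 3L) stop("n_settings must be >= 3 (the aggregation rule needs >= 3 settings)")
  if (prop_de_in_causal < 0 || prop_de_in_causal > 1) stop("prop_de_in_causal outside [0,1]")
  set.seed(seed + 2000L)
  chroms <- truth$chromosomes
  ci <- sample.int(nrow(chroms), n_genes, replace = TRUE, prob = chroms$length_bp)
  start <- floor(stats::runif(n_genes, 1, chroms$length_bp[ci] - 3000))
  genes <- data.frame(gene_id = sprintf("GENE%04d", seq_len(n_genes)),
                      chrom = chroms$name[ci], start_bp = as.integer(start),
                      end_bp = as.integer(start + 2999), strand = "+",
                      stringsAsFactors = FALSE)
  near_causal <- rep(FALSE, n_genes)
  for (k in seq_len(nrow(causal))) {
    near_causal <- near_causal | (genes$chrom == causal$chrom[k] &
      abs((genes$start_bp + genes$end_bp) / 2 - causal$pos_bp[k]) <= window_bp)
  }
  responsive <- near_causal & stats::runif(n_genes) < prop_de_in_causal
  hk_pool <- which(!near_causal)
  housekeeping <- genes$gene_id[sample(hk_pool, min(housekeeping_n, length(hk_pool)))]
  sign_g <- sample(c(-1, 1), n_genes, replace = TRUE)
  platform <- rep(c("microarray", "rnaseq"), length.out = n_settings)
  tables <- vector("list", n_settings)
  for (s in seq_len(n_settings)) {
    bg_sd <- if (platform[s] == "microarray") 0.15 else 0.6
    de_mag <- if (platform[s] == "microarray") 1 else 3
    lfc <- stats::rnorm(n_genes, 0, bg_sd)
    lfc[responsive] <- sign_g[responsive] * (de_mag + stats::rnorm(sum(responsive), 0, 0.2))
    lfc[genes$gene_id %in% housekeeping] <-
      stats::rnorm(sum(genes$gene_id %in% housekeeping), 0, 0.1)
    p <- 2 * stats::pnorm(-abs(lfc) / bg_sd)
    tables[[s]] <- data.frame(setting_id = sprintf("setting%02d", s),
                              platform_class = platform[s],
                              gene_id = genes$gene_id, log2fc = lfc, pvalue = p,
                              stringsAsFactors = FALSE)
  }
  list(tables = do.call(rbind, tables), genes = genes,
       housekeeping_ids = housekeeping, responsive_ids = genes$gene_id[responsive])
}

#' Write a gene annotation as GFF3
#' @param genes data.frame(gene_id, chrom, start_bp, end_bp, strand).
#' @param path output path.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(genes)) {
    strand <- ifelse(genes$strand %in% c("+", "-"), genes$strand, ".")
    writeLines(sprintf("%s\tcsslqtl\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       genes$chrom, genes$start_bp, genes$end_bp, strand,
                       genes$gene_id), con)
  }
  invisible(NULL)
}
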