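TRAIT_GROUPS <- c("salt_injury_score", "tolerant_phenotype", "physiological_trait")
TOLERANCE_DIRECTIONS <- c("higher_better", "lower_better", "unknown")

#' Construct a validated genotype matrix
#'
#' Internal container for CSSL donor-allele indicator genotypes: a marker map
#' (marker id, chromosome, 1-based physical position) plus a lines x markers
#' matrix of calls in \{0, 1, NA\}, where 1 marks the donor-parent allele and
#' 0 the recurrent-parent allele.
#'
#' @param map data.frame with columns `marker_id`, `chrom`, `pos_bp`.
#' @param calls numeric matrix, lines in rows, markers in columns; values in
#'   \{0, 1, NA\}. Column names must equal `map$marker_id`.
#' @return An object of class `"geno_matrix"`: a list with elements `map` and
#'   `calls`, markers sorted by (chromosome, position).
#' @export
geno_matrix <- function(map, calls) {
  stopifnot(is.data.frame(map), all(c("marker_id", "chrom", "pos_bp") %in% names(map)))
  map$marker_id <- as.character(map$marker_id)
  map$chrom <- as.character(map$chrom)
  map$pos_bp <- as.integer(map$pos_bp)
  if (anyDuplicated(map$marker_id))
    stop("duplicate marker ids: ", paste(unique(map$marker_id[duplicated(map$marker_id)]), collapse = ", "))
  if (any(map$pos_bp <= 0L, na.rm = TRUE)) stop("marker positions must be positive (1-based)")
  calls <- as.matrix(calls)
  if (is.null(rownames(calls))) stop("calls matrix needs line ids as rownames")
  if (nrow(calls) < 2L) stop("need at least 2 lines")
  if (ncol(calls) != nrow(map)) stop("calls has ", ncol(calls), " columns but map has ", nrow(map), " markers")
  if (is.null(colnames(calls))) colnames(calls) <- map$marker_id
  bad <- !(calls %in% c(0, 1) | is.na(calls))
  if (any(bad)) {
    idx <- which(matrix(bad, nrow(calls)), arr.ind = TRUE)[1L, ]
    stop("genotype call not in {0,1,NA} for line '", rownames(calls)[idx[1L]],
         "', marker '", colnames(calls)[idx[2L]], "'")
  }
  ord <- order(map$chrom, map$pos_bp)
  map <- map[ord, , drop = FALSE]
  rownames(map) <- NULL
  calls <- calls[, map$marker_id, drop = FALSE]
  structure(list(map = map, calls = calls), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("CSSL genotype matrix: ", nrow(x$calls), " lines x ", ncol(x$calls),
      " markers on ", length(unique(x$map$chrom)), " chromosome(s)\n", sep = "")
  cat("donor-allele frequency range: ",
      paste(signif(range(colMeans(x$calls, na.rm = TRUE)), 3), collapse = " - "), "\n", sep = "")
  invisible(x)
}

#' Construct a validated trait table
#'
#' @param values numeric matrix, lines x traits, missing allowed.
#' @param meta data.frame with columns `trait_id`, `group` (one of
#'   `salt_injury_score`, `tolerant_phenotype`, `physiological_trait`),
#'   `experiment_id`, `tolerance_direction`.
#' @return Object of class `"trait_table"`: list with `values`, `meta` and a
#'   logical `scannable` flag per trait (>= 5 non-missing values).
#' @export
trait_table <- function(values, meta) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("trait values need line ids as rownames")
  stopifnot(is.data.frame(meta), all(c("trait_id", "group") %in% names(meta)))
  meta$trait_id <- as.character(meta$trait_id)
  if (anyDuplicated(meta$trait_id)) stop("duplicate trait ids")
  if (!"experiment_id" %in% names(meta)) meta$experiment_id <- NA_character_
  meta$experiment_id <- as.character(meta$experiment_id)
  if (!"tolerance_direction" %in% names(meta)) meta$tolerance_direction <- "unknown"
  meta$tolerance_direction <- as.character(meta$tolerance_direction)
  bad_grp <- setdiff(unique(meta$group), TRAIT_GROUPS)
  if (length(bad_grp))
    stop("unknown trait group(s) ", paste(sQuote(bad_grp), collapse = ", "),
         "; allowed: ", paste(TRAIT_GROUPS, collapse = ", "))
  bad_dir <- setdiff(unique(meta$tolerance_direction), TOLERANCE_DIRECTIONS)
  if (length(bad_dir)) stop("unknown tolerance_direction(s): ", paste(bad_dir, collapse = ", "))
  missing_meta <- setdiff(colnames(values), meta$trait_id)
  if (length(missing_meta)) stop("traits without metadata: ", paste(missing_meta, collapse = ", "))
  meta <- meta[match(colnames(values), meta$trait_id), , drop = FALSE]
  rownames(meta) <- NULL
  scannable <- colSums(!is.na(values)) >= 5L
  structure(list(values = values, meta = meta, scannable = scannable),
            class = "trait_table")
}

#' @export
print.trait_table <- function(x, ...) {
  cat("Trait table: ", nrow(x$values), " lines x ", ncol(x$values), " traits (",
      sum(x$scannable), " scannable)\n", sep = "")
  print(table(group = x$meta$group))
  invisible(x)
}

#' Read a donor-allele genotype TSV
#'
#' Expected columns: `marker_id`, `chrom`, `pos_bp`, then one column per CSSL
#' line with cells in \{0, 1, NA\}.
#'
#' @param path path to a tab-separated file.
#' @return A [geno_matrix()].
#' @export
read_genotypes_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                         na.strings = "NA")
  if (ncol(d) < 5L) stop("genotype TSV needs marker_id, chrom, pos_bp and at least 2 line columns")
  line_cols <- names(d)[-(1:3)]
  for (j in line_cols) {
    v <- d[[j]]
    bad <- which(!(is.na(v) | v %in% c(0, 1)))
    if (length(bad))
      stop("invalid genotype cell at row ", bad[1L], ", column '", j, "': ", v[bad[1L]])
  }
  calls <- t(as.matrix(d[line_cols]))
  colnames(calls) <- as.character(d[[1L]])
  geno_matrix(data.frame(marker_id = d[[1L]], chrom = d[[2L]], pos_bp = d[[3L]],
                         stringsAsFactors = FALSE), calls)
}

#' Write a genotype matrix to TSV
#'
#' Inverse of [read_genotypes_tsv()]; the roundtrip is lossless.
#' @param geno a [geno_matrix()].
#' @param path output path.
#' @export
write_genotypes_tsv <- function(geno, path) {
  d <- cbind(geno$map, as.data.frame(t(geno$calls), check.names = FALSE))
  names(d)[1:3] <- c("marker_id", "chrom", "pos_bp")
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Read CSSL genotypes from a VCF with explicit parent samples
#'
#' Each biallelic site is recoded against the two homozygous parents: a CSSL
#' call is 1 if its genotype equals the donor parent's, 0 if it equals the
#' recurrent parent's, and missing otherwise (heterozygotes are unresolvable
#' under the homozygous-line model). Sites where the parents agree are
#' uninformative and dropped; multiallelic records are skipped.
#'
#' @param path VCF path (plain or bgzipped).
#' @param donor_sample,recurrent_sample sample names of the two parents.
#' @return A [geno_matrix()] over the non-parent samples, with attribute
#'   `"dropped"` = c(uninformative = , multiallelic = ) counters.
#' @export
read_genotypes_vcf <- function(path, donor_sample, recurrent_sample) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  if (!donor_sample %in% samples) stop("donor sample '", donor_sample, "' not in VCF")
  if (!recurrent_sample %in% samples) stop("recurrent sample '", recurrent_sample, "' not in VCF")
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  norm_gt <- function(g) {
    g <- sub(":.*", "", g)
    gsub("|", "/", g, fixed = TRUE)
  }
  gt <- apply(gt, 2, norm_gt)
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, samples))
  don <- gt[, donor_sample]
  rec <- gt[, recurrent_sample]
  hom <- function(g) g %in% c("0/0", "1/1")
  informative <- !multi & hom(don) & hom(rec) & don != rec
  n_unif <- sum(!multi & (!hom(don) | !hom(rec) | don == rec), na.rm = TRUE)
  if (any(multi)) warning(sum(multi), " multiallelic record(s) skipped")
  cssl <- setdiff(samples, c(donor_sample, recurrent_sample))
  gtk <- gt[informative, cssl, drop = FALSE]
  calls <- matrix(NA_real_, nrow = length(cssl), ncol = nrow(gtk),
                  dimnames = list(cssl, NULL))
  for (i in seq_len(nrow(gtk))) {
    calls[gtk[i, ] == don[informative][i], i] <- 1
    calls[gtk[i, ] == rec[informative][i], i] <- 0
  }
  map <- data.frame(marker_id = paste0(fix[informative, "CHROM"], "_", fix[informative, "POS"]),
                    chrom = fix[informative, "CHROM"],
                    pos_bp = as.integer(fix[informative, "POS"]),
                    stringsAsFactors = FALSE)
  colnames(calls) <- map$marker_id
  out <- geno_matrix(map, calls)
  attr(out, "dropped") <- c(uninformative = n_unif, multiallelic = sum(multi))
  out
}

#' Read phenotype values and trait metadata TSVs
#'
#' @param values_path TSV: first column line id, remaining columns one per trait.
#' @param metadata_path TSV with columns trait_id, group, experiment_id,
#'   tolerance_direction.
#' @return A [trait_table()].
#' @export
read_traits_tsv <- function(values_path, metadata_path) {
  vals <- utils::read.delim(values_path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  m <- as.matrix(vals[, -1L, drop = FALSE])
  rownames(m) <- as.character(vals[[1L]])
  trait_table(m, meta)
}

#' Write a trait table to value and metadata TSVs
#' @param traits a [trait_table()].
#' @param values_path,metadata_path output paths.
#' @export
write_traits_tsv <- function(traits, values_path, metadata_path) {
  d <- data.frame(line_id = rownames(traits$values),
                  as.data.frame(traits$values, check.names = FALSE),
                  check.names = FALSE)
  utils::write.table(d, values_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(traits$meta, metadata_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Align genotype and trait tables on their common lines
#'
#' The studies feeding a comparative scan usually phenotype different CSSL
#' subsets; the intersection is used and discarded ids are reported in a
#' warning.
#'
#' @param geno a [geno_matrix()].
#' @param traits a [trait_table()].
#' @return list(geno, traits) restricted to the shared, identically ordered lines.
#' @export
align_lines <- function(geno, traits) {
  common <- intersect(rownames(geno$calls), rownames(traits$values))
  if (length(common) < 2L) stop("fewer than 2 shared line ids between genotypes and traits")
  dropped <- setdiff(union(rownames(geno$calls), rownames(traits$values)), common)
  if (length(dropped))
    warning("line ids dropped by intersection: ", paste(dropped, collapse = ", "))
  geno$calls <- geno$calls[common, , drop = FALSE]
  traits$values <- traits$values[common, , drop = FALSE]
  traits$scannable <- colSums(!is.na(traits$values)) >= 5L
  list(geno = geno, traits = traits)
}

#' Read a benchmark set of known salinity-related markers or intervals
#'
#' @param path TSV with either a `marker_id` column or `chrom`, `start_bp`,
#'   `end_bp` columns (1-based inclusive). Both kinds may be mixed across rows.
#' @return list with character `marker_ids` and data.frame `intervals`.
#' @export
read_benchmark_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  marker_ids <- character(0)
  intervals <- data.frame(chrom = character(0), start_bp = integer(0), end_bp = integer(0))
  if ("marker_id" %in% names(d)) marker_ids <- unique(stats::na.omit(as.character(d$marker_id)))
  if (all(c("chrom", "start_bp", "end_bp") %in% names(d))) {
    intervals <- d[!is.na(d$chrom), c("chrom", "start_bp", "end_bp"), drop = FALSE]
    if (any(intervals$start_bp > intervals$end_bp)) stop("benchmark interval with start > end")
  }
  if (!length(marker_ids) && !nrow(intervals))
    stop("benchmark file has neither marker_id nor chrom/start_bp/end_bp columns")
  structure(list(marker_ids = marker_ids, intervals = intervals), class = "benchmark_set")
}

#' Read gene records from a GFF3 annotation
#'
#' Only features of type `gene` are kept; the `ID` attribute is required and
#' must be unique. Coordinates stay 1-based inclusive.
#'
#' @param path GFF3 path.
#' @return data.frame with gene_id, chrom, start_bp, end_bp, strand.
#' @export
read_gff3 <- function(path) {
  g <- ape::read.gff(path)
  g <- g[g$type == "gene", , drop = FALSE]
  if (!nrow(g)) {
    warning("no 'gene' features in ", path)
    return(data.frame(gene_id = character(0), chrom = character(0),
                      start_bp = integer(0), end_bp = integer(0), strand = character(0)))
  }
  ids <- sub(".*ID=([^;]+).*", "\\1", g$attributes)
  no_id <- !grepl("ID=", g$attributes)
  if (any(no_id)) stop("gene feature without ID attribute at line(s) ", which(no_id)[1L])
  if (anyDuplicated(ids)) stop("duplicated gene ID: ", ids[duplicated(ids)][1L])
  if (any(g$end < g$start)) stop("gene feature with end < start")
  strand <- as.character(g$strand)
  strand[!strand %in% c("+", "-")] <- "unknown"
  data.frame(gene_id = ids, chrom = as.character(g$seqid),
             start_bp = as.integer(g$start), end_bp = as.integer(g$end),
             strand = strand, stringsAsFactors = FALSE)
}

#' Read a directory or files of differential-expression tables
#'
#' Each table has columns `setting_id`, `platform_class` (`microarray` or
#' `rnaseq`), `gene_id`, `log2fc`, `pvalue`.
#'
#' @param paths character vector of TSV paths.
#' @return one data.frame with the five columns, validated.
#' @export
read_de_tables <- function(paths) {
  d <- do.call(rbind, lapply(paths, utils::read.delim, stringsAsFactors = FALSE))
  need <- c("setting_id", "platform_class", "gene_id", "log2fc", "pvalue")
  if (!all(need %in% names(d))) stop("DE tables need columns: ", paste(need, collapse = ", "))
  if (any(d$pvalue < 0 | d$pvalue > 1, na.rm = TRUE)) stop("p-values outside [0,1]")
  bad <- setdiff(unique(d$platform_class), c("microarray", "rnaseq"))
  if (length(bad)) stop("unknown platform_class: ", paste(bad, collapse = ", "))
  if (anyDuplicated(d[c("setting_id", "gene_id")])) stop("duplicated gene within a setting")
  d
}

#' Write QTL regions to annotated TSV and BED6
#'
#' The TSV keeps 1-based inclusive coordinates and the full annotation; the
#' BED6 uses 0-based half-open coordinates, the region id as name, and
#' `min(1000, round(10 * mean PR of member SNPs))` as score.
#'
#' @param regions data.frame as returned by [call_regions()].
#' @param tsv_path,bed_path output paths; either may be `NULL` to skip.
#' @export
write_regions <- function(regions, tsv_path = NULL, bed_path = NULL) {
  if (!is.null(tsv_path)) {
    out <- regions
    out$markers <- vapply(out$markers, paste, "", collapse = ",")
    out$traits <- vapply(out$traits, paste, "", collapse = ",")
    out$trait_groups_hit <- vapply(out$trait_groups_hit, paste, "", collapse = ",")
    utils::write.table(out, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(bed_path)) {
    if (nrow(regions)) {
      bed <- data.frame(chrom = regions$chrom,
                        start = regions$start_bp - 1L,      # 0-based half-open
                        end = regions$end_bp,
                        name = regions$region_id,
                        score = pmin(1000, round(10 * regions$mean_pr)),
                        strand = ".")
    } else {
      bed <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                        name = character(0), score = numeric(0), strand = character(0))
    }
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(NULL)
}
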