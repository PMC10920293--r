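#' Derive a fold-change cutoff from housekeeping genes
#'
#' Housekeeping genes are stably expressed, so their average absolute log2
#' fold change under stress calibrates what "no meaningful change" looks
#' like on a platform; the cutoff is the mean of |log2FC| over all
#' housekeeping-gene records across the settings of one platform class.
#'
#' @param de DE table (see [read_de_tables()]).
#' @param housekeeping_ids character vector of housekeeping gene ids.
#' @param platform_class `"microarray"` or `"rnaseq"`.
#' @return nonnegative scalar cutoff.
#' @export
derive_fc_cutoff <- function(de, housekeeping_ids, platform_class) {
  d <- de[de$platform_class == platform_class & de$gene_id %in% housekeeping_ids, ]
  if (!nrow(d))
    stop("no housekeeping gene found in any '", platform_class,
         "' setting; supply an explicit fc_cutoff")
  mean(abs(d$log2fc), na.rm = TRUE)
}

#' Call differentially expressed genes in one experimental setting
#'
#' A gene is a DEG when `p < p_cutoff` (strict) and `|log2FC| >= fc_cutoff`
#' (inclusive).
#'
#' @param de_setting rows of a DE table for one setting.
#' @param p_cutoff p-value cutoff (default 0.05).
#' @param fc_cutoff nonnegative |log2FC| cutoff (e.g. 0.2 for microarray,
#'   2 for RNA-seq, or a housekeeping-derived value).
#' @return character vector of DEG gene ids.
#' @export
call_degs <- function(de_setting, p_cutoff = 0.05, fc_cutoff) {
  if (fc_cutoff < 0) stop("fc_cutoff must be nonnegative")
  hit <- !is.na(de_setting$pvalue) & de_setting$pvalue < p_cutoff &
    abs(de_setting$log2fc) >= fc_cutoff
  unique(de_setting$gene_id[hit])
}

#' Aggregate DEG calls across independent experimental settings
#'
#' A gene is a robust DEG when it passes the cutoffs in at least
#' `min_settings` settings.
#'
#' @param deg_sets named list (by setting_id) of DEG id vectors.
#' @param min_settings minimum settings (default 3).
#' @return data.frame of class `"expression_evidence"`: gene_id,
#'   n_settings_deg, robust.
#' @export
aggregate_degs <- function(deg_sets, min_settings = 3L) {
  if (length(deg_sets) < min_settings)
    stop("need at least min_settings = ", min_settings, " settings, got ", length(deg_sets))
  counts <- table(unlist(lapply(deg_sets, unique)))
  out <- data.frame(gene_id = as.character(names(counts)),
                    n_settings_deg = as.integer(counts),
                    robust = as.integer(counts) >= min_settings,
                    stringsAsFactors = FALSE)
  if (!nrow(out))
    out <- data.frame(gene_id = character(0), n_settings_deg = integer(0),
                      robust = logical(0))
  structure(out[order(-out$n_settings_deg, out$gene_id), ],
            min_settings = min_settings,
            class = c("expression_evidence", "data.frame"))
}

#' Run the full DEG aggregation over a DE table
#'
#' Splits the table by setting, derives (or takes) per-platform fold-change
#' cutoffs, calls DEGs per setting, and aggregates.
#'
#' @param de DE table (see [read_de_tables()]).
#' @param housekeeping_ids housekeeping gene ids for cutoff derivation;
#'   ignored for a platform whose explicit cutoff is supplied.
#' @param p_cutoff p-value cutoff.
#' @param fc_cutoffs optional named numeric, e.g.
#'   `c(microarray = 0.2, rnaseq = 2)`; platforms missing from it get the
#'   housekeeping-derived cutoff.
#' @param min_settings robustness requirement.
#' @return list: `evidence` (see [aggregate_degs()]), `deg_sets`,
#'   `fc_cutoffs` actually used.
#' @export
expression_evidence <- function(de, housekeeping_ids = NULL, p_cutoff = 0.05,
                                fc_cutoffs = NULL, min_settings = 3L) {
  platforms <- unique(de$platform_class)
  cuts <- stats::setNames(numeric(length(platforms)), platforms)
  for (pl in platforms) {
    cuts[pl] <- if (!is.null(fc_cutoffs) && pl %in% names(fc_cutoffs))
      fc_cutoffs[[pl]] else derive_fc_cutoff(de, housekeeping_ids, pl)
  }
  settings <- split(de, de$setting_id)
  deg_sets <- lapply(settings, function(d)
    call_degs(d, p_cutoff, cuts[[d$platform_class[1L]]]))
  list(evidence = aggregate_degs(deg_sets, min_settings),
       deg_sets = deg_sets, fc_cutoffs = cuts)
}

#' Refine region candidate genes by expression evidence
#'
#' Intersects region candidates with robust DEGs; candidates absent from all
#' expression tables are reported separately rather than silently dropped.
#'
#' @param candidates character vector of candidate gene ids (e.g. from
#'   [map_regions_to_genes()], unlisted).
#' @param evidence `"expression_evidence"` data.frame from
#'   [aggregate_degs()].
#' @param all_measured_ids optional character vector of every gene id with
#'   any expression record; defaults to the evidence table's genes (which
#'   only contains genes that were a DEG somewhere).
#' @return list: `refined`, `not_robust`, `no_expression_data`.
#' @export
refine_candidates <- function(candidates, evidence, all_measured_ids = NULL) {
  candidates <- unique(candidates)
  if (is.null(all_measured_ids)) all_measured_ids <- evidence$gene_id
  measured <- intersect(candidates, all_measured_ids)
  robust <- evidence$gene_id[evidence$robust]
  list(refined = intersect(measured, robust),
       not_robust = setdiff(measured, robust),
       no_expression_data = setdiff(candidates, all_measured_ids))
}
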