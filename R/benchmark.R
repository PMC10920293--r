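#' Resolve a benchmark set to marker ids
#'
#' Interval entries match every marker they contain; explicit marker ids are
#' kept as given (intersected with the map).
#'
#' @param benchmark a benchmark set from [read_benchmark_tsv()] (or a list
#'   with `marker_ids` / `intervals`).
#' @param map marker map data.frame.
#' @return character vector of benchmark marker ids present in the map.
#' @export
resolve_benchmark <- function(benchmark, map) {
  ids <- intersect(benchmark$marker_ids, map$marker_id)
  iv <- benchmark$intervals
  if (!is.null(iv) && nrow(iv)) {
    for (k in seq_len(nrow(iv))) {
      hit <- map$chrom == iv$chrom[k] & map$pos_bp >= iv$start_bp[k] &
        map$pos_bp <= iv$end_bp[k]
      ids <- union(ids, map$marker_id[hit])
    }
  }
  ids
}

#' Evaluate high-confidence calls against a benchmark marker set
#'
#' A benchmark marker counts as recovered when it is high-confidence for at
#' least one trait. The confusion matrix is taken over the filtered
#' (informative) marker universe of the consensus table. Sensitivity is
#' TP/(TP+FN); selectivity is implemented as specificity TN/(TN+FP), and
#' precision TP/(TP+FP) is emitted as well so either reading of
#' "selectivity" is recoverable.
#'
#' @param ctab a [consensus_table()].
#' @param benchmark benchmark set (see [read_benchmark_tsv()]).
#' @param map marker map data.frame.
#' @return one-row data.frame: sensitivity, selectivity, precision, tp, fp,
#'   tn, fn, n_predicted, n_benchmark_recovered, n_universe.
#' @export
evaluate_against_benchmark <- function(ctab, benchmark, map) {
  universe <- unique(ctab$marker_id)
  bench <- intersect(resolve_benchmark(benchmark, map), universe)
  if (!length(bench)) stop("benchmark set resolves to no marker in the tested universe")
  predicted <- unique(ctab$marker_id[ctab$high_confidence])
  tp <- length(intersect(predicted, bench))
  fp <- length(setdiff(predicted, bench))
  fn <- length(setdiff(bench, predicted))
  tn <- length(universe) - tp - fp - fn
  data.frame(sensitivity = tp / (tp + fn),
             selectivity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
             precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
             tp = tp, fp = fp, tn = tn, fn = fn,
             n_predicted = length(predicted), n_benchmark_recovered = tp,
             n_universe = length(universe))
}

#' Sensitivity/selectivity sweep over the filter and PR cutoffs
#'
#' Full-factorial evaluation over grids of the informativeness filter
#' (`min_lines`) and percentile cutoff (`pr_cutoff`); the suggested cutoff is
#' the grid point where the sensitivity and selectivity curves come closest
#' to crossing (argmin |sensitivity - selectivity|).
#'
#' @param scans nested scan list from [scan_all()].
#' @param geno the [geno_matrix()].
#' @param benchmark benchmark set.
#' @param min_lines_grid,pr_grid numeric grids.
#' @param min_methods consensus vote requirement.
#' @return data.frame of class `"cutoff_sweep"`, one row per combination,
#'   with attribute `"crossing"` = the suggested (min_lines, pr_cutoff) row.
#' @export
sweep_cutoffs <- function(scans, geno, benchmark, min_lines_grid = 2:10,
                          pr_grid = seq(50, 95, 5), min_methods = 2L) {
  if (!length(min_lines_grid) || !length(pr_grid)) stop("empty sweep grid")
  rows <- list()
  for (ml in min_lines_grid) for (pc in pr_grid) {
    ct <- consensus_table(scans, geno, min_lines = ml, pr_cutoff = pc,
                          min_methods = min_methods)
    ev <- evaluate_against_benchmark(ct, benchmark, geno$map)
    rows[[length(rows) + 1L]] <- cbind(data.frame(min_lines = ml, pr_cutoff = pc,
                                                  min_methods = min_methods), ev)
  }
  out <- do.call(rbind, rows)
  cross <- out[which.min(abs(out$sensitivity - out$selectivity)), , drop = FALSE]
  structure(out, crossing = cross, class = c("cutoff_sweep", class(out)))
}

#' Planted-locus recovery and region-level false discovery
#'
#' Simulator-side validation: a planted (trait, locus) pair is recovered when
#' the causal marker lies inside some called region linked to that trait; a
#' region is a false discovery when it contains no causal marker of any of
#' its linked traits.
#'
#' @param regions classified regions from [call_regions()].
#' @param causal causal-locus data.frame from [simulate_traits()]
#'   (`trait_id`, `chrom`, `pos_bp`, `marker_id`).
#' @param map marker map data.frame.
#' @return list: `recovery` (rate over planted trait-locus pairs), `fdp`
#'   (region-level false-discovery proportion), `n_regions`, and the
#'   per-pair logical `recovered`.
#' @export
evaluate_recovery <- function(regions, causal, map) {
  if (!nrow(causal)) stop("no planted loci to evaluate")
  cpos <- map$pos_bp[match(causal$marker_id, map$marker_id)]
  recovered <- vapply(seq_len(nrow(causal)), function(k) {
    any(regions$chrom == causal$chrom[k] &
          regions$start_bp <= cpos[k] & regions$end_bp >= cpos[k] &
          vapply(regions$traits, function(tr) causal$trait_id[k] %in% tr, TRUE))
  }, TRUE)
  false_region <- vapply(seq_len(nrow(regions)), function(i) {
    linked <- causal$trait_id %in% regions$traits[[i]]
    !any(linked & causal$chrom == regions$chrom[i] &
           cpos >= regions$start_bp[i] & cpos <= regions$end_bp[i])
  }, TRUE)
  list(recovery = mean(recovered),
       fdp = if (nrow(regions)) mean(false_region) else NA_real_,
       n_regions = nrow(regions), recovered = recovered)
}
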