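#' Informativeness filter for CSSL markers
#'
#' Markers whose donor allele is carried by fewer than `min_lines` CSSLs are
#' considered uninformative and excluded before percentile-rank
#' normalization. Markers whose recurrent-allele group has fewer than two
#' lines are also excluded, since no contrast is possible.
#'
#' @param geno a [geno_matrix()].
#' @param min_lines minimum donor-allele carriers (default 5, the cutoff at
#'   which between-method agreement and benchmark sensitivity/selectivity
#'   intersect in the reference analysis).
#' @return character vector of retained marker ids.
#' @export
filter_informative <- function(geno, min_lines = 5L) {
  if (min_lines < 1L) stop("min_lines must be >= 1")
  donor <- colSums(geno$calls == 1, na.rm = TRUE)
  recur <- colSums(geno$calls == 0, na.rm = TRUE)
  keep <- donor >= min_lines & recur >= 2L
  if (!any(keep)) warning("no marker passes the informativeness filter")
  colnames(geno$calls)[keep]
}

#' Percentile-rank normalization of raw confidence scores
#'
#' Maps heterogeneous scan scores (LOD, -log10 p) onto a common 0-100 scale:
#' `PR(s_i) = 100 * rank(s_i) / N` with average ranks for ties, computed
#' within one trait x method score vector. Missing scores stay missing and do
#' not enter N. PR is invariant under any strictly increasing transform of
#' the scores.
#'
#' @param scores numeric vector of raw scores for one trait x method.
#' @return numeric vector of percentile ranks in (0, 100].
#' @export
percentile_rank <- function(scores) {
  fin <- !is.na(scores)
  n <- sum(fin)
  if (n < 2L) stop("need at least 2 finite scores to rank")
  out <- rep(NA_real_, length(scores))
  if (length(unique(scores[fin])) == 1L)
    warning("all scores identical; percentile ranks are degenerate")
  out[fin] <- 100 * rank(scores[fin], ties.method = "average") / n
  out
}

#' Consensus vote across scan methods for one trait
#'
#' A marker passes a method when its percentile rank strictly exceeds
#' `pr_cutoff`; markers passing in at least `min_methods` methods are
#' high-confidence. The tier records whether two or all three methods agree.
#'
#' @param pr list of named PR vectors (one per method, aligned on the same
#'   marker set; names are marker ids). At least 2 methods required.
#' @param pr_cutoff strict percentile cutoff (default 80).
#' @param min_methods votes needed for high confidence (default 2).
#' @return data.frame: marker_id, one `pr_<method>` column per method,
#'   `votes`, `tier`, `high_confidence`.
#' @export
consensus_vote <- function(pr, pr_cutoff = 80, min_methods = 2L) {
  if (length(pr) < 2L) stop("consensus vote needs at least 2 methods")
  if (pr_cutoff <= 0 || pr_cutoff >= 100) stop("pr_cutoff must be in (0,100)")
  if (!min_methods %in% 1:3) stop("min_methods must be 1, 2 or 3")
  ids <- names(pr[[1L]])
  if (!all(vapply(pr, function(v) identical(names(v), ids), TRUE)))
    stop("methods do not share one marker set")
  prm <- do.call(cbind, pr)
  pass <- !is.na(prm) & prm > pr_cutoff
  votes <- rowSums(pass)
  tier <- ifelse(votes >= 3, "all_methods", ifelse(votes == 2, "two_methods", "none"))
  out <- data.frame(marker_id = ids, prm, votes = votes, tier = tier,
                    high_confidence = votes >= min_methods,
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out)[1L + seq_along(pr)] <- paste0("pr_", names(pr))
  out
}

#' Build the full consensus table from raw scans
#'
#' Applies the informativeness filter, percentile-rank normalizes each
#' trait x method score vector across the filtered markers, and votes.
#'
#' @param scans nested list from [scan_all()].
#' @param geno the [geno_matrix()] the scans were computed on.
#' @param min_lines informativeness filter (donor carriers).
#' @param pr_cutoff,min_methods see [consensus_vote()].
#' @return `"consensus_table"` data.frame: trait_id, marker_id, chrom,
#'   pos_bp, pr_* columns, votes, tier, high_confidence, carriers, mean_pr.
#' @export
consensus_table <- function(scans, geno, min_lines = 5L, pr_cutoff = 80,
                            min_methods = 2L) {
  keep <- filter_informative(geno, min_lines)
  map <- geno$map[match(keep, geno$map$marker_id), ]
  carriers <- colSums(geno$calls[, keep, drop = FALSE] == 1, na.rm = TRUE)
  out <- lapply(names(scans), function(tr) {
    pr <- lapply(scans[[tr]], function(s) {
      sc <- s$score[match(keep, s$marker_id)]
      v <- percentile_rank(sc)
      names(v) <- keep
      v
    })
    cv <- consensus_vote(pr, pr_cutoff = pr_cutoff, min_methods = min_methods)
    prcols <- grep("^pr_", names(cv))
    cv$mean_pr <- rowMeans(cv[prcols], na.rm = TRUE)
    cv$mean_pr[is.nan(cv$mean_pr)] <- NA_real_
    cbind(data.frame(trait_id = tr, stringsAsFactors = FALSE),
          cv["marker_id"], map[c("chrom", "pos_bp")],
          cv[c(names(cv)[prcols], "votes", "tier", "high_confidence", "mean_pr")],
          data.frame(carriers = unname(carriers)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, pr_cutoff = pr_cutoff, min_methods = min_methods,
            min_lines = min_lines, class = c("consensus_table", class(res)))
}

#' Per-trait scalar marker confidence
#'
#' The across-method mean of the available percentile ranks per marker; the
#' per-trait vector used for QTL-confidence-based trait correlations.
#'
#' @param ctab a [consensus_table()].
#' @param trait_id trait to extract.
#' @return named numeric vector over the filtered markers.
#' @export
aggregate_trait_score <- function(ctab, trait_id) {
  d <- ctab[ctab$trait_id == trait_id, , drop = FALSE]
  if (!nrow(d)) stop("trait '", trait_id, "' not in consensus table")
  stats::setNames(d$mean_pr, d$marker_id)
}
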