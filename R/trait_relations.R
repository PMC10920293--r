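spearman_matrix <- function(X, basis) {
  n_tr <- ncol(X)
  rho <- matrix(NA_real_, n_tr, n_tr, dimnames = list(colnames(X), colnames(X)))
  p <- rho
  n <- matrix(0L, n_tr, n_tr, dimnames = dimnames(rho))
  for (i in seq_len(n_tr)) for (j in i:n_tr) {
    cc <- !is.na(X[, i]) & !is.na(X[, j])
    n[i, j] <- n[j, i] <- sum(cc)
    if (n[i, j] < 3L) next
    r <- stats::cor(X[cc, i], X[cc, j], method = "spearman")
    rho[i, j] <- rho[j, i] <- r
    if (i == j) { p[i, j] <- 0; next }
    # two-sided p via the t-approximation
    if (abs(r) >= 1) { p[i, j] <- p[j, i] <- 0 } else {
      tstat <- r * sqrt((n[i, j] - 2) / (1 - r^2))
      p[i, j] <- p[j, i] <- 2 * stats::pt(-abs(tstat), df = n[i, j] - 2)
    }
  }
  diag(rho) <- 1
  structure(list(rho = rho, p = p, n = n, basis = basis), class = "cor_matrix")
}

#' @export
print.cor_matrix <- function(x, ...) {
  cat("Spearman trait correlation matrix (", x$basis, "): ",
      nrow(x$rho), " traits\n", sep = "")
  print(round(x$rho, 3))
  invisible(x)
}

#' Trait-trait Spearman correlations of phenotype scores
#'
#' Pairwise-complete Spearman correlations of trait values across lines,
#' with two-sided p-values from the t-approximation. Traits with fewer than
#' 3 values are excluded with a warning; pairs with fewer than 3 complete
#' observations are reported missing.
#'
#' @param traits a [trait_table()].
#' @return object of class `"cor_matrix"`: list(rho, p, n, basis =
#'   "phenotype_scores").
#' @export
trait_correlation_phenotype <- function(traits) {
  X <- traits$values
  ok <- colSums(!is.na(X)) >= 3L
  if (any(!ok)) warning("trait(s) with < 3 values excluded: ",
                        paste(colnames(X)[!ok], collapse = ", "))
  X <- X[, ok, drop = FALSE]
  if (ncol(X) < 2L) stop("need at least 2 usable traits")
  spearman_matrix(X, "phenotype_scores")
}

#' Trait-trait Spearman correlations of QTL-confidence scores
#'
#' The same correlation analysis on the genetic side: per trait, the
#' across-method mean percentile-rank vector over the filtered markers (see
#' [aggregate_trait_score()]); correlations are computed across markers.
#' Together with [trait_correlation_phenotype()] this exposes discordant
#' trait pairs -- phenotypically correlated traits mapping to different loci
#' and vice versa.
#'
#' @param ctab a [consensus_table()].
#' @return object of class `"cor_matrix"` with basis
#'   `"qtl_confidence_scores"`.
#' @export
trait_correlation_qtl <- function(ctab) {
  traits <- unique(ctab$trait_id)
  markers <- unique(ctab$marker_id)
  X <- vapply(traits, function(tr) {
    v <- aggregate_trait_score(ctab, tr)
    v[markers]
  }, numeric(length(markers)))
  rownames(X) <- markers
  ok <- colSums(!is.na(X)) >= 3L
  X <- X[, ok, drop = FALSE]
  if (ncol(X) < 2L) stop("need at least 2 traits with scanned markers")
  spearman_matrix(X, "qtl_confidence_scores")
}

#' Hierarchical clustering of traits from a correlation matrix
#'
#' Agglomerative clustering of the correlation matrix rows using Euclidean
#' distance and classical Ward linkage on unsquared distances (the "ward.D"
#' convention); "ward.D2" is available by flag. Missing cells are imputed as
#' 0 with a warning before computing distances. The returned `hclust` object
#' carries the merge heights and the leaf order used to sort output
#' matrices; leaf-order ties are broken deterministically by trait id via
#' the input row order.
#'
#' @param cm a `"cor_matrix"`.
#' @param method `"ward.D"` (default) or `"ward.D2"`.
#' @return a [stats::hclust] object.
#' @export
cluster_traits <- function(cm, method = c("ward.D", "ward.D2")) {
  method <- match.arg(method)
  rho <- cm$rho[order(rownames(cm$rho)), order(rownames(cm$rho)), drop = FALSE]
  if (nrow(rho) < 2L) stop("need at least 2 traits to cluster")
  if (anyNA(rho)) {
    warning("missing correlation cells imputed as 0 for clustering")
    rho[is.na(rho)] <- 0
  }
  stats::hclust(stats::dist(rho, method = "euclidean"), method = method)
}
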