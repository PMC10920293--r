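#' Convert physical marker positions to genetic map positions
#'
#' CSSL genotype panels usually come with physical coordinates only; for
#' interval mapping a genetic map is derived with a constant conversion rate
#' per chromosome, origin at the first marker. If the map already carries a
#' `pos_cM` column it is passed through and the rate ignored.
#'
#' @param map marker map data.frame (`marker_id`, `chrom`, `pos_bp`, and
#'   optionally `pos_cM`).
#' @param rate_bp_per_cM physical distance per centimorgan; default 250 kb/cM,
#'   a genome-wide average of the right order of magnitude for rice.
#' @return the map with a `pos_cM` column appended.
#' @export
physical_to_genetic <- function(map, rate_bp_per_cM = 250000) {
  if ("pos_cM" %in% names(map)) return(map)
  if (rate_bp_per_cM <= 0) stop("rate_bp_per_cM must be positive")
  map$pos_cM <- stats::ave(map$pos_bp, map$chrom,
                           FUN = function(p) (p - min(p)) / rate_bp_per_cM)
  map
}

#' Haldane map function
#'
#' Converts genetic distance (cM) to a recombination fraction under no
#' interference: `r = (1 - exp(-2 d / 100)) / 2`.
#'
#' @param d_cM nonnegative genetic distance in centimorgans (vectorized).
#' @return recombination fraction in `[0, 0.5)`.
#' @export
haldane <- function(d_cM) {
  if (any(d_cM < 0)) stop("negative genetic distance")
  (1 - exp(-2 * d_cM / 100)) / 2
}

#' Conditional donor-genotype probabilities on a scan grid
#'
#' Models each homozygous line's genome along a chromosome as a two-state
#' (recurrent/donor) Markov chain with Haldane transition probabilities. At a
#' grid position t between the nearest informative flanking calls g_L and g_R,
#' `P(donor | g_L, g_R) = P(g_L -> donor; r_L) P(donor -> g_R; r_R) / P(g_L -> g_R; r_LR)`.
#' One-sided conditioning applies at chromosome ends or across missing
#' flanks; with no informative call on the chromosome the prior is used. The
#' grid consists of the observed markers plus pseudo-positions so that
#' spacing never exceeds `step_cM`.
#'
#' @param geno a [geno_matrix()].
#' @param gmap genetic map (see [physical_to_genetic()]); computed with the
#'   default rate if the plain map is passed.
#' @param step_cM maximum grid spacing in cM.
#' @param prior prior donor probability in (0,1) used without flanking
#'   information; 0.5 corresponds to an uninformed two-state chain, and the
#'   empirical donor frequency is a reasonable alternative.
#' @return object of class `"geno_prob"`: list with `grid` (chrom, pos_bp,
#'   pos_cM, marker_id -- `NA` for pseudo-positions) and `probs`
#'   (lines x grid matrix of donor probabilities).
#' @export
compute_genotype_probabilities <- function(geno, gmap = NULL, step_cM = 1, prior = 0.5) {
  if (step_cM <= 0) stop("step_cM must be positive")
  if (prior <= 0 || prior >= 1) stop("prior must be in (0,1)")
  if (is.null(gmap)) gmap <- physical_to_genetic(geno$map)
  if (!all(geno$map$marker_id %in% gmap$marker_id)) stop("genetic map does not cover all markers")
  gmap <- gmap[match(geno$map$marker_id, gmap$marker_id), ]
  grid_list <- lapply(split(seq_len(nrow(gmap)), gmap$chrom), function(ix) {
    cm <- gmap$pos_cM[ix]
    bp <- gmap$pos_bp[ix]
    g <- data.frame(chrom = gmap$chrom[ix][1], pos_bp = bp, pos_cM = cm,
                    marker_id = gmap$marker_id[ix], stringsAsFactors = FALSE)
    if (length(ix) > 1L) {
      extra <- lapply(seq_len(length(ix) - 1L), function(k) {
        gap <- cm[k + 1L] - cm[k]
        if (gap <= step_cM) return(NULL)
        n_in <- ceiling(gap / step_cM) - 1L
        cms <- cm[k] + gap * seq_len(n_in) / (n_in + 1L)
        data.frame(chrom = g$chrom[1],
                   pos_bp = round(bp[k] + (bp[k + 1L] - bp[k]) * (cms - cm[k]) / gap),
                   pos_cM = cms, marker_id = NA_character_, stringsAsFactors = FALSE)
      })
      g <- rbind(g, do.call(rbind, extra))
    }
    g[order(g$pos_cM, g$pos_bp), ]
  })
  grid <- do.call(rbind, grid_list[unique(gmap$chrom)])
  rownames(grid) <- NULL
  n <- nrow(geno$calls)
  probs <- matrix(NA_real_, n, nrow(grid), dimnames = list(rownames(geno$calls), NULL))
  trans <- function(g, r) ifelse(g == 1, 1 - r, r)    # P(state g -> donor) over fraction r
  for (chr in unique(grid$chrom)) {
    gidx <- which(grid$chrom == chr)
    midx <- which(gmap$chrom == chr)
    gcm <- grid$pos_cM[gidx]
    mcm <- gmap$pos_cM[midx]
    for (li in seq_len(n)) {
      calls <- geno$calls[li, midx]
      inf <- which(!is.na(calls))
      if (!length(inf)) { probs[li, gidx] <- prior; next }
      ocm <- mcm[inf]
      oc <- calls[inf]
      left <- findInterval(gcm, ocm)
      right <- left + 1L
      p <- numeric(length(gidx))
      has_l <- left >= 1L
      has_r <- right <= length(inf)
      b <- has_l & has_r
      if (any(b)) {
        rl <- haldane(gcm[b] - ocm[left[b]])
        rr <- haldane(ocm[right[b]] - gcm[b])
        rlr <- haldane(ocm[right[b]] - ocm[left[b]])
        gl <- oc[left[b]]; gr <- oc[right[b]]
        num <- trans(gl, rl) * ifelse(gr == 1, 1 - rr, rr)
        den <- ifelse(gl == gr, 1 - rlr, rlr)
        p[b] <- num / den
      }
      if (any(has_l & !has_r))
        p[has_l & !has_r] <- trans(oc[left[has_l & !has_r]],
                                   haldane(gcm[has_l & !has_r] - ocm[left[has_l & !has_r]]))
      if (any(!has_l & has_r))
        p[!has_l & has_r] <- trans(oc[right[!has_l & has_r]],
                                   haldane(ocm[right[!has_l & has_r]] - gcm[!has_l & has_r]))
      probs[li, gidx] <- p
    }
  }
  structure(list(grid = grid, probs = probs, prior = prior, step_cM = step_cM),
            class = "geno_prob")
}

new_scan_result <- function(tab, trait_id, method, n_used, extra = list()) {
  structure(tab, trait_id = trait_id, method = method, n_used = n_used,
            extra = extra, class = c("scan_result", class(tab)))
}

#' Haley-Knott interval-mapping scan
#'
#' At each grid position the trait is regressed on the conditional donor
#' probability; the score is `LOD = (n/2) log10(RSS0 / RSS1)` against the
#' intercept-only model. At a fully observed marker this reduces to the
#' two-group contrast LOD. A constant trait gives LOD 0 everywhere;
#' positions with fewer complete lines than `min_lines` are flagged and
#' skipped.
#'
#' @param probs a `"geno_prob"` from [compute_genotype_probabilities()].
#' @param y named numeric trait vector (names = line ids; missing allowed).
#' @param trait_id trait label carried into the result.
#' @param min_lines minimum complete observations per position.
#' @return `"scan_result"` data.frame: grid columns plus `score` (LOD) and
#'   `skipped` flag; attribute `n_used`.
#' @export
interval_mapping_scan <- function(probs, y, trait_id = "trait", min_lines = 10L) {
  y <- y[rownames(probs$probs)]
  cc <- which(!is.na(y))
  n <- length(cc)
  X <- probs$probs[cc, , drop = FALSE]
  lod <- rep(NA_real_, ncol(X))
  skipped <- rep(n < min_lines, ncol(X))
  if (n >= min_lines) {
    yc <- y[cc] - mean(y[cc])
    syy <- sum(yc^2)
    if (syy == 0) {
      lod[] <- 0
    } else {
      Xc <- sweep(X, 2, colMeans(X))
      sxx <- colSums(Xc^2)
      sxy <- as.numeric(crossprod(Xc, yc))
      rss1 <- syy - ifelse(sxx > 1e-12, sxy^2 / sxx, 0)
      rss1 <- pmax(rss1, syy * 1e-12)
      lod <- (n / 2) * log10(syy / rss1)
    }
    skipped[] <- FALSE
  }
  tab <- cbind(probs$grid, data.frame(score = lod, skipped = skipped))
  new_scan_result(tab, trait_id, "interval_mapping", n)
}

#' Genome-wide permutation threshold for the interval-mapping LOD
#'
#' Permutes the trait values across lines, rescans, and records the
#' genome-wide maximum LOD of each permutation; the stated quantile of these
#' maxima is the significance threshold.
#'
#' @param probs a `"geno_prob"`.
#' @param y named trait vector.
#' @param n_perm number of permutations (the reference protocol uses 1,000).
#' @param quantile_level quantile of the null maxima (default 0.95).
#' @param seed integer seed; the threshold is deterministic given the seed.
#' @return numeric threshold with attribute `"max_lods"` (the null maxima).
#' @export
permutation_threshold <- function(probs, y, n_perm = 1000L, quantile_level = 0.95,
                                  seed = 1L) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  y <- y[rownames(probs$probs)]
  cc <- which(!is.na(y))
  n <- length(cc)
  yobs <- y[cc]
  set.seed(seed)
  Y <- vapply(seq_len(n_perm), function(i) sample(yobs), numeric(n))
  Yc <- sweep(Y, 2, colMeans(Y))
  syy <- colSums(Yc^2)
  X <- probs$probs[cc, , drop = FALSE]
  Xc <- sweep(X, 2, colMeans(X))
  sxx <- colSums(Xc^2)
  sxy <- crossprod(Xc, Yc)                      # grid x n_perm
  ok <- sxx > 1e-12
  frac <- sxy[ok, , drop = FALSE]^2 / sxx[ok]
  rss1 <- sweep(-frac, 2, syy, `+`)
  rss1 <- pmax(rss1, rep(syy * 1e-12, each = nrow(rss1)))
  lods <- (n / 2) * log10(sweep(1 / rss1, 2, syy, `*`))
  max_lods <- apply(lods, 2, max)
  thr <- as.numeric(stats::quantile(max_lods, quantile_level))
  attr(thr, "max_lods") <- max_lods
  thr
}

#' Single-marker rank-sum scan
#'
#' At each marker, trait values of donor-allele lines are compared with those
#' of recurrent-allele lines by the two-sample Wilcoxon rank-sum
#' (Mann-Whitney) test: exact p by enumeration when the pooled size is at
#' most 12 with no ties, otherwise the normal approximation with tie and
#' continuity corrections. The score is `-log10` of the two-sided p.
#'
#' @param geno a [geno_matrix()].
#' @param y named trait vector.
#' @param trait_id trait label.
#' @param min_group minimum lines per allele group; markers failing it are
#'   skipped with a reason code.
#' @return `"scan_result"` data.frame: map columns plus `score`, `n_donor`,
#'   `n_recurrent`, `skipped`, `skip_reason`.
#' @export
wilcoxon_scan <- function(geno, y, trait_id = "trait", min_group = 2L) {
  y <- y[rownames(geno$calls)]
  m <- ncol(geno$calls)
  score <- rep(NA_real_, m); n1 <- integer(m); n0 <- integer(m)
  reason <- rep(NA_character_, m)
  for (j in seq_len(m)) {
    g <- geno$calls[, j]
    cc <- !is.na(g) & !is.na(y)
    x1 <- y[cc & g == 1]; x0 <- y[cc & g == 0]
    n1[j] <- length(x1); n0[j] <- length(x0)
    if (n1[j] < min_group || n0[j] < min_group) { reason[j] <- "group_too_small"; next }
    score[j] <- -log10(wilcoxon_p(x1, x0))
  }
  tab <- cbind(geno$map,
               data.frame(score = score, n_donor = n1, n_recurrent = n0,
                          skipped = !is.na(reason), skip_reason = reason))
  new_scan_result(tab, trait_id, "wilcoxon", sum(!is.na(y)))
}

# two-sided rank-sum p; exact iff pooled n <= 12 and untied
wilcoxon_p <- function(x1, x0) {
  if (stats::var(c(x1, x0)) == 0) return(1)
  exact <- (length(x1) + length(x0)) <= 12L && !anyDuplicated(c(x1, x0))
  p <- suppressWarnings(stats::wilcox.test(x1, x0, exact = exact,
                                           correct = TRUE)$p.value)
  max(min(p, 1), 1e-300)
}

# Firth-penalized logistic fit of y on design X (first column intercept).
# IRLS on the hat-value adjusted score; maximizes ll(b) + 0.5 log det(X'WX).
firth_logit <- function(X, y, max_iter = 100L, tol = 1e-10) {
  b <- numeric(ncol(X))
  b[1] <- stats::qlogis((sum(y) + 0.5) / (length(y) + 1))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% b)
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    XtWX <- crossprod(X * sqrt(w))
    inv <- tryCatch(solve(XtWX), error = function(e) NULL)
    if (is.null(inv)) return(list(converged = FALSE))
    h <- rowSums((X %*% inv) * X) * w
    U <- crossprod(X, y - p + h * (0.5 - p))
    delta <- drop(inv %*% U)
    if (any(!is.finite(delta))) return(list(converged = FALSE))
    delta <- pmax(pmin(delta, 5), -5)           # step damping
    b <- b + delta
    if (max(abs(delta)) < tol) {
      eta <- drop(X %*% b); p <- stats::plogis(eta); w <- p * (1 - p)
      XtWX <- crossprod(X * sqrt(w))
      return(list(converged = TRUE, coef = b, vcov = solve(XtWX),
                  loglik = sum(y * eta - log1p(exp(eta)))))
    }
  }
  list(converged = FALSE)
}

#' Single-marker logistic-regression scan
#'
#' Fits, per marker, a logistic regression with the binary donor-allele
#' indicator as response and the standardized trait value as predictor (the
#' only orientation consistent with a binomial family when the trait is
#' continuous). A Firth-type penalty keeps the estimates finite under
#' complete separation. The score is `-log10` of the two-sided Wald p for the
#' slope; the slope (SNP effect) and McFadden's R-squared are reported as
#' auxiliaries.
#'
#' @param geno a [geno_matrix()].
#' @param y named trait vector.
#' @param trait_id trait label.
#' @param min_group minimum lines per allele group among complete cases.
#' @return `"scan_result"` data.frame: map columns plus `score`, `slope`,
#'   `r2_mcfadden`, `converged`, `skipped`, `skip_reason`.
#' @export
logistic_scan <- function(geno, y, trait_id = "trait", min_group = 2L) {
  y <- y[rownames(geno$calls)]
  m <- ncol(geno$calls)
  score <- rep(NA_real_, m); slope <- rep(NA_real_, m); r2 <- rep(NA_real_, m)
  conv <- rep(NA, m); reason <- rep(NA_character_, m)
  for (j in seq_len(m)) {
    g <- geno$calls[, j]
    cc <- which(!is.na(g) & !is.na(y))
    gj <- g[cc]; yj <- y[cc]
    if (sum(gj == 1) < min_group || sum(gj == 0) < min_group) {
      reason[j] <- "group_too_small"; next
    }
    if (stats::sd(yj) == 0) { reason[j] <- "constant_trait"; next }
    z <- (yj - mean(yj)) / stats::sd(yj)
    fit <- firth_logit(cbind(1, z), gj)
    conv[j] <- fit$converged
    if (!fit$converged) { reason[j] <- "no_convergence"; next }
    slope[j] <- fit$coef[2]
    se <- sqrt(fit$vcov[2, 2])
    p <- 2 * stats::pnorm(-abs(fit$coef[2] / se))
    score[j] <- -log10(max(p, 1e-300))
    ll0 <- {
      p0 <- mean(gj)
      sum(gj * log(p0) + (1 - gj) * log(1 - p0))
    }
    r2[j] <- if (ll0 < 0) 1 - fit$loglik / ll0 else NA_real_
  }
  tab <- cbind(geno$map,
               data.frame(score = score, slope = slope, r2_mcfadden = r2,
                          converged = conv, skipped = !is.na(reason),
                          skip_reason = reason))
  new_scan_result(tab, trait_id, "logistic", sum(!is.na(y)))
}

#' Run all three scan methods for every scannable trait
#'
#' Convenience wrapper: interval mapping (scores reduced to observed marker
#' positions so that all methods share one position set), rank-sum and
#' logistic scans. The full interval-mapping grid is kept as an attribute of
#' each interval-mapping result.
#'
#' @param geno a [geno_matrix()] (already line-aligned with `traits`).
#' @param traits a [trait_table()].
#' @param step_cM,prior see [compute_genotype_probabilities()].
#' @param min_lines,min_group scan preconditions.
#' @param methods subset of `c("interval_mapping", "wilcoxon", "logistic")`.
#' @return nested list `scans[[trait_id]][[method]]` of `"scan_result"`s.
#' @export
scan_all <- function(geno, traits, step_cM = 1, prior = 0.5,
                     min_lines = 10L, min_group = 2L,
                     methods = c("interval_mapping", "wilcoxon", "logistic")) {
  probs <- if ("interval_mapping" %in% methods)
    compute_genotype_probabilities(geno, step_cM = step_cM, prior = prior)
  out <- list()
  for (tr in colnames(traits$values)[traits$scannable]) {
    y <- traits$values[, tr]
    res <- list()
    if ("interval_mapping" %in% methods) {
      im <- interval_mapping_scan(probs, y, tr, min_lines = min_lines)
      at_marker <- im[!is.na(im$marker_id), , drop = FALSE]
      marker_tab <- cbind(geno$map,
                          data.frame(score = at_marker$score[match(geno$map$marker_id,
                                                                   at_marker$marker_id)],
                                     skipped = at_marker$skipped[match(geno$map$marker_id,
                                                                       at_marker$marker_id)]))
      res$interval_mapping <- new_scan_result(marker_tab, tr, "interval_mapping",
                                              attr(im, "n_used"),
                                              extra = list(full_grid = im))
    }
    if ("wilcoxon" %in% methods)
      res$wilcoxon <- wilcoxon_scan(geno, y, tr, min_group = min_group)
    if ("logistic" %in% methods)
      res$logistic <- logistic_scan(geno, y, tr, min_group = min_group)
    out[[tr]] <- res
  }
  out
}
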