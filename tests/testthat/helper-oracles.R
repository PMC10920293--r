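# Independent oracles used across tests. These deliberately avoid the code
# paths they check.

# Exact two-sided rank-sum p by full enumeration over all C(n1+n2, n1)
# group assignments of the pooled sample.
enum_wilcox_p <- function(x1, x0) {
  pooled <- c(x1, x0)
  n1 <- length(x1)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  ws <- apply(combos, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  p_le <- mean(ws <= w_obs)
  p_ge <- mean(ws >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Conditional donor probability at a query position by brute-force
# enumeration of every hidden two-state path over (markers + query), with a
# uniform chain start and Haldane transitions. obs: 0/1/NA calls at cm
# positions; query_cm anywhere on the chromosome.
enum_hk_prob <- function(obs, cm, query_cm) {
  pos <- sort(unique(c(cm, query_cm)))
  k <- length(pos)
  obs_at <- rep(NA_real_, k)
  obs_at[match(cm, pos)] <- obs
  qi <- match(query_cm, pos)
  states <- as.matrix(expand.grid(rep(list(c(0, 1)), k)))
  tr <- function(a, b, d) { r <- (1 - exp(-2 * d / 100)) / 2; ifelse(a == b, 1 - r, r) }
  w <- apply(states, 1, function(s) {
    if (any(!is.na(obs_at) & s != obs_at)) return(0)
    p <- 0.5
    for (i in seq_len(k - 1))
      p <- p * tr(s[i], s[i + 1], pos[i + 1] - pos[i])
    p
  })
  sum(w[states[, qi] == 1]) / sum(w)
}

# Firth-penalized logistic log-likelihood (for an optim()-based oracle).
firth_penalized_loglik <- function(b, X, y) {
  eta <- drop(X %*% b)
  p <- plogis(eta)
  W <- p * (1 - p)
  sum(y * eta - log1p(exp(eta))) + 0.5 * determinant(crossprod(X * sqrt(W)))$modulus
}

# Small helper fixtures ------------------------------------------------------

make_geno <- function(calls, chrom = NULL, pos = NULL) {
  m <- ncol(calls)
  if (is.null(chrom)) chrom <- rep("chr1", m)
  if (is.null(pos)) pos <- seq(1e5, by = 1e5, length.out = m)
  if (is.null(rownames(calls))) rownames(calls) <- sprintf("L%02d", seq_len(nrow(calls)))
  if (is.null(colnames(calls))) colnames(calls) <- sprintf("M%02d", seq_len(m))
  geno_matrix(data.frame(marker_id = colnames(calls), chrom = chrom, pos_bp = pos,
                         stringsAsFactors = FALSE), calls)
}

make_traits <- function(values, groups = NULL) {
  if (is.null(colnames(values))) colnames(values) <- sprintf("T%02d", seq_len(ncol(values)))
  if (is.null(groups)) groups <- rep(c("salt_injury_score", "tolerant_phenotype",
                                       "physiological_trait"),
                                     length.out = ncol(values))
  trait_table(values, data.frame(trait_id = colnames(values), group = groups,
                                 stringsAsFactors = FALSE))
}

# Standard simulated study: 12 traits on 3 planted loci (one shared by
# 4 traits across 2 groups), effect 1 residual SD, 120 lines, 5 x 100 markers.
planted_study <- function(seed) {
  pop <- simulate_population(seed = seed)
  specs <- list(
    qtl_spec("chr1", 15e6, c(SIS1 = 1, SIS2 = 1, DW1 = 1, DW2 = 1)),
    qtl_spec("chr2", 10e6, c(EL1 = 1, EL2 = 1, EL3 = 1, EL4 = 1)),
    qtl_spec("chr4", 20e6, c(CH1 = 1, CH2 = 1, CH3 = 1, CH4 = 1)))
  grp <- c(SIS1 = "salt_injury_score", SIS2 = "salt_injury_score",
           DW1 = "tolerant_phenotype", DW2 = "tolerant_phenotype",
           EL1 = "physiological_trait", EL2 = "physiological_trait",
           EL3 = "physiological_trait", EL4 = "physiological_trait",
           CH1 = "physiological_trait", CH2 = "physiological_trait",
           CH3 = "physiological_trait", CH4 = "physiological_trait")
  sim <- simulate_traits(pop, specs, group_assignment = grp, seed = seed)
  list(pop = pop, sim = sim)
}
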