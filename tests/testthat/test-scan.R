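test_that("haldane map function matches its closed form and limits", {
  expect_equal(haldane(0), 0)
  expect_equal(haldane(100), (1 - exp(-2)) / 2, tolerance = 1e-12)
  expect_lt(0.5 - haldane(1e6), 1e-12)
  expect_error(haldane(-1), "negative")
})

test_that("physical-to-genetic conversion is per-chromosome with origin at first marker", {
  map <- data.frame(marker_id = c("a", "b", "c", "d"),
                    chrom = c("chr1", "chr1", "chr2", "chr2"),
                    pos_bp = c(100000, 350000, 500000, 750000))
  g <- physical_to_genetic(map, rate_bp_per_cM = 250000)
  expect_equal(g$pos_cM, c(0, 1, 0, 1))
  # user-supplied cM column wins over the rate
  map$pos_cM <- c(0, 5, 0, 7)
  expect_equal(physical_to_genetic(map, 1)$pos_cM, c(0, 5, 0, 7))
  expect_error(physical_to_genetic(map[1:2, 1:3], -1), "positive")
})

test_that("genotype probabilities honour observed calls, priors and the Markov chain", {
  # three markers at 0/10/20 cM (2.5 Mb apart at the default rate)
  calls <- rbind(L1 = c(0, NA, 0), L2 = c(1, NA, 0), L3 = c(NA, NA, NA))
  g <- make_geno(calls, pos = c(1, 2500001, 5000001))  # 0/10/20 cM at 250 kb/cM
  pr <- compute_genotype_probabilities(g, step_cM = 100, prior = 0.5)
  mid <- which(pr$grid$marker_id == "M02")
  # flanks 0/0 at 10 cM each: r^2 / ((1-r)^2 + r^2)
  r <- haldane(10)
  expect_equal(unname(pr$probs["L1", mid]), r^2 / ((1 - r)^2 + r^2),
               tolerance = 1e-12)
  # observed-call invariance
  obs <- which(pr$grid$marker_id == "M01")
  expect_equal(unname(pr$probs[c("L1", "L2"), obs]), c(0, 1))
  # all-missing line sits at the prior everywhere
  expect_true(all(pr$probs["L3", ] == 0.5))
  expect_error(compute_genotype_probabilities(g, step_cM = 0), "positive")
  expect_error(compute_genotype_probabilities(g, prior = 1), "0,1")
})

test_that("conditional probabilities match exhaustive path enumeration", {
  set.seed(301)
  for (rep in 1:25) {
    cm <- sort(runif(3, 0, 40))
    obs <- sample(c(0, 1, NA), 3, replace = TRUE)
    if (all(is.na(obs))) obs[1] <- 1
    pos_bp <- round(cm * 250000) + 1
    calls <- matrix(rep(obs, each = 2), nrow = 2,
                    dimnames = list(c("A", "B"), NULL))
    g <- make_geno(calls, pos = pos_bp)
    pr <- compute_genotype_probabilities(g, step_cM = 5, prior = 0.5)
    for (q in seq_len(nrow(pr$grid))) {
      expected <- enum_hk_prob(obs, pr$grid$pos_cM[match(g$map$marker_id,
                                                         pr$grid$marker_id)],
                               pr$grid$pos_cM[q])
      expect_equal(unname(pr$probs["A", q]), expected, tolerance = 1e-12)
    }
  }
})

test_that("interval-mapping LOD equals the closed-form RSS ratio at observed markers", {
  calls <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), nrow = 4,
                  dimnames = list(paste0("L", 1:4), c("M01", "M02")))
  g <- make_geno(calls, pos = c(1e5, 2e5))
  pr <- compute_genotype_probabilities(g)
  y <- setNames(c(1, 2, 3, 4), paste0("L", 1:4))
  res <- interval_mapping_scan(pr, y, min_lines = 4)
  expect_equal(res$score[res$marker_id == "M01"], 2 * log10(5), tolerance = 1e-9)
  # affine trait transform leaves LOD unchanged
  res2 <- interval_mapping_scan(pr, 3 * y - 7, min_lines = 4)
  expect_equal(res2$score, res$score, tolerance = 1e-9)
  # constant trait: LOD 0 everywhere, not an error
  res0 <- interval_mapping_scan(pr, y * 0 + 2, min_lines = 4)
  expect_true(all(res0$score == 0))
  # too few lines -> positions flagged
  resk <- interval_mapping_scan(pr, y, min_lines = 10)
  expect_true(all(resk$skipped))
})

test_that("permutation threshold is seeded, monotone in the quantile, and a max at q = 1", {
  pop <- simulate_population(sim_config(n_lines = 40,
    chromosomes = data.frame(name = "chr1", length_bp = 20e6),
    markers_per_chromosome = 30), seed = 8)
  pr <- compute_genotype_probabilities(pop$geno)
  y <- setNames(rnorm(40), rownames(pop$geno$calls))
  t1 <- permutation_threshold(pr, y, n_perm = 100, seed = 9)
  t2 <- permutation_threshold(pr, y, n_perm = 100, seed = 9)
  expect_identical(t1, t2)
  tmax <- permutation_threshold(pr, y, n_perm = 100, quantile_level = 1, seed = 9)
  expect_equal(as.numeric(tmax), max(attr(t1, "max_lods")))
  expect_error(permutation_threshold(pr, y, n_perm = 0), ">= 1")
})

test_that("rank-sum scan reproduces exact p-values and skip rules", {
  calls <- matrix(c(1, 1, 1, 0, 0, 0,
                    1, 0, 0, 0, 0, 0), nrow = 6,
                  dimnames = list(paste0("L", 1:6), c("M01", "M02")))
  g <- make_geno(calls, pos = c(1e5, 2e5))
  y <- setNames(c(4, 5, 6, 1, 2, 3), paste0("L", 1:6))
  res <- wilcoxon_scan(g, y, min_group = 2)
  expect_equal(res$score[res$marker_id == "M01"], 1, tolerance = 1e-12)  # p = 0.1
  expect_true(res$skipped[res$marker_id == "M02"])
  expect_equal(res$skip_reason[res$marker_id == "M02"], "group_too_small")
  # identical constant values -> p = 1, score 0
  res0 <- wilcoxon_scan(g, y * 0 + 1, min_group = 2)
  expect_equal(res0$score[res0$marker_id == "M01"], 0)
  # strictly monotone trait transform leaves the score unchanged
  rese <- wilcoxon_scan(g, exp(y), min_group = 2)
  expect_equal(rese$score, res$score)
})

test_that("logistic scan is null-calibrated and finite under complete separation", {
  set.seed(77)
  n <- 200
  calls <- matrix(rbinom(n, 1, 0.3), ncol = 1,
                  dimnames = list(sprintf("L%03d", 1:n), "M01"))
  g <- make_geno(calls, pos = 1e5)
  y <- setNames(rnorm(n), rownames(calls))
  res <- logistic_scan(g, y)
  expect_lt(abs(res$slope[1]), 0.35)
  expect_lt(res$score[1], 2)
  # complete separation: all donor lines have larger trait values
  y2 <- setNames(ifelse(calls[, 1] == 1, rnorm(n, 5), rnorm(n, 0)), rownames(calls))
  res2 <- logistic_scan(g, y2)
  expect_true(res2$converged[1])
  expect_true(is.finite(res2$slope[1]))
})

test_that("Firth fit agrees with direct penalized-likelihood maximization", {
  g8 <- c(0, 0, 0, 0, 1, 1, 1, 1)
  y8 <- c(0.2, -1.1, 0.4, -0.6, 1.5, 0.8, 2.2, 0.3)
  calls <- matrix(g8, ncol = 1, dimnames = list(paste0("L", 1:8), "M01"))
  res <- logistic_scan(make_geno(calls, pos = 1e5),
                       setNames(y8, paste0("L", 1:8)))
  z <- (y8 - mean(y8)) / sd(y8)
  X <- cbind(1, z)
  opt <- optim(c(0, 0), function(b) -firth_penalized_loglik(b, X, g8),
               control = list(reltol = 1e-15, maxit = 10000))
  opt <- optim(opt$par, function(b) -firth_penalized_loglik(b, X, g8),
               control = list(reltol = 1e-15, maxit = 10000))
  expect_equal(res$slope[1], opt$par[2], tolerance = 1e-6)
})

test_that("scan_all shares one marker position set across methods", {
  pop <- simulate_population(sim_config(n_lines = 30,
    chromosomes = data.frame(name = "chr1", length_bp = 20e6),
    markers_per_chromosome = 25), seed = 12)
  sim <- simulate_traits(pop, list(qtl_spec("chr1", 1e7, c(TA = 1))),
                         n_null_traits = 1, seed = 12)
  scans <- scan_all(pop$geno, sim$traits)
  for (m in names(scans$TA))
    expect_equal(scans$TA[[m]]$marker_id, pop$geno$map$marker_id)
  expect_s3_class(attr(scans$TA$interval_mapping, "extra")$full_grid, "scan_result")
})
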