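hc_row <- function(trait, marker, chrom, pos, pr = 95) {
  data.frame(trait_id = trait, marker_id = marker, chrom = chrom, pos_bp = pos,
             votes = 2L, tier = "two_methods", high_confidence = TRUE,
             mean_pr = pr, carriers = 6L, stringsAsFactors = FALSE)
}

test_that("LD r-squared matches the two-locus formula", {
  expect_equal(ld_r2(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_equal(ld_r2(c(1, 1, 0, 0), c(1, 0, 0, 0)), 1 / 3, tolerance = 1e-12)
  expect_true(is.na(ld_r2(c(1, 1, 1, 1), c(1, 0, 0, 0))))  # monomorphic: undefined
  set.seed(13)
  a <- rbinom(5000, 1, 0.5); b <- rbinom(5000, 1, 0.5)
  expect_lt(ld_r2(a, b), 0.01)
})

test_that("region chaining follows the distance-or-LD rule", {
  calls <- cbind(M1 = c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0),
                 M2 = c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0),   # r2 = 1 with M1
                 M3 = c(0, 1, 0, 1, 1, 1, 0, 1, 1, 0))   # low LD with M2
  rownames(calls) <- paste0("L", 1:10)
  g <- make_geno(calls, pos = c(1e6, 1.01e6, 3.2e6))
  # adjacent SNPs 10 kb apart in full LD -> one region with M3 2.19 Mb away split off
  ctab <- rbind(hc_row("T1", "M1", "chr1", 1e6), hc_row("T1", "M2", "chr1", 1.01e6),
                hc_row("T1", "M3", "chr1", 3.2e6))
  regs <- call_regions(ctab, g, gap_bp = 1e6, r2_min = 0.8)
  expect_equal(nrow(regs), 2L)
  expect_equal(regs$n_passing, c(2L, 1L))
  # high LD chains across a large gap even when distance alone would split
  ctab2 <- rbind(hc_row("T1", "M1", "chr1", 1e6), hc_row("T1", "M2", "chr1", 1.01e6))
  g2 <- make_geno(calls[, 1:2], pos = c(1e6, 5e6))
  ctab2$pos_bp <- c(1e6, 5e6)
  expect_equal(nrow(call_regions(ctab2, g2, gap_bp = 1e6, r2_min = 0.8)), 1L)
  # different chromosomes never merge
  ctab3 <- rbind(hc_row("T1", "M1", "chr1", 1e6), hc_row("T1", "M2", "chr2", 1.01e6))
  g3 <- make_geno(calls[, 1:2], chrom = c("chr1", "chr2"), pos = c(1e6, 1.01e6))
  expect_equal(nrow(call_regions(ctab3, g3, gap_bp = 1e8, r2_min = 0)), 2L)
  # no high-confidence SNPs -> empty region list, not an error
  ctab0 <- ctab; ctab0$high_confidence <- FALSE
  expect_equal(nrow(call_regions(ctab0, g)), 0L)
})

test_that("region calling is invariant to input row order and merges across traits", {
  calls <- matrix(rbinom(80, 1, 0.4), nrow = 8,
                  dimnames = list(paste0("L", 1:8), sprintf("M%02d", 1:10)))
  g <- make_geno(calls, pos = seq(1e6, 10e6, by = 1e6))
  ctab <- rbind(hc_row("T1", "M01", "chr1", 1e6), hc_row("T1", "M02", "chr1", 2e6),
                hc_row("T2", "M02", "chr1", 2e6), hc_row("T2", "M03", "chr1", 3e6))
  r1 <- call_regions(ctab, g)
  r2 <- call_regions(ctab[sample(nrow(ctab)), ], g)
  expect_equal(r1, r2)
  expect_equal(nrow(r1), 1L)
  expect_setequal(r1$traits[[1]], c("T1", "T2"))
  expect_equal(r1$n_passing, 3L)
})

test_that("shrinking gap or raising the LD threshold never merges regions further", {
  std <- planted_study(31)
  fit_scans <- scan_all(std$pop$geno, std$sim$traits)
  ctab <- consensus_table(fit_scans, std$pop$geno)
  n_loose <- nrow(call_regions(ctab, std$pop$geno, gap_bp = 2e6, r2_min = 0.5))
  n_tight <- nrow(call_regions(ctab, std$pop$geno, gap_bp = 5e5, r2_min = 0.95))
  expect_gte(n_tight, n_loose)
})

test_that("multi-trait classification is decided at trait level", {
  meta <- data.frame(trait_id = c("SIS1", "SIS2", "EL1"),
                     group = c("salt_injury_score", "salt_injury_score",
                               "physiological_trait"))
  regions <- data.frame(region_id = c("R1", "R2", "R3"), chrom = "chr1",
                        start_bp = c(1, 100, 200), end_bp = c(50, 150, 250))
  regions$markers <- I(list("a", "b", "c"))
  regions$traits <- I(list(c("SIS1", "EL1"), "SIS1", c("SIS1", "SIS2")))
  cl <- classify_regions(regions, meta)
  expect_equal(cl$specificity_class, c("multi_trait", "trait_specific", "multi_trait"))
  expect_equal(cl$trait_groups_hit[[1]], c("physiological_trait", "salt_injury_score"))
  expect_equal(cl$trait_groups_hit[[3]], "salt_injury_score")  # two traits, one group
  regions$traits <- I(list(character(0), "SIS1", "SIS1"))
  expect_error(classify_regions(regions, meta), "zero linked traits")
})

test_that("gene mapping uses the any-overlap rule at exact boundaries", {
  ann <- data.frame(gene_id = c("inside", "edge", "outside"), chrom = "chr1",
                    start_bp = c(1200L, 1901L, 2002L),
                    end_bp = c(1300L, 2500L, 2400L), strand = "+")
  regions <- data.frame(region_id = "R1", chrom = "chr1",
                        start_bp = 1001L, end_bp = 2000L)
  got <- map_regions_to_genes(regions, ann)
  expect_equal(got$R1, c("inside", "edge"))
  regions$chrom <- "chrX"
  expect_warning(got2 <- map_regions_to_genes(regions, ann), "absent")
  expect_equal(got2$R1, character(0))
})
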