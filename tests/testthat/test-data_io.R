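test_that("genotype TSV reader validates schema and roundtrips losslessly", {
  calls <- matrix(c(0, 1, NA, 1, 0, 0, 1, 1, 0, 0, 1, NA), nrow = 4,
                  dimnames = list(paste0("L", 1:4), paste0("M", 1:3)))
  g <- make_geno(calls)
  expect_equal(dim(g$calls), c(4L, 3L))
  f <- tempfile(fileext = ".tsv")
  write_genotypes_tsv(g, f)
  g2 <- read_genotypes_tsv(f)
  expect_equal(g2$map, g$map)
  expect_equal(g2$calls, g$calls)
})

test_that("invalid genotype cells are rejected with row and column named", {
  f <- tempfile(fileext = ".tsv")
  d <- data.frame(marker_id = paste0("M", 1:8), chrom = "chr1",
                  pos_bp = 1:8 * 1000, LA = 0, LB = 1)
  d$LB[7] <- 2
  write.table(d, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_genotypes_tsv(f), "row 7.*'LB'")
})

test_that("genotype TSV needs at least two line columns", {
  f <- tempfile(fileext = ".tsv")
  write.table(data.frame(marker_id = "M1", chrom = "chr1", pos_bp = 1, LA = 0),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_genotypes_tsv(f), "2 line columns")
})

test_that("container validation catches duplicates and bad positions", {
  calls <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("M1", "M1")))
  expect_error(make_geno(calls), "duplicate marker ids")
  expect_error(geno_matrix(data.frame(marker_id = "M1", chrom = "chr1", pos_bp = 0),
                           matrix(0, 2, 1, dimnames = list(c("a", "b"), "M1"))),
               "positive")
})

test_that("VCF recoding follows the homozygous-parent mapping rule", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tDON\tREC\tC1\tC2",
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t1/1\t0/0\t1/1\t0/1",
    "chr1\t200\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/0\t1/1\t0/0",
    "chr1\t300\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t1/1\t1/1\t0/0",
    "chr1\t400\t.\tA\tG,T\t.\tPASS\t.\tGT\t1/1\t0/0\t1/1\t0/0"), f)
  expect_warning({g <- read_genotypes_vcf(f, "DON", "REC")}, "multiallelic")
  # site 100: donor-matching call 1, heterozygote unresolvable -> NA
  expect_equal(unname(g$calls[c("C1", "C2"), "chr1_100"]), c(1, NA))
  # site 300: parents swapped relative to site 100
  expect_equal(unname(g$calls[c("C1", "C2"), "chr1_300"]), c(0, 1))
  # site 200 (parents agree) dropped and counted; site 400 multiallelic skipped
  expect_equal(ncol(g$calls), 2L)
  expect_equal(unname(attr(g, "dropped")["uninformative"]), 1)
  expect_error(read_genotypes_vcf(f, "NOPE", "REC"), "donor sample")
})

test_that("trait table enforces the three trait groups and scannability", {
  vals <- matrix(rnorm(20), 5, 4, dimnames = list(paste0("L", 1:5), paste0("T", 1:4)))
  expect_error(make_traits(vals, groups = rep("misc", 4)),
               "salt_injury_score, tolerant_phenotype, physiological_trait")
  vals[, 2] <- NA
  tt <- make_traits(vals)
  expect_false(tt$scannable[["T2"]])
  expect_true(tt$scannable[["T1"]])
  # roundtrip through TSVs
  vp <- tempfile(); mp <- tempfile()
  write_traits_tsv(tt, vp, mp)
  tt2 <- read_traits_tsv(vp, mp)
  expect_equal(tt2$values, tt$values)
  expect_equal(tt2$meta, tt$meta)
})

test_that("line alignment intersects and warns about discards", {
  g <- make_geno(matrix(0, 3, 2, dimnames = list(c("a", "b", "c"), NULL)))
  vals <- matrix(rnorm(10), 5, 2,
                 dimnames = list(c("a", "b", "x", "y", "z"), c("T1", "T2")))
  expect_warning(al <- align_lines(g, make_traits(vals)), "dropped")
  expect_equal(rownames(al$geno$calls), c("a", "b"))
  expect_equal(rownames(al$traits$values), c("a", "b"))
})

test_that("GFF3 gene reader filters by feature type and validates IDs", {
  genes <- data.frame(gene_id = c("OsTEST", "OsB"), chrom = "chr4",
                      start_bp = c(100L, 900L), end_bp = c(500L, 1200L), strand = "+")
  f <- tempfile(fileext = ".gff3")
  write_gff3(genes, f)
  ann <- read_gff3(f)
  expect_equal(ann$gene_id, c("OsTEST", "OsB"))
  expect_equal(ann$start_bp, c(100L, 900L))
  # mRNA-only file -> empty with warning
  writeLines(c("##gff-version 3",
               "chr1\tx\tmRNA\t1\t10\t.\t+\t.\tID=t1"), f)
  expect_warning(empty <- read_gff3(f), "no 'gene' features")
  expect_equal(nrow(empty), 0L)
  # duplicated gene ID -> error
  writeLines(c("##gff-version 3",
               "chr1\tx\tgene\t1\t10\t.\t+\t.\tID=g1",
               "chr1\tx\tgene\t20\t30\t.\t+\t.\tID=g1"), f)
  expect_error(read_gff3(f), "duplicated gene ID")
})

test_that("region writer uses 1-based TSV and 0-based half-open BED with PR score", {
  regions <- data.frame(region_id = "R001", chrom = "chr1", start_bp = 1001L,
                        end_bp = 2000L, width_bp = 1000L, n_passing = 3L,
                        mean_pr = 92.5)
  regions$markers <- I(list(c("M1", "M2", "M3")))
  regions$traits <- I(list("T1"))
  regions$trait_groups_hit <- I(list("salt_injury_score"))
  tf <- tempfile(); bf <- tempfile()
  write_regions(regions, tf, bf)
  bed <- read.delim(bf, header = FALSE)
  expect_equal(unlist(bed[1, 1:5], use.names = FALSE),
               c("chr1", "1000", "2000", "R001", "925"))
  tsv <- read.delim(tf)
  expect_equal(tsv$start_bp, 1001L)
  # empty region list -> valid empty files, TSV keeps its header
  write_regions(regions[0, ], tf, bf)
  expect_match(readLines(tf)[1], "region_id")
  expect_equal(length(readLines(bf)), 0L)
})

test_that("DE table reader validates columns, p-values and duplicates", {
  f <- tempfile()
  d <- data.frame(setting_id = "s1", platform_class = "microarray",
                  gene_id = c("g1", "g2"), log2fc = c(0.5, -1), pvalue = c(0.01, 0.9))
  write.table(d, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(nrow(read_de_tables(f)), 2L)
  d$pvalue[1] <- 1.5
  write.table(d, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_de_tables(f), "0,1")
})
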