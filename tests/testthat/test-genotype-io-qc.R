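test_that("plink .raw fixture reads with the stated codes", {
  path <- withr::local_tempfile(fileext = ".raw")
  writeLines(c(
    "FID IID PAT MAT SEX PHENOTYPE rs1_A rs2_G",
    "F1 S1 0 0 0 -9 0 2",
    "F1 S2 0 0 0 -9 1 NA",
    "F1 S3 0 0 0 -9 2 0"), path)
  g <- read_genotypes(path, "plink_raw")
  expect_equal(dim(g), c(3L, 2L))
  expect_equal(g$sample_ids, c("S1", "S2", "S3"))
  expect_equal(g$snp_ids, c("rs1", "rs2"))
  expect_equal(g$counted_allele, c("A", "G"))
  expect_equal(unname(g$values[, 1]), c(0, 1, 2))
  expect_true(is.na(g$values[2, 2]))
  expect_error(read_genotypes(path, "bogus"))
  bad <- withr::local_tempfile(fileext = ".raw")
  writeLines(c("IID FID X", "a b 1"), bad)
  expect_error(read_genotypes(bad, "plink_raw"), "header")
})

test_that("VCF GT maps to alternate-allele dosage and ploidy is checked", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", sep = "\t"),
    paste("1", "100", "rs1", "A", "T", ".", ".", ".", "GT",
          "0/1", "1|1", sep = "\t"),
    paste("2", "200", "rs2", "G", "C", ".", ".", ".", "GT",
          "0/0", "./.", sep = "\t")), path)
  g <- read_genotypes(path, "vcf")
  expect_equal(unname(g$values["S1", ]), c(1, 0))
  expect_equal(unname(g$values["S2", "rs1"]), 2)
  expect_true(is.na(g$values["S2", "rs2"]))
  expect_equal(g$chromosome, c("1", "2"))
  haploid <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", sep = "\t"),
    paste("X", "1", "rs9", "A", "T", ".", ".", ".", "GT", "1",
          sep = "\t")), haploid)
  expect_error(read_genotypes(haploid, "vcf"), "ploidy")
})

test_that("write/read round-trips preserve the panel in both formats", {
  g <- toy_panel(n = 8, m = 12, seed = 31)
  g$values[2, 3] <- NA
  for (fmt in c("plink_raw", "vcf")) {
    path <- withr::local_tempfile()
    write_genotypes(g, path, fmt)
    g2 <- read_genotypes(path, fmt)
    expect_equal(unname(g2$values), unname(g$values), ignore_attr = TRUE)
    expect_equal(g2$sample_ids, g$sample_ids)
    expect_equal(g2$snp_ids, g$snp_ids)
  }
})

test_that("QC removes SNPs by the first failing rule in fixed order", {
  # 10 SNPs: 2 monomorphic, 1 on X, 1 with call rate 0.5, 6 clean
  set.seed(2)
  n <- 10
  clean <- function() {
    v <- rbinom(n, 2, 0.5)
    if (length(unique(v)) == 1) v[1] <- (v[1] + 1) %% 3
    v
  }
  vals <- cbind(rep(0, n), rep(2, n), clean(), clean(), clean(), clean(),
                clean(), clean(), clean(), clean())
  vals[1:5, 10] <- NA                      # call rate 0.5
  chrom <- c("1", "1", "X", rep("2", 7))
  g <- genotype_matrix(vals, chromosome = chrom)
  res <- qc_filter(g, maf_min = 0.05, snp_callrate_min = 0.9,
                   sample_callrate_min = 0)
  expect_equal(res$report$n_removed_monomorphic, 2)
  expect_equal(res$report$n_removed_sex_chrom, 1)
  expect_equal(res$report$n_removed_maf, 0)
  expect_equal(res$report$n_removed_snp_callrate, 1)
  expect_equal(res$report$n_snps_out, 6)
  expect_equal(res$report$n_snps_in -
                 (res$report$n_removed_monomorphic +
                  res$report$n_removed_sex_chrom +
                  res$report$n_removed_maf +
                  res$report$n_removed_snp_callrate),
               res$report$n_snps_out)
})

test_that("QC matches a per-SNP loop oracle on random panels and is idempotent", {
  for (seed in c(11, 12, 13)) {
    set.seed(seed)
    n <- 40; m <- 60
    p <- runif(m, 0.0, 0.6)
    vals <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
    vals[sample(length(vals), 200)] <- NA
    chrom <- sample(c(as.character(1:5), "X"), m, replace = TRUE)
    g <- genotype_matrix(vals, chromosome = chrom)
    maf_min <- 0.05; cr_min <- 0.95
    # loop oracle: first-failing-rule per SNP
    keep <- logical(m)
    for (j in seq_len(m)) {
      col <- vals[, j]
      pj <- mean(col, na.rm = TRUE) / 2
      cr <- mean(!is.na(col))
      keep[j] <- !(pj %in% c(0, 1)) && !(chrom[j] == "X") &&
        !(min(pj, 1 - pj) < maf_min) && !(cr < cr_min)
    }
    res <- qc_filter(g, maf_min, cr_min, sample_callrate_min = 0)
    expect_equal(res$report$n_snps_out, sum(keep))
    expect_identical(res$genotypes$snp_ids, g$snp_ids[keep])
    # idempotence: second pass removes nothing
    res2 <- qc_filter(res$genotypes, maf_min, cr_min, 0)
    expect_equal(res2$report$n_snps_out, res$report$n_snps_out)
    expect_equal(res2$report$n_removed_maf +
                   res2$report$n_removed_monomorphic +
                   res2$report$n_removed_sex_chrom +
                   res2$report$n_removed_snp_callrate, 0)
  }
  # vacuous MAF threshold removes nothing by MAF
  g <- toy_panel(30, 40, seed = 5)
  expect_equal(qc_filter(g, maf_min = 0)$report$n_removed_maf, 0)
})

test_that("mean imputation fills gaps, keeps observed data and frequencies", {
  vals <- rbind(c(0, 1), c(2, 0), c(NA, 1))
  g <- genotype_matrix(vals)
  for (m in c("snp_mean", "snp_mean_rounded")) {
    gi <- impute_missing(g, m)
    expect_equal(unname(gi$values[3, 1]), 1)   # mean of 0 and 2
    expect_equal(gi$values[1:2, ], g$values[1:2, ], ignore_attr = TRUE)
    expect_false(anyNA(gi$values))
  }
  # no missing -> unchanged
  g2 <- toy_panel(5, 6, seed = 3)
  expect_identical(impute_missing(g2), g2)
  # frequency invariance of mean imputation
  set.seed(4)
  vals <- matrix(rbinom(200, 2, 0.3), 20, 10)
  miss <- vals; miss[sample(200, 30)] <- NA
  gm <- impute_missing(genotype_matrix(miss))
  expect_equal(unname(colMeans(gm$values) / 2),
               colMeans(miss, na.rm = TRUE) / 2, tolerance = 1e-12)
  # fully missing SNP errors with its id
  allna <- genotype_matrix(cbind(c(0, 1, 2), c(NA, NA, NA)),
                           snp_ids = c("ok", "gone"))
  expect_error(impute_missing(allna), "gone")
})
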