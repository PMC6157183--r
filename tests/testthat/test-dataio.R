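make_vcf <- function(lines) {
  f <- withr::local_tempfile(fileext = ".vcf", .local_envir = parent.frame())
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", "s1", "s2", "s3"), collapse = "\t"),
               lines), f)
  f
}

test_that("VCF dosages follow the minor-allele convention from the file", {
  f <- make_vcf(c(
    "1\t100\trsA\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\trsB\tA\tG\t.\tPASS\t.\tGT\t1/1\t1/1\t0/1",  # REF is minor
    "1\t300\trsC\tA\tG\t.\tPASS\t.\tGT\t./.\t0/1\t0|1"))
  g <- read_genotypes(f, "vcf")
  expect_equal(unname(g$dosages[, "rsA"]), c(0, 1, 2))
  expect_equal(unname(g$dosages[, "rsB"]), c(0, 0, 1))  # complemented
  expect_equal(unname(g$dosages[, "rsC"]), c(NA, 1, 1))
})

test_that("multiallelic records are rejected or dropped per flag", {
  f <- make_vcf("1\t100\trsM\tA\tG,T\t.\tPASS\t.\tGT\t0/0\t0/1\t0/2")
  expect_error(read_genotypes(f, "vcf"), "multiallelic")
  f2 <- make_vcf(c("1\t100\trsM\tA\tG,T\t.\tPASS\t.\tGT\t0/0\t0/1\t0/2",
                   "1\t200\trsOK\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1"))
  expect_warning(g <- read_genotypes(f2, "vcf", strict_biallelic = FALSE),
                 "dropping")
  expect_equal(colnames(g$dosages), "rsOK")
})

test_that("PLINK ped/map text gives the same dosages as the equivalent VCF", {
  d <- withr::local_tempdir()
  writeLines(c("F1 s1 0 0 1 0 A A C C",
               "F1 s2 0 0 1 0 A G C C",
               "F1 s3 0 0 2 0 G G C A"), file.path(d, "toy.ped"))
  writeLines(c("1 rsA 0 100", "1 rsB 0 200"), file.path(d, "toy.map"))
  g <- read_genotypes(file.path(d, "toy.ped"), "plink_text")
  expect_equal(unname(g$dosages[, "rsA"]), c(0, 1, 2))
  expect_equal(unname(g$dosages[, "rsB"]), c(0, 0, 1))
})

test_that("sample ids are validated against the pedigree when given", {
  ped <- pedigree(data.frame(id = c("s1", "s2"), father = NA, mother = NA,
                             sex = "unknown", family = "F1"))
  f <- make_vcf("1\t100\trsA\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1")
  expect_error(read_genotypes(f, "vcf", ped = ped), "s3")
})

test_that("QC applies the missing, monomorphic and rare-genotype rules in order", {
  d <- cbind(two_ok   = c(rep(0, 50), rep(1, 50)),
             rare2    = c(rep(0, 96), rep(1, 4)),
             mono     = rep(0, 100),
             missing1 = c(NA, rep(1, 49), rep(0, 50)),
             rare_hom = c(rep(0, 90), rep(1, 8), rep(2, 2)))
  g <- genotype_matrix(d, data.frame(snp_id = colnames(d), chrom = "1",
                                     bp = seq_len(5) * 100L))
  res <- qc_filter(g)
  expect_setequal(colnames(res$genotypes$dosages), c("two_ok", "rare_hom"))
  expect_equal(res$report$removed_missing, 1)
  expect_equal(res$report$removed_monomorphic, 1)
  expect_equal(res$report$removed_rare_genotype, 1)
  # three observed genotype classes: the < 5% rule does not apply
  expect_true("rare_hom" %in% colnames(res$genotypes$dosages))
  # idempotence
  res2 <- qc_filter(res$genotypes)
  expect_equal(res2$genotypes$dosages, res$genotypes$dosages)
  # optional MAF filter is off by default but works
  res3 <- qc_filter(g, maf_min = 0.2)
  expect_false("rare_hom" %in% colnames(res3$genotypes$dosages))
  # everything removed is an error
  gm <- genotype_matrix(matrix(0, 10, 1, dimnames = list(NULL, "m")),
                        data.frame(snp_id = "m", chrom = "1", bp = 1L))
  expect_error(qc_filter(gm), "review")
})

test_that("phenotype and covariate tables round-trip at full precision", {
  iid <- c("i1", "i2", "i3")
  set.seed(5)
  tg <- matrix(exp(exp(rnorm(12, 1.5, 0.3))), 3, 4)
  hdl <- matrix(exp(exp(rnorm(12, 1.36, 0.2))), 3, 4)
  tg[2, 3] <- NA
  p <- long_phenotypes(iid, tg, hdl)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_phenotypes(p, f)
  p2 <- read_phenotypes(f)
  expect_identical(p2$tg, p$tg)
  expect_identical(p2$hdl, p$hdl)
  expect_true(is.na(p2$tg[2, 3]))

  cv <- covariate_table(data.frame(iid = iid, age = c(30, 45.5, 60),
                                   smoking = c(0, 1, 0)))
  fc <- withr::local_tempfile(fileext = ".tsv")
  write_covariates(cv, fc)
  expect_equal(read_covariates(fc)$age, cv$age)
})

test_that("invalid phenotype and covariate inputs are rejected", {
  expect_error(long_phenotypes("i1", matrix(0, 1, 4), matrix(50, 1, 4)),
               "nonpositive")
  expect_error(covariate_table(data.frame(iid = "a", age = NA, smoking = 0)),
               "missing")
  expect_error(covariate_table(data.frame(iid = "a", age = 30, smoking = 2)),
               "smoking")
  expect_error(genotype_matrix(matrix(3, 1, 1),
                               data.frame(snp_id = "s", chrom = "1", bp = 1L)),
               "dosages")
})

test_that("genotype columns are ordered by chromosome and position", {
  d <- matrix(c(0, 1, 2, 0, 1, 1), 2, 3)
  g <- genotype_matrix(d, data.frame(snp_id = c("b", "a", "c"),
                                     chrom = c("2", "1", "1"),
                                     bp = c(50L, 500L, 100L)))
  expect_equal(g$map$snp_id, c("c", "a", "b"))
  expect_equal(colnames(g$dosages), c("c", "a", "b"))
})

test_that("simulated genotypes survive a VCF write/read round trip", {
  ped <- sim_pedigree(5, "nuclear", seed = 3)
  G <- sim_genotypes(ped, 12, seed = 4)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_genotypes_vcf(G, f)
  G2 <- read_genotypes(f, "vcf")
  # reading re-applies the minor-allele convention, so compare after
  # normalizing the simulated dosages the same way (sampling drift can push
  # a simulated frequency past 0.5)
  expected <- G$dosages
  flip <- colMeans(expected) / 2 > 0.5
  expected[, flip] <- 2 - expected[, flip]
  expect_equal(G2$dosages[rownames(G$dosages), colnames(G$dosages)],
               expected)
})
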