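#' Construct a genotype matrix object
#'
#' @param dosages n x m numeric matrix of minor-allele counts in
#'   `{0, 1, 2, NA}`; rownames are individual ids, colnames SNP ids.
#' @param map Data frame with columns `snp_id`, `chrom`, `bp` (1-based),
#'   one row per column of `dosages`.
#' @return A `genotype_matrix` (list with `dosages` and `map`), columns
#'   ordered deterministically by (chrom, bp).
#' @export
genotype_matrix <- function(dosages, map) {
  stopifnot(is.matrix(dosages), nrow(map) == ncol(dosages),
            all(c("snp_id", "chrom", "bp") %in% names(map)))
  bad <- !(dosages %in% c(0, 1, 2) | is.na(dosages))
  if (any(bad)) stop("dosages must be 0, 1, 2 or missing")
  if (any(map$bp <= 0)) stop("bp must be positive (1-based)")
  ord <- order(map$chrom, map$bp)
  map <- map[ord, , drop = FALSE]
  rownames(map) <- NULL
  dosages <- dosages[, ord, drop = FALSE]
  colnames(dosages) <- map$snp_id
  structure(list(dosages = dosages, map = map), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosages), "individuals x",
      ncol(x$dosages), "SNPs\n")
  invisible(x)
}

#' Read genotypes from VCF or PLINK-style text
#'
#' Dosages are counted on the minor allele as determined from the file
#' itself: after counting ALT (VCF) or the second observed allele (PED),
#' any column whose counted-allele frequency exceeds 0.5 is complemented
#' (`2 - dosage`). Missing calls are preserved as `NA`.
#'
#' @param path VCF file, or a PLINK `.ped` path / fileset prefix (a sibling
#'   `.map` is required).
#' @param format `"vcf"` or `"plink_text"`.
#' @param strict_biallelic If `TRUE` (default) a multiallelic VCF record is
#'   an error; if `FALSE` such records are dropped with a warning.
#' @param ped Optional `fam_pedigree`; sample ids absent from it are an
#'   error listing the offenders.
#' @return A `genotype_matrix`.
#' @export
read_genotypes <- function(path, format = c("vcf", "plink_text"),
                           strict_biallelic = TRUE, ped = NULL) {
  format <- match.arg(format)
  g <- if (format == "vcf") {
    .read_genotypes_vcf(path, strict_biallelic)
  } else {
    .read_genotypes_ped(path)
  }
  if (!is.null(ped)) {
    unknown <- setdiff(rownames(g$dosages), ped$id)
    if (length(unknown))
      stop("genotyped sample id(s) absent from pedigree: ",
           paste(unknown, collapse = ", "))
  }
  g
}

.read_genotypes_vcf <- function(path, strict_biallelic) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    if (strict_biallelic)
      stop("multiallelic record(s) at: ",
           paste(fix[multi, "ID"], collapse = ", "))
    warning("dropping ", sum(multi), " multiallelic record(s)")
  }
  keep <- !multi
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  lut <- c("0/0" = 0, "0/1" = 1, "1/0" = 1, "1/1" = 2)
  clean <- gsub("|", "/", gt, fixed = TRUE)
  dos <- matrix(unname(lut[clean]), nrow = nrow(gt), ncol = ncol(gt))
  # minor-allele convention from the data in the file
  dos <- t(.flip_to_minor(t(dos)))
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  map <- data.frame(snp_id = ids, chrom = as.character(fix[, "CHROM"]),
                    bp = as.integer(fix[, "POS"]), stringsAsFactors = FALSE)
  dmat <- t(dos)
  rownames(dmat) <- colnames(gt)
  colnames(dmat) <- map$snp_id
  genotype_matrix(dmat, map)
}

# columns = SNPs; complement columns where the counted allele is the major one
.flip_to_minor <- function(dmat) {
  af <- colMeans(dmat, na.rm = TRUE) / 2
  flip <- !is.na(af) & af > 0.5
  dmat[, flip] <- 2 - dmat[, flip, drop = FALSE]
  dmat
}

.read_genotypes_ped <- function(path) {
  ped_path <- if (grepl("\\.ped$", path)) path else paste0(path, ".ped")
  map_path <- sub("\\.ped$", ".map", ped_path)
  if (!file.exists(ped_path) || !file.exists(map_path))
    stop("need both .ped and .map files for plink_text")
  map_raw <- utils::read.table(map_path, header = FALSE,
                               colClasses = c("character", "character",
                                              "character", "integer"))
  m <- nrow(map_raw)
  ped_raw <- utils::read.table(ped_path, header = FALSE, colClasses = "character")
  if (ncol(ped_raw) != 6 + 2 * m)
    stop(".ped has ", ncol(ped_raw), " columns; expected ", 6 + 2 * m)
  ids <- ped_raw[[2]]
  n <- nrow(ped_raw)
  dmat <- matrix(NA_real_, n, m)
  for (j in seq_len(m)) {
    a1 <- ped_raw[[6 + 2 * j - 1]]
    a2 <- ped_raw[[6 + 2 * j]]
    miss <- a1 == "0" | a2 == "0"
    alleles <- sort(unique(c(a1[!miss], a2[!miss])))
    if (length(alleles) > 2)
      stop("more than two alleles at SNP ", map_raw[[2]][j])
    counted <- alleles[length(alleles)]  # count the last allele; flipped below
    dmat[, j] <- (a1 == counted) + (a2 == counted)
    dmat[miss, j] <- NA_real_
  }
  dmat <- .flip_to_minor(dmat)
  rownames(dmat) <- ids
  map <- data.frame(snp_id = map_raw[[2]], chrom = map_raw[[1]],
                    bp = map_raw[[4]], stringsAsFactors = FALSE)
  genotype_matrix(dmat, map)
}

#' SNP-level quality control
#'
#' Applies, in order: (i) removal of SNPs whose fraction of missing genotypes
#' exceeds `max_missing` (default 0: any missing call removes the SNP);
#' (ii) removal of monomorphic SNPs (a single observed genotype class);
#' (iii) for SNPs with exactly two observed genotype classes, removal when the
#' rarer class frequency is below `rare_genotype_min`. SNPs showing all three
#' genotype classes are not subject to rule (iii); an optional minor-allele
#' frequency filter (`maf_min`, default `NULL` = off) can be applied last.
#'
#' @param g A `genotype_matrix`.
#' @param rare_genotype_min Two-genotype rarer-class frequency threshold
#'   (default 0.05; removal when strictly below).
#' @param max_missing Maximum tolerated per-SNP missing fraction (default 0).
#' @param maf_min Optional minor-allele frequency threshold, default off.
#' @return List with `genotypes` (filtered `genotype_matrix`) and `report`
#'   (a `qc_report`: counts removed per rule, in application order).
#' @export
qc_filter <- function(g, rare_genotype_min = 0.05, max_missing = 0,
                      maf_min = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$dosages
  m0 <- ncol(d)
  miss_frac <- colMeans(is.na(d))
  rm_missing <- miss_frac > max_missing
  keep <- !rm_missing

  n_classes <- apply(d, 2, function(x) length(unique(x[!is.na(x)])))
  rm_mono <- keep & n_classes <= 1L
  keep <- keep & !rm_mono

  rare2 <- function(x) {
    tab <- table(x[!is.na(x)])
    if (length(tab) != 2L) return(FALSE)
    min(tab) / sum(tab) < rare_genotype_min
  }
  rm_rare <- keep & apply(d, 2, rare2)
  keep <- keep & !rm_rare

  rm_maf <- rep(FALSE, m0)
  if (!is.null(maf_min)) {
    maf <- colMeans(d, na.rm = TRUE) / 2
    maf <- pmin(maf, 1 - maf)
    rm_maf <- keep & maf < maf_min
    keep <- keep & !rm_maf
  }
  if (!any(keep))
    stop("QC removed every SNP; review thresholds (rare_genotype_min = ",
         rare_genotype_min, ", max_missing = ", max_missing, ")")
  report <- structure(list(
    n_input = m0,
    removed_missing = sum(rm_missing),
    removed_monomorphic = sum(rm_mono),
    removed_rare_genotype = sum(rm_rare),
    removed_maf = sum(rm_maf),
    n_retained = sum(keep),
    removed_ids = g$map$snp_id[!keep]
  ), class = "qc_report")
  out <- genotype_matrix(d[, keep, drop = FALSE], g$map[keep, , drop = FALSE])
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("SNP QC:", x$n_input, "input;",
      x$removed_missing, "removed (missing),",
      x$removed_monomorphic, "(monomorphic),",
      x$removed_rare_genotype, "(rare genotype class),",
      x$removed_maf, "(MAF);",
      x$n_retained, "retained\n")
  invisible(x)
}

#' Write a QC report as TSV
#' @param report A `qc_report`.
#' @param path Output path.
#' @export
write_qc_report <- function(report, path) {
  df <- data.frame(rule = c("input", "missing", "monomorphic",
                            "rare_genotype", "maf", "retained"),
                   n = c(report$n_input, report$removed_missing,
                         report$removed_monomorphic, report$removed_rare_genotype,
                         report$removed_maf, report$n_retained))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Construct a longitudinal phenotype table
#'
#' Two traits (triglycerides and HDL, mg/dL on the raw scale) at four visits;
#' visits 1-2 are pre-treatment and 3-4 post-treatment.
#'
#' @param iid Character vector of individual ids.
#' @param tg,hdl n x 4 numeric matrices (NA = missing visit).
#' @param scale `"raw"` (strictly positive values required) or
#'   `"transformed"`.
#' @return A `long_phenotypes` list with elements `iid`, `tg`, `hdl`,
#'   `pre` (= 1:2), `post` (= 3:4) and `scale`.
#' @export
long_phenotypes <- function(iid, tg, hdl, scale = c("raw", "transformed")) {
  scale <- match.arg(scale)
  tg <- as.matrix(tg); hdl <- as.matrix(hdl)
  stopifnot(length(iid) == nrow(tg), nrow(tg) == nrow(hdl),
            ncol(tg) == 4, ncol(hdl) == 4)
  if (scale == "raw") {
    for (nm in c("tg", "hdl")) {
      v <- if (nm == "tg") tg else hdl
      bad <- which(!is.na(v) & v <= 0, arr.ind = TRUE)
      if (nrow(bad))
        stop("nonpositive raw ", nm, " value for individual ",
             iid[bad[1, 1]], ", visit ", bad[1, 2],
             " (log-log transform undefined)")
    }
  }
  dimnames(tg) <- list(iid, paste0("tg_v", 1:4))
  dimnames(hdl) <- list(iid, paste0("hdl_v", 1:4))
  structure(list(iid = as.character(iid), tg = tg, hdl = hdl,
                 pre = 1:2, post = 3:4, scale = scale),
            class = "long_phenotypes")
}

#' Read / write the longitudinal phenotype TSV
#'
#' TSV with header `iid tg_v1..tg_v4 hdl_v1..hdl_v4`; blank cells are
#' missing visits. Raw values must be strictly positive.
#'
#' @param path File path.
#' @param ped Optional `fam_pedigree` for id validation.
#' @return A `long_phenotypes` object.
#' @export
read_phenotypes <- function(path, ped = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", rep("numeric", 8)),
                          na.strings = c("", "NA"))
  need <- c("iid", paste0("tg_v", 1:4), paste0("hdl_v", 1:4))
  if (!identical(names(df), need))
    stop("phenotype TSV must have header: ", paste(need, collapse = " "))
  if (!is.null(ped)) {
    unknown <- setdiff(df$iid, ped$id)
    if (length(unknown))
      stop("phenotype id(s) absent from pedigree: ",
           paste(unknown, collapse = ", "))
  }
  long_phenotypes(df$iid, as.matrix(df[, 2:5]), as.matrix(df[, 6:9]))
}

#' @rdname read_phenotypes
#' @param p A `long_phenotypes` object.
#' @export
write_phenotypes <- function(p, path) {
  df <- data.frame(iid = p$iid,
                   format(cbind(p$tg, p$hdl), digits = 17, trim = TRUE),
                   check.names = FALSE)
  df[df == "NA"] <- ""
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read / write the covariate TSV
#'
#' TSV with header `iid age smoking`; no missing values are allowed after
#' validation. `smoking` is 0/1.
#'
#' @param path File path.
#' @param ped Optional `fam_pedigree` for id validation.
#' @return A `covariate_table` data frame with columns `iid`, `age`,
#'   `smoking`.
#' @export
read_covariates <- function(path, ped = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "numeric", "numeric"),
                          na.strings = c("", "NA"))
  if (!all(c("iid", "age", "smoking") %in% names(df)))
    stop("covariate TSV must have header: iid age smoking")
  covariate_table(df)
}

#' @rdname read_covariates
#' @param records Data frame with columns `iid`, `age`, `smoking`.
#' @export
covariate_table <- function(records) {
  df <- as.data.frame(records, stringsAsFactors = FALSE)
  stopifnot(all(c("iid", "age", "smoking") %in% names(df)))
  if (anyDuplicated(df$iid)) stop("duplicate iid in covariates")
  if (anyNA(df[, c("age", "smoking")]))
    stop("missing covariate values are not allowed")
  if (!all(df$smoking %in% c(0, 1))) stop("smoking must be 0/1")
  class(df) <- c("covariate_table", "data.frame")
  df
}

#' @rdname read_covariates
#' @param covar A `covariate_table`.
#' @export
write_covariates <- function(covar, path) {
  utils::write.table(as.data.frame(covar), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Write a pedigree in FAM-like text
#' @param ped A `fam_pedigree`.
#' @param path Output path.
#' @export
write_pedigree <- function(ped, path) {
  sex_code <- c(male = "1", female = "2", unknown = "0")[ped$sex]
  df <- data.frame(ped$family, ped$id,
                   ifelse(is.na(ped$father), "0", ped$father),
                   ifelse(is.na(ped$mother), "0", ped$mother),
                   sex_code)
  utils::write.table(df, path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Write genotypes as a minimal VCF
#'
#' Emits a VCF v4.2 with GT fields only; the minor allele is written as ALT,
#' so reading the file back reproduces the dosage matrix.
#' @param g A `genotype_matrix`.
#' @param path Output path.
#' @export
write_genotypes_vcf <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(g$dosages)), collapse = "\t")),
             con)
  code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(g$dosages))) {
    dj <- g$dosages[, j]
    gt <- ifelse(is.na(dj), "./.", code[dj + 1])
    writeLines(paste(c(g$map$chrom[j], g$map$bp[j], g$map$snp_id[j],
                       "A", "C", ".", "PASS", ".", "GT", gt), collapse = "\t"),
               con)
  }
  invisible(path)
}
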