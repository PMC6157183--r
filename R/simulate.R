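#' Simulate a multigenerational family pedigree
#'
#' Deterministic given the seed. `nuclear` families have two founder
#' parents and `k_children` children; `three_generation` families have four
#' founder grandparents, two of their children married to founder spouses
#' is not modeled — instead the two middle-generation parents are one child
#' of each grandparental couple, and they have `k_children` children, so
#' grandparent-grandchild and first-cousin-free structures arise naturally.
#'
#' @param n_families Number of families.
#' @param design `"nuclear"` or `"three_generation"`.
#' @param k_children Children in the youngest generation (default 2).
#' @param seed Integer seed (`NULL` leaves the RNG state alone).
#' @return A `fam_pedigree`.
#' @export
sim_pedigree <- function(n_families, design = c("nuclear", "three_generation"),
                         k_children = 2, seed = NULL) {
  design <- match.arg(design)
  if (!is.null(seed)) set.seed(seed)
  recs <- vector("list", n_families)
  for (f in seq_len(n_families)) {
    fam <- sprintf("F%04d", f)
    id <- function(s) paste0(fam, "_", s)
    if (design == "nuclear") {
      df <- data.frame(
        id = id(c("fa", "mo", sprintf("c%d", seq_len(k_children)))),
        father = c(NA, NA, rep(id("fa"), k_children)),
        mother = c(NA, NA, rep(id("mo"), k_children)),
        sex = c("male", "female",
                ifelse(stats::runif(k_children) < 0.5, "male", "female")),
        family = fam, stringsAsFactors = FALSE)
    } else {
      df <- data.frame(
        id = id(c("gf1", "gm1", "gf2", "gm2", "fa", "mo",
                  sprintf("c%d", seq_len(k_children)))),
        father = c(NA, NA, NA, NA, id("gf1"), id("gf2"),
                   rep(id("fa"), k_children)),
        mother = c(NA, NA, NA, NA, id("gm1"), id("gm2"),
                   rep(id("mo"), k_children)),
        sex = c("male", "female", "male", "female", "male", "female",
                ifelse(stats::runif(k_children) < 0.5, "male", "female")),
        family = fam, stringsAsFactors = FALSE)
    }
    recs[[f]] <- df
  }
  pedigree(do.call(rbind, recs))
}

#' Simulate Mendelian genotypes by gene dropping
#'
#' Founder alleles are drawn per SNP at the given minor-allele frequency
#' under Hardy-Weinberg; each non-founder inherits one uniformly chosen
#' allele from each parent (gene dropping), so genotype correlations between
#' relatives follow the kinship structure. Dosages count the simulated
#' minor allele. SNPs are laid out on chromosomes 1-22 cyclically at 10 kb
#' spacing.
#'
#' @param ped A `fam_pedigree`.
#' @param m_snps Number of SNPs.
#' @param maf_range Range of per-SNP minor-allele frequencies, drawn
#'   uniformly (default `c(0.05, 0.5)`).
#' @param seed Integer seed.
#' @return A `genotype_matrix` with rows in pedigree order.
#' @export
sim_genotypes <- function(ped, m_snps, maf_range = c(0.05, 0.5), seed = NULL) {
  stopifnot(inherits(ped, "fam_pedigree"),
            maf_range[1] > 0, maf_range[2] <= 0.5)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(ped)
  maf <- stats::runif(m_snps, maf_range[1], maf_range[2])
  ord <- .topo_order(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  fa <- idx[ped$father]; mo <- idx[ped$mother]
  A1 <- matrix(0L, n, m_snps)
  A2 <- matrix(0L, n, m_snps)
  for (i in ord) {
    if (is.na(fa[i])) {
      A1[i, ] <- stats::rbinom(m_snps, 1, maf)
    } else {
      pick <- stats::runif(m_snps) < 0.5
      A1[i, ] <- ifelse(pick, A1[fa[i], ], A2[fa[i], ])
    }
    if (is.na(mo[i])) {
      A2[i, ] <- stats::rbinom(m_snps, 1, maf)
    } else {
      pick <- stats::runif(m_snps) < 0.5
      A2[i, ] <- ifelse(pick, A1[mo[i], ], A2[mo[i], ])
    }
  }
  d <- A1 + A2
  rownames(d) <- ped$id
  chrom <- as.character(rep_len(1:22, m_snps))
  bp <- integer(m_snps)
  for (cc in unique(chrom)) {
    ii <- which(chrom == cc)
    bp[ii] <- 10000L * seq_along(ii)
  }
  map <- data.frame(snp_id = sprintf("snp%05d", seq_len(m_snps)),
                    chrom = chrom, bp = bp, stringsAsFactors = FALSE)
  genotype_matrix(d * 1.0, map)
}

#' Default variance components for simulated longitudinal traits
#'
#' Moderate-heritability defaults on the doubly-log scale: polygenic
#' variance 0.4 and residual variance 0.6 per trait (heritability 0.4, in
#' the range reported for lipid traits), genetic correlation 0.4,
#' environmental correlation 0.3, and decaying adjacent-visit correlations
#' (0.7, 0.6, 0.5) for both traits.
#' @return A `bivar_vc`.
#' @export
default_bivar_vc <- function() {
  bivar_vc(sigma2_u = c(0.4, 0.4), rho_g = 0.4, sigma2_e = c(0.6, 0.6),
           markov_t1 = c(0.7, 0.6, 0.5), markov_t2 = c(0.7, 0.6, 0.5),
           rho_eps = 0.3)
}

#' Simulate longitudinal bivariate phenotypes from the model
#'
#' Draws `Y ~ N(X beta, C1 kron I + C2 kron K)` through the structured-
#' covariance sampler, then (by default) inverts the log-log transform so
#' the raw-scale output round-trips through the preprocessing pipeline.
#' Visit means default to plausible doubly-logged TG and HDL levels with a
#' small post-treatment TG drop.
#'
#' @param ped A `fam_pedigree` (kinship is computed internally unless `K`
#'   is supplied).
#' @param G Optional `genotype_matrix` holding the causal SNP.
#' @param causal Optional list `snp_id`, `beta_tg`, `beta_hdl`: per-copy
#'   additive effect of the causal SNP on each trait.
#' @param vc_truth A `bivar_vc` (default [default_bivar_vc()]).
#' @param visit_means 4 x 2 matrix of visit means (columns TG, HDL).
#' @param missing_rate Completely-at-random per-cell missingness in `[0, 1)`.
#' @param output `"raw"` (default) or `"transformed"`.
#' @param seed Integer seed.
#' @param K Optional precomputed `kinship_matrix` or [kinship_eigen()] list.
#' @return A `long_phenotypes`.
#' @export
sim_longitudinal <- function(ped, G = NULL, causal = NULL,
                             vc_truth = default_bivar_vc(),
                             visit_means = cbind(tg = c(1.53, 1.53, 1.50, 1.50),
                                                 hdl = c(1.36, 1.36, 1.38, 1.38)),
                             missing_rate = 0, output = c("raw", "transformed"),
                             seed = NULL, K = NULL) {
  output <- match.arg(output)
  stopifnot(missing_rate >= 0, missing_rate < 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(K)) K <- compute_kinship(ped)
  sc <- build_structured_cov(vc_truth, K)
  n <- sc$n
  M <- matrix(c(visit_means[, 1], visit_means[, 2]), 8, n)
  if (!is.null(causal)) {
    stopifnot(!is.null(G), causal$snp_id %in% colnames(G$dosages))
    g <- G$dosages[ped$id, causal$snp_id]
    M[1:4, ] <- M[1:4, ] + rep(causal$beta_tg * g, each = 4)
    M[5:8, ] <- M[5:8, ] + rep(causal$beta_hdl * g, each = 4)
  }
  Y <- sample_structured(sc, M)
  if (missing_rate > 0) {
    drop <- matrix(stats::runif(8 * n) < missing_rate, 8, n)
    Y[drop] <- NA
  }
  tg <- t(Y[1:4, , drop = FALSE])
  hdl <- t(Y[5:8, , drop = FALSE])
  p <- long_phenotypes(ped$id, tg, hdl, scale = "transformed")
  if (output == "raw") loglog_inverse(p) else p
}

#' Simulate the treatment-response phenotype from the Henderson model
#'
#' Draws `Y = X beta + u + e` with `u ~ N(0, sigma2_g K)` and
#' `e ~ N(0, sigma2_e R)`. Covariates default to age uniform on 20-70
#' years and smoking Bernoulli(0.3).
#'
#' @param ped A `fam_pedigree`.
#' @param G Optional `genotype_matrix` holding causal SNPs.
#' @param beta Named fixed effects: `intercept`, `age`, `smoking` (defaults
#'   -0.05, 0.001, 0.02).
#' @param causal Optional list `snp_id`, `beta` (per-copy SNP effect).
#' @param sigma2_g,sigma2_e Variance components (defaults 0.4, 0.6).
#' @param R Optional residual correlation matrix (default identity).
#' @param seed Integer seed.
#' @param K Optional precomputed `kinship_matrix`.
#' @return List with `response` (a `response_vector`-compatible named
#'   vector wrapped as one), `covariates` (a `covariate_table`) and
#'   `u` (the simulated polygenic effects).
#' @export
sim_response <- function(ped, G = NULL,
                         beta = c(intercept = -0.05, age = 0.001,
                                  smoking = 0.02),
                         causal = NULL, sigma2_g = 0.4, sigma2_e = 0.6,
                         R = NULL, seed = NULL, K = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(ped)
  if (is.null(K)) K <- compute_kinship(ped)
  age <- sample(20:70, n, replace = TRUE)
  smoking <- stats::rbinom(n, 1, 0.3)
  mu <- beta["intercept"] + beta["age"] * age + beta["smoking"] * smoking
  if (!is.null(causal)) {
    stopifnot(!is.null(G), causal$snp_id %in% colnames(G$dosages))
    mu <- mu + causal$beta * G$dosages[ped$id, causal$snp_id]
  }
  ke <- kinship_eigen(K)
  u <- as.vector(ke$vectors %*% (sqrt(pmax(ke$values, 0) * sigma2_g) *
                                   stats::rnorm(n)))
  e <- if (is.null(R)) stats::rnorm(n, sd = sqrt(sigma2_e)) else
    as.vector(t(chol(R)) %*% stats::rnorm(n)) * sqrt(sigma2_e)
  yv <- stats::setNames(as.numeric(mu) + u + e, ped$id)
  resp <- structure(list(response = yv,
                         excluded = data.frame(iid = character(0),
                                               reason = character(0)),
                         trait = "tg", direction = "post_minus_pre"),
                    class = "response_vector")
  covar <- covariate_table(data.frame(iid = ped$id, age = age,
                                      smoking = smoking,
                                      stringsAsFactors = FALSE))
  list(response = resp, covariates = covar, u = u)
}

#' Derive reproducible per-component substreams from a root seed
#'
#' Small fixed offsets from one root seed so that pedigree, genotype and
#' phenotype draws can be regenerated independently; kept below 2^31.
#' @param seed Integer root seed.
#' @return Named integer vector of derived seeds.
#' @export
derive_seeds <- function(seed) {
  stats::setNames(as.integer((as.numeric(seed) * 7 + c(1, 3, 5, 7, 11)) %%
                               2147483647L),
                  c("pedigree", "genotypes", "longitudinal", "response",
                    "extra"))
}
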