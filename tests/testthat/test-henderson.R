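rand_henderson <- function(n_fams = 10, k_children = 2, q_extra = 2,
                           use_R = FALSE, use_family_Z = FALSE) {
  ped <- sim_pedigree(n_fams, "nuclear", k_children = k_children)
  K <- compute_kinship(ped)
  n <- nrow(ped)
  X <- cbind(intercept = 1, matrix(rnorm(n * q_extra), n,
                                   dimnames = list(NULL, paste0("x", 1:q_extra))))
  R <- NULL
  if (use_R) {
    A <- matrix(rnorm(n * n), n, n)
    R <- crossprod(A) / n + diag(n)
  }
  Z <- NULL; Ku <- K
  if (use_family_Z) {
    fams <- factor(ped$family)
    Z <- stats::model.matrix(~ fams - 1)
    Ku <- structure(diag(nlevels(fams)), class = class(K),
                    dimnames = list(levels(fams), levels(fams)))
  }
  sg <- runif(1, 0.3, 2); se <- runif(1, 0.3, 2)
  blup <- dense_gls_blup(rep(0, n), X, Ku, Z, R, sg, se)  # just for V
  y <- as.vector(X %*% rnorm(ncol(X)) + t(chol(blup$V)) %*% rnorm(n))
  list(m = henderson_model(y, X, Ku, Z = Z, R = R), K = Ku, Z = Z, R = R,
       sg = sg, se = se, y = y, X = X)
}

test_that("MME block solve equals dense GLS and BLUP closed forms", {
  set.seed(51)
  for (i in 1:20) {
    d <- rand_henderson(n_fams = sample(5:12, 1),
                        use_R = i %% 3 == 0, use_family_Z = i %% 4 == 0)
    s <- solve_mme(d$m, d$sg, d$se)
    o <- dense_gls_blup(d$y, d$X, d$K, d$Z, d$R, d$sg, d$se)
    expect_lt(max(abs(s$beta - o$beta)), 1e-8)
    expect_lt(max(abs(s$u - o$u)), 1e-8)
  }
})

test_that("MME degenerates to OLS as the genetic component vanishes", {
  set.seed(52)
  d <- rand_henderson()
  s <- solve_mme(d$m, 1e-10, 1)
  ols <- lm.fit(d$X, d$y)$coefficients
  expect_lt(max(abs(s$beta - ols)), 1e-6)
  # perfect fit: beta recovered exactly, BLUPs vanish
  cvec <- c(2, -1, 0.5)
  yc <- as.vector(d$X %*% cvec)
  mc <- henderson_model(yc, d$X, d$K)
  sc <- solve_mme(mc, 0.8, 0.6)
  expect_equal(unname(sc$beta), cvec, tolerance = 1e-8)
  expect_lt(max(abs(sc$u)), 1e-8)
})

test_that("rank-deficient fixed designs are rejected by name", {
  ped <- sim_pedigree(4, "nuclear", seed = 53)
  K <- compute_kinship(ped)
  X <- cbind(intercept = 1, dup1 = rep(2, 16), stringsAsFactors = NULL)
  expect_error(henderson_model(rnorm(16), X, K), "rank deficient")
})

test_that("EM-REML is monotone and recovers a balanced-sibship closed form", {
  # families of k sibs: kinship 0.25 off-diagonal maps the model onto the
  # balanced one-way random-effects layout with sigma_a^2 = sg / 4 and
  # sigma_w^2 = se + sg / 4, whose REML estimates are the ANOVA ones
  set.seed(54)
  n_fam <- 40; k <- 3
  fam <- rep(seq_len(n_fam), each = k)
  Kb <- structure(kronecker(diag(n_fam), 0.25 * diag(k) + 0.25),
                  dimnames = list(paste0("i", 1:(n_fam * k)),
                                  paste0("i", 1:(n_fam * k))),
                  family = fam, class = c("kinship_matrix", "matrix", "array"))
  sg <- 1.2; se <- 0.5
  a <- rnorm(n_fam, sd = sqrt(sg / 4))
  y <- 3 + a[fam] + rnorm(n_fam * k, sd = sqrt(se + sg / 4))
  m <- henderson_model(y, cbind(intercept = rep(1, n_fam * k)), Kb)
  fit <- em_reml(m, tol = 1e-10, max_iter = 5000)
  expect_true(fit$converged)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  gm <- tapply(y, fam, mean)
  msb <- k * sum((gm - mean(y))^2) / (n_fam - 1)
  msw <- sum((y - gm[fam])^2) / (n_fam * (k - 1))
  sa2 <- (msb - msw) / k                      # ANOVA = REML when interior
  expect_equal(fit$sigma2_g, 4 * sa2, tolerance = 1e-4)
  expect_equal(fit$sigma2_e, msw - sa2, tolerance = 1e-4)
})

test_that("structurally confounded models are refused", {
  n <- 20
  K <- structure(diag(n), dimnames = list(paste0("i", 1:n), paste0("i", 1:n)),
                 class = c("kinship_matrix", "matrix", "array"))
  m <- henderson_model(rnorm(n), cbind(intercept = rep(1, n)), K)
  expect_error(em_reml(m), "not identifiable")
})

test_that("EM-REML supports a non-diagonal residual correlation", {
  set.seed(55)
  ped <- sim_pedigree(30, "nuclear")
  K <- compute_kinship(ped)
  R <- residual_exchangeable(ped$family, 0.2)
  sr <- sim_response(ped, sigma2_g = 0.8, sigma2_e = 0.5, R = R, K = K)
  m <- henderson_model(sr$response$response,
                       cbind(intercept = 1, age = sr$covariates$age,
                             smoking = sr$covariates$smoking), K, R = R)
  fit <- em_reml(m)
  expect_true(fit$converged)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  # the fitted components reproduce the MME solution
  s <- solve_mme(m, fit$sigma2_g, fit$sigma2_e)
  expect_equal(unname(fit$beta), unname(s$beta), tolerance = 1e-6)
  expect_error(residual_exchangeable(ped$family, 0.99999999 + 1e-9), NA)
  expect_error(residual_exchangeable(ped$family, -0.9), "positive-definite")
})

test_that("F-test satisfies the Wald identity and the OLS partial-F reduction", {
  set.seed(56)
  d <- rand_henderson()
  fit <- em_reml(d$m)
  q <- ncol(d$X)
  # p = 1: F equals the squared Wald ratio of that coefficient
  Msel <- matrix(c(rep(0, q - 1), 1), 1, q)
  ft <- f_test(fit, Msel)
  wald2 <- fit$beta[q]^2 / solve(fit$XtVinvX)[q, q]
  expect_equal(ft$f_stat, as.numeric(wald2), tolerance = 1e-10)
  expect_equal(ft$df1, 1L)
  expect_equal(ft$df2, fit$n - q)
  # a contrast orthogonal to beta-hat gives F = 0, p = 1
  v <- c(-fit$beta[2], fit$beta[1], 0)
  ft0 <- f_test(fit, matrix(v, 1, q))
  expect_lt(ft0$f_stat, 1e-20)
  expect_equal(ft0$p_value, 1)
  # sigma2_g = 0, R = I with the REML residual variance: classical partial F
  rss <- sum(lm.fit(d$X, d$y)$residuals^2)
  glsfit <- henderson_gls(d$m, 0, rss / (fit$n - q))
  fto <- f_test(glsfit, Msel)
  sm <- summary(lm(d$y ~ d$X[, -1]))
  expect_equal(fto$f_stat, sm$coefficients[q, 3]^2, tolerance = 1e-10)
  expect_equal(fto$p_value, sm$coefficients[q, 4], tolerance = 1e-10)
  expect_error(f_test(fit, rbind(Msel, Msel)), "full row rank")
})

test_that("response scan pinpoints a planted SNP and records failures", {
  ped <- sim_pedigree(50, "nuclear", seed = 57)  # n = 200
  K <- compute_kinship(ped)
  G <- sim_genotypes(ped, 10, maf_range = c(0.2, 0.5), seed = 58)
  causal_id <- G$map$snp_id[4]
  sr <- sim_response(ped, G = G, causal = list(snp_id = causal_id, beta = 0.5),
                     sigma2_g = 0.4, sigma2_e = 0.6, seed = 59, K = K)
  # inject a constant column
  d <- G$dosages; d[, 7] <- 1
  Gc <- genotype_matrix(d, G$map)
  scan <- gwas_response(sr$response, sr$covariates, Gc, K)
  expect_equal(scan$unit_id[which.min(scan$p)], causal_id)
  const_row <- scan[scan$unit_id == G$map$snp_id[7], ]
  expect_true(is.na(const_row$p))
  expect_match(const_row$reason, "constant")
  # shared-components approximation agrees on the top SNP
  scan2 <- gwas_response(sr$response, sr$covariates, Gc, K, refit = FALSE)
  expect_equal(scan2$unit_id[which.min(scan2$p)], causal_id)
})

test_that("region tests reduce to single-SNP scans and are order-invariant", {
  ped <- sim_pedigree(40, "nuclear", seed = 60)
  K <- compute_kinship(ped)
  G <- sim_genotypes(ped, 6, maf_range = c(0.2, 0.5), seed = 61)
  sr <- sim_response(ped, sigma2_g = 0.4, sigma2_e = 0.6, seed = 62, K = K)
  one <- list(region_id = "r1", pruned_snp_ids = G$map$snp_id[2])
  rt <- region_test(sr$response, sr$covariates, one, G, K)
  scan <- gwas_response(sr$response, sr$covariates, G, K)
  expect_equal(rt$p_value, scan$p[scan$unit_id == G$map$snp_id[2]],
               tolerance = 1e-10)
  # order invariance
  r3a <- region_test(sr$response, sr$covariates,
                     list(region_id = "r3", pruned_snp_ids = G$map$snp_id[1:3]),
                     G, K)
  r3b <- region_test(sr$response, sr$covariates,
                     list(region_id = "r3", pruned_snp_ids = G$map$snp_id[3:1]),
                     G, K)
  expect_equal(r3a$p_value, r3b$p_value, tolerance = 1e-10)
  expect_equal(r3a$df1, 3L)
  # collinear SNP columns are dropped with a warning, then retested
  d <- cbind(G$dosages, dupe = G$dosages[, 1])
  Gd <- genotype_matrix(d, rbind(G$map, data.frame(snp_id = "dupe",
                                                   chrom = "22",
                                                   bp = 999L)))
  expect_warning(
    rdup <- region_test(sr$response, sr$covariates,
                        list(region_id = "rd",
                             pruned_snp_ids = c(G$map$snp_id[1], "dupe")),
                        Gd, K),
    "collinear")
  expect_equal(rdup$df1, 1L)
  # saturated designs are refused
  suppressWarnings(
    expect_error(region_test(sr$response[["response"]][1:8],
                             sr$covariates[1:8, ],
                             list(region_id = "rs",
                                  pruned_snp_ids = G$map$snp_id[1:6]),
                             G, K),
                 "saturated|rank deficient"))
})
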