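bivar_test_data <- local({
  ped <- sim_pedigree(25, "nuclear", k_children = 2, seed = 41)  # n = 100
  K <- compute_kinship(ped)
  p <- sim_longitudinal(ped, output = "transformed", seed = 42, K = K)
  G <- sim_genotypes(ped, 3, seed = 43)
  list(ped = ped, K = K, Y = pheno_matrix(p), G = G)
})

test_that("alternative fit never falls below the nested null fit", {
  d <- bivar_test_data
  null_fit <- fit_bivar(d$Y, K = d$K, n_restarts = 1)
  expect_true(null_fit$converged)
  expect_identical(null_fit$fixed$beta_t1[5], 0)
  alt <- fit_bivar(d$Y, g = d$G$dosages[, 1], K = d$K,
                   constrain_snp_to_zero = FALSE, start_vc = null_fit$vc)
  expect_gte(alt$loglik, null_fit$loglik - 1e-6)
})

test_that("maximized likelihood matches an independent dense-oracle optimizer", {
  ped <- sim_pedigree(10, "nuclear", k_children = 1, seed = 44)  # n = 30
  K <- compute_kinship(ped)
  p <- sim_longitudinal(ped, output = "transformed", seed = 45, K = K)
  Y <- pheno_matrix(p)
  fit <- fit_bivar(Y, K = K)
  # oracle: generic Nelder-Mead on the dense multivariate-normal likelihood
  # with GLS-profiled means, started from several deterministic points
  n <- ncol(Y)
  X <- do.call(cbind, lapply(1:8, function(r) {
    D <- matrix(0, 8, n); D[r, ] <- 1; bivar_vec(D)
  }))
  yv <- bivar_vec(Y)
  dense_negll <- function(theta) {
    vc <- famgwas:::.theta_to_vc(theta)
    V <- dense_bivar_cov(vc, K)
    Vi <- tryCatch(solve(V), error = function(e) NULL)
    if (is.null(Vi)) return(1e10)
    beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% yv)
    r <- yv - X %*% beta
    0.5 * (8 * n * log(2 * pi) + determinant(V)$modulus[1] +
             sum(r * (Vi %*% r)))
  }
  th0 <- famgwas:::.vc_to_theta(famgwas:::.moment_start(Y))
  best <- Inf
  for (sc in c(1, 0.7, 1.3)) {
    o <- optim(th0 * sc, dense_negll, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-12))
    best <- min(best, o$value)
  }
  expect_lte(-fit$loglik, best + 1e-4)     # our optimum at least as good
  # and our reported loglik is the dense likelihood at our estimate
  expect_equal(-dense_negll(famgwas:::.vc_to_theta(fit$vc)), fit$loglik,
               tolerance = 1e-6)
})

test_that("optional per-trait covariates enter the fixed design correctly", {
  d <- bivar_test_data
  n <- ncol(d$Y)
  set.seed(401)
  z <- rnorm(n)
  Yc <- d$Y
  Yc[1:4, ] <- Yc[1:4, ] + rep(0.8 * z, each = 4)   # covariate hits TG only
  fit <- fit_bivar(Yc, K = d$K, covariates = cbind(age = z), n_restarts = 1)
  expect_equal(unname(fit$fixed$covariates["t1", "age"]), 0.8,
               tolerance = 0.15)
  expect_lt(abs(fit$fixed$covariates["t2", "age"]), 0.3)
  # adjusting for the covariate can only improve the likelihood
  fit0 <- fit_bivar(Yc, K = d$K, n_restarts = 1)
  expect_gte(fit$loglik, fit0$loglik - 1e-6)
  # and the profiled likelihood with covariates matches a dense GLS oracle
  vc <- default_bivar_vc()
  ke <- kinship_eigen(d$K)
  pr <- famgwas:::.bivar_prep(d$Y, ke, g = d$G$dosages[, 1],
                              covariates = cbind(z))
  r <- famgwas:::.bivar_profile_ll(vc, pr, TRUE)
  V <- dense_bivar_cov(vc, d$K)
  Xo <- do.call(cbind, lapply(1:8, function(rr) {
    D <- matrix(0, 8, n); D[rr, ] <- 1; bivar_vec(D)
  }))
  blocks <- function(v) cbind(bivar_vec(rbind(matrix(rep(v, 4), 4, byrow = TRUE),
                                              matrix(0, 4, n))),
                              bivar_vec(rbind(matrix(0, 4, n),
                                              matrix(rep(v, 4), 4, byrow = TRUE))))
  X2 <- cbind(Xo, blocks(d$G$dosages[, 1]), blocks(z))
  Vi <- solve(V)
  yv <- bivar_vec(d$Y)
  bet <- solve(t(X2) %*% Vi %*% X2, t(X2) %*% Vi %*% yv)
  res <- yv - X2 %*% bet
  ll_o <- -0.5 * (8 * n * log(2 * pi) + determinant(V)$modulus[1] +
                    sum(res * (Vi %*% res)))
  expect_equal(r$ll, as.numeric(ll_o), tolerance = 1e-8)
  expect_equal(r$beta, as.vector(bet), tolerance = 1e-8)
})

test_that("likelihood is invariant under consistent permutation of individuals", {
  d <- bivar_test_data
  vc <- default_bivar_vc()
  set.seed(46)
  perm <- sample(ncol(d$Y))
  ids_perm <- colnames(d$Y)[perm]
  ll1 <- gaussian_loglik(d$Y, 1.4, build_structured_cov(vc, d$K))
  ll2 <- gaussian_loglik(d$Y[, perm], 1.4,
                         build_structured_cov(vc, kinship_subset(d$K, ids_perm)))
  expect_lt(abs(ll1 - ll2), 1e-9)
})

test_that("LRT statistics are nonnegative with chi-square(2) p-values", {
  d <- bivar_test_data
  null_fit <- fit_bivar(d$Y, K = d$K, n_restarts = 1)
  for (j in 1:3) {
    r <- lrt_snp(d$Y, d$G$dosages[, j], d$K, null_fit = null_fit,
                 mode = "full_refit", snp_id = d$G$map$snp_id[j])
    expect_gte(r$lrt_stat, 0)
    expect_equal(r$df, 2L)
    expect_equal(r$p_value,
                 pchisq(r$lrt_stat, 2, lower.tail = FALSE))
    rf <- lrt_snp(d$Y, d$G$dosages[, j], d$K, null_fit = null_fit,
                  mode = "fixed_vc")
    expect_gte(r$lrt_stat, rf$lrt_stat - 1e-6)  # fixed-vc is conservative
  }
  expect_error(fit_bivar(d$Y, g = rep(1, ncol(d$Y)), K = d$K,
                         constrain_snp_to_zero = FALSE), "constant genotype")
})

test_that("the scan ranks a strongly planted SNP first in both modes", {
  ped <- sim_pedigree(35, "nuclear", seed = 47)  # n = 140
  K <- compute_kinship(ped)
  G <- sim_genotypes(ped, 12, maf_range = c(0.2, 0.5), seed = 48)
  causal_id <- G$map$snp_id[5]
  p <- sim_longitudinal(ped, G = G,
                        causal = list(snp_id = causal_id, beta_tg = 0.6,
                                      beta_hdl = 0.5),
                        output = "transformed", seed = 49, K = K)
  Y <- pheno_matrix(p)
  scan_fast <- gwas_longitudinal(Y, G, K, mode = "fixed_vc")
  expect_equal(scan_fast$snp_id[which.min(scan_fast$p)], causal_id)
  scan_full <- gwas_longitudinal(Y, G, K, mode = "full_refit")
  expect_equal(scan_full$snp_id[which.min(scan_full$p)], causal_id)
  expect_true(all(scan_full$df == 2))
  # empty genotype matrix: empty result, no error
  G0 <- genotype_matrix(matrix(numeric(0), nrow(ped), 0),
                        data.frame(snp_id = character(0),
                                   chrom = character(0), bp = integer(0)))
  expect_equal(nrow(gwas_longitudinal(Y, G0, K)), 0)
})
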