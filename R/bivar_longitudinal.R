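.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# unconstrained parameterization of the 12 variance parameters:
# log-variances and atanh-correlations, in the order
# (su1, su2, rho_g, se1, se2, m1 (3), m2 (3), rho_eps)
.vc_to_theta <- function(vc) {
  c(log(vc$sigma2_u), atanh(vc$rho_g), log(vc$sigma2_e),
    atanh(vc$markov_t1), atanh(vc$markov_t2), atanh(vc$rho_eps))
}

.theta_to_vc <- function(theta) {
  # tanh/exp make any real theta a valid parameter set; skip re-validation
  structure(list(sigma2_u = exp(theta[1:2]), rho_g = tanh(theta[3]),
                 sigma2_e = exp(theta[4:5]), markov_t1 = tanh(theta[6:8]),
                 markov_t2 = tanh(theta[9:11]), rho_eps = tanh(theta[12])),
            class = "bivar_vc")
}

.markov4 <- function(r) {
  m13 <- r[1] * r[2]; m24 <- r[2] * r[3]; m14 <- m13 * r[3]
  matrix(c(1, r[1], m13, m14,
           r[1], 1, r[2], m24,
           m13, r[2], 1, r[3],
           m14, m24, r[3], 1), 4, 4)
}

# Simultaneous diagonalization of the 8x8 per-individual blocks.
# C1 factorizes exactly as blkdiag(R1, R2) (Mrho kron I4) blkdiag(R1, R2)
# with R_t the symmetric root of sigma2_e[t] * Markov_t and
# Mrho = [[1, rho_eps], [rho_eps, 1]] (eigenvalues 1 +/- rho_eps), so C1 is
# positive definite whenever all correlations are inside (-1, 1) and the
# whitening W1 (W1 C1 W1' = I) is assembled from analytic 2x2 pieces.
# C2 = Sigma_u kron J4 is PSD, hence every C1 + lambda C2 is PD.
.simdiag <- function(vc, with_inverse = TRUE) {
  s1 <- vc$sigma2_e[1]; s2 <- vc$sigma2_e[2]; rho <- vc$rho_eps
  E1 <- eigen(.markov4(vc$markov_t1), symmetric = TRUE)
  E2 <- eigen(.markov4(vc$markov_t2), symmetric = TRUE)
  if (min(E1$values, E2$values) <= 1e-12) return(NULL)
  R1i <- E1$vectors %*% ((1 / sqrt(E1$values * s1)) * t(E1$vectors))
  R2i <- E2$vectors %*% ((1 / sqrt(E2$values * s2)) * t(E2$vectors))
  ah <- 1 / sqrt(1 + rho); al <- 1 / sqrt(1 - rho)
  d1 <- (ah + al) / 2; d2 <- (ah - al) / 2
  W1 <- rbind(cbind(d1 * R1i, d2 * R2i), cbind(d2 * R1i, d1 * R2i))
  su1 <- vc$sigma2_u[1]; su2 <- vc$sigma2_u[2]; rg <- vc$rho_g
  # C2 = F F' with F = chol(Sigma_u) kron 1_4; B = W1 C2 W1' has rank <= 2
  Fm <- rbind(matrix(c(sqrt(su1), 0), 4, 2, byrow = TRUE),
              matrix(c(rg * sqrt(su2), sqrt(su2 * (1 - rg^2))), 4, 2,
                     byrow = TRUE))
  G <- W1 %*% Fm
  eB <- eigen(tcrossprod(G), symmetric = TRUE)
  logdetC1 <- 4 * (log1p(-rho^2) + log(s1) + log(s2)) +
    sum(log(E1$values)) + sum(log(E2$values))
  out <- list(T = t(eB$vectors) %*% W1, delta = pmax(eB$values, 0),
              logdetC1 = logdetC1, Tinv = NULL)
  if (with_inverse) {
    R1 <- E1$vectors %*% (sqrt(E1$values * s1) * t(E1$vectors))
    R2 <- E2$vectors %*% (sqrt(E2$values * s2) * t(E2$vectors))
    b1 <- sqrt(1 + rho); b2 <- sqrt(1 - rho)
    f1 <- (b1 + b2) / 2; f2 <- (b1 - b2) / 2
    Winv <- rbind(cbind(f1 * R1, f2 * R1), cbind(f2 * R2, f1 * R2))
    out$Tinv <- Winv %*% eB$vectors
  }
  out
}

# per-dataset precomputation: phenotypes and design vectors rotated onto the
# kinship eigenbasis (computed once; every likelihood evaluation reuses it).
# Extra design columns beyond the visit means (the SNP, optional covariates)
# all factor as (trait-block indicator) x (per-individual vector); zmat holds
# the distinct rotated individual vectors and `extras` maps each extra fixed
# effect to (trait rows, z column).
.bivar_prep <- function(Y, ke, g = NULL, covariates = NULL) {
  zmat <- NULL
  extras <- list()
  add_z <- function(z) {
    zmat <<- cbind(zmat, as.vector(crossprod(z, ke$vectors)))
    ncol(zmat)
  }
  if (!is.null(g)) {
    j <- add_z(g)
    extras <- c(extras, list(list(rows = 1:4, z = j),
                             list(rows = 5:8, z = j)))
  }
  if (!is.null(covariates)) {
    for (k in seq_len(ncol(covariates))) {
      j <- add_z(covariates[, k])
      extras <- c(extras, list(list(rows = 1:4, z = j),
                               list(rows = 5:8, z = j)))
    }
  }
  list(Yr = Y %*% ke$vectors, ones_rot = colSums(ke$vectors),
       zmat = zmat, extras = extras, lambda = pmax(ke$values, 0),
       n = ncol(Y))
}

# profiled Gaussian log-likelihood at variance components vc: the fixed
# effects (4 visit means per trait, plus any extras) are concentrated out by
# GLS in the doubly rotated basis. Every design column factors as
# (T s_c) x (rotated individual vector), so the normal equations collapse to
# 8x8 algebra: A[c,d] = sum_i ts_c,i ts_d,i q_i with q = Dinv %*% (z_c * z_d).
.bivar_profile_ll <- function(vc, prep, include_extras = FALSE) {
  sd8 <- .simdiag(vc, with_inverse = FALSE)
  if (is.null(sd8)) return(NULL)
  n <- prep$n
  Dmat <- 1 + outer(sd8$delta, prep$lambda)
  if (any(Dmat <= 0)) return(NULL)
  Dinv <- 1 / Dmat
  Yt <- sd8$T %*% prep$Yr
  YD <- Yt * Dinv
  q11 <- Dinv %*% (prep$ones_rot^2)
  A_mean <- crossprod(sd8$T, drop(q11) * sd8$T)
  b_mean <- crossprod(sd8$T, YD %*% prep$ones_rot)
  if (include_extras && length(prep$extras)) {
    ex <- prep$extras
    E <- length(ex)
    TS <- vapply(ex, function(e) rowSums(sd8$T[, e$rows, drop = FALSE]),
                 numeric(8))
    # q vectors for the distinct (z_a, z_b) products, memoized
    nz <- ncol(prep$zmat)
    qz1 <- lapply(seq_len(nz), function(a)
      drop(Dinv %*% (prep$ones_rot * prep$zmat[, a])))
    qzz <- vector("list", nz * nz)
    get_qzz <- function(a, b) {
      key <- (min(a, b) - 1) * nz + max(a, b)
      if (is.null(qzz[[key]]))
        qzz[[key]] <<- drop(Dinv %*% (prep$zmat[, a] * prep$zmat[, b]))
      qzz[[key]]
    }
    hz <- lapply(seq_len(nz), function(a) drop(YD %*% prep$zmat[, a]))
    Amix <- matrix(0, 8, E)
    Aex <- matrix(0, E, E)
    bex <- numeric(E)
    for (e in seq_len(E)) {
      Amix[, e] <- crossprod(sd8$T, qz1[[ex[[e]]$z]] * TS[, e])
      bex[e] <- sum(TS[, e] * hz[[ex[[e]]$z]])
      for (f in e:E) {
        Aex[e, f] <- Aex[f, e] <-
          sum(TS[, e] * TS[, f] * get_qzz(ex[[e]]$z, ex[[f]]$z))
      }
    }
    A <- rbind(cbind(A_mean, Amix), cbind(t(Amix), Aex))
    b <- c(b_mean, bex)
  } else {
    A <- A_mean
    b <- drop(b_mean)
  }
  cA <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(cA)) return(NULL)
  v <- forwardsolve(t(cA), b)
  beta <- backsolve(cA, v)
  quad <- sum(Yt * YD) - sum(v * v)
  ll <- -0.5 * (8 * n * log(2 * pi) + n * sd8$logdetC1 + sum(log(Dmat)) + quad)
  list(ll = ll, beta = as.vector(beta))
}

# moment-based starting values from the stacked 8 x n phenotype matrix
.moment_start <- function(Y) {
  start_t <- function(rows) {
    S <- stats::cov(t(Y[rows, , drop = FALSE]))
    vt <- mean(diag(S))
    su <- 0.4 * vt
    se <- 0.6 * vt
    obs <- vapply(1:3, function(k) S[k, k + 1] / sqrt(S[k, k] * S[k + 1, k + 1]),
                  numeric(1))
    rho <- .clip((obs * vt - su) / se, -0.8, 0.9)
    list(su = su, se = se, rho = rho)
  }
  s1 <- start_t(1:4); s2 <- start_t(5:8)
  cc <- mean(vapply(1:4, function(v) stats::cor(Y[v, ], Y[4 + v, ]), numeric(1)))
  cc <- .clip(cc, -0.85, 0.85)
  bivar_vc(sigma2_u = c(s1$su, s2$su), rho_g = cc,
           sigma2_e = c(s1$se, s2$se), markov_t1 = s1$rho, markov_t2 = s2$rho,
           rho_eps = cc)
}

.start_list <- function(Y, n_restarts) {
  base <- .moment_start(Y)
  shrink <- bivar_vc(base$sigma2_u * 0.6, base$rho_g * 0.5,
                     base$sigma2_e * 0.8, base$markov_t1 * 0.5,
                     base$markov_t2 * 0.5, base$rho_eps * 0.5)
  inflate <- bivar_vc(base$sigma2_u * 1.8, .clip(base$rho_g * 1.4, -0.9, 0.9),
                      base$sigma2_e * 1.4, .clip(base$markov_t1 * 1.3, -0.9, 0.9),
                      .clip(base$markov_t2 * 1.3, -0.9, 0.9),
                      .clip(base$rho_eps * 1.4, -0.9, 0.9))
  list(base, shrink, inflate)[seq_len(min(n_restarts, 3))]
}

#' Fit the bivariate longitudinal mixed model
#'
#' Maximum-likelihood fit of the two-trait (TG, HDL) four-visit model: fixed
#' visit means per trait plus an optional shared-locus SNP effect per trait;
#' random polygenic effects with kinship covariance and cross-trait genetic
#' correlation; residuals with per-trait Markov-product temporal correlation
#' and cross-trait environmental correlation. The 12 variance parameters are
#' optimized quasi-Newton on log-variance / atanh-correlation scale with the
#' fixed effects profiled out by GLS at each proposal; proposals whose
#' implied covariance is not positive definite are rejected. ML (not REML)
#' is used so that likelihood-ratio tests on fixed effects are valid.
#'
#' @param y Complete transformed `long_phenotypes`, or an 8 x n matrix as
#'   from [pheno_matrix()].
#' @param g Optional numeric genotype dosage vector (length n).
#' @param K `kinship_matrix` for the same individuals in the same order, or
#'   a precomputed [kinship_eigen()] list.
#' @param constrain_snp_to_zero If `TRUE` the SNP effect is fixed at 0 (the
#'   null model); default `TRUE` when `g` is absent.
#' @param covariates Optional n x c numeric matrix appended to the fixed
#'   design with one effect per trait per column (off by default: the
#'   standard design holds only visit means and the SNP).
#' @param n_restarts Number of deterministic optimizer starts (moment-based,
#'   shrunk, inflated; default 3).
#' @param start_vc Optional `bivar_vc` used as the only start (overrides
#'   `n_restarts`), e.g. to warm-start alternative fits from the null.
#' @param maxit,factr Passed to [stats::optim()] (`L-BFGS-B`).
#' @return A `bivar_fit` list: `fixed` (list `beta_t1`, `beta_t2`, each
#'   visit means + SNP effect, the latter exactly 0 under the null), `vc`
#'   (a `bivar_vc`), `loglik`, `converged`, `iterations`.
#' @export
fit_bivar <- function(y, g = NULL, K, constrain_snp_to_zero = is.null(g),
                      covariates = NULL, n_restarts = 3, start_vc = NULL,
                      maxit = 300, factr = 1e7) {
  Y <- if (is.matrix(y)) y else pheno_matrix(y)
  n <- ncol(Y)
  include_snp <- !is.null(g) && !constrain_snp_to_zero
  if (include_snp) {
    stopifnot(length(g) == n)
    if (length(unique(g)) < 2)
      stop("constant genotype column (should have been removed by QC)")
  }
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n)
  }
  ke <- if (is.list(K) && !is.null(K$values)) K else kinship_eigen(K)
  prep <- .bivar_prep(Y, ke, g = if (include_snp) g else NULL,
                      covariates = covariates)
  has_extras <- length(prep$extras) > 0
  cache <- new.env(parent = emptyenv())
  negll <- function(theta) {
    r <- .bivar_profile_ll(.theta_to_vc(theta), prep, has_extras)
    val <- if (is.null(r) || !is.finite(r$ll)) 1e10 else -r$ll
    cache$theta <- theta
    cache$value <- val
    val
  }
  # forward-difference gradient reusing the cached objective at theta
  grad <- function(theta) {
    f0 <- if (!is.null(cache$theta) && identical(theta, cache$theta))
      cache$value else negll(theta)
    h <- 1e-6 * pmax(1, abs(theta))
    vapply(seq_along(theta), function(i) {
      th <- theta; th[i] <- th[i] + h[i]
      (negll(th) - f0) / h[i]
    }, numeric(1))
  }
  starts <- if (!is.null(start_vc)) list(start_vc) else .start_list(Y, n_restarts)
  best <- NULL
  iters <- 0L
  for (s in starts) {
    th0 <- .vc_to_theta(s)
    opt <- stats::optim(th0, negll, gr = grad, method = "L-BFGS-B",
                        lower = c(-15, -15, -6, -15, -15, rep(-6, 7)),
                        upper = c(15, 15, 6, 15, 15, rep(6, 7)),
                        control = list(maxit = maxit, factr = factr))
    iters <- iters + opt$counts[1]
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  vc_hat <- .theta_to_vc(best$par)
  fin <- .bivar_profile_ll(vc_hat, prep, has_extras)
  beta <- fin$beta
  if (include_snp) {
    fixed <- list(beta_t1 = c(beta[1:4], beta[9]),
                  beta_t2 = c(beta[5:8], beta[10]))
    nxt <- 10L
  } else {
    fixed <- list(beta_t1 = c(beta[1:4], 0), beta_t2 = c(beta[5:8], 0))
    nxt <- 8L
  }
  if (!is.null(covariates)) {
    fixed$covariates <- matrix(beta[(nxt + 1):length(beta)], nrow = 2,
                               dimnames = list(c("t1", "t2"),
                                               colnames(covariates)))
  }
  structure(list(fixed = fixed, vc = vc_hat, loglik = fin$ll,
                 converged = best$convergence == 0,
                 iterations = unname(iters), include_snp = include_snp),
            class = "bivar_fit")
}

#' Per-SNP likelihood-ratio test of the bivariate longitudinal model
#'
#' Tests no association of one SNP with the two traits jointly:
#' `stat = 2 * (loglik_alt - loglik_null)` with 2 degrees of freedom (the
#' SNP effect enters both traits), referred to the upper chi-square tail.
#' Small negative statistics from optimizer slack are clipped to 0 (with a
#' warning beyond 1e-6).
#'
#' @inheritParams fit_bivar
#' @param null_fit Optional precomputed null `bivar_fit` (reused across SNPs).
#' @param mode `"full_refit"` re-estimates all variance components under the
#'   alternative; `"fixed_vc"` holds them at the null estimates and refits
#'   only the fixed effects (a fast approximation, labeled in the result).
#' @param snp_id Identifier carried into the result.
#' @return An `lrt_result` list: `snp_id`, `lrt_stat`, `df` (= 2), `p_value`,
#'   `converged`, `mode`.
#' @export
lrt_snp <- function(y, g, K, null_fit = NULL, mode = c("full_refit", "fixed_vc"),
                    covariates = NULL, snp_id = "snp") {
  mode <- match.arg(mode)
  Y <- if (is.matrix(y)) y else pheno_matrix(y)
  ke <- if (is.list(K) && !is.null(K$values)) K else kinship_eigen(K)
  if (is.null(null_fit))
    null_fit <- fit_bivar(Y, K = ke, covariates = covariates)
  if (mode == "full_refit") {
    alt <- fit_bivar(Y, g = g, K = ke, constrain_snp_to_zero = FALSE,
                     covariates = covariates, start_vc = null_fit$vc)
    ll_alt <- alt$loglik
    conv <- null_fit$converged && alt$converged
  } else {
    prep <- .bivar_prep(Y, ke, g = g, covariates = covariates)
    r <- .bivar_profile_ll(null_fit$vc, prep, include_extras = TRUE)
    if (is.null(r)) stop("null variance components give a non-PD covariance")
    ll_alt <- r$ll
    conv <- null_fit$converged
  }
  stat <- 2 * (ll_alt - null_fit$loglik)
  if (stat < -1e-6)
    warning("negative LRT statistic (", format(stat), ") clipped to 0")
  stat <- max(stat, 0)
  structure(list(snp_id = snp_id, lrt_stat = stat, df = 2L,
                 p_value = stats::pchisq(stat, df = 2, lower.tail = FALSE),
                 converged = conv, mode = mode),
            class = "lrt_result")
}

#' Genome-wide longitudinal LRT scan
#'
#' Fits the null model once (it has no SNP term, so it is shared by all
#' SNPs) and tests every genotype column. `full_refit` re-estimates variance
#' components per SNP, warm-started from the null; `fixed_vc` profiles only
#' the fixed effects at the null components. Per-SNP failures are recorded
#' without aborting the scan. Fitting involves no randomness, so the scan is
#' deterministic given data and mode.
#'
#' @inheritParams fit_bivar
#' @param G A `genotype_matrix` (QC'd; rows in phenotype order).
#' @param mode See [lrt_snp()].
#' @return Data frame: `snp_id`, `chrom`, `bp`, `lrt`, `df`, `p`,
#'   `converged`, `mode`, `reason` (NA unless the SNP failed).
#' @export
gwas_longitudinal <- function(y, G, K, mode = c("full_refit", "fixed_vc"),
                              covariates = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(G, "genotype_matrix"))
  Y <- if (is.matrix(y)) y else pheno_matrix(y)
  m <- ncol(G$dosages)
  out <- data.frame(snp_id = character(m), chrom = character(m),
                    bp = integer(m), lrt = rep(NA_real_, m), df = rep(2L, m),
                    p = rep(NA_real_, m), converged = rep(NA, m),
                    mode = rep(mode, m), reason = rep(NA_character_, m),
                    stringsAsFactors = FALSE)
  if (m == 0) return(out)
  ke <- if (is.list(K) && !is.null(K$values)) K else kinship_eigen(K)
  null_fit <- fit_bivar(Y, K = ke, covariates = covariates)
  for (j in seq_len(m)) {
    out$snp_id[j] <- G$map$snp_id[j]
    out$chrom[j] <- G$map$chrom[j]
    out$bp[j] <- G$map$bp[j]
    res <- tryCatch(
      lrt_snp(Y, g = G$dosages[, j], K = ke, null_fit = null_fit,
              mode = mode, covariates = covariates,
              snp_id = G$map$snp_id[j]),
      error = function(e) e)
    if (inherits(res, "error")) {
      out$reason[j] <- conditionMessage(res)
    } else if (!res$converged) {
      out$lrt[j] <- res$lrt_stat
      out$converged[j] <- FALSE
      out$reason[j] <- "fit did not converge"
    } else {
      out$lrt[j] <- res$lrt_stat
      out$p[j] <- res$p_value
      out$converged[j] <- TRUE
    }
  }
  out
}
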