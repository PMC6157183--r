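#' Markov-product temporal correlation matrix
#'
#' Four-visit correlation matrix parameterized by the three adjacent-visit
#' correlations: `corr(i, j) = rho_i * ... * rho_(j-1)` for `i < j`. This
#' gives the product identity `corr(i, k) = corr(i, j) * corr(j, k)`.
#'
#' @param rho Numeric length-3 vector of adjacent-visit correlations, each
#'   strictly inside (-1, 1).
#' @return A 4 x 4 correlation matrix.
#' @export
markov_corr <- function(rho) {
  if (length(rho) != 3 || any(abs(rho) >= 1))
    stop("rho must be 3 adjacent-visit correlations with |rho| < 1")
  M <- diag(4)
  for (i in 1:3) for (j in (i + 1):4) {
    M[i, j] <- M[j, i] <- prod(rho[i:(j - 1)])
  }
  M
}

#' Symmetric PSD matrix square root
#'
#' The unique symmetric positive semidefinite root `R` with `R %*% R = S`,
#' via eigendecomposition. Eigenvalues in `[-1e-10, 0)` are clipped to 0;
#' materially negative eigenvalues are an error.
#'
#' @param S Symmetric PSD matrix.
#' @return Symmetric PSD matrix of the same dimension.
#' @export
sym_sqrt <- function(S) {
  if (!isSymmetric(unname(S), tol = 1e-8)) stop("S must be symmetric")
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < -1e-10)
    stop("S has a materially negative eigenvalue: ", min(e$values))
  d <- sqrt(pmax(e$values, 0))
  e$vectors %*% (d * t(e$vectors))
}

#' Variance components of the bivariate longitudinal model
#'
#' The 12 parameters of the two-trait four-visit model: per-trait polygenic
#' variances and their genetic correlation, per-trait residual variances
#' with Markov-product temporal correlations, and the environmental
#' cross-trait correlation.
#'
#' @param sigma2_u Length-2 positive polygenic variances (trait 1 = TG,
#'   trait 2 = HDL).
#' @param rho_g Genetic correlation in (-1, 1).
#' @param sigma2_e Length-2 positive residual variances (common across
#'   visits within trait).
#' @param markov_t1,markov_t2 Length-3 adjacent-visit correlations per trait.
#' @param rho_eps Environmental cross-trait correlation in (-1, 1).
#' @return A `bivar_vc` list.
#' @export
bivar_vc <- function(sigma2_u, rho_g, sigma2_e, markov_t1, markov_t2, rho_eps) {
  stopifnot(length(sigma2_u) == 2, all(sigma2_u > 0),
            length(sigma2_e) == 2, all(sigma2_e > 0),
            length(markov_t1) == 3, length(markov_t2) == 3)
  if (abs(rho_g) >= 1 || abs(rho_eps) >= 1 ||
      any(abs(c(markov_t1, markov_t2)) >= 1))
    stop("correlations must lie strictly inside (-1, 1)")
  structure(list(sigma2_u = as.numeric(sigma2_u), rho_g = rho_g,
                 sigma2_e = as.numeric(sigma2_e),
                 markov_t1 = as.numeric(markov_t1),
                 markov_t2 = as.numeric(markov_t2), rho_eps = rho_eps),
            class = "bivar_vc")
}

#' @export
print.bivar_vc <- function(x, ...) {
  cat("bivariate variance components\n")
  cat("  sigma2_u:", format(x$sigma2_u, digits = 4),
      " rho_g:", format(x$rho_g, digits = 4), "\n")
  cat("  sigma2_e:", format(x$sigma2_e, digits = 4),
      " rho_eps:", format(x$rho_eps, digits = 4), "\n")
  cat("  markov t1:", format(x$markov_t1, digits = 4), "\n")
  cat("  markov t2:", format(x$markov_t2, digits = 4), "\n")
  invisible(x)
}

# 8x8 per-individual blocks of the model covariance, trait-major ordering
# (TG visits 1..4, then HDL visits 1..4):
#   C1 = environmental block: diag blocks sigma2_e[t] * Markov correlation,
#        off-diagonal rho_eps * sqrt(Sigma_1) %*% sqrt(Sigma_2);
#   C2 = genetic block: Sigma_u (2x2) kron J4 (all-ones), since the polygenic
#        effect is shared across visits.
.bivar_blocks <- function(vc) {
  M1 <- markov_corr(vc$markov_t1)
  M2 <- markov_corr(vc$markov_t2)
  S1 <- vc$sigma2_e[1] * M1
  S2 <- vc$sigma2_e[2] * M2
  R1 <- sym_sqrt(S1)
  R2 <- sym_sqrt(S2)
  C1 <- rbind(cbind(S1, vc$rho_eps * R1 %*% R2),
              cbind(vc$rho_eps * R2 %*% R1, S2))
  C1 <- (C1 + t(C1)) / 2
  su <- matrix(c(vc$sigma2_u[1],
                 vc$rho_g * sqrt(prod(vc$sigma2_u)),
                 vc$rho_g * sqrt(prod(vc$sigma2_u)),
                 vc$sigma2_u[2]), 2, 2)
  C2 <- kronecker(su, matrix(1, 4, 4))
  list(C1 = C1, C2 = C2)
}

#' Structured covariance of the bivariate longitudinal model
#'
#' Assembles the per-individual 8 x 8 environmental block `C1` and genetic
#' block `C2` such that, under (trait, visit) x individual ordering,
#' `Var(Y) = C1 kron I_n + C2 kron K`. Also computes the simultaneous
#' diagonalization used for fast likelihood evaluation: an 8 x 8 transform
#' `T` with `T C1 T' = I` and `T C2 T' = diag(delta)`, so that for each
#' kinship eigenvalue `lambda_i` the per-individual covariance
#' `C1 + lambda_i C2` rotates to `diag(1 + lambda_i * delta)`.
#'
#' Overall positive definiteness requires `C1` positive definite (since
#' `C2` and `K` are PSD); a violation is reported naming `rho_eps`, the
#' usual offender, as `|rho_eps| < 1` alone does not guarantee it.
#'
#' @param vc A `bivar_vc`.
#' @param K A `kinship_matrix` (PSD), or a precomputed list as returned by
#'   [kinship_eigen()] (then `n` is taken from it).
#' @return A `structured_cov` list with `C1`, `C2`, `T`, `Tinv`, `delta`,
#'   `logdetC1`, `lambda`, `U` and `n`.
#' @export
build_structured_cov <- function(vc, K) {
  stopifnot(inherits(vc, "bivar_vc"))
  bl <- .bivar_blocks(vc)
  e1 <- eigen(bl$C1, symmetric = TRUE)
  if (min(e1$values) <= 1e-12)
    stop("environmental block C1 is not positive definite ",
         "(min eigenvalue ", format(min(e1$values)), "); check rho_eps = ",
         vc$rho_eps, " against the temporal correlations")
  Linv <- (1 / sqrt(e1$values)) * t(e1$vectors)      # Linv C1 Linv' = I
  B <- Linv %*% bl$C2 %*% t(Linv)
  eB <- eigen((B + t(B)) / 2, symmetric = TRUE)
  delta <- pmax(eB$values, 0)
  Tm <- t(eB$vectors) %*% Linv
  Tinv <- e1$vectors %*% (sqrt(e1$values) * eB$vectors)
  ke <- if (is.list(K) && !is.null(K$values)) K else kinship_eigen(K)
  if (min(ke$values) < -1e-8) stop("K is not positive semidefinite")
  lambda <- pmax(ke$values, 0)
  structure(list(C1 = bl$C1, C2 = bl$C2, T = Tm, Tinv = Tinv, delta = delta,
                 logdetC1 = sum(log(e1$values)), lambda = lambda,
                 U = ke$vectors, n = length(lambda)),
            class = "structured_cov")
}

#' Dense model covariance (for small n)
#'
#' Literal `C1 kron I_n + C2 kron K` under (trait, visit) x individual
#' ordering; intended for debugging and cross-checks at small n.
#' @param sc A `structured_cov`.
#' @return An `8n x 8n` matrix.
#' @export
dense_structured_cov <- function(sc) {
  K <- sc$U %*% (sc$lambda * t(sc$U))
  kronecker(sc$C1, diag(sc$n)) + kronecker(sc$C2, K)
}

#' Stack a complete longitudinal phenotype table as an 8 x n matrix
#'
#' Rows are TG visits 1-4 then HDL visits 1-4 (trait-major ordering);
#' columns are individuals in table order.
#' @param p A complete transformed `long_phenotypes`.
#' @return 8 x n numeric matrix with individual ids as colnames.
#' @export
pheno_matrix <- function(p) {
  stopifnot(inherits(p, "long_phenotypes"))
  if (anyNA(p$tg) || anyNA(p$hdl))
    stop("phenotypes must be complete (impute first)")
  Y <- rbind(t(p$tg), t(p$hdl))
  colnames(Y) <- p$iid
  rownames(Y) <- c(paste0("tg_v", 1:4), paste0("hdl_v", 1:4))
  Y
}

#' Gaussian log-likelihood under the structured covariance
#'
#' Evaluates the log-density of `N(mean, C1 kron I + C2 kron K)` by rotating
#' the individual axis onto the kinship eigenbasis and the trait-visit axis
#' onto the simultaneous diagonalization, leaving `8n` independent scalar
#' components with variances `1 + lambda_i * delta_j`. Exact up to floating
#' point.
#'
#' @param y Observations: an 8 x n matrix (see [pheno_matrix()]) or an
#'   8n-vector in (trait, visit) x individual order.
#' @param mean Mean, same shape as `y` (a scalar is recycled).
#' @param sc A `structured_cov`.
#' @return The log-likelihood (scalar).
#' @export
gaussian_loglik <- function(y, mean, sc) {
  stopifnot(inherits(sc, "structured_cov"))
  n <- sc$n
  Y <- if (is.matrix(y)) y else matrix(y, nrow = 8, ncol = n, byrow = TRUE)
  M <- if (length(mean) == 1) matrix(mean, 8, n)
       else if (is.matrix(mean)) mean
       else matrix(mean, nrow = 8, ncol = n, byrow = TRUE)
  stopifnot(all(dim(Y) == c(8, n)), all(dim(M) == c(8, n)))
  Fm <- sc$T %*% ((Y - M) %*% sc$U)
  Dmat <- 1 + outer(sc$delta, sc$lambda)
  if (any(Dmat <= 0)) stop("non-positive-definite per-individual block")
  -0.5 * (8 * n * log(2 * pi) + n * sc$logdetC1 + sum(log(Dmat)) +
            sum(Fm * Fm / Dmat))
}

#' Draw one sample from the structured Gaussian model
#'
#' @param sc A `structured_cov`.
#' @param mean 8 x n mean matrix (or scalar).
#' @return An 8 x n matrix distributed as `N(mean, C1 kron I + C2 kron K)`.
#' @export
sample_structured <- function(sc, mean = 0) {
  n <- sc$n
  Dmat <- 1 + outer(sc$delta, sc$lambda)
  Z <- matrix(stats::rnorm(8 * n), 8, n)
  M <- if (is.matrix(mean)) mean else matrix(mean, 8, n)
  M + (sc$Tinv %*% (Z * sqrt(Dmat))) %*% t(sc$U)
}

#' Dump the per-individual covariance blocks as TSV
#' @param sc A `structured_cov`.
#' @param path_c1,path_c2 Output paths.
#' @export
write_structured_cov <- function(sc, path_c1, path_c2) {
  utils::write.table(format(sc$C1, digits = 17), path_c1, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(format(sc$C2, digits = 17), path_c2, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
}
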