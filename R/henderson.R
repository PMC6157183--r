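#' Specify the Henderson response model
#'
#' The treatment-response model `y = X beta + Z u + e` with
#' `u ~ N(0, sigma2_g K)` and `e ~ N(0, sigma2_e R)`, so that
#' `Var(y) = sigma2_g Z K Z' + sigma2_e R`. By default `Z` is the identity
#' (an individual-level polygenic effect whose covariance is carried
#' entirely by the kinship matrix) and `R` the identity; `R` may be any
#' symmetric positive-definite matrix, e.g. from
#' [residual_exchangeable()].
#'
#' @param y Numeric response vector (length n).
#' @param X n x q fixed-effect design matrix (full column rank; give it
#'   colnames).
#' @param K r x r `kinship_matrix` (or plain PSD matrix) for the random
#'   effects.
#' @param Z Optional n x r random-effect design (default identity, r = n).
#' @param R Optional n x n residual correlation matrix (default identity).
#' @return A `henderson_model` list.
#' @export
henderson_model <- function(y, X, K, Z = NULL, R = NULL) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n)
  if (qr(X)$rank < ncol(X)) {
    stop("fixed-effect design is rank deficient; check columns: ",
         paste(colnames(X), collapse = ", "))
  }
  r <- if (is.null(Z)) n else ncol(Z)
  stopifnot(ncol(K) == r)
  if (!is.null(Z)) stopifnot(nrow(Z) == n)
  if (!is.null(R)) stopifnot(all(dim(R) == n), isSymmetric(unname(R), tol = 1e-8))
  structure(list(y = y, X = X, K = K, Z = Z, R = R, n = n, q = ncol(X), r = r),
            class = "henderson_model")
}

#' Exchangeable within-family residual correlation
#'
#' Builds a block-diagonal correlation matrix with 1 on the diagonal and
#' `rho` between members of the same family, a simple non-diagonal choice
#' for the residual matrix `R`.
#'
#' @param families Family id per individual, in model order.
#' @param rho Within-family correlation; PD requires
#'   `-1/(max block size - 1) < rho < 1`.
#' @return n x n correlation matrix.
#' @export
residual_exchangeable <- function(families, rho) {
  n <- length(families)
  R <- diag(n)
  for (f in unique(families)) {
    ii <- which(families == f)
    if (length(ii) > 1) R[ii, ii] <- rho + (1 - rho) * diag(length(ii))
  }
  kmax <- max(table(families))
  if (kmax > 1 && (rho <= -1 / (kmax - 1) || rho >= 1))
    stop("rho outside the positive-definite range for block size ", kmax)
  R
}

# one-time O(n^3) whitening: returns Tm, lam with Tm R Tm' = I and
# Tm (Z K Z') Tm' = diag(lam), so V = sigma2_g ZKZ' + sigma2_e R rotates to
# diag(sigma2_g * lam + sigma2_e). Uses the family-block eigendecomposition
# of K in the common Z = I, R = I case.
#' Whitening decomposition for the Henderson model
#'
#' Precomputes the simultaneous diagonalization of `(Z K Z', R)` used by
#' [em_reml()]; compute it once per dataset and pass it to repeated fits on
#' the same individuals (e.g. a per-SNP scan).
#' @param m A `henderson_model`.
#' @return List with `Tm` (n x n) and `lam` (length n).
#' @export
henderson_decomp <- function(m) {
  if (is.null(m$Z) && is.null(m$R)) {
    ke <- kinship_eigen(m$K)
    return(list(Tm = t(ke$vectors), lam = pmax(ke$values, 0)))
  }
  G0 <- if (is.null(m$Z)) unclass(m$K) else m$Z %*% unclass(m$K) %*% t(m$Z)
  if (is.null(m$R)) {
    e <- eigen((G0 + t(G0)) / 2, symmetric = TRUE)
    return(list(Tm = t(e$vectors), lam = pmax(e$values, 0)))
  }
  Lr <- t(chol(m$R))
  B <- forwardsolve(Lr, t(forwardsolve(Lr, G0)))
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  Lr_inv <- forwardsolve(Lr, diag(m$n))
  list(Tm = t(e$vectors) %*% Lr_inv, lam = pmax(e$values, 0))
}

#' Solve Henderson's mixed-model equations
#'
#' Literal block solve of the mixed-model equations at fixed variance
#' components, with `D = sigma2_g K` and the residual covariance
#' `sigma2_e R`:
#' ```
#' | X' S X      X' S Z       | beta |   | X' S y |
#' | Z' S X      Z' S Z + D^-1| u    | = | Z' S y |
#' ```
#' where `S = (sigma2_e R)^-1`. The resulting `beta` equals the GLS
#' estimator `(X' V^-1 X)^-1 X' V^-1 y` and `u` the BLUP
#' `sigma2_g K Z' V^-1 (y - X beta)`. A singular `K` is regularized by
#' `1e-8 * I` (with a message).
#'
#' @param m A `henderson_model`.
#' @param sigma2_g,sigma2_e Positive variance components.
#' @return List with `beta` (named by X colnames) and `u`.
#' @export
solve_mme <- function(m, sigma2_g, sigma2_e) {
  stopifnot(sigma2_g > 0, sigma2_e > 0)
  n <- m$n; q <- m$q; r <- m$r
  Z <- if (is.null(m$Z)) diag(n) else m$Z
  Rs <- if (is.null(m$R)) diag(n) * sigma2_e else m$R * sigma2_e
  Kd <- unclass(m$K) * sigma2_g
  Dinv <- tryCatch(chol2inv(chol(Kd)), error = function(e) {
    message("kinship matrix singular; regularizing with 1e-8 * I")
    chol2inv(chol(Kd + 1e-8 * diag(r)))
  })
  Sinv <- chol2inv(chol(Rs))
  XtS <- crossprod(m$X, Sinv)
  ZtS <- crossprod(Z, Sinv)
  A <- rbind(cbind(XtS %*% m$X, XtS %*% Z),
             cbind(ZtS %*% m$X, ZtS %*% Z + Dinv))
  rhs <- c(XtS %*% m$y, ZtS %*% m$y)
  sol <- solve(A, rhs)
  list(beta = stats::setNames(sol[seq_len(q)], colnames(m$X)),
       u = sol[q + seq_len(r)])
}

#' EM-REML variance-component estimation for the Henderson model
#'
#' Standard two-component EM-REML: at the current `(sigma2_g, sigma2_e)`,
#' the E-step takes conditional moments of `u` and `e` given `y` (through
#' the REML projection `P`), and the M-step updates
#' `sigma2_g <- sigma2_g + sigma2_g^2 (y'P G0 P y - tr(P G0)) / r` and
#' `sigma2_e <- sigma2_e + sigma2_e^2 (y'P R P y - tr(P R)) / n` in whitened
#' coordinates, where `G0 = Z K Z'`. The REML log-likelihood is
#' nondecreasing at every iteration (recorded in `loglik_trace`).
#'
#' @param m A `henderson_model`.
#' @param init Optional positive length-2 initial `(sigma2_g, sigma2_e)`
#'   (default: half the response variance each).
#' @param tol Convergence tolerance on the maximum relative component change
#'   (default 1e-6).
#' @param max_iter Iteration cap (default 1000; exceeding it flags
#'   `converged = FALSE`).
#' @param decomp Optional precomputed [henderson_decomp()].
#' @return A `henderson_fit`: `beta`, `u` (BLUPs), `sigma2_g`, `sigma2_e`,
#'   `XtVinvX` (q x q, the information for the fixed effects),
#'   `loglik_reml`, `loglik_trace`, `iterations`, `converged`, `boundary`,
#'   `n`, `q`.
#' @export
em_reml <- function(m, init = NULL, tol = 1e-6, max_iter = 1000, decomp = NULL) {
  stopifnot(inherits(m, "henderson_model"))
  n <- m$n; q <- m$q
  if (n <= q) stop("need more observations than fixed effects (n > q)")
  if (is.null(decomp)) decomp <- henderson_decomp(m)
  lam <- decomp$lam
  if (max(lam) - min(lam) < 1e-8 * (1 + abs(mean(lam))))
    stop("genetic and residual components are structurally confounded ",
         "(Z K Z' proportional to R); the model is not identifiable")
  yt <- as.vector(decomp$Tm %*% m$y)
  Xt <- decomp$Tm %*% m$X
  vy <- stats::var(m$y)
  sg <- if (is.null(init)) 0.5 * vy else init[1]
  se <- if (is.null(init)) 0.5 * vy else init[2]
  stopifnot(sg > 0, se > 0)
  trace <- numeric(0)
  converged <- FALSE
  boundary <- c(sigma2_g = FALSE, sigma2_e = FALSE)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d <- sg * lam + se
    C <- Xt / d
    A <- crossprod(Xt, C)
    beta <- solve(A, crossprod(Xt, yt / d))
    Py <- yt / d - as.vector(C %*% beta)
    trPLam <- sum(lam / d) - sum(diag(solve(A, crossprod(C, lam * C))))
    trP <- sum(1 / d) - sum(diag(solve(A, crossprod(C, C))))
    ll <- -0.5 * (sum(log(d)) + determinant(A)$modulus[1] + sum(yt * Py))
    trace <- c(trace, ll)
    sg_new <- sg + sg^2 * (sum(lam * Py^2) - trPLam) / length(lam)
    se_new <- se + se^2 * (sum(Py^2) - trP) / n
    if (sg_new < 1e-12) { sg_new <- 1e-12; boundary["sigma2_g"] <- TRUE }
    if (se_new < 1e-12) { se_new <- 1e-12; boundary["sigma2_e"] <- TRUE }
    rel <- max(abs(c(sg_new - sg, se_new - se)) /
                 pmax(abs(c(sg, se)), 1e-12))
    sg <- sg_new; se <- se_new
    if (rel < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (any(boundary))
    warning("variance component pinned at the 1e-12 boundary: ",
            paste(names(boundary)[boundary], collapse = ", "))
  d <- sg * lam + se
  C <- Xt / d
  A <- crossprod(Xt, C)
  beta <- solve(A, crossprod(Xt, yt / d))
  Py <- yt / d - as.vector(C %*% beta)
  ll <- -0.5 * (sum(log(d)) + determinant(A)$modulus[1] + sum(yt * Py))
  Z <- if (is.null(m$Z)) NULL else m$Z
  Vinv_res <- crossprod(decomp$Tm, Py)
  u <- if (is.null(Z)) sg * unclass(m$K) %*% Vinv_res
       else sg * unclass(m$K) %*% crossprod(Z, Vinv_res)
  structure(list(beta = stats::setNames(as.vector(beta), colnames(m$X)),
                 u = as.vector(u), sigma2_g = sg, sigma2_e = se,
                 XtVinvX = A, loglik_reml = ll, loglik_trace = trace,
                 iterations = iter, converged = converged,
                 boundary = boundary, n = n, q = q, model = m),
            class = "henderson_fit")
}

#' Fitted covariance of the response
#' @param fit A `henderson_fit`.
#' @return The n x n matrix `sigma2_g Z K Z' + sigma2_e R`.
#' @export
henderson_vy <- function(fit) {
  m <- fit$model
  G0 <- if (is.null(m$Z)) unclass(m$K) else m$Z %*% unclass(m$K) %*% t(m$Z)
  R <- if (is.null(m$R)) diag(m$n) else m$R
  fit$sigma2_g * G0 + fit$sigma2_e * R
}

#' Mixed-model F-test of a fixed-effect contrast
#'
#' Tests `H0: M beta = 0` with
#' `F = (M beta)' [M (X' V^-1 X)^-1 M']^-1 (M beta) / p`, referred to
#' `F(p, n - q)` where `p = rank(M)` and `q` the number of fixed effects.
#'
#' @param fit A converged `henderson_fit`.
#' @param M p x q contrast matrix of full row rank.
#' @param unit_id Identifier carried into the result.
#' @return An `ftest_result` list: `unit_id`, `f_stat`, `df1`, `df2`,
#'   `p_value`.
#' @export
f_test <- function(fit, M, unit_id = "contrast") {
  stopifnot(inherits(fit, "henderson_fit"))
  M <- matrix(M, ncol = fit$q)
  p <- nrow(M)
  if (qr(M)$rank < p) stop("contrast matrix is not of full row rank")
  Mb <- M %*% fit$beta
  mid <- M %*% solve(fit$XtVinvX, t(M))
  mid_chol <- tryCatch(chol((mid + t(mid)) / 2), error = function(e)
    stop("singular contrast covariance (redundant contrasts)"))
  f <- sum(backsolve(mid_chol, Mb, transpose = TRUE)^2) / p
  df2 <- fit$n - fit$q
  structure(list(unit_id = unit_id, f_stat = as.numeric(f), df1 = p,
                 df2 = df2,
                 p_value = stats::pf(f, p, df2, lower.tail = FALSE)),
            class = "ftest_result")
}

# align response, covariates, genotypes and kinship on the response ids
.align_response <- function(y, covar, G, K) {
  yv <- if (inherits(y, "response_vector")) y$response else y
  ids <- names(yv)
  if (is.null(ids)) stop("response must be a named vector")
  stopifnot(inherits(covar, "covariate_table"))
  if (!all(ids %in% covar$iid))
    stop("covariates missing for: ",
         paste(setdiff(ids, covar$iid), collapse = ", "))
  cv <- covar[match(ids, covar$iid), ]
  if (!is.null(G)) {
    if (!all(ids %in% rownames(G$dosages)))
      stop("genotypes missing for: ",
           paste(setdiff(ids, rownames(G$dosages)), collapse = ", "))
    G <- genotype_matrix(G$dosages[ids, , drop = FALSE], G$map)
  }
  Ks <- if (all(ids %in% colnames(K))) kinship_subset(K, ids) else
    stop("kinship missing for some response individuals")
  X0 <- cbind(intercept = 1, age = cv$age, smoking = cv$smoking)
  list(y = unname(yv), ids = ids, X0 = X0, G = G, K = Ks)
}

#' Genome-wide single-SNP response scan
#'
#' For each SNP, fits `y = intercept + age + smoking + g` by EM-REML
#' (variance components re-estimated per SNP by default; `refit = FALSE`
#' estimates them once under the covariate-only model and holds them fixed,
#' a fast approximation labeled in the output) and tests the SNP coefficient
#' with the 1-df mixed-model F-test. Constant genotype columns and per-SNP
#' failures are recorded with a reason and the scan continues.
#'
#' @param y A `response_vector` or named numeric vector.
#' @param covar A `covariate_table` (ids covering the response).
#' @param G A `genotype_matrix` (QC'd).
#' @param K `kinship_matrix` covering the response ids.
#' @param R Optional residual correlation matrix (response order).
#' @param refit Re-estimate variance components per SNP (default `TRUE`).
#' @param tol,max_iter Passed to [em_reml()].
#' @return Data frame: `unit_id`, `chrom`, `bp`, `f`, `df1`, `df2`, `p`,
#'   `converged`, `refit`, `reason`.
#' @export
gwas_response <- function(y, covar, G, K, R = NULL, refit = TRUE,
                          tol = 1e-6, max_iter = 1000) {
  al <- .align_response(y, covar, G, K)
  m <- ncol(al$G$dosages)
  out <- data.frame(unit_id = al$G$map$snp_id, chrom = al$G$map$chrom,
                    bp = al$G$map$bp, f = NA_real_, df1 = 1L,
                    df2 = NA_integer_, p = NA_real_, converged = NA,
                    refit = refit, reason = NA_character_,
                    stringsAsFactors = FALSE)
  if (m == 0) return(out)
  m0 <- henderson_model(al$y, al$X0, al$K, R = R)
  decomp <- henderson_decomp(m0)
  base_fit <- if (!refit) em_reml(m0, tol = tol, max_iter = max_iter,
                                  decomp = decomp) else NULL
  q <- ncol(al$X0) + 1L
  Msel <- matrix(c(rep(0, q - 1), 1), 1, q)
  for (j in seq_len(m)) {
    g <- al$G$dosages[, j]
    if (anyNA(g)) { out$reason[j] <- "missing genotypes"; next }
    if (length(unique(g)) < 2) { out$reason[j] <- "constant genotype"; next }
    res <- tryCatch({
      mj <- henderson_model(al$y, cbind(al$X0, snp = g), al$K, R = R)
      fit <- if (refit) {
        em_reml(mj, tol = tol, max_iter = max_iter, decomp = decomp)
      } else {
        .gls_fixed_components(mj, decomp, base_fit$sigma2_g,
                              base_fit$sigma2_e)
      }
      list(fit = fit, ft = f_test(fit, Msel, unit_id = al$G$map$snp_id[j]))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      out$reason[j] <- conditionMessage(res)
    } else {
      out$f[j] <- res$ft$f_stat
      out$df2[j] <- res$ft$df2
      out$p[j] <- res$ft$p_value
      out$converged[j] <- res$fit$converged
      if (!res$fit$converged) {
        out$p[j] <- NA_real_
        out$reason[j] <- "EM-REML did not converge"
      }
    }
  }
  out
}

#' GLS fit of the Henderson model at fixed variance components
#'
#' Fits only the fixed effects, holding `(sigma2_g, sigma2_e)` at supplied
#' values (used by the shared-components scan mode, and the bridge to
#' ordinary least squares: with `sigma2_g = 0`, `R = I` and
#' `sigma2_e = RSS / (n - q)` the downstream [f_test()] reproduces the
#' classical partial F-test exactly).
#'
#' @param m A `henderson_model`.
#' @param sigma2_g,sigma2_e Variance components (`sigma2_g >= 0`).
#' @param decomp Optional precomputed [henderson_decomp()].
#' @return A `henderson_fit` (without BLUPs or a REML likelihood).
#' @export
henderson_gls <- function(m, sigma2_g, sigma2_e, decomp = NULL) {
  if (is.null(decomp)) decomp <- henderson_decomp(m)
  .gls_fixed_components(m, decomp, sigma2_g, sigma2_e)
}

# GLS fit at externally supplied variance components (shared-component scan)
.gls_fixed_components <- function(m, decomp, sigma2_g, sigma2_e) {
  yt <- as.vector(decomp$Tm %*% m$y)
  Xt <- decomp$Tm %*% m$X
  d <- sigma2_g * decomp$lam + sigma2_e
  C <- Xt / d
  A <- crossprod(Xt, C)
  beta <- solve(A, crossprod(Xt, yt / d))
  structure(list(beta = stats::setNames(as.vector(beta), colnames(m$X)),
                 u = NULL, sigma2_g = sigma2_g, sigma2_e = sigma2_e,
                 XtVinvX = A, loglik_reml = NA_real_,
                 loglik_trace = numeric(0), iterations = 0L,
                 converged = TRUE, boundary = c(FALSE, FALSE),
                 n = m$n, q = m$q, model = m),
            class = "henderson_fit")
}

#' Multi-SNP (genomic region) response test
#'
#' Joint F-test of all pruned SNPs in one region: the design is
#' `[intercept, age, smoking, g_1 .. g_p]` and the contrast selects the `p`
#' SNP coefficients, giving `F(p, n - q)`. Collinear SNP columns surviving
#' pruning are dropped with a warning before testing; a saturated design
#' (`p >= n - 3`) is an error.
#'
#' @inheritParams gwas_response
#' @param region A single-region row/list with `region_id` and
#'   `pruned_snp_ids` (falling back to `snp_ids`).
#' @return An `ftest_result` with the region id.
#' @export
region_test <- function(y, covar, region, G, K, R = NULL,
                        tol = 1e-6, max_iter = 1000) {
  snp_ids <- region$pruned_snp_ids
  if (is.null(snp_ids)) snp_ids <- region$snp_ids
  snp_ids <- unlist(snp_ids)
  if (!length(snp_ids)) stop("region has no SNPs to test")
  al <- .align_response(y, covar, G, K)
  stopifnot(all(snp_ids %in% colnames(al$G$dosages)))
  gmat <- al$G$dosages[, snp_ids, drop = FALSE]
  if (anyNA(gmat)) stop("missing genotypes in region (QC first)")
  X <- cbind(al$X0, gmat)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    keep_idx <- qr_x$pivot[seq_len(qr_x$rank)]
    dropped <- setdiff(colnames(X), colnames(X)[keep_idx])
    dropped <- intersect(dropped, snp_ids)
    warning("dropping collinear SNP column(s): ",
            paste(dropped, collapse = ", "))
    snp_ids <- setdiff(snp_ids, dropped)
    X <- cbind(al$X0, al$G$dosages[, snp_ids, drop = FALSE])
  }
  p <- length(snp_ids)
  if (p >= length(al$y) - 3)
    stop("saturated design: ", p, " SNP columns for ", length(al$y),
         " observations")
  mj <- henderson_model(al$y, X, al$K, R = R)
  fit <- em_reml(mj, tol = tol, max_iter = max_iter)
  M <- cbind(matrix(0, p, 3), diag(p))
  f_test(fit, M, unit_id = region$region_id)
}
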