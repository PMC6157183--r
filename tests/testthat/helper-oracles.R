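# Independent oracles used across the test suite. These deliberately avoid
# the package's own computational paths: kinship by Wright's path counting,
# mixed-model solutions by dense GLS/BLUP closed forms, likelihoods by dense
# multivariate-normal evaluation, BH by a literal textbook step-up.

# --- random pedigrees (outbred: existing members always mate new founders,
#     so common ancestors are non-inbred and path counting applies cleanly)
rand_pedigree <- function(max_members = 40) {
  n_start <- sample(2:4, 1)
  id <- paste0("p", seq_len(n_start))
  fa <- rep(NA_character_, n_start)
  mo <- rep(NA_character_, n_start)
  sex <- rep(c("male", "female"), length.out = n_start)
  nxt <- n_start + 1L
  for (round in 1:6) {
    if (length(id) >= max_members - 3) break
    mater <- sample(seq_along(id), 1)
    spouse <- paste0("p", nxt); nxt <- nxt + 1L
    spouse_sex <- if (sex[mater] == "male") "female" else "male"
    id <- c(id, spouse); fa <- c(fa, NA); mo <- c(mo, NA)
    sex <- c(sex, spouse_sex)
    for (k in seq_len(sample(1:3, 1))) {
      child <- paste0("p", nxt); nxt <- nxt + 1L
      id <- c(id, child)
      if (sex[mater] == "male") {
        fa <- c(fa, id[mater]); mo <- c(mo, spouse)
      } else {
        fa <- c(fa, spouse); mo <- c(mo, id[mater])
      }
      sex <- c(sex, sample(c("male", "female"), 1))
      if (length(id) >= max_members) break
    }
  }
  pedigree(data.frame(id = id, father = fa, mother = mo, sex = sex,
                      family = "F1", stringsAsFactors = FALSE))
}

# --- Wright path-counting kinship -------------------------------------------
# phi(i, j) = sum over common ancestors A and node-disjoint path pairs of
# (1/2)^(n1 + n2 + 1) * (1 + f_A); phi(i, i) = (1 + phi(father, mother)) / 2
kinship_path_oracle <- function(ped) {
  idx <- stats::setNames(seq_len(nrow(ped)), ped$id)
  fa <- idx[ped$father]; mo <- idx[ped$mother]
  paths_memo <- vector("list", nrow(ped))
  paths_up <- function(i) {
    if (!is.null(paths_memo[[i]])) return(paths_memo[[i]])
    out <- list(i)
    for (p in c(fa[i], mo[i])) {
      if (!is.na(p)) out <- c(out, lapply(paths_up(p), function(pp) c(i, pp)))
    }
    paths_memo[[i]] <<- out
    out
  }
  inb <- function(i) {
    if (is.na(fa[i]) || is.na(mo[i])) return(0)
    phi_pair(fa[i], mo[i])
  }
  phi_pair <- function(i, j) {
    if (i == j) return(0.5 * (1 + inb(i)))
    tot <- 0
    for (p1 in paths_up(i)) for (p2 in paths_up(j)) {
      a <- p1[length(p1)]
      if (p2[length(p2)] != a) next
      if (length(intersect(p1, p2)) != 1L) next
      tot <- tot + 0.5^(length(p1) - 1 + length(p2) - 1 + 1) * (1 + inb(a))
    }
    tot
  }
  n <- nrow(ped)
  K <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) for (j in i:n) K[i, j] <- K[j, i] <- phi_pair(i, j)
  K
}

# --- dense GLS / BLUP closed forms ------------------------------------------
dense_gls_blup <- function(y, X, K, Z = NULL, R = NULL, sg, se) {
  n <- length(y)
  Zm <- if (is.null(Z)) diag(n) else Z
  Rm <- if (is.null(R)) diag(n) else R
  V <- sg * Zm %*% unclass(K) %*% t(Zm) + se * Rm
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  u <- sg * unclass(K) %*% t(Zm) %*% Vi %*% (y - X %*% beta)
  list(beta = as.vector(beta), u = as.vector(u), V = V)
}

# --- dense bivariate-model covariance via the literal Z-form ----------------
# Var(Y) = Zbig (Sigma_u kron K) Zbig' + Sigma_eps kron I_n under
# (trait, visit) x individual ordering, with symmetric roots in the
# environmental off-diagonal blocks (eigendecomposition done here, not via
# the package).
dense_bivar_cov <- function(vc, Kmat) {
  n <- ncol(Kmat)
  msqrt <- function(S) {
    e <- eigen(S, symmetric = TRUE)
    e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  }
  mk <- function(r) {
    M <- diag(4)
    for (i in 1:3) for (j in (i + 1):4) M[i, j] <- M[j, i] <- prod(r[i:(j - 1)])
    M
  }
  S1 <- vc$sigma2_e[1] * mk(vc$markov_t1)
  S2 <- vc$sigma2_e[2] * mk(vc$markov_t2)
  Seps <- rbind(cbind(S1, vc$rho_eps * msqrt(S1) %*% msqrt(S2)),
                cbind(vc$rho_eps * msqrt(S2) %*% msqrt(S1), S2))
  Su <- matrix(c(vc$sigma2_u[1], vc$rho_g * sqrt(prod(vc$sigma2_u)),
                 vc$rho_g * sqrt(prod(vc$sigma2_u)), vc$sigma2_u[2]), 2, 2)
  Ztr <- kronecker(matrix(1, 4, 1), diag(n))      # one trait: visits x indiv
  Zbig <- rbind(cbind(Ztr, matrix(0, 4 * n, n)),
                cbind(matrix(0, 4 * n, n), Ztr))
  Zbig %*% kronecker(Su, unclass(Kmat)) %*% t(Zbig) +
    kronecker(Seps, diag(n))
}

dense_mvn_loglik <- function(y, mean, V) {
  r <- y - mean
  -0.5 * (length(y) * log(2 * pi) + determinant(V)$modulus[1] +
            sum(r * solve(V, r)))
}

# --- textbook BH step-up ----------------------------------------------------
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, m * ps[i] / i)
    adj[i] <- min(running, 1)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# stack a complete 8 x n matrix into the (trait, visit) x individual vector
bivar_vec <- function(Y) as.vector(t(Y))
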