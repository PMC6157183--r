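#' Log-log transform of raw phenotypes
#'
#' Applies `y = log(log(x))` elementwise (natural logs by default; another
#' base applies the same double logarithm in that base). The transform is
#' defined only for raw values strictly greater than 1 and is monotone there.
#' Missing cells stay missing.
#'
#' @param p A `long_phenotypes` object on the raw scale.
#' @param base Logarithm base (default `exp(1)`).
#' @return A `long_phenotypes` object with `scale = "transformed"`.
#' @export
loglog_transform <- function(p, base = exp(1)) {
  stopifnot(inherits(p, "long_phenotypes"))
  if (p$scale != "raw") stop("phenotypes are already transformed")
  f <- function(mat, nm) {
    bad <- which(!is.na(mat) & mat <= 1, arr.ind = TRUE)
    if (nrow(bad))
      stop("raw ", nm, " value <= 1 for individual ", p$iid[bad[1, 1]],
           ", visit ", bad[1, 2], ": log-log transform undefined")
    log(log(mat, base = base), base = base)
  }
  out <- long_phenotypes(p$iid, f(p$tg, "tg"), f(p$hdl, "hdl"),
                         scale = "transformed")
  out
}

#' Invert the log-log transform
#' @param p A transformed `long_phenotypes`.
#' @param base Logarithm base used in the forward transform.
#' @return Raw-scale `long_phenotypes`.
#' @export
loglog_inverse <- function(p, base = exp(1)) {
  stopifnot(inherits(p, "long_phenotypes"), p$scale == "transformed")
  long_phenotypes(p$iid, base^(base^p$tg), base^(base^p$hdl), scale = "raw")
}

#' Impute missing phenotypes under the no-SNP null model
#'
#' For each trait-visit column independently, fits the null polygenic model
#' `y = mu + u + e` with `Var(y) = sigma2 * (h2 * K + (1 - h2) * I)` at a
#' fixed heritability `h2`: `mu` is the GLS mean over observed entries and
#' `sigma2` the GLS residual quadratic form divided by (n_obs - 1). Each
#' missing cell is then replaced by its conditional (multivariate-normal)
#' mean given the observed cells of that column. Observed cells are
#' returned unchanged. With `h2 = 0` the conditioning is vacuous and every
#' missing cell receives the estimated column mean.
#'
#' The heritability is a user-visible constant (default 0.5), not estimated.
#'
#' @param p A transformed `long_phenotypes` (ids must match `K`'s order).
#' @param K `kinship_matrix` for the phenotyped individuals, in `p$iid`
#'   order.
#' @param h2 Heritability in `[0, 1)` shared by all columns.
#' @return A `long_phenotypes` with no missing cells.
#' @export
impute_null_model <- function(p, K, h2 = 0.5) {
  stopifnot(inherits(p, "long_phenotypes"), p$scale == "transformed")
  if (!is.numeric(h2) || length(h2) != 1 || h2 < 0 || h2 >= 1)
    stop("h2 must be a single value in [0, 1)")
  n <- length(p$iid)
  stopifnot(ncol(K) == n)
  if (!is.null(colnames(K)) && !identical(colnames(K), p$iid))
    stop("kinship ids do not match phenotype ids/order")
  Omega <- h2 * unclass(K) + (1 - h2) * diag(n)
  impute_col <- function(y) {
    o <- which(!is.na(y)); m <- which(is.na(y))
    if (!length(o)) stop("a trait-visit column is fully missing")
    if (!length(m)) return(y)
    Ooo <- Omega[o, o, drop = FALSE]
    ones <- rep(1, length(o))
    Oinv_y <- solve(Ooo, cbind(y[o], ones))
    mu <- sum(Oinv_y[, 1]) / sum(Oinv_y[, 2])
    r <- y[o] - mu
    y[m] <- mu + Omega[m, o, drop = FALSE] %*% solve(Ooo, r)
    y
  }
  tg <- apply(p$tg, 2, impute_col)
  hdl <- apply(p$hdl, 2, impute_col)
  long_phenotypes(p$iid, tg, hdl, scale = "transformed")
}

#' Build the treatment-response phenotype
#'
#' Per individual, the response is the mean of the post-treatment transformed
#' triglyceride visits minus the mean of the pre-treatment ones (default
#' direction `post_minus_pre`; a negative value means the drug lowered TG).
#' When exactly one visit of a pre (post) pair is missing it is replaced by
#' the other visit of that pair, which equals taking the mean over available
#' visits. Individuals missing both pre or both post visits are excluded and
#' reported.
#'
#' @param p A transformed `long_phenotypes`.
#' @param trait `"tg"` (default) or `"hdl"`.
#' @param direction `"post_minus_pre"` (default) or `"pre_minus_post"`.
#' @return A `response_vector`: list with `response` (named numeric vector
#'   over retained individuals) and `excluded` (data frame `iid`, `reason`).
#' @export
build_response <- function(p, trait = c("tg", "hdl"),
                           direction = c("post_minus_pre", "pre_minus_post")) {
  stopifnot(inherits(p, "long_phenotypes"), p$scale == "transformed")
  trait <- match.arg(trait)
  direction <- match.arg(direction)
  mat <- p[[trait]]
  pre <- mat[, p$pre, drop = FALSE]
  post <- mat[, p$post, drop = FALSE]
  pre_n <- rowSums(!is.na(pre)); post_n <- rowSums(!is.na(post))
  keep <- pre_n >= 1 & post_n >= 1
  reason <- ifelse(pre_n == 0 & post_n == 0, "no pre or post visits",
                   ifelse(pre_n == 0, "no pre-treatment visits",
                          "no post-treatment visits"))
  excluded <- data.frame(iid = p$iid[!keep], reason = reason[!keep],
                         stringsAsFactors = FALSE)
  y <- rowMeans(post, na.rm = TRUE) - rowMeans(pre, na.rm = TRUE)
  if (direction == "pre_minus_post") y <- -y
  structure(list(response = stats::setNames(y[keep], p$iid[keep]),
                 excluded = excluded, trait = trait, direction = direction),
            class = "response_vector")
}

#' Write the response exclusion report as TSV
#' @param r A `response_vector`.
#' @param path Output path.
#' @export
write_exclusion_report <- function(r, path) {
  utils::write.table(r$excluded, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
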