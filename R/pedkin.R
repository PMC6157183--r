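#' Read a pedigree file
#'
#' Parses a pedigree in one of two text dialects and validates its structure:
#' unique individual ids, every named parent present (or auto-promoted to a
#' founder when `promote_missing_parents = TRUE`), and an acyclic parent
#' graph (no individual is its own ancestor).
#'
#' @param path Path to the pedigree file.
#' @param dialect `"fam_like"`: whitespace-delimited columns
#'   `family_id individual_id father_id mother_id sex` with `"0"` (or empty)
#'   for a missing parent and sex coded `1`/`M` = male, `2`/`F` = female,
#'   anything else unknown. `"three_generation_tsv"`: a TSV with header
#'   columns `individual_id father_id mother_id sex family_id`.
#' @param promote_missing_parents If `TRUE`, ids that appear only as parents
#'   are added as founder records (with a warning); if `FALSE` (default) they
#'   are a parse error.
#' @return A `fam_pedigree`: a data frame with columns `id`, `father`,
#'   `mother` (`NA` when missing), `sex` (`"male"`, `"female"`, `"unknown"`)
#'   and `family`, in file order (promoted founders appended).
#' @export
read_pedigree <- function(path, dialect = c("fam_like", "three_generation_tsv"),
                          promote_missing_parents = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  if (dialect == "fam_like") {
    raw <- utils::read.table(path, header = FALSE, colClasses = "character",
                             col.names = c("family", "id", "father", "mother", "sex"))
  } else {
    raw <- utils::read.table(path, header = TRUE, sep = "\t",
                             colClasses = "character")
    need <- c("individual_id", "father_id", "mother_id", "sex", "family_id")
    if (!all(need %in% names(raw)))
      stop("three_generation_tsv requires header columns: ",
           paste(need, collapse = ", "))
    raw <- data.frame(family = raw$family_id, id = raw$individual_id,
                      father = raw$father_id, mother = raw$mother_id,
                      sex = raw$sex, stringsAsFactors = FALSE)
  }
  raw$father[raw$father %in% c("0", "")] <- NA_character_
  raw$mother[raw$mother %in% c("0", "")] <- NA_character_
  sex <- tolower(raw$sex)
  sex <- ifelse(sex %in% c("1", "m", "male"), "male",
                ifelse(sex %in% c("2", "f", "female"), "female", "unknown"))
  ped <- data.frame(id = raw$id, father = raw$father, mother = raw$mother,
                    sex = sex, family = raw$family, stringsAsFactors = FALSE)
  pedigree(ped, promote_missing_parents = promote_missing_parents)
}

#' Construct and validate a pedigree
#'
#' @param records Data frame with columns `id`, `father`, `mother`, `sex`,
#'   `family`; missing parents as `NA`.
#' @param promote_missing_parents See [read_pedigree()].
#' @return A validated `fam_pedigree` data frame.
#' @export
pedigree <- function(records, promote_missing_parents = FALSE) {
  ped <- as.data.frame(records, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "father", "mother", "sex", "family") %in% names(ped)))
  if (anyDuplicated(ped$id))
    stop("duplicate individual id(s): ",
         paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "))
  named_parents <- stats::na.omit(unique(c(ped$father, ped$mother)))
  orphans <- setdiff(named_parents, ped$id)
  if (length(orphans)) {
    if (!promote_missing_parents)
      stop("parent id(s) absent from pedigree: ", paste(orphans, collapse = ", "))
    warning("promoting ", length(orphans),
            " parent id(s) without records to founders: ",
            paste(orphans, collapse = ", "))
    fam_of <- function(p) {
      hit <- ped$family[ped$father %in% p | ped$mother %in% p][1]
      hit
    }
    add <- data.frame(id = orphans, father = NA_character_,
                      mother = NA_character_, sex = "unknown",
                      family = vapply(orphans, fam_of, character(1)),
                      stringsAsFactors = FALSE)
    ped <- rbind(ped, add)
  }
  .check_acyclic(ped)
  rownames(ped) <- NULL
  class(ped) <- c("fam_pedigree", "data.frame")
  ped
}

# Kahn-style topological sort of the parent graph; returns ids ordered
# parents-before-children, or stops naming an individual on a cycle.
.topo_order <- function(ped) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  fa <- idx[ped$father]; mo <- idx[ped$mother]  # NA for founders
  npar <- (!is.na(fa)) + (!is.na(mo))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(fa[i], mo[i])) if (!is.na(p))
      children[[p]] <- c(children[[p]], i)
  }
  queue <- which(npar == 0L)
  out <- integer(0)
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    out <- c(out, i)
    for (ch in children[[i]]) {
      npar[ch] <- npar[ch] - 1L
      if (npar[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) < n) {
    bad <- ped$id[setdiff(seq_len(n), out)]
    stop("cycle in parent graph involving individual(s): ",
         paste(bad, collapse = ", "))
  }
  out
}

.check_acyclic <- function(ped) {
  self <- ped$id == ped$father | ped$id == ped$mother
  if (any(self, na.rm = TRUE))
    stop("cycle in parent graph involving individual(s): ",
         paste(ped$id[which(self)], collapse = ", "), " (own parent)")
  invisible(.topo_order(ped))
}

#' Family partition of a pedigree
#' @param ped A `fam_pedigree`.
#' @return Named list of id vectors, one per family id.
#' @export
pedigree_families <- function(ped) split(ped$id, ped$family)

#' Expected kinship matrix from a pedigree
#'
#' Computes kinship coefficients by the standard tabular recursion, filling
#' individuals in an order where parents precede children:
#' \deqn{\Phi_{ii} = \tfrac12 (1 + \Phi_{f_i m_i}), \qquad
#'       \Phi_{ij} = \tfrac12 (\Phi_{f_i j} + \Phi_{m_i j})}
#' with missing-parent terms equal to 0 and founders mutually unrelated.
#' Inbred pedigrees are handled (diagonal exceeds 0.5). Kinship itself is
#' stored (self = 0.5 for non-inbred individuals), not the additive
#' relationship 2*Phi; downstream model code uses K exactly as returned.
#'
#' @param ped A `fam_pedigree`.
#' @param subset Optional ordered character vector of ids; the kinship is
#'   computed on the whole pedigree and then restricted to (and ordered by)
#'   this subset.
#' @return A `kinship_matrix`: a symmetric numeric matrix with id dimnames
#'   and a `family` attribute (family id per column) used to exploit the
#'   block-diagonal structure downstream.
#' @export
compute_kinship <- function(ped, subset = NULL) {
  stopifnot(inherits(ped, "fam_pedigree"))
  n <- nrow(ped)
  ord <- .topo_order(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  fa <- idx[ped$father]; mo <- idx[ped$mother]
  K <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  done <- integer(0)
  for (i in ord) {
    f <- fa[i]; m <- mo[i]
    phi_fm <- if (!is.na(f) && !is.na(m)) K[f, m] else 0
    K[i, i] <- 0.5 * (1 + phi_fm)
    if (length(done)) {
      kf <- if (!is.na(f)) K[f, done] else 0
      km <- if (!is.na(m)) K[m, done] else 0
      v <- 0.5 * (kf + km)
      K[i, done] <- v
      K[done, i] <- v
    }
    done <- c(done, i)
  }
  fam <- stats::setNames(ped$family, ped$id)
  if (!is.null(subset)) {
    if (length(subset) == 0) stop("subset is empty")
    missing_ids <- setdiff(subset, ped$id)
    if (length(missing_ids))
      stop("subset id(s) not in pedigree: ", paste(missing_ids, collapse = ", "))
    K <- K[subset, subset, drop = FALSE]
    fam <- fam[subset]
  }
  structure(K, family = unname(fam), class = c("kinship_matrix", "matrix", "array"))
}

#' Restrict a kinship matrix to a set of ids
#' @param K A `kinship_matrix`.
#' @param ids Ordered ids to keep.
#' @return The restricted `kinship_matrix`.
#' @export
kinship_subset <- function(K, ids) {
  stopifnot(all(ids %in% colnames(K)))
  fam <- attr(K, "family")
  names(fam) <- colnames(K)
  structure(unclass(K)[ids, ids, drop = FALSE], family = unname(fam[ids]),
            class = class(K))
}

#' Write / read a kinship matrix as TSV
#'
#' TSV with a header row of ids and an id column, values at full precision.
#' @param K A `kinship_matrix`.
#' @param path Output path.
#' @export
write_kinship <- function(K, path) {
  df <- data.frame(id = colnames(K), format(unclass(K), digits = 17, trim = TRUE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_kinship
#' @param family Optional family id per column to reattach on read.
#' @return `read_kinship` returns a `kinship_matrix`.
#' @export
read_kinship <- function(path, family = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  ids <- as.character(df$id)
  M <- as.matrix(df[, -1, drop = FALSE])
  dimnames(M) <- list(ids, ids)
  structure(M, family = family, class = c("kinship_matrix", "matrix", "array"))
}

# Eigen-structure of K, exploiting block-diagonality over families when the
# family attribute is present: eigenvalues and an orthogonal rotation U with
# K = U diag(values) U'. Cached by callers; O(sum of block sizes cubed).
#' Eigendecomposition of a kinship matrix
#'
#' Computed family-block by family-block when the matrix carries a `family`
#' attribute (kinship between families is zero), which reduces the cost from
#' one dense n x n decomposition to one small decomposition per family.
#'
#' @param K A `kinship_matrix` (or plain symmetric matrix).
#' @return List with `values` (length n) and `vectors` (n x n orthogonal).
#' @export
kinship_eigen <- function(K) {
  n <- ncol(K)
  fam <- attr(K, "family")
  if (is.null(fam)) {
    e <- eigen(unclass(K), symmetric = TRUE)
    return(list(values = e$values, vectors = e$vectors))
  }
  vals <- numeric(n)
  U <- matrix(0, n, n)
  for (f in unique(fam)) {
    ii <- which(fam == f)
    if (length(ii) == 1L) {
      vals[ii] <- K[ii, ii]
      U[ii, ii] <- 1
    } else {
      e <- eigen(unclass(K)[ii, ii], symmetric = TRUE)
      vals[ii] <- e$values
      U[ii, ii] <- e$vectors
    }
  }
  list(values = vals, vectors = U)
}
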