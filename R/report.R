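#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up false-discovery-rate adjustment in input order: sort ascending,
#' set `adj_(i) = min_(j >= i) (m * p_(j) / j)` capped at 1, and map back.
#' Missing p-values (failed fits) are propagated as missing and excluded
#' from `m`. Delegates to [stats::p.adjust()], whose BH method implements
#' exactly this step-up.
#'
#' @param pvals Numeric vector of p-values in (0, 1] (NAs allowed).
#' @return Adjusted p-values in the same order.
#' @export
bh_adjust <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] <= 0 | pvals[ok] > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Assemble an association result table
#'
#' Adds BH-adjusted p-values (computed within this table: apply it per
#' analysis family, never across scans) and a unique p-value rank (ties
#' broken by chrom then position).
#'
#' @param df Data frame with at least `unit_id`, `chrom`, `p`; `bp` or
#'   `start` used for tie-breaks when present.
#' @param statistic,df1,df2 Optional column names copied through.
#' @return An `assoc_table` data frame with `p_bh` and `rank` columns.
#' @export
assoc_table <- function(df) {
  stopifnot(all(c("unit_id", "chrom", "p") %in% names(df)))
  df$p_bh <- bh_adjust(df$p)
  pos <- if ("bp" %in% names(df)) df$bp else if ("start" %in% names(df))
    df$start else seq_len(nrow(df))
  df$rank <- NA_integer_
  tested <- !is.na(df$p)
  ord <- order(df$p[tested], df$chrom[tested], pos[tested])
  df$rank[which(tested)[ord]] <- seq_len(sum(tested))
  class(df) <- c("assoc_table", "data.frame")
  df
}

#' Top-k rows of an association table
#'
#' The `k` smallest raw p-values, ties broken by (chrom, position);
#' untested rows (missing p) are never included.
#' @param t An `assoc_table`.
#' @param k Number of rows (a larger `k` returns the full tested table).
#' @return The selected rows, smallest p first.
#' @export
top_table <- function(t, k = 20) {
  stopifnot(k >= 1)
  tested <- t[!is.na(t$p), , drop = FALSE]
  pos <- if ("bp" %in% names(tested)) tested$bp else if
    ("start" %in% names(tested)) tested$start else seq_len(nrow(tested))
  ord <- order(tested$p, tested$chrom, pos)
  tested[ord[seq_len(min(k, nrow(tested)))], , drop = FALSE]
}

#' Manhattan-plot-ready coordinates
#'
#' Adds a cumulative genome coordinate (chromosome offsets stacked in
#' order), `neg_log10_p`, and an alternating chromosome color index.
#' Single-chromosome input keeps its physical coordinate.
#' @param t An `assoc_table` with `chrom` and `bp` (or `start`).
#' @return Data frame with `unit_id`, `chrom`, `bp`, `genome_bp`,
#'   `neg_log10_p`, `color_index`.
#' @export
manhattan_data <- function(t) {
  bp <- if ("bp" %in% names(t)) t$bp else t$start
  chroms <- unique(t$chrom)
  num <- suppressWarnings(as.numeric(chroms))
  chroms <- chroms[order(is.na(num), num, chroms)]  # 1..22 then X, Y, ...
  chrom_max <- vapply(chroms, function(cc) max(bp[t$chrom == cc]), numeric(1))
  offsets <- stats::setNames(c(0, cumsum(chrom_max))[seq_along(chroms)], chroms)
  data.frame(unit_id = t$unit_id, chrom = t$chrom, bp = bp,
             genome_bp = bp + offsets[t$chrom],
             neg_log10_p = -log10(t$p),
             color_index = (match(t$chrom, chroms) - 1) %% 2,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write an association table as TSV
#' @param t An `assoc_table` (list-columns are dropped).
#' @param path Output path.
#' @export
write_assoc_table <- function(t, path) {
  keep <- !vapply(t, is.list, logical(1))
  utils::write.table(as.data.frame(t)[, keep], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
}
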