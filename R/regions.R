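#' Read gene annotation intervals from BED
#'
#' BED is 0-based half-open; intervals are converted to the package-wide
#' 1-based inclusive convention.
#' @param path BED file (chrom, start, end, name).
#' @return Data frame `gene_id`, `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_genes_bed <- function(path) {
  gr <- as.data.frame(rtracklayer::import(path, format = "BED"))
  df <- data.frame(gene_id = if ("name" %in% names(gr)) as.character(gr$name)
                   else paste0("gene", seq_len(nrow(gr))),
                   chrom = as.character(gr$seqnames),
                   start = gr$start,   # GRanges coordinates are 1-based inclusive
                   end = gr$end,
                   stringsAsFactors = FALSE)
  df[order(df$chrom, df$start), ]
}

#' Build genic and intergenic testing regions
#'
#' One genic region per gene and one intergenic region per gap between two
#' consecutive genes on the same chromosome; only regions containing at
#' least one genotyped SNP are emitted, and a SNP belongs to every region
#' covering it (overlapping genes can share SNPs). SNPs before the first or
#' after the last gene of a chromosome go to terminal regions of kind
#' `intergenic_telomeric` when `telomeric = TRUE` (default), so that on a
#' gap-free map every SNP belongs to at least one region.
#'
#' @param genes Data frame `gene_id`, `chrom`, `start`, `end` (1-based
#'   inclusive), e.g. from [read_genes_bed()]; must be valid intervals.
#' @param G A `genotype_matrix`.
#' @param telomeric Emit terminal intergenic regions (default `TRUE`).
#' @return A `region_set`: data frame with `region_id`, `chrom`, `start`,
#'   `end`, `kind` (`genic`, `intergenic`, `intergenic_telomeric`),
#'   `flank_gene_ids`, `n_snps` and a list-column `snp_ids`.
#' @export
build_regions <- function(genes, G, telomeric = TRUE) {
  stopifnot(inherits(G, "genotype_matrix"),
            all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  if (any(genes$end < genes$start)) stop("invalid gene interval (end < start)")
  rows <- list()
  add <- function(id, chrom, start, end, kind, flank) {
    snps <- G$map$snp_id[G$map$chrom == chrom & G$map$bp >= start &
                           G$map$bp <= end]
    if (!length(snps)) return()
    rows[[length(rows) + 1]] <<- data.frame(
      region_id = id, chrom = chrom, start = start, end = end, kind = kind,
      flank_gene_ids = flank, n_snps = length(snps),
      snp_ids = I(list(snps)), stringsAsFactors = FALSE)
  }
  for (chrom in unique(genes$chrom)) {
    gc <- genes[genes$chrom == chrom, , drop = FALSE]
    gc <- gc[order(gc$start, gc$end), , drop = FALSE]
    if (is.unsorted(gc$start)) stop("gene intervals unsorted")  # defensive
    for (i in seq_len(nrow(gc)))
      add(paste0("genic_", gc$gene_id[i]), chrom, gc$start[i], gc$end[i],
          "genic", gc$gene_id[i])
    if (nrow(gc) > 1) {
      for (i in seq_len(nrow(gc) - 1)) {
        gap_start <- max(gc$end[seq_len(i)]) + 1
        gap_end <- gc$start[i + 1] - 1
        if (gap_start > gap_end) next
        add(paste0("intergenic_", gc$gene_id[i], "_", gc$gene_id[i + 1]),
            chrom, gap_start, gap_end, "intergenic",
            paste(gc$gene_id[i], gc$gene_id[i + 1]))
      }
    }
    if (telomeric) {
      bp_chr <- G$map$bp[G$map$chrom == chrom]
      if (length(bp_chr)) {
        if (min(gc$start) > 1)
          add(paste0("intergenic_telomeric_", chrom, "_left"), chrom,
              1, min(gc$start) - 1, "intergenic_telomeric", gc$gene_id[1])
        hi <- max(gc$end)
        if (max(bp_chr) > hi)
          add(paste0("intergenic_telomeric_", chrom, "_right"), chrom,
              hi + 1, max(bp_chr), "intergenic_telomeric",
              gc$gene_id[nrow(gc)])
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(region_id = character(0), chrom = character(0),
               start = integer(0), end = integer(0), kind = character(0),
               flank_gene_ids = character(0), n_snps = integer(0),
               snp_ids = I(list()))
  rownames(out) <- NULL
  class(out) <- c("region_set", "data.frame")
  out
}

#' Greedy LD pruning of a SNP list
#'
#' Walks the SNPs left to right by position and keeps a SNP iff its squared
#' Pearson correlation of dosages with every already-kept SNP is at most
#' `r2_max` (strictly greater is removed, so a pair at exactly the
#' threshold is kept). Deterministic; r2 is computed on dosages (composite
#' LD, no phasing).
#'
#' @param G A `genotype_matrix` with complete (post-QC) dosages for the
#'   listed SNPs.
#' @param snp_ids SNP ids to prune (ordered by position internally).
#' @param r2_max Threshold (default 0.5).
#' @return Character vector of kept SNP ids, in position order.
#' @export
ld_prune <- function(G, snp_ids, r2_max = 0.5) {
  stopifnot(length(snp_ids) >= 1, all(snp_ids %in% G$map$snp_id))
  map <- G$map[match(snp_ids, G$map$snp_id), ]
  ord <- order(map$chrom, map$bp)
  snp_ids <- snp_ids[ord]
  d <- G$dosages[, snp_ids, drop = FALSE]
  if (anyNA(d)) stop("missing dosages; run QC first")
  sds <- apply(d, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance dosage column(s): ",
         paste(snp_ids[sds == 0], collapse = ", "))
  kept <- character(0)
  for (s in snp_ids) {
    if (!length(kept)) { kept <- s; next }
    r2 <- stats::cor(d[, s], d[, kept, drop = FALSE])^2
    if (all(r2 <= r2_max)) kept <- c(kept, s)
  }
  kept
}

#' LD-prune every region of a region set
#'
#' @param regions A `region_set`.
#' @param G A `genotype_matrix`.
#' @param r2_max Threshold passed to [ld_prune()].
#' @return The `region_set` with list-column `pruned_snp_ids` and column
#'   `n_pruned` added.
#' @export
prune_regions <- function(regions, G, r2_max = 0.5) {
  pruned <- lapply(regions$snp_ids, function(s) ld_prune(G, s, r2_max))
  regions$pruned_snp_ids <- I(pruned)
  regions$n_pruned <- vapply(pruned, length, integer(1))
  regions
}

#' Write a region table as TSV
#' @param regions A `region_set`.
#' @param path Output path.
#' @export
write_regions <- function(regions, path) {
  df <- regions[, c("region_id", "chrom", "start", "end", "kind", "n_snps")]
  df$n_pruned <- if ("n_pruned" %in% names(regions)) regions$n_pruned else NA
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
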