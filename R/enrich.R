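#' Map SNP positions to genes by interval overlap
#'
#' A gene is returned iff at least one query SNP lies within its
#' \[start, end\] interval (1-based, inclusive at both ends).
#'
#' @param positions data.frame with columns `chr` and `pos` (1-based).
#' @param intervals gene-interval data.frame with columns `gene`, `chr`,
#'   `start`, `end` (1-based inclusive), e.g. from [read_gene_intervals()].
#' @return Sorted character vector of unique gene symbols.
#' @export
snps_to_genes <- function(positions, intervals) {
  stopifnot(all(c("chr", "pos") %in% names(positions)),
            all(c("gene", "chr", "start", "end") %in% names(intervals)))
  if (any(intervals$start > intervals$end)) stop("interval start > end")
  if (!nrow(positions)) return(character(0))
  snp_gr <- GenomicRanges::GRanges(
    seqnames = as.character(positions$chr),
    ranges = IRanges::IRanges(start = positions$pos, width = 1))
  gene_gr <- GenomicRanges::GRanges(
    seqnames = as.character(intervals$chr),
    ranges = IRanges::IRanges(start = intervals$start, end = intervals$end))
  hits <- GenomicRanges::findOverlaps(snp_gr, gene_gr)
  sort(unique(intervals$gene[S4Vectors::subjectHits(hits)]))
}

#' Gene-set over-representation analysis
#'
#' One-sided Fisher exact (hypergeometric tail) test of each gene set
#' against a query gene list over a background universe, with fold
#' enrichment `(k/n) / (K/N)` and Bonferroni adjustment over the number of
#' tested sets. With `ease = TRUE`, one overlapping gene is subtracted
#' before the test (the EASE score penalty for categories supported by few
#' genes); margins are otherwise unchanged, so the EASE P is always at
#' least the Fisher P.
#'
#' @param query character vector of query genes; must be a subset of
#'   `background`.
#' @param sets named list of gene-symbol vectors (e.g. from [read_gmt()]).
#' @param background character vector of background genes; each set is
#'   intersected with it before testing.
#' @param ease logical; apply the EASE penalty (default `FALSE`).
#' @param alpha significance threshold on the adjusted P recorded in the
#'   `significant` column (default 0.01).
#' @return data.frame sorted by P with columns `set`, `k` (overlap), `n`
#'   (query size), `K` (set size in background), `N` (background size),
#'   `fold`, `p`, `p_adjusted`, `significant`.
#' @export
overrepresent <- function(query, sets, background, ease = FALSE, alpha = 0.01) {
  background <- unique(background)
  if (!length(background)) stop("empty background")
  query <- unique(query)
  if (!all(query %in% background))
    stop("query must be a subset of the background")
  if (any(!lengths(sets))) stop("empty gene set supplied")
  N <- length(background)
  n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    S <- intersect(unique(sets[[nm]]), background)
    K <- length(S)
    k <- length(intersect(query, S))
    fold <- if (K > 0) (k / n) / (K / N) else NA_real_
    k_test <- if (ease) max(k - 1L, 0L) else k
    p <- if (K == 0) 1 else
      stats::phyper(k_test - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, n = n, K = K, N = N, fold = fold, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bonferroni(out$p, length(sets))
  out$significant <- out$p_adjusted < alpha
  out[order(out$p, out$set), , drop = FALSE]
}
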