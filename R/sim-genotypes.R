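#' Simulate LD-blocked allele dosages
#'
#' Draws a subjects x SNPs dosage matrix with block-structured linkage
#' disequilibrium. SNPs are organized in `n_ld_blocks` contiguous blocks;
#' within a block, each subject's latent Gaussian values are equicorrelated
#' with correlation `block_r2` and are cut at the binomial(2, p) genotype
#' quantiles of each SNP's allele frequency p (drawn uniform over
#' `maf_range`), so marginal genotype frequencies follow Hardy-Weinberg
#' exactly; blocks are mutually independent. Quantile thresholding
#' attenuates the realized dosage correlation below the latent value
#' (empirically about 0.6-0.75 for a latent 0.8).
#'
#' Blocks are laid out 1 Mb apart along chromosomes 1-22 with 1 kb SNP
#' spacing, so a 250 kb clumping window spans a block but never two.
#' Allele pairs are drawn from the strand-unambiguous set (A/C, A/G, T/C,
#' T/G), mirroring the usual array-QC exclusion of ambiguous SNPs.
#'
#' @param cfg a [sim_config()].
#' @return A [dosage_matrix()] with no missing values; deterministic given
#'   `cfg` (including its seed).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_snps %% cfg$n_ld_blocks != 0)
    stop("n_snps must be divisible by n_ld_blocks")
  set.seed(cfg$seed)
  n <- cfg$n_subjects
  m <- cfg$n_snps
  per_block <- m %/% cfg$n_ld_blocks
  p <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
  q <- 1 - p
  thr0 <- qnorm(q^2)                    # below: genotype 0
  thr1 <- qnorm(q^2 + 2 * p * q)        # between: genotype 1; above: 2
  load <- sqrt(cfg$block_r2)
  values <- matrix(0, n, m)
  for (b in seq_len(cfg$n_ld_blocks)) {
    cols <- ((b - 1) * per_block + 1):(b * per_block)
    common <- rnorm(n)
    z <- load * common +
      sqrt(1 - cfg$block_r2) * matrix(rnorm(n * per_block), n, per_block)
    values[, cols] <- (z > rep(thr0[cols], each = n)) +
      (z > rep(thr1[cols], each = n))
  }
  # genomic layout: blocks cycle over chromosomes, 1 Mb apart, 1 kb spacing
  blk <- rep(seq_len(cfg$n_ld_blocks), each = per_block)
  chr <- ((blk - 1L) %% 22L) + 1L
  blk_within <- (blk - 1L) %/% 22L
  within <- rep(seq_len(per_block), cfg$n_ld_blocks)
  pos <- 1e6 * (blk_within + 1) + (within - 1L) * 1000L + 1L
  pairs <- matrix(c("A", "C", "A", "G", "T", "C", "T", "G"), ncol = 2, byrow = TRUE)
  pick <- sample.int(4L, m, replace = TRUE)
  map <- data.frame(snp = sprintf("snp%05d", seq_len(m)), chr = chr,
                    pos = as.integer(pos), A1 = pairs[pick, 1],
                    A2 = pairs[pick, 2], stringsAsFactors = FALSE)
  dosage_matrix(values, subject_ids = sprintf("S%04d", seq_len(n)), map = map)
}
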