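#' Simulate two overlapping sets of GWAS summary statistics
#'
#' Plants nonzero effects on a `causal_fraction` of SNPs for the discovery
#' disorder (ASD) and on an equally sized set for the comparison disorder
#' (SCZ), of which a fraction `overlap_fraction` is shared with the ASD
#' causal set and the remainder drawn from non-ASD-causal SNPs. Planted
#' effects are N(0, `effect_sd`^2). The reported per-SNP effect is the
#' planted effect plus Gaussian sampling noise of scale
#' `effect_sd / sqrt(n_eff)`, and the P value is the two-sided normal test
#' of that estimate against its sampling scale, so null SNPs have uniform
#' P values. P values are floored at 1e-300 to stay in (0, 1].
#'
#' @param cfg a [sim_config()]; must match the one used for `dosages`.
#' @param dosages the [dosage_matrix()] from [simulate_genotypes()]
#'   (supplies the SNP map so both tables share the dosage namespace).
#' @return list with elements `asd` and `scz`, each a summary-statistic
#'   data.frame (columns `snp`, `chr`, `pos`, `A1`, `A2`, `beta`, `p`) with
#'   a `truth` attribute recording the causal ids and true effects.
#' @export
simulate_summary_stats <- function(cfg, dosages) {
  stopifnot(inherits(cfg, "sim_config"), inherits(dosages, "dosage_matrix"))
  if (ncol(dosages$values) != cfg$n_snps)
    stop("dosages do not match cfg (SNP count differs)")
  set.seed(cfg$seed + 1L)
  m <- cfg$n_snps
  ids <- dosages$snp_ids
  n_causal <- round(cfg$causal_fraction * m)
  asd_causal <- sort(sample.int(m, n_causal))
  n_shared <- round(cfg$overlap_fraction * n_causal)
  scz_causal <- sort(c(sample(asd_causal, n_shared),
                       sample(setdiff(seq_len(m), asd_causal),
                              n_causal - n_shared)))
  one_table <- function(causal_idx, n_eff) {
    beta_true <- numeric(m)
    beta_true[causal_idx] <- rnorm(length(causal_idx), 0, cfg$effect_sd)
    se <- cfg$effect_sd / sqrt(n_eff)
    beta_hat <- beta_true + rnorm(m, 0, se)
    p <- pmax(2 * pnorm(-abs(beta_hat / se)), 1e-300)
    out <- data.frame(snp = ids, chr = dosages$map$chr, pos = dosages$map$pos,
                      A1 = dosages$map$A1, A2 = dosages$map$A2,
                      beta = beta_hat, p = p, stringsAsFactors = FALSE)
    attr(out, "truth") <- list(causal = ids[causal_idx],
                               beta_true = beta_true)
    out
  }
  list(asd = one_table(asd_causal, cfg$n_eff_asd),
       scz = one_table(scz_causal, cfg$n_eff_scz))
}
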