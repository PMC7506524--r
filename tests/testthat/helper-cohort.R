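# shared fixtures: small, fast configurations built in code

small_cfg <- function(...) {
  args <- list(...)
  defaults <- list(n_subjects = 80L, n_cases = 30L, n_snps = 100L,
                   n_ld_blocks = 10L, n_timepoints = 64L, seed = 42L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# dosage matrix from an explicit value matrix with unambiguous alleles
make_dosages <- function(values, chr = NULL, pos = NULL) {
  m <- ncol(values)
  if (is.null(chr)) chr <- rep(1L, m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  dosage_matrix(values,
                subject_ids = sprintf("S%03d", seq_len(nrow(values))),
                map = data.frame(snp = sprintf("v%03d", seq_len(m)),
                                 chr = chr, pos = pos, A1 = "A", A2 = "G",
                                 stringsAsFactors = FALSE))
}

# summary statistics matching a dosage matrix's map
make_stats <- function(dosages, beta, p) {
  data.frame(snp = dosages$map$snp, chr = dosages$map$chr,
             pos = dosages$map$pos, A1 = dosages$map$A1, A2 = dosages$map$A2,
             beta = beta, p = p, stringsAsFactors = FALSE)
}

# independent brute-force re-implementation of the greedy clumping rule,
# used as an oracle: visit by ascending p (ties: position, then id); an
# unclaimed SNP becomes an index and claims unclaimed same-chromosome SNPs
# within the window with squared correlation above the cutoff
clump_oracle <- function(stats, dosages, r2_cutoff = 0.1, window_kb = 250) {
  r2 <- suppressWarnings(cor(dosages$values[, stats$snp, drop = FALSE]))^2
  ord <- order(stats$p, stats$pos, stats$snp)
  claimed <- setNames(rep(FALSE, nrow(stats)), stats$snp)
  retained <- character(0)
  for (s in stats$snp[ord]) {
    if (claimed[[s]]) next
    claimed[[s]] <- TRUE
    retained <- c(retained, s)
    i <- match(s, stats$snp)
    for (t in stats$snp[!claimed]) {
      j <- match(t, stats$snp)
      ok <- stats$chr[j] == stats$chr[i] &&
        abs(stats$pos[j] - stats$pos[i]) <= window_kb * 1000 &&
        !is.na(r2[i, j]) && r2[i, j] > r2_cutoff
      if (ok) claimed[[t]] <- TRUE
    }
  }
  retained
}
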