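#' Quality-control thresholds
#'
#' Defaults follow standard array-QC practice: exclude SNPs with minor
#' allele frequency below 1%, call rate below 95% or Hardy-Weinberg
#' equilibrium P below 1e-5, and samples with missingness above 5%, a
#' flagged sex mismatch, or pairwise identity-by-descent above 0.90.
#'
#' @param maf_min minimum minor allele frequency.
#' @param call_rate_min minimum per-SNP call rate.
#' @param hwe_p_min minimum Hardy-Weinberg P value.
#' @param sample_missing_max maximum per-sample missing fraction.
#' @param ibd_max maximum pairwise PI_HAT.
#' @return A named list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(maf_min = 0.01, call_rate_min = 0.95,
                          hwe_p_min = 1e-5, sample_missing_max = 0.05,
                          ibd_max = 0.90) {
  vals <- c(maf_min, call_rate_min, hwe_p_min, sample_missing_max, ibd_max)
  if (any(vals < 0 | vals > 1)) stop("all thresholds must lie in [0, 1]")
  structure(list(maf_min = maf_min, call_rate_min = call_rate_min,
                 hwe_p_min = hwe_p_min, sample_missing_max = sample_missing_max,
                 ibd_max = ibd_max), class = "qc_thresholds")
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom chi-square goodness-of-fit of the observed
#' genotype counts against the p^2 / 2pq / q^2 expectation at the sample
#' allele frequency.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, total > 0).
#' @return Two-sided P value; monomorphic sites return 1 by convention
#'   (with a message).
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n <= 0) stop("total genotype count must be positive")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  if (p <= 0 || p >= 1) {
    message("monomorphic site: HWE P set to 1")
    return(1)
  }
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  stat <- sum((c(n_AA, n_Aa, n_aa) - expected)^2 / expected)
  pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Per-SNP quality control
#'
#' Computes minor allele frequency (mean dosage / 2 folded to <= 0.5), call
#' rate (1 - missing fraction) and the Hardy-Weinberg P value on hard calls
#' (dosage rounded to the nearest integer), and flags SNPs failing any
#' threshold with all failing reasons.
#'
#' @param dosages a [dosage_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @return A list of class `qc_report` with elements `variants`
#'   (data.frame: snp, maf, call_rate, hwe_p, pass, reason), `counts`
#'   (removed per criterion) and `pass_ids`.
#' @export
variant_qc <- function(dosages, thresholds = qc_thresholds()) {
  stopifnot(inherits(dosages, "dosage_matrix"))
  v <- dosages$values
  if (length(v) == 0) stop("empty dosage matrix")
  call_rate <- 1 - colMeans(is.na(v))
  af <- colMeans(v, na.rm = TRUE) / 2
  af[is.nan(af)] <- 0
  maf <- pmin(af, 1 - af)
  hard <- round(v)
  hwe_p <- vapply(seq_len(ncol(v)), function(j) {
    g <- hard[, j]
    g <- g[!is.na(g)]
    if (!length(g)) return(NA_real_)
    suppressMessages(hwe_test(sum(g == 2), sum(g == 1), sum(g == 0)))
  }, numeric(1))
  fail_maf <- maf < thresholds$maf_min
  fail_cr <- call_rate < thresholds$call_rate_min
  fail_hwe <- !is.na(hwe_p) & hwe_p < thresholds$hwe_p_min
  reason <- vapply(seq_along(fail_maf), function(j)
    paste(c(if (fail_maf[j]) "maf", if (fail_cr[j]) "call_rate",
            if (fail_hwe[j]) "hwe"), collapse = ";"), character(1))
  pass <- !(fail_maf | fail_cr | fail_hwe)
  variants <- data.frame(snp = dosages$snp_ids, maf = maf,
                         call_rate = call_rate, hwe_p = hwe_p,
                         pass = pass, reason = reason,
                         stringsAsFactors = FALSE, row.names = NULL)
  structure(list(variants = variants,
                 counts = c(maf = sum(fail_maf), call_rate = sum(fail_cr),
                            hwe = sum(fail_hwe), removed = sum(!pass)),
                 pass_ids = dosages$snp_ids[pass]),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  what <- if (!is.null(x$variants)) "variants" else "samples"
  tab <- if (!is.null(x$variants)) x$variants else x$samples
  cat(sprintf("qc_report (%s): %d tested, %d removed\n", what,
              nrow(tab), sum(!tab$pass)))
  print(x$counts)
  invisible(x)
}

# expected IBS-state proportions per SNP given allele frequency, used by the
# method-of-moments IBD estimator (PLINK-style, without small-sample terms)
ibs_expectations <- function(p) {
  q <- 1 - p
  list(e00 = 2 * p^2 * q^2,
       e10 = 4 * p^3 * q + 4 * p * q^3,
       e20 = p^4 + q^4 + 4 * p^2 * q^2,
       e11 = 2 * p^2 * q + 2 * p * q^2,
       e21 = p^3 + q^3 + p^2 * q + p * q^2)
}

#' Method-of-moments identity-by-descent estimate for one pair
#'
#' PLINK-style moment estimator: counts identity-by-state (IBS) states over
#' hard-called genotypes, compares them with their expectations under
#' IBD = 0/1/2 given the sample allele frequencies, and returns
#' PI_HAT = P(IBD=1)/2 + P(IBD=2), clipped to \[0, 1\].
#'
#' @param dosages a [dosage_matrix()].
#' @param pair character vector of two subject ids.
#' @return PI_HAT in \[0, 1\].
#' @export
estimate_ibd <- function(dosages, pair) {
  stopifnot(inherits(dosages, "dosage_matrix"), length(pair) == 2)
  miss <- setdiff(pair, dosages$subject_ids)
  if (length(miss)) stop("unknown subjects: ", paste(miss, collapse = ", "))
  hard <- round(dosages$values)
  g1 <- hard[pair[1], ]
  g2 <- hard[pair[2], ]
  af <- colMeans(hard, na.rm = TRUE) / 2
  ok <- !is.na(g1) & !is.na(g2) & af > 0 & af < 1
  if (sum(ok) < 100)
    stop(sprintf("fewer than 100 shared non-missing SNPs for pair (%s, %s)",
                 pair[1], pair[2]))
  g1 <- g1[ok]; g2 <- g2[ok]; af <- af[ok]
  dif <- abs(g1 - g2)
  n0 <- sum(dif == 2)
  n1 <- sum(dif == 1)
  n2 <- sum(dif == 0)
  ex <- ibs_expectations(af)
  E <- list(e00 = sum(ex$e00), e10 = sum(ex$e10), e20 = sum(ex$e20),
            e11 = sum(ex$e11), e21 = sum(ex$e21))
  nsnp <- length(g1)
  P0 <- n0 / E$e00
  P1 <- (n1 - P0 * E$e10) / E$e11
  P2 <- (n2 - P0 * E$e20 - P1 * E$e21) / nsnp
  z <- pmin(1, pmax(0, c(P0, P1, P2)))
  min(1, max(0, z[2] / 2 + z[3]))
}

#' Per-sample quality control
#'
#' Excludes samples with missingness above `sample_missing_max`, a flagged
#' sex mismatch, or membership in a pair with PI_HAT above `ibd_max`. Of an
#' over-related pair, the member with higher missingness is removed; on a
#' tie, the lexicographically smaller id.
#'
#' @param dosages a [dosage_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @param sex_mismatch optional logical vector (or character vector of ids)
#'   flagging reported-vs-genetic sex mismatches.
#' @param pi_hat optional precomputed symmetric PI_HAT matrix with subject
#'   dimnames; computed from `dosages` when omitted.
#' @return A `qc_report` with elements `samples` (data.frame: subject,
#'   missingness, max_pi_hat, pass, reason), `counts` and `pass_ids`.
#' @export
sample_qc <- function(dosages, thresholds = qc_thresholds(),
                      sex_mismatch = NULL, pi_hat = NULL) {
  stopifnot(inherits(dosages, "dosage_matrix"))
  ids <- dosages$subject_ids
  n <- length(ids)
  missingness <- rowMeans(is.na(dosages$values))
  if (is.character(sex_mismatch)) sex_mismatch <- ids %in% sex_mismatch
  if (is.null(sex_mismatch)) sex_mismatch <- rep(FALSE, n)
  if (is.null(pi_hat)) pi_hat <- ibd_matrix(dosages)
  fail_miss <- missingness > thresholds$sample_missing_max
  fail_sex <- sex_mismatch
  # resolve over-related pairs
  fail_ibd <- rep(FALSE, n)
  names(fail_ibd) <- ids
  ut <- which(upper.tri(pi_hat) & pi_hat > thresholds$ibd_max, arr.ind = TRUE)
  if (nrow(ut)) {
    for (r in seq_len(nrow(ut))) {
      a <- rownames(pi_hat)[ut[r, 1]]
      b <- colnames(pi_hat)[ut[r, 2]]
      drop <- if (missingness[a] != missingness[b]) {
        if (missingness[a] > missingness[b]) a else b
      } else min(a, b)
      fail_ibd[drop] <- TRUE
    }
  }
  max_pi <- apply(pi_hat + diag(NA_real_, n), 1, max, na.rm = n > 1)
  if (n == 1) max_pi <- 0
  reason <- vapply(seq_len(n), function(i)
    paste(c(if (fail_miss[i]) "missingness", if (fail_sex[i]) "sex",
            if (fail_ibd[i]) "ibd"), collapse = ";"), character(1))
  pass <- !(fail_miss | fail_sex | fail_ibd)
  samples <- data.frame(subject = ids, missingness = missingness,
                        max_pi_hat = max_pi, pass = pass, reason = reason,
                        stringsAsFactors = FALSE, row.names = NULL)
  structure(list(samples = samples,
                 counts = c(missingness = sum(fail_miss), sex = sum(fail_sex),
                            ibd = sum(fail_ibd), removed = sum(!pass)),
                 pass_ids = ids[pass]),
            class = "qc_report")
}

#' Pairwise PI_HAT matrix
#'
#' Applies the [estimate_ibd()] moment estimator to every subject pair.
#' Intended for modest cohort sizes; the loop is over pairs.
#'
#' @param dosages a [dosage_matrix()].
#' @return Symmetric matrix of PI_HAT values (diagonal 1).
#' @export
ibd_matrix <- function(dosages) {
  stopifnot(inherits(dosages, "dosage_matrix"))
  ids <- dosages$subject_ids
  n <- length(ids)
  hard <- round(dosages$values)
  af <- colMeans(hard, na.rm = TRUE) / 2
  ok <- af > 0 & af < 1
  hard <- hard[, ok, drop = FALSE]
  ex <- ibs_expectations(af[ok])
  E00 <- sum(ex$e00); E10 <- sum(ex$e10); E20 <- sum(ex$e20)
  E11 <- sum(ex$e11); E21 <- sum(ex$e21)
  nsnp <- ncol(hard)
  out <- diag(1, n)
  dimnames(out) <- list(ids, ids)
  if (nsnp < 100) stop("fewer than 100 polymorphic SNPs for IBD estimation")
  for (i in seq_len(n - 1)) {
    di <- abs(sweep(hard[(i + 1):n, , drop = FALSE], 2, hard[i, ]))
    n0 <- rowSums(di == 2, na.rm = TRUE)
    n2 <- rowSums(di == 0, na.rm = TRUE)
    n1 <- nsnp - n0 - n2
    P0 <- n0 / E00
    P1 <- (n1 - P0 * E10) / E11
    P2 <- (n2 - P0 * E20 - P1 * E21) / nsnp
    z1 <- pmin(1, pmax(0, P1))
    z2 <- pmin(1, pmax(0, P2))
    ph <- pmin(1, pmax(0, z1 / 2 + z2))
    out[i, (i + 1):n] <- ph
    out[(i + 1):n, i] <- ph
  }
  out
}
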