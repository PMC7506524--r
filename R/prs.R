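#' High-resolution P-value threshold grid
#'
#' The 103 thresholds used for the PRS scan: every multiple of 0.005 in
#' (0, 0.5] plus 1e-5, 1e-4 and 1e-3, sorted ascending. A threshold of 0
#' is excluded because it selects no SNPs.
#'
#' @return Numeric vector of 103 strictly increasing thresholds in (0, 0.5].
#' @export
make_grid <- function() {
  sort(c(1e-5, 1e-4, 1e-3, seq_len(100) * 0.005))
}

#' P-value-informed LD clumping
#'
#' Greedy clumping as performed by standard PRS software: SNPs are visited
#' by ascending discovery P value (ties broken by ascending position, then
#' id); each unclaimed SNP becomes an index SNP and claims every unclaimed
#' SNP on the same chromosome within `window_kb` kilobases whose squared
#' dosage correlation with it exceeds `r2_cutoff`. LD is computed from the
#' target-sample dosages.
#'
#' @param stats summary-statistic data.frame (columns `snp`, `chr`, `pos`,
#'   `A1`, `A2`, `beta`, `p`).
#' @param ld_source a [dosage_matrix()] containing every SNP in `stats`.
#' @param r2_cutoff squared-correlation cutoff (default 0.1).
#' @param window_kb window half-width in kilobases (default 250).
#' @return A list of class `clump_result` with `retained` (index SNP ids),
#'   `absorbed` (data.frame: snp, index, r2) and the parameters.
#' @export
clump <- function(stats, ld_source, r2_cutoff = 0.1, window_kb = 250) {
  stopifnot(inherits(ld_source, "dosage_matrix"))
  missing <- setdiff(stats$snp, ld_source$snp_ids)
  if (length(missing))
    stop("SNP(s) absent from LD source: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5))
  ord <- order(stats$p, stats$pos, stats$snp)
  s <- stats[ord, , drop = FALSE]
  window <- window_kb * 1000
  claimed <- rep(FALSE, nrow(s))
  retained <- character(0)
  abs_snp <- character(0); abs_index <- character(0); abs_r2 <- numeric(0)
  vals <- ld_source$values[, s$snp, drop = FALSE]
  for (i in seq_len(nrow(s))) {
    if (claimed[i]) next
    claimed[i] <- TRUE
    retained <- c(retained, s$snp[i])
    cand <- which(!claimed & s$chr == s$chr[i] &
                    abs(s$pos - s$pos[i]) <= window)
    if (!length(cand)) next
    r <- suppressWarnings(
      cor(vals[, i], vals[, cand, drop = FALSE], use = "pairwise.complete.obs"))
    r2 <- as.vector(r)^2
    r2[is.na(r2)] <- 0
    hit <- cand[r2 > r2_cutoff]
    if (length(hit)) {
      claimed[hit] <- TRUE
      abs_snp <- c(abs_snp, s$snp[hit])
      abs_index <- c(abs_index, rep(s$snp[i], length(hit)))
      abs_r2 <- c(abs_r2, r2[r2 > r2_cutoff])
    }
  }
  structure(list(retained = retained,
                 absorbed = data.frame(snp = abs_snp, index = abs_index,
                                       r2 = abs_r2, stringsAsFactors = FALSE),
                 r2_cutoff = r2_cutoff, window_kb = window_kb),
            class = "clump_result")
}

#' @export
print.clump_result <- function(x, ...) {
  cat(sprintf("clump_result: %d index SNPs retained, %d absorbed (r2 > %g, %g kb)\n",
              length(x$retained), nrow(x$absorbed), x$r2_cutoff, x$window_kb))
  invisible(x)
}

# Align summary-statistic effect alleles to target dosages.
# Returns list(dosage = aligned matrix, beta, ids, dropped = data.frame).
align_alleles <- function(dosages, stats, ids) {
  st <- stats[match(ids, stats$snp), , drop = FALSE]
  mp <- dosages$map[match(ids, dosages$map$snp), , drop = FALSE]
  ambiguous <- (st$A1 == "A" & st$A2 == "T") | (st$A1 == "T" & st$A2 == "A") |
    (st$A1 == "C" & st$A2 == "G") | (st$A1 == "G" & st$A2 == "C")
  direct <- !ambiguous & st$A1 == mp$A1 & st$A2 == mp$A2
  swapped <- !ambiguous & st$A1 == mp$A2 & st$A2 == mp$A1
  keep <- direct | swapped
  dropped <- data.frame(
    snp = ids[!keep],
    reason = ifelse(ambiguous[!keep], "strand_ambiguous", "allele_mismatch"),
    stringsAsFactors = FALSE)
  ids <- ids[keep]
  x <- dosages$values[, ids, drop = FALSE]
  if (anyNA(x)) {                       # missing dosage -> per-SNP mean
    mu <- colMeans(x, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- mu[idx[, 2]]
  }
  sw <- swapped[keep]
  if (any(sw)) x[, sw] <- 2 - x[, sw, drop = FALSE]
  list(dosage = x, beta = st$beta[keep], ids = ids, dropped = dropped)
}

#' Score subjects at one P-value threshold
#'
#' Additive dosage-weighted sum over the clump-retained SNPs with discovery
#' P at or below `p_t` (optionally intersected with `snp_subset`), in the
#' convention of standard PRS software: effect alleles are aligned to the
#' target (swapped alleles use 2 - dosage), strand-ambiguous A/T and C/G
#' SNPs are dropped with a logged count, and missing dosages are replaced
#' by the SNP's mean dosage.
#'
#' @param dosages a [dosage_matrix()].
#' @param stats summary-statistic data.frame.
#' @param clump a [clump()] result on `stats`.
#' @param p_t P-value threshold.
#' @param snp_subset optional character vector restricting the SNPs used
#'   (e.g. a partition from [partition_snps()]).
#' @return list with `score` (named numeric vector), `n_snps`, and
#'   `dropped` (data.frame of dropped SNPs with reasons).
#' @export
prs_score <- function(dosages, stats, clump, p_t, snp_subset = NULL) {
  stopifnot(inherits(clump, "clump_result"))
  sel <- clump$retained[clump$retained %in% stats$snp[stats$p <= p_t]]
  if (!is.null(snp_subset)) sel <- intersect(sel, snp_subset)
  if (!length(sel)) stop("all SNPs dropped: empty selection at p_t = ", p_t)
  al <- align_alleles(dosages, stats, sel)
  if (nrow(al$dropped))
    message(sprintf("dropped %d SNP(s): %s", nrow(al$dropped),
                    paste(unique(al$dropped$reason), collapse = ", ")))
  if (!length(al$ids)) stop("all SNPs dropped: no alignable SNPs at p_t = ", p_t)
  score <- as.vector(al$dosage %*% al$beta)
  names(score) <- dosages$subject_ids
  list(score = score, n_snps = length(al$ids), dropped = al$dropped)
}

#' Score subjects across a threshold grid
#'
#' Computes the PRS of every subject at each threshold of `grid` in one
#' pass (SNP contributions are accumulated in ascending-P order, so the
#' per-threshold SNP sets are nested). Thresholds selecting no SNPs get an
#' `NA` score and `n_snps = 0`.
#'
#' @inheritParams prs_score
#' @param grid threshold vector, default [make_grid()].
#' @param label score label (e.g. "ASD", "SCZ", "ASD&SCZ", "ASD-specific").
#' @return An object of class `prs_profile`: list with `subjects`,
#'   `thresholds`, `scores` (subjects x thresholds matrix), `n_snps`,
#'   `label`, `dropped`.
#' @export
score_profile <- function(dosages, stats, clump, grid = make_grid(),
                          snp_subset = NULL, label = "ASD") {
  stopifnot(inherits(clump, "clump_result"))
  sel <- intersect(clump$retained, stats$snp)
  if (!is.null(snp_subset)) sel <- intersect(sel, snp_subset)
  al <- align_alleles(dosages, stats, sel)
  p <- stats$p[match(al$ids, stats$snp)]
  ord <- order(p)
  contrib <- sweep(al$dosage[, ord, drop = FALSE], 2, al$beta[ord], "*")
  cum <- if (ncol(contrib) > 1) t(apply(contrib, 1, cumsum)) else contrib
  psort <- p[ord]
  n <- nrow(dosages$values)
  scores <- matrix(NA_real_, n, length(grid),
                   dimnames = list(dosages$subject_ids, as.character(grid)))
  n_snps <- integer(length(grid))
  for (j in seq_along(grid)) {
    k <- findInterval(grid[j], psort)   # number of SNPs with p <= grid[j]
    n_snps[j] <- k
    if (k > 0) scores[, j] <- cum[, k]
  }
  structure(list(subjects = dosages$subject_ids, thresholds = grid,
                 scores = scores, n_snps = n_snps, label = label,
                 dropped = al$dropped),
            class = "prs_profile")
}

#' @export
print.prs_profile <- function(x, ...) {
  cat(sprintf("prs_profile [%s]: %d subjects x %d thresholds (n_snps %d..%d)\n",
              x$label, length(x$subjects), length(x$thresholds),
              min(x$n_snps), max(x$n_snps)))
  invisible(x)
}

#' Partition the discovery PRS SNP set into shared and specific subsets
#'
#' Over the ASD SNPs retained by clumping with ASD P at or below `p_t`,
#' returns the SNPs shared with the comparison (SCZ) summary statistics
#' and those specific to ASD. Under the default rule a SNP is "shared"
#' when it is present in the SCZ table with SCZ P at or below the same
#' `p_t`; with `scz_rule = "present"`, mere presence in the SCZ table
#' suffices.
#'
#' @param asd_stats,scz_stats summary-statistic data.frames sharing the
#'   SNP-id namespace.
#' @param clump a [clump()] result on `asd_stats`.
#' @param p_t P-value threshold.
#' @param scz_rule `"p_le_t"` (default) or `"present"`.
#' @return list with character vectors `shared` and `specific`
#'   (disjoint; union = the ASD selection at `p_t`).
#' @export
partition_snps <- function(asd_stats, scz_stats, clump, p_t,
                           scz_rule = c("p_le_t", "present")) {
  scz_rule <- match.arg(scz_rule)
  stopifnot(inherits(clump, "clump_result"))
  asd_sel <- clump$retained[clump$retained %in% asd_stats$snp[asd_stats$p <= p_t]]
  scz_ok <- if (scz_rule == "p_le_t")
    scz_stats$snp[scz_stats$p <= p_t] else scz_stats$snp
  shared <- intersect(asd_sel, scz_ok)
  list(shared = shared, specific = setdiff(asd_sel, shared))
}
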