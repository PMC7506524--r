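#' Ancestry principal components from dosages
#'
#' Computes principal-component scores of the column-standardized dosage
#' matrix for use as population-stratification covariates. Missing dosages
#' are mean-imputed per SNP; each SNP is centered at twice its allele
#' frequency and scaled by sqrt(2 p (1 - p)), the population-genetics
#' convention. Components are ordered by decreasing variance explained and
#' signed so that each loading vector's largest-magnitude element is
#' positive.
#'
#' @param dosages a [dosage_matrix()] (QC-passing).
#' @param k number of components (default 4).
#' @return data.frame with `subject` and columns `PC1..PCk`, with the
#'   proportion of variance explained in attribute `var_explained`.
#' @export
compute_pcs <- function(dosages, k = 4L) {
  stopifnot(inherits(dosages, "dosage_matrix"))
  n <- nrow(dosages$values)
  if (k >= n) stop("k must be smaller than the number of subjects")
  x <- dosages$values
  # mean-impute missing values per SNP
  if (anyNA(x)) {
    mu <- colMeans(x, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- mu[idx[, 2]]
  }
  p <- colMeans(x) / 2
  keep <- p > 0 & p < 1
  x <- x[, keep, drop = FALSE]
  p <- p[keep]
  xs <- sweep(sweep(x, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
  sv <- svd(xs, nu = k, nv = k)
  signs <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] >= 0) 1 else -1
  }, numeric(1))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k) %*% diag(signs, k)
  colnames(scores) <- paste0("PC", seq_len(k))
  out <- data.frame(subject = dosages$subject_ids, scores,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "var_explained") <- (sv$d[seq_len(k)]^2) / sum(sv$d^2)
  out
}
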