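#' Run the full cross-disorder PRS association pipeline on a cohort
#'
#' End-to-end convenience wrapper mirroring the study design: variant QC,
#' ancestry PCs, P-value-informed clumping of the discovery (ASD) summary
#' statistics, scoring over the threshold grid, a case-control scan
#' selecting the `top_k` thresholds, motion screening, region-wise
#' normalized ALFF, and covariate-adjusted association of the selected
#' scores with the 90 regional ALFF values (Bonferroni family 90) and the
#' four emotion scores (family 4). Covariates are age, sex, education,
#' disease status and the first `n_pcs` ancestry components.
#'
#' @param cohort a `synthetic_cohort` (or an equivalently shaped list read
#'   from disk).
#' @param grid threshold grid, default [make_grid()].
#' @param top_k thresholds selected by the scan (default 10).
#' @param n_pcs number of ancestry PCs used as covariates (default 4).
#' @param thresholds a [qc_thresholds()].
#' @param run_sample_qc logical; also run missingness/IBD sample QC
#'   (quadratic in subjects; default `FALSE` since synthetic cohorts are
#'   clean by construction).
#' @return list with elements `scan` (a `scan_result`), `alff_assoc` and
#'   `emotion_assoc` (data.frames over selected thresholds x outcomes),
#'   `alff` (subjects x 90 normalized matrix), `profile`, `clump`, `pcs`,
#'   `kept_subjects`.
#' @export
run_pipeline <- function(cohort, grid = make_grid(), top_k = 10L, n_pcs = 4L,
                         thresholds = qc_thresholds(), run_sample_qc = FALSE) {
  dos <- cohort$dosages
  vqc <- variant_qc(dos, thresholds)
  if (length(vqc$pass_ids) < ncol(dos$values))
    dos <- subset_dosages(dos, snps = vqc$pass_ids)
  if (run_sample_qc) {
    sqc <- sample_qc(dos, thresholds)
    if (length(sqc$pass_ids) < nrow(dos$values))
      dos <- subset_dosages(dos, subjects = sqc$pass_ids)
  }
  keep_motion <- motion_screen(cohort$motion[, -1, drop = FALSE])
  kept <- intersect(dos$subject_ids, cohort$motion$subject[keep_motion])
  dos <- subset_dosages(dos, subjects = kept)

  pcs <- compute_pcs(dos, k = n_pcs)
  cov_rows <- match(kept, cohort$covariates$subject)
  covars <- data.frame(age = cohort$covariates$age[cov_rows],
                       sex = cohort$covariates$sex[cov_rows],
                       education = cohort$covariates$education[cov_rows],
                       pcs[, -1, drop = FALSE])
  status <- cohort$covariates$status[cov_rows]

  stats <- cohort$asd_stats[cohort$asd_stats$snp %in% dos$snp_ids, , drop = FALSE]
  cl <- clump(stats, dos)
  profile <- score_profile(dos, stats, cl, grid = grid, label = "ASD")
  scan <- prs_scan(profile, status, covars, top_k = top_k)
  selected <- attr(scan, "selected")

  alff_mat <- cohort_alff(cohort$series[kept])
  covars_status <- cbind(covars, status = status)
  em_rows <- match(kept, cohort$emotion$subject)
  emotion <- as.matrix(cohort$emotion[em_rows, c("positive", "neutral",
                                                 "negative", "total")])
  alff_assoc <- do.call(rbind, lapply(selected, function(pt) {
    j <- match(pt, profile$thresholds)
    fit_assoc_matrix(alff_mat, profile$scores[, j], covars_status,
                     label = profile$label, p_t = pt, m_tests = 90L)
  }))
  emotion_assoc <- do.call(rbind, lapply(selected, function(pt) {
    j <- match(pt, profile$thresholds)
    fit_assoc_matrix(emotion, profile$scores[, j], covars_status,
                     label = profile$label, p_t = pt, m_tests = 4L)
  }))
  list(scan = scan, alff_assoc = alff_assoc, emotion_assoc = emotion_assoc,
       alff = alff_mat, profile = profile, clump = cl, pcs = pcs,
       kept_subjects = kept)
}
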