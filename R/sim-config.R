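#' Configuration for the synthetic-cohort generator
#'
#' Bundles every knob of the simulator. Defaults reproduce the study
#' conditions the pipeline is designed for: a target sample of 328 subjects
#' (116 schizophrenia cases, 212 healthy controls), LD-blocked dosages,
#' two overlapping discovery GWAS (ASD and SCZ, with effective discovery
#' sizes 46,350 and 65,967), 90-region resting-state BOLD series of 170
#' volumes at TR = 2 s, a planted PRS effect on the in-band amplitude of
#' the left-amygdala region (AAL index 41), and a planted negative effect
#' of the score on negative-emotion recognition.
#'
#' The planted effect sizes default to `planted_beta = 0.095` (sinusoid
#' amplitude units per score SD) and `emotion_beta = 0.73` (items per score
#' SD), calibrated analytically so that the measured covariate-adjusted
#' partial correlations are about +0.21 (ALFF) and -0.23 (negative
#' emotions) under the default noise model; see the methods vignette.
#'
#' @param n_subjects number of target-sample subjects.
#' @param n_cases number of cases (first `n_cases` subjects).
#' @param n_snps number of SNPs; must be divisible by `n_ld_blocks`.
#' @param n_ld_blocks number of independent LD blocks.
#' @param block_r2 latent within-block correlation in \[0, 1).
#' @param maf_range range minor allele frequencies are drawn from.
#' @param causal_fraction fraction of SNPs with nonzero planted ASD effect.
#' @param effect_sd SD of planted per-SNP effects (log-odds scale); the
#'   summary-statistic sampling noise has scale `effect_sd / sqrt(n_eff)`.
#' @param overlap_fraction fraction of ASD causal SNPs shared with SCZ.
#' @param n_eff_asd,n_eff_scz effective discovery sample sizes.
#' @param planted_region atlas index (1-90) of the region carrying the
#'   planted PRS effect; default 41 (left amygdala).
#' @param planted_beta slope of the in-band sinusoid amplitude on the true
#'   standardized score (amplitude units per score SD); 0 plants nothing.
#' @param emotion_beta drop in negative-emotion items per score SD.
#' @param planted_freq_hz nominal frequency of the planted oscillation;
#'   snapped to the nearest Fourier frequency of (`n_timepoints`, `tr_seconds`).
#' @param alff_base_amp baseline in-band sinusoid amplitude common to all
#'   subjects in the planted region.
#' @param noise_sd SD of the white noise in every region's series.
#' @param n_timepoints BOLD volumes per subject (after discarding initial
#'   volumes); must be at least 64.
#' @param tr_seconds sampling interval (repetition time), seconds.
#' @param max_items items per emotion category (score ceiling).
#' @param emotion_sd SD of the noise on emotion scores (items).
#' @param demographics list of case/control means and SDs for age and
#'   education plus male fractions; defaults mimic the direction of the
#'   study cohort (controls older and more educated).
#' @param seed integer seed; all generator stages derive their RNG state
#'   from it, so identical configurations give identical cohorts.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(n_subjects = 328L, n_cases = 116L,
                       n_snps = 2000L, n_ld_blocks = 200L,
                       block_r2 = 0.8, maf_range = c(0.05, 0.5),
                       causal_fraction = 0.1, effect_sd = 0.05,
                       overlap_fraction = 0.5,
                       n_eff_asd = 46350L, n_eff_scz = 65967L,
                       planted_region = 41L, planted_beta = 0.095,
                       emotion_beta = 0.73, planted_freq_hz = 0.04,
                       alff_base_amp = 1, noise_sd = 1,
                       n_timepoints = 170L, tr_seconds = 2,
                       max_items = 20L, emotion_sd = 2.5,
                       demographics = NULL, seed = 1L) {
  if (is.null(demographics))
    demographics <- list(
      age_mean = c(case = 24.24, control = 34.71),
      age_sd = c(case = 9.03, control = 12.69),
      edu_mean = c(case = 10.78, control = 13.76),
      edu_sd = c(case = 2.92, control = 3.71),
      male_frac = c(case = 36 / 116, control = 83 / 212),
      emotion_mean = list(
        positive = c(case = 11.25, control = 11.55),
        neutral = c(case = 13.45, control = 14.74),
        negative = c(case = 11.98, control = 13.20)))
  cfg <- list(n_subjects = as.integer(n_subjects), n_cases = as.integer(n_cases),
              n_snps = as.integer(n_snps), n_ld_blocks = as.integer(n_ld_blocks),
              block_r2 = block_r2, maf_range = maf_range,
              causal_fraction = causal_fraction, effect_sd = effect_sd,
              overlap_fraction = overlap_fraction,
              n_eff_asd = as.integer(n_eff_asd), n_eff_scz = as.integer(n_eff_scz),
              planted_region = as.integer(planted_region),
              planted_beta = planted_beta, emotion_beta = emotion_beta,
              planted_freq_hz = planted_freq_hz,
              alff_base_amp = alff_base_amp, noise_sd = noise_sd,
              n_timepoints = as.integer(n_timepoints), tr_seconds = tr_seconds,
              max_items = as.integer(max_items), emotion_sd = emotion_sd,
              demographics = demographics, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_subjects >= 2, n_cases >= 0, n_cases <= n_subjects,
              n_snps >= 1, n_ld_blocks >= 1,
              block_r2 >= 0, block_r2 < 1,
              causal_fraction >= 0, causal_fraction <= 1,
              overlap_fraction >= 0, overlap_fraction <= 1,
              effect_sd > 0, n_eff_asd > 0, n_eff_scz > 0,
              planted_region >= 1, planted_region <= 90,
              planted_freq_hz > 0, alff_base_amp >= 0, noise_sd > 0,
              n_timepoints >= 64, tr_seconds > 0,
              max_items >= 1, emotion_sd > 0)
    if (planted_freq_hz >= 1 / (2 * tr_seconds))
      stop("planted_freq_hz must be below the Nyquist frequency")
  })
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "sim_config: %d subjects (%d cases), %d SNPs in %d LD blocks (r2 = %.2f)\n",
    "  planted region %d, planted_beta = %.3g, emotion_beta = %.3g, seed = %d\n"),
    x$n_subjects, x$n_cases, x$n_snps, x$n_ld_blocks, x$block_r2,
    x$planted_region, x$planted_beta, x$emotion_beta, x$seed))
  invisible(x)
}
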