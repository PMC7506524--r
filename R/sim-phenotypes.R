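#' Simulate phenotypes, covariates and BOLD series with planted effects
#'
#' Builds the per-subject data the association pipeline consumes. The true
#' polygenic score is the dosage-weighted sum of planted ASD effects,
#' standardized. The planted atlas region's series is white noise plus an
#' in-band sinusoid (frequency snapped to the nearest Fourier bin of the
#' series) whose amplitude is `alff_base_amp + planted_beta * score`,
#' floored at zero; all other regions are pure white noise. The
#' negative-emotion score is `round(base - emotion_beta * score + noise)`
#' clipped to \[0, max_items\]; positive and neutral scores carry no score
#' effect, and the total is the sum of the three. Age, sex and education
#' are drawn with case-control differences in the directions seen in
#' clinical cohorts (controls older, more educated).
#'
#' @param cfg a [sim_config()].
#' @param dosages output of [simulate_genotypes()] under the same `cfg`.
#' @param asd_stats ASD element of [simulate_summary_stats()] under the
#'   same `cfg` (its `truth` attribute supplies the planted effects).
#' @return An object of class `synthetic_cohort`: list with elements
#'   `dosages`, `asd_stats`, `scz_stats` (if supplied via attribute, else
#'   `NULL`), `covariates` (data.frame: subject, status, age, sex,
#'   education, handedness), `emotion` (data.frame: subject, positive,
#'   neutral, negative, total), `series` (named list of [region_series()]),
#'   `motion` (data.frame of per-axis maxima), and `truth` (planted
#'   parameters, causal SNPs and the true score).
#' @export
simulate_phenotypes <- function(cfg, dosages, asd_stats) {
  stopifnot(inherits(cfg, "sim_config"), inherits(dosages, "dosage_matrix"))
  truth_in <- attr(asd_stats, "truth")
  if (is.null(truth_in))
    stop("asd_stats must carry the 'truth' attribute from simulate_summary_stats()")
  set.seed(cfg$seed + 2L)
  n <- cfg$n_subjects
  ids <- dosages$subject_ids
  status <- c(rep(1L, cfg$n_cases), rep(0L, n - cfg$n_cases))

  ## true standardized score
  g <- as.vector(dosages$values %*% truth_in$beta_true)
  score <- if (sd(g) > 0) as.vector(scale(g)) else numeric(n)

  ## demographics with case-control shifts
  d <- cfg$demographics
  grp <- ifelse(status == 1L, "case", "control")
  age <- pmax(16, rnorm(n, d$age_mean[grp], d$age_sd[grp]))
  education <- pmax(0, rnorm(n, d$edu_mean[grp], d$edu_sd[grp]))
  sex <- rbinom(n, 1L, d$male_frac[grp])          # 1 = male
  handedness <- sample(c("R", "L", "MIX"), n, replace = TRUE,
                       prob = c(0.94, 0.02, 0.04))
  covariates <- data.frame(subject = ids, status = status, age = age,
                           sex = sex, education = education,
                           handedness = handedness, stringsAsFactors = FALSE)

  ## emotion-recognition scores (integer counts, ceiling max_items)
  clipi <- function(x) pmin(cfg$max_items, pmax(0L, as.integer(round(x))))
  em <- d$emotion_mean
  positive <- clipi(em$positive[grp] + rnorm(n, 0, cfg$emotion_sd))
  neutral  <- clipi(em$neutral[grp] + rnorm(n, 0, cfg$emotion_sd))
  negative <- clipi(em$negative[grp] - cfg$emotion_beta * score +
                      rnorm(n, 0, cfg$emotion_sd))
  emotion <- data.frame(subject = ids, positive = positive, neutral = neutral,
                        negative = negative,
                        total = positive + neutral + negative,
                        stringsAsFactors = FALSE)

  ## region-wise BOLD series; planted sinusoid at an exact Fourier bin
  nt <- cfg$n_timepoints
  k0 <- max(1L, round(cfg$planted_freq_hz * nt * cfg$tr_seconds))
  f0 <- k0 / (nt * cfg$tr_seconds)
  tt <- seq_len(nt) * cfg$tr_seconds
  amp <- pmax(0, cfg$alff_base_amp + cfg$planted_beta * score)
  phase <- runif(n, 0, 2 * pi)
  series <- vector("list", n)
  names(series) <- ids
  for (i in seq_len(n)) {
    mat <- matrix(rnorm(nt * 90L, 0, cfg$noise_sd), nt, 90L)
    mat[, cfg$planted_region] <- mat[, cfg$planted_region] +
      amp[i] * sin(2 * pi * f0 * tt + phase[i])
    series[[i]] <- region_series(mat, tr = cfg$tr_seconds, subject_id = ids[i])
  }

  motion <- data.frame(subject = ids,
                       trans_x = runif(n, 0, 2.5), trans_y = runif(n, 0, 2.5),
                       trans_z = runif(n, 0, 2.5), rot_x = runif(n, 0, 2.5),
                       rot_y = runif(n, 0, 2.5), rot_z = runif(n, 0, 2.5),
                       stringsAsFactors = FALSE)

  structure(list(dosages = dosages, asd_stats = asd_stats, scz_stats = NULL,
                 covariates = covariates, emotion = emotion, series = series,
                 motion = motion,
                 truth = list(planted_region = cfg$planted_region,
                              planted_beta = cfg$planted_beta,
                              emotion_beta = cfg$emotion_beta,
                              planted_freq_hz = f0,
                              causal = truth_in$causal,
                              beta_true = truth_in$beta_true,
                              score = score)),
            class = "synthetic_cohort")
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper running [simulate_genotypes()],
#' [simulate_summary_stats()] and [simulate_phenotypes()] in order.
#'
#' @param cfg a [sim_config()].
#' @return A `synthetic_cohort` with both `asd_stats` and `scz_stats` filled.
#' @export
simulate_cohort <- function(cfg) {
  dosages <- simulate_genotypes(cfg)
  stats <- simulate_summary_stats(cfg, dosages)
  cohort <- simulate_phenotypes(cfg, dosages, stats$asd)
  cohort$scz_stats <- stats$scz
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0(
    "synthetic_cohort: %d subjects (%d cases), %d SNPs, %d causal ASD SNPs\n",
    "  planted region %d (beta = %.3g), emotion beta = %.3g\n"),
    nrow(x$covariates), sum(x$covariates$status), ncol(x$dosages$values),
    length(x$truth$causal), x$truth$planted_region, x$truth$planted_beta,
    x$truth$emotion_beta))
  invisible(x)
}
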