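test_that("generator is deterministic under a fixed configuration", {
  cfg <- small_cfg(seed = 11L)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$dosages$values, c2$dosages$values)
  expect_identical(c1$asd_stats, c2$asd_stats)
  expect_identical(c1$scz_stats$beta, c2$scz_stats$beta)
  expect_identical(c1$covariates, c2$covariates)
  expect_identical(c1$series[[5]]$mat, c2$series[[5]]$mat)
  expect_identical(c1$truth$score, c2$truth$score)
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(n_cases = 400, n_subjects = 300))
  expect_error(sim_config(block_r2 = 1))
  expect_error(sim_config(planted_region = 91))
  expect_error(sim_config(tr_seconds = 0))
  expect_error(simulate_genotypes(small_cfg(n_snps = 101L)),
               "divisible")
})

test_that("LD blocks have the intended correlation structure", {
  within_r <- function(d, per) {
    unlist(lapply(seq_len(ncol(d$values) / per), function(b) {
      cm <- cor(d$values[, ((b - 1) * per + 1):(b * per)])
      cm[upper.tri(cm)]
    }))
  }
  d0 <- simulate_genotypes(small_cfg(n_subjects = 2000L, block_r2 = 0,
                                     n_snps = 100L, n_ld_blocks = 10L))
  expect_lt(mean(abs(within_r(d0, 10))), 0.05)

  d8 <- simulate_genotypes(small_cfg(n_subjects = 2000L, block_r2 = 0.8,
                                     n_snps = 100L, n_ld_blocks = 10L))
  # quantile thresholding attenuates the latent 0.8 to about 0.6 in dosage
  # units (bound fixed from an empirical run of this generator)
  r8 <- mean(within_r(d8, 10))
  expect_gt(r8, 0.55)
  expect_lt(r8, 0.9)

  # across blocks, independent
  cross <- cor(d8$values[, 1:10], d8$values[, 11:20])
  expect_lt(mean(abs(cross)), 0.05)

  expect_true(all(d8$values >= 0 & d8$values <= 2))
})

test_that("null summary statistics have uniform P values", {
  cfg <- small_cfg(n_subjects = 50L, n_snps = 5000L, n_ld_blocks = 500L,
                   causal_fraction = 0)
  d <- simulate_genotypes(cfg)
  st <- simulate_summary_stats(cfg, d)
  for (tab in st) {
    frac <- mean(tab$p < 0.05)
    expect_gte(frac, 0.03)
    expect_lte(frac, 0.07)
  }
  expect_true(all(st$asd$snp %in% d$snp_ids))
  expect_true(all(st$asd$p > 0 & st$asd$p <= 1))
})

test_that("overlap_fraction controls sharing of planted SNPs", {
  cfg1 <- small_cfg(overlap_fraction = 1)
  d <- simulate_genotypes(cfg1)
  st1 <- simulate_summary_stats(cfg1, d)
  expect_setequal(attr(st1$scz, "truth")$causal, attr(st1$asd, "truth")$causal)

  cfg0 <- small_cfg(overlap_fraction = 0)
  st0 <- simulate_summary_stats(cfg0, simulate_genotypes(cfg0))
  expect_length(intersect(attr(st0$scz, "truth")$causal,
                          attr(st0$asd, "truth")$causal), 0)
})

test_that("phenotypes respect construction invariants", {
  cfg <- small_cfg(n_subjects = 2000L, n_cases = 700L, emotion_beta = 0.6,
                   n_snps = 50L, n_ld_blocks = 10L)
  d <- simulate_genotypes(cfg)
  st <- simulate_summary_stats(cfg, d)
  co <- simulate_phenotypes(cfg, d, st$asd)
  em <- co$emotion
  expect_identical(em$total, em$positive + em$neutral + em$negative)
  expect_true(all(em$negative >= 0 & em$negative <= cfg$max_items))
  # planted negative-emotion effect has the right sign
  expect_lt(cor(co$truth$score, em$negative), 0)
  # case-control covariate shifts point the configured way
  expect_lt(mean(co$covariates$age[co$covariates$status == 1]),
            mean(co$covariates$age[co$covariates$status == 0]))
  # planted oscillation frequency snapped inside the band
  expect_gte(co$truth$planted_freq_hz, 0.01)
  expect_lte(co$truth$planted_freq_hz, 0.08)
})

test_that("association P for the planted region is calibrated under the null", {
  n_rep <- 200
  hits <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- small_cfg(planted_beta = 0, emotion_beta = 0, seed = 1000L + r,
                     n_snps = 50L, n_ld_blocks = 10L)
    d <- simulate_genotypes(cfg)
    st <- simulate_summary_stats(cfg, d)
    co <- simulate_phenotypes(cfg, d, st$asd)
    al <- cohort_alff(co$series)
    covars <- co$covariates[, c("age", "sex", "education", "status")]
    fit <- fit_assoc(al[, cfg$planted_region], co$truth$score, covars)
    hits[r] <- fit$p < 0.05
  }
  expect_gte(mean(hits), 0.01)
  expect_lte(mean(hits), 0.10)
})

test_that("the full pipeline runs end to end on a small cohort", {
  cfg <- sim_config(n_snps = 600L, n_ld_blocks = 60L, seed = 4L)
  co <- simulate_cohort(cfg)
  res <- run_pipeline(co)
  expect_s3_class(res$scan, "scan_result")
  expect_length(attr(res$scan, "selected"), 10)
  expect_equal(nrow(res$alff_assoc), 10 * 90)
  expect_equal(nrow(res$emotion_assoc), 10 * 4)
  expect_equal(dim(res$alff), c(328, 90))
  # normalized ALFF averages one per subject
  expect_equal(unname(rowMeans(res$alff)), rep(1, 328), tolerance = 1e-9)
})
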