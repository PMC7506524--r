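test_that("threshold grid is the high-resolution 103-value grid", {
  g <- make_grid()
  expect_length(g, 103)
  expect_equal(min(g), 1e-5)
  expect_equal(max(g), 0.5)
  expect_false(0 %in% g)
  expect_true(all(diff(g) > 0))
  expect_true(all(c(1e-5, 1e-4, 1e-3) %in% g))
  expect_true(all(abs(setdiff(g, c(1e-5, 1e-4, 1e-3)) / 0.005 -
                        round(setdiff(g, c(1e-5, 1e-4, 1e-3)) / 0.005)) < 1e-12))
})

test_that("clumping matches an independent brute-force oracle", {
  # degenerate cases
  set.seed(10)
  d1 <- make_dosages(matrix(runif(20, 0, 2), 10, 2)[, 1, drop = FALSE])
  s1 <- make_stats(d1, 0.1, 0.5)
  expect_equal(clump(s1, d1)$retained, d1$snp_ids)

  # independent SNPs: everything retained
  d <- make_dosages(matrix(rbinom(200 * 8, 2, 0.4), 200, 8))
  s <- make_stats(d, rnorm(8), runif(8))
  cl <- clump(s, d, r2_cutoff = 0.999)
  expect_setequal(cl$retained, d$snp_ids)

  # 100 random 10-SNP instances against the oracle
  for (i in 1:100) {
    n <- 40
    base <- matrix(runif(n * 10, 0, 2), n, 10)
    # induce random LD by mixing columns
    mix <- sample(10, 5)
    base[, mix] <- base[, sample(10, 1)] + matrix(rnorm(n * 5, 0, 0.4), n, 5)
    base <- pmin(pmax(base, 0), 2)
    dd <- make_dosages(base, chr = sample(1:2, 10, TRUE),
                       pos = sample.int(6e5, 10))
    ss <- make_stats(dd, rnorm(10), runif(10))
    got <- clump(ss, dd)$retained
    expect_identical(got, clump_oracle(ss, dd))
    # invariant: no two retained SNPs within the window share r2 > cutoff
    r2 <- suppressWarnings(cor(dd$values[, got, drop = FALSE]))^2
    keep <- match(got, ss$snp)
    for (a in seq_along(got)) for (b in seq_along(got)) {
      if (a >= b) next
      if (ss$chr[keep[a]] == ss$chr[keep[b]] &&
          abs(ss$pos[keep[a]] - ss$pos[keep[b]]) <= 250000)
        expect_lte(r2[a, b], 0.1)
    }
  }

  expect_error(clump(make_stats(d, 0, 0.5)[1:2, ] |>
                       transform(snp = c("v001", "absent")), d), "absent")
})

test_that("scoring follows the additive dosage-weighted PRS convention", {
  vals <- rbind(c(1, 2, 0), c(0, 0, 0))
  d <- make_dosages(vals, chr = c(1, 2, 3))   # unlinked: clumping keeps all
  s <- make_stats(d, c(0.1, -0.2, 0.3), c(0.01, 0.02, 0.03))
  cl <- clump(s, d)
  sc <- prs_score(d, s, cl, p_t = 0.5)
  expect_equal(unname(sc$score), c(-0.3, 0))
  expect_equal(sc$n_snps, 3L)

  # all-zero effects give all-zero scores
  s0 <- make_stats(d, c(0, 0, 0), c(0.01, 0.02, 0.03))
  expect_equal(unname(prs_score(d, s0, cl, 0.5)$score), c(0, 0))

  # empty subset errors
  expect_error(prs_score(d, s, cl, 0.5, snp_subset = character(0)),
               "all SNPs dropped")

  # swapped alleles use 2 - dosage
  s_sw <- s
  s_sw$A1 <- "G"; s_sw$A2 <- "A"
  sc_sw <- prs_score(d, s_sw, cl, 0.5)
  expect_equal(unname(sc_sw$score),
               c(sum((2 - vals[1, ]) * s$beta), sum(2 * s$beta)))

  # strand-ambiguous SNPs dropped, mismatches dropped
  s_mix <- s
  s_mix$A1[1] <- "C"; s_mix$A2[1] <- "G"       # ambiguous
  s_mix$A1[2] <- "T"; s_mix$A2[2] <- "A"       # ambiguous
  s_mix$A1[3] <- "C"; s_mix$A2[3] <- "T"       # unresolvable vs A/G
  expect_error(suppressMessages(prs_score(d, s_mix, cl, 0.5)),
               "all SNPs dropped")
  s_mix$A1[3] <- "A"; s_mix$A2[3] <- "G"
  sc_mix <- suppressMessages(prs_score(d, s_mix, cl, 0.5))
  expect_equal(sc_mix$n_snps, 1L)
  expect_setequal(sc_mix$dropped$reason, "strand_ambiguous")
})

test_that("allele-flip relabeling leaves scores unchanged", {
  set.seed(11)
  d <- make_dosages(matrix(rbinom(50 * 6, 2, 0.4), 50, 6))
  s <- make_stats(d, rnorm(6), runif(6, 0.001, 0.4))
  cl <- clump(s, d)
  base <- prs_score(d, s, cl, 0.5)$score
  # flip target A1/A2 labels of SNP 2 and replace dosage d by 2 - d
  d2 <- d
  d2$values[, 2] <- 2 - d2$values[, 2]
  d2$map$A1[2] <- d$map$A2[2]
  d2$map$A2[2] <- d$map$A1[2]
  flipped <- dosage_matrix(d2$values, d2$subject_ids, d2$map)
  expect_equal(prs_score(flipped, s, cl, 0.5)$score, base, tolerance = 1e-12)
})

test_that("profiles are monotone in the threshold and match single scores", {
  cfg <- small_cfg(seed = 12L)
  co <- simulate_cohort(cfg)
  cl <- clump(co$asd_stats, co$dosages)
  prof <- score_profile(co$dosages, co$asd_stats, cl)
  expect_true(all(diff(prof$n_snps) >= 0))
  for (pt in c(0.005, 0.1, 0.5)) {
    j <- match(pt, prof$thresholds)
    single <- prs_score(co$dosages, co$asd_stats, cl, pt)
    expect_equal(prof$scores[, j], single$score, tolerance = 1e-12)
    expect_equal(prof$n_snps[j], single$n_snps)
  }
})

test_that("partition splits the selection into disjoint shared/specific sets", {
  d <- make_dosages(matrix(runif(30, 0, 2), 10, 3))
  asd <- make_stats(d, c(0.2, -0.1, 0.3), c(0.01, 0.05, 0.3))
  asd$snp <- c("a", "b", "c"); asd$pos <- c(1e5, 3e6, 6e6)
  d$map$snp <- c("a", "b", "c"); d$map$pos <- asd$pos
  d <- dosage_matrix(d$values, d$subject_ids, d$map)
  cl <- clump(asd, d)
  scz <- asd[c(1, 3), ]
  scz$p <- c(0.04, 0.5)

  part <- partition_snps(asd, scz, cl, p_t = 0.1)
  expect_setequal(part$shared, "a")
  expect_setequal(part$specific, "b")

  # SCZ-side rule: mere presence
  part2 <- partition_snps(asd, scz, cl, p_t = 0.1, scz_rule = "present")
  expect_setequal(part2$shared, c("a"))
  part3 <- partition_snps(asd, scz, cl, p_t = 0.5, scz_rule = "present")
  expect_setequal(part3$shared, c("a", "c"))

  # empty SCZ table: everything specific
  part4 <- partition_snps(asd, scz[0, ], cl, p_t = 0.5)
  expect_length(part4$shared, 0)
  expect_setequal(part4$specific, c("a", "b", "c"))

  # identical tables: everything shared
  part5 <- partition_snps(asd, asd, cl, p_t = 0.5)
  expect_setequal(part5$shared, c("a", "b", "c"))
  expect_length(part5$specific, 0)
})

test_that("Nagelkerke R2 matches its closed form", {
  expect_equal(nagelkerke_r2(-5, -5, 10), 0)
  expect_equal(nagelkerke_r2(2 * log(0.5), 0, 2), 1)
  expect_error(nagelkerke_r2(0, 0, 10), "degenerate")
  expect_error(nagelkerke_r2(-1, -2, 10), "ll_full")
  # random small logistic fits against an independently coded evaluation
  set.seed(13)
  for (i in 1:20) {
    n <- 50
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(0.5 * x))
    full <- glm(y ~ x, family = binomial())
    null <- glm(y ~ 1, family = binomial())
    l1 <- as.numeric(logLik(full)); l0 <- as.numeric(logLik(null))
    cox_snell <- 1 - (exp(l0) / exp(l1))^(2 / n)
    oracle <- cox_snell / (1 - exp(l0)^(2 / n))
    expect_equal(nagelkerke_r2(l0, l1, n), oracle, tolerance = 1e-12)
  }
})

test_that("case-control scan selects thresholds by smallest association p", {
  set.seed(14)
  n <- 300
  sc <- rnorm(n)
  status <- rbinom(n, 1, 0.4)
  prof <- structure(list(subjects = as.character(1:n),
                         thresholds = c(0.01, 0.05, 0.1, 0.2),
                         scores = matrix(sc, n, 4),
                         n_snps = c(5L, 10L, 20L, 40L), label = "ASD",
                         dropped = data.frame()),
                    class = "prs_profile")
  res <- prs_scan(prof, status, top_k = 2)
  expect_equal(length(unique(signif(res$p, 10))), 1)  # identical columns -> identical p
  expect_equal(attr(res, "selected"), c(0.01, 0.05))  # ties -> smaller P_T
  expect_true(all(res$r2 >= 0 & res$r2 <= 1))
})

test_that("scan finds planted case-control signal and stays calibrated without it", {
  # planted 0.3-SD shift: the signal columns win the selection
  set.seed(15)
  wins <- 0L
  for (r in 1:100) {
    n <- 2000
    status <- rbinom(n, 1, 0.35)
    signal <- sapply(1:3, function(i) rnorm(n) + 0.3 * status)
    noise <- matrix(rnorm(n * 3), n, 3)
    prof <- structure(list(subjects = as.character(1:n),
                           thresholds = (1:6) / 100,
                           scores = cbind(signal, noise),
                           n_snps = rep(10L, 6), label = "ASD",
                           dropped = data.frame()),
                      class = "prs_profile")
    res <- prs_scan(prof, status, top_k = 3)
    if (setequal(attr(res, "selected"), c(0.01, 0.02, 0.03))) wins <- wins + 1L
  }
  expect_gte(wins, 95)

  # covariate-only signal: score p uniform
  set.seed(16)
  hits <- logical(200)
  for (r in 1:200) {
    n <- 400
    age <- rnorm(n, 30, 10)
    status <- rbinom(n, 1, plogis((age - 30) / 10))
    prof <- structure(list(subjects = as.character(1:n), thresholds = 0.1,
                           scores = matrix(rnorm(n), n, 1), n_snps = 10L,
                           label = "ASD", dropped = data.frame()),
                      class = "prs_profile")
    res <- prs_scan(prof, status, covariates = data.frame(age = age), top_k = 1)
    hits[r] <- res$p[1] < 0.05
  }
  expect_gte(mean(hits), 0.02)
  expect_lte(mean(hits), 0.08)
})
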