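test_that("fit_assoc reports the signed partial correlation of the score", {
  # y = score exactly: partial r = 1
  set.seed(30)
  sc <- rnorm(50)
  fit <- fit_assoc(sc, sc)
  expect_equal(fit$partial_r, 1, tolerance = 1e-8)
  expect_equal(sign(fit$partial_r), sign(fit$beta))

  # Frisch-Waugh: partial r equals the correlation of the two residual vectors
  for (i in 1:20) {
    n <- 120
    covars <- data.frame(a = rnorm(n), b = rnorm(n), c = rbinom(n, 1, 0.5))
    score <- rnorm(n) + 0.5 * covars$a
    y <- rnorm(n) + 0.3 * score + 0.2 * covars$b
    fit <- fit_assoc(y, score, covars)
    ry <- residuals(lm(y ~ a + b + c, covars))
    rs <- residuals(lm(score ~ a + b + c, covars))
    expect_equal(fit$partial_r, cor(ry, rs), tolerance = 1e-10)
  }

  # affine rescaling of score and covariates leaves partial r unchanged
  n <- 200
  covars <- data.frame(a = rnorm(n), b = rnorm(n))
  score <- rnorm(n); y <- rnorm(n) + 0.2 * score
  f1 <- fit_assoc(y, score, covars)
  f2 <- fit_assoc(y, 10 * score - 3,
                  data.frame(a = 0.1 * covars$a + 5, b = covars$b))
  expect_equal(f1$partial_r, f2$partial_r, tolerance = 1e-10)
  expect_equal(f1$p, f2$p, tolerance = 1e-10)

  expect_error(fit_assoc(y, score, data.frame(a = covars$a, b = covars$a)),
               "collinear")
})

test_that("fit_assoc is calibrated under the null", {
  set.seed(31)
  hits <- replicate(200, {
    n <- 300
    covars <- data.frame(a = rnorm(n), b = rnorm(n))
    y <- rnorm(n) + 0.4 * covars$a
    fit_assoc(y, rnorm(n), covars)$p < 0.05
  })
  expect_gte(mean(hits), 0.02)
  expect_lte(mean(hits), 0.08)
})

test_that("multi-outcome fit matches fit_assoc column by column", {
  set.seed(32)
  n <- 150
  covars <- data.frame(a = rnorm(n), b = rbinom(n, 1, 0.4))
  score <- rnorm(n)
  Y <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("o", 1:5)))
  Y[, 2] <- Y[, 2] + 0.4 * score
  multi <- crossprs:::fit_assoc_matrix(Y, score, covars, m_tests = 5L)
  for (j in 1:5) {
    single <- fit_assoc(Y[, j], score, covars, m_tests = 5L)
    expect_equal(multi$beta[j], single$beta, tolerance = 1e-12)
    expect_equal(multi$t[j], single$t, tolerance = 1e-12)
    expect_equal(multi$p[j], single$p, tolerance = 1e-12)
    expect_equal(multi$partial_r[j], single$partial_r, tolerance = 1e-12)
  }
})

test_that("interaction test is calibrated, powered, and coding-invariant", {
  set.seed(33)
  # equal slopes in both groups: uniform p
  hits <- replicate(200, {
    n <- 200
    status <- rbinom(n, 1, 0.5)
    score <- rnorm(n)
    y <- 0.5 * score + rnorm(n)
    interaction_test(y, score, status) < 0.05
  })
  expect_gte(mean(hits), 0.02)
  expect_lte(mean(hits), 0.08)

  # opposite slopes: detected
  power <- replicate(100, {
    n <- 1000
    status <- rbinom(n, 1, 0.5)
    score <- rnorm(n)
    y <- ifelse(status == 1, 0.5, -0.5) * score + rnorm(n)
    interaction_test(y, score, status) < 0.01
  })
  expect_gte(sum(power), 95)

  # affine recoding of status changes nothing
  n <- 300
  status <- rbinom(n, 1, 0.5)
  score <- rnorm(n)
  y <- 0.3 * score + 0.2 * status * score + rnorm(n)
  expect_equal(interaction_test(y, score, status),
               interaction_test(y, score, status + 1), tolerance = 1e-12)

  expect_error(interaction_test(y, score, rep(1, n)), "two groups")
})

test_that("Bonferroni correction caps at one and is monotone", {
  expect_equal(bonferroni(0.9, 90), 1)
  expect_equal(bonferroni(c(0.001, 0.01), 4), c(0.004, 0.04))
  p <- runif(20)
  expect_true(all(bonferroni(p, 5) <= bonferroni(p, 10)))
  expect_true(all(diff(bonferroni(sort(p), 7)) >= 0))
  expect_error(bonferroni(0.5, 0))
})

test_that("pooled t statistic agrees with t.test on raw vectors", {
  set.seed(34)
  for (i in 1:20) {
    x <- rnorm(sample(10:50, 1), mean = runif(1, -1, 1))
    y <- rnorm(sample(10:50, 1), sd = runif(1, 0.5, 2))
    got <- two_sample_t(x, y)
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
    expect_equal(got$df, unname(ref$parameter))
    # summary interface reproduces the vector interface
    from_sum <- two_sample_t(mean(x), sd(x), length(x),
                             mean(y), sd(y), length(y))
    expect_equal(from_sum$statistic, got$statistic, tolerance = 1e-12)
  }
  expect_equal(two_sample_t(5, 1, 10, 5, 1, 10)$statistic, 0)
})

test_that("chi-square test matches the brute-force Pearson sum", {
  # perfectly proportional table: statistic 0
  expect_equal(chi_square_test(rbind(c(10, 20), c(30, 60)))$statistic, 0,
               tolerance = 1e-12)
  set.seed(35)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 30) + 1, 2, 2)
    got <- chi_square_test(tab)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(got$statistic, sum((tab - e)^2 / e), tolerance = 1e-9)
    expect_equal(got$df, 1)
  }
  # 2 x 3 table has df = 2
  expect_equal(chi_square_test(rbind(c(10, 5, 4), c(8, 9, 2)))$df, 2)
  expect_error(chi_square_test(rbind(c(0, 0), c(5, 5))), "expected")
})
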