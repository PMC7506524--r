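#' Covariate-adjusted linear association of an outcome with a score
#'
#' Ordinary least squares of `y` on an intercept, the score and the
#' covariates, using complete cases only. Reports the score coefficient,
#' its t statistic and two-sided P value, and the signed partial
#' correlation `r = t / sqrt(t^2 + df)` (the correlation between `y` and
#' the score after both are adjusted for the covariates, by the
#' Frisch-Waugh theorem).
#'
#' @param y numeric outcome vector.
#' @param score numeric score vector.
#' @param covars optional covariate data.frame/matrix (non-numeric columns
#'   are expanded via [stats::model.matrix()]).
#' @param outcome outcome name carried into the result.
#' @param label score label carried into the result.
#' @param p_t threshold annotation carried into the result.
#' @param m_tests Bonferroni family size for `p_corrected` (default 1).
#' @return A one-row data.frame of class `assoc_result` with columns
#'   `outcome`, `label`, `p_t`, `n`, `beta`, `se`, `t`, `df`, `partial_r`,
#'   `p`, `p_corrected`, `m_tests`.
#' @export
fit_assoc <- function(y, score, covars = NULL, outcome = "y", label = "PRS",
                      p_t = NA_real_, m_tests = 1L) {
  cv <- if (is.null(covars)) matrix(nrow = length(y), ncol = 0) else
    stats::model.matrix(~ ., data = as.data.frame(covars))[, -1, drop = FALSE]
  cc <- stats::complete.cases(y, score, cv)
  y <- y[cc]; score <- score[cc]; cv <- cv[cc, , drop = FALSE]
  n <- length(y)
  p_model <- 2L + ncol(cv)              # intercept + score + covariates
  if (n <= p_model + 2) stop("too few complete cases for the model size")
  x <- cbind(intercept = 1, score = score, cv)
  if (qr(x)$rank < ncol(x)) stop("collinear design matrix")
  fit <- stats::lm.fit(x, y)
  df <- n - p_model
  rss <- sum(fit$residuals^2)
  xtx_inv <- chol2inv(chol(crossprod(x)))
  se <- sqrt(rss / df * xtx_inv[2, 2])
  beta <- fit$coefficients["score"]
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df)
  out <- data.frame(outcome = outcome, label = label, p_t = p_t, n = n,
                    beta = unname(beta), se = se, t = unname(tval), df = df,
                    partial_r = unname(tval / sqrt(tval^2 + df)), p = p,
                    p_corrected = bonferroni(p, m_tests),
                    m_tests = as.integer(m_tests),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("assoc_result", "data.frame")
  out
}

# Fast multi-outcome version of fit_assoc for a fixed design: regresses
# every column of Y on [intercept, score, covars] at once. Returns a
# data.frame with one row per outcome, identical to stacking fit_assoc.
fit_assoc_matrix <- function(Y, score, covars = NULL, label = "PRS",
                             p_t = NA_real_, m_tests = 1L) {
  Y <- as.matrix(Y)
  cv <- if (is.null(covars)) matrix(nrow = nrow(Y), ncol = 0) else
    stats::model.matrix(~ ., data = as.data.frame(covars))[, -1, drop = FALSE]
  cc <- stats::complete.cases(Y, score, cv)
  Y <- Y[cc, , drop = FALSE]; score <- score[cc]; cv <- cv[cc, , drop = FALSE]
  n <- nrow(Y)
  x <- cbind(intercept = 1, score = score, cv)
  if (qr(x)$rank < ncol(x)) stop("collinear design matrix")
  df <- n - ncol(x)
  fit <- stats::lm.fit(x, Y)
  res <- as.matrix(fit$residuals)
  rss <- colSums(res^2)
  xtx_inv <- chol2inv(chol(crossprod(x)))
  beta <- fit$coefficients["score", ]
  se <- sqrt(rss / df * xtx_inv[2, 2])
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df)
  nm <- colnames(Y)
  if (is.null(nm)) nm <- paste0("y", seq_len(ncol(Y)))
  data.frame(outcome = nm, label = label, p_t = p_t, n = n, beta = unname(beta),
             se = unname(se), t = unname(tval), df = df,
             partial_r = unname(tval / sqrt(tval^2 + df)), p = unname(p),
             p_corrected = bonferroni(unname(p), m_tests),
             m_tests = as.integer(m_tests),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Score-by-status interaction test
#'
#' OLS of `y` on intercept, score, status, score x status and covariates;
#' returns the two-sided P value of the product term. Status may use any
#' two-level coding (it is recoded 0/1 internally, so the P value is
#' invariant to affine recoding).
#'
#' @inheritParams fit_assoc
#' @param status two-level group vector; both groups need at least 10
#'   complete cases.
#' @return Two-sided P value of the interaction coefficient.
#' @export
interaction_test <- function(y, score, status, covars = NULL) {
  cv <- if (is.null(covars)) matrix(nrow = length(y), ncol = 0) else
    stats::model.matrix(~ ., data = as.data.frame(covars))[, -1, drop = FALSE]
  cc <- stats::complete.cases(y, score, status, cv)
  y <- y[cc]; score <- score[cc]; status <- status[cc]
  cv <- cv[cc, , drop = FALSE]
  lev <- sort(unique(status))
  if (length(lev) != 2) stop("status must have exactly two groups")
  st <- as.numeric(status == lev[2])
  if (min(table(st)) < 10) stop("both status groups need at least 10 subjects")
  x <- cbind(intercept = 1, score = score, status = st,
             inter = score * st, cv)
  if (qr(x)$rank < ncol(x)) stop("collinear design matrix")
  n <- length(y)
  df <- n - ncol(x)
  fit <- stats::lm.fit(x, y)
  rss <- sum(fit$residuals^2)
  xtx_inv <- chol2inv(chol(crossprod(x)))
  se <- sqrt(rss / df * xtx_inv[4, 4])
  tval <- fit$coefficients["inter"] / se
  unname(2 * stats::pt(-abs(tval), df))
}

#' Bonferroni correction
#'
#' `min(1, p * m)`, vectorized over `p`. In this pipeline the family size
#' is 90 for the region-wise ALFF analysis and 4 for the emotion analysis
#' (positive, neutral, negative, total).
#'
#' @param p P value(s).
#' @param m number of tests in the family (at least 1).
#' @return Corrected P value(s), capped at 1.
#' @export
bonferroni <- function(p, m) {
  stopifnot(m >= 1)
  pmin(1, p * m)
}

#' Pooled-variance two-sample t test
#'
#' Computes the classical pooled two-sample t statistic with
#' `df = n1 + n2 - 2`, either from group summaries (means, SDs, sizes) or
#' from two raw vectors (`two_sample_t(x, y)`), whose summaries are taken
#' internally.
#'
#' @param mean1 first group mean, or a raw numeric vector (then the second
#'   argument is the second group's vector).
#' @param sd1,n1 first group SD and size.
#' @param mean2,sd2,n2 second group summaries.
#' @param variable variable name carried into the result.
#' @return A one-row data.frame of class `group_test` with columns
#'   `variable`, `statistic`, `df`, `p`, `method`.
#' @export
two_sample_t <- function(mean1, sd1 = NULL, n1 = NULL,
                         mean2 = NULL, sd2 = NULL, n2 = NULL,
                         variable = "x") {
  if (length(mean1) > 1) {              # raw-vector interface: (x, y)
    x <- mean1; y <- sd1
    stopifnot(is.numeric(x), is.numeric(y))
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    mean1 <- mean(x); sd1 <- sd(x); n1 <- length(x)
    mean2 <- mean(y); sd2 <- sd(y); n2 <- length(y)
  }
  stopifnot(n1 >= 2, n2 >= 2, sd1 > 0 || sd2 > 0)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  stat <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  out <- data.frame(variable = variable, statistic = stat, df = df,
                    p = 2 * stats::pt(-abs(stat), df),
                    method = "pooled t", stringsAsFactors = FALSE,
                    row.names = NULL)
  class(out) <- c("group_test", "data.frame")
  out
}

#' Pearson chi-square test on a 2 x k contingency table
#'
#' Pearson's chi-square without continuity correction, `df = k - 1`.
#' Errors when any expected count is zero.
#'
#' @param table 2 x k matrix of counts.
#' @param variable variable name carried into the result.
#' @return A one-row data.frame of class `group_test`.
#' @export
chi_square_test <- function(table, variable = "x") {
  table <- as.matrix(table)
  if (nrow(table) != 2) stop("expected a 2 x k table")
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected <= 0)) stop("zero expected cell count")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  out <- data.frame(variable = variable,
                    statistic = unname(ct$statistic),
                    df = unname(ct$parameter), p = unname(ct$p.value),
                    method = "Pearson chi-square",
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("group_test", "data.frame")
  out
}
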