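#' Nagelkerke pseudo-R-squared
#'
#' Rescaled likelihood-ratio R-squared for binary-outcome models:
#' `(1 - exp(2 (ll_null - ll_full) / n)) / (1 - exp(2 ll_null / n))`.
#'
#' @param ll_null log-likelihood of the null (covariates-only) model.
#' @param ll_full log-likelihood of the full model; must be at least
#'   `ll_null`.
#' @param n number of observations.
#' @return R-squared in \[0, 1\].
#' @export
nagelkerke_r2 <- function(ll_null, ll_full, n) {
  stopifnot(n > 0)
  if (ll_full < ll_null - 1e-8)
    stop("ll_full must be >= ll_null")
  if (ll_null == 0)
    stop("degenerate null likelihood (ll_null = 0)")
  (1 - exp(2 * (ll_null - ll_full) / n)) / (1 - exp(2 * ll_null / n))
}

#' Case-control scan over the PRS threshold grid
#'
#' For each threshold, fits a logistic regression of case-control status on
#' the score plus covariates, records the Wald P value of the score
#' coefficient and the Nagelkerke R-squared of the full model against the
#' covariates-only model, and selects the `top_k` thresholds with the
#' smallest P (ties broken by smaller threshold). Thresholds whose fit does
#' not converge (or with no SNPs selected) are flagged and excluded from
#' selection.
#'
#' @param profile a [score_profile()] result.
#' @param status 0/1 case-control vector aligned with `profile$subjects`.
#' @param covariates optional data.frame/matrix of covariates (e.g. age,
#'   sex, education and four ancestry PCs); non-numeric columns are
#'   expanded via [stats::model.matrix()].
#' @param top_k number of thresholds to select (default 10).
#' @return An object of class `scan_result`: data.frame with columns
#'   `p_t`, `n_snps`, `beta`, `se`, `p`, `r2`, `converged`, plus attributes
#'   `selected` (chosen thresholds) and `n`.
#' @export
prs_scan <- function(profile, status, covariates = NULL, top_k = 10L) {
  stopifnot(inherits(profile, "prs_profile"))
  status <- as.integer(status)
  if (!all(status %in% c(0L, 1L))) stop("status must be 0/1")
  n <- length(profile$subjects)
  stopifnot(length(status) == n)
  cv <- if (is.null(covariates)) matrix(nrow = n, ncol = 0) else
    stats::model.matrix(~ ., data = as.data.frame(covariates))[, -1, drop = FALSE]
  null_df <- data.frame(status = status, cv)
  fit0 <- stats::glm(status ~ ., data = null_df, family = stats::binomial())
  ll0 <- as.numeric(stats::logLik(fit0))
  res <- data.frame(p_t = profile$thresholds, n_snps = profile$n_snps,
                    beta = NA_real_, se = NA_real_, p = NA_real_,
                    r2 = NA_real_, converged = FALSE)
  for (j in seq_along(profile$thresholds)) {
    sc <- profile$scores[, j]
    if (profile$n_snps[j] == 0 || all(!is.finite(sc)) || sd(sc) == 0) next
    dat <- data.frame(status = status, score = sc, cv)
    fit <- suppressWarnings(
      stats::glm(status ~ ., data = dat, family = stats::binomial()))
    co <- summary(fit)$coefficients
    if (!fit$converged || !"score" %in% rownames(co) ||
        any(!is.finite(co["score", ]))) next
    res$beta[j] <- co["score", 1]
    res$se[j] <- co["score", 2]
    res$p[j] <- co["score", 4]
    res$r2[j] <- nagelkerke_r2(ll0, as.numeric(stats::logLik(fit)), n)
    res$converged[j] <- TRUE
  }
  ok <- which(res$converged)
  sel <- ok[order(res$p[ok], res$p_t[ok])][seq_len(min(top_k, length(ok)))]
  structure(res, selected = res$p_t[sel], n = n, class = c("scan_result", "data.frame"))
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("scan_result: %d thresholds (%d converged), n = %d\n",
              nrow(x), sum(x$converged), attr(x, "n")))
  cat("selected P_T:", paste(format(attr(x, "selected")), collapse = ", "), "\n")
  invisible(x)
}

#' Plot a case-control scan
#'
#' Bar plot of Nagelkerke R-squared against the P-value threshold, with
#' the selected thresholds highlighted.
#'
#' @param x a `scan_result`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.scan_result <- function(x, ...) {
  sel <- x$p_t %in% attr(x, "selected")
  graphics::barplot(x$r2, names.arg = format(x$p_t, trim = TRUE),
                    col = ifelse(sel, "firebrick", "grey70"), border = NA,
                    xlab = expression(P[T]),
                    ylab = expression(Nagelkerke ~ R^2), las = 2,
                    cex.names = 0.4, ...)
  invisible(x)
}
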