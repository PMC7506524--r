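#' Region-wise BOLD time series
#'
#' @param mat numeric matrix, timepoints x 90 atlas regions (AAL order),
#'   at least 64 timepoints, no missing values.
#' @param tr repetition time (sampling interval), seconds.
#' @param subject_id optional subject identifier.
#' @param n_discarded_initial number of initial volumes already discarded
#'   upstream (informational).
#' @return An object of class `region_series`.
#' @export
region_series <- function(mat, tr, subject_id = NULL, n_discarded_initial = 0L) {
  mat <- as.matrix(mat)
  if (ncol(mat) != 90) stop("series must have 90 region columns")
  if (nrow(mat) < 64) stop("series must have at least 64 timepoints")
  if (anyNA(mat)) stop("series must not contain missing values")
  if (tr <= 0) stop("tr must be positive")
  structure(list(mat = mat, tr = tr, subject_id = subject_id,
                 n_discarded_initial = as.integer(n_discarded_initial)),
            class = "region_series")
}

#' @export
print.region_series <- function(x, ...) {
  cat(sprintf("region_series%s: %d timepoints x %d regions, TR = %g s\n",
              if (is.null(x$subject_id)) "" else paste0(" [", x$subject_id, "]"),
              nrow(x$mat), ncol(x$mat), x$tr))
  invisible(x)
}

#' Head-motion screening
#'
#' A subject is kept iff every translation maximum is at most `trans_max`
#' millimetres and every rotation maximum at most `rot_max` degrees
#' (exclusion is strict: translation > 3 mm or rotation > 3 degrees).
#'
#' @param motion data.frame with per-axis maxima (columns matching
#'   `trans_*` and `rot_*`), or a list/vector pair via `translation` and
#'   `rotation`.
#' @param trans_max translation cutoff, mm (default 3).
#' @param rot_max rotation cutoff, degrees (default 3).
#' @return Logical vector (one per row of `motion`): `TRUE` = keep.
#' @export
motion_screen <- function(motion, trans_max = 3, rot_max = 3) {
  motion <- as.data.frame(motion)
  tc <- grep("^trans", names(motion), value = TRUE)
  rc <- grep("^rot", names(motion), value = TRUE)
  if (!length(tc) || !length(rc))
    stop("motion must have trans_* and rot_* columns")
  keep_t <- apply(as.matrix(motion[tc]) <= trans_max, 1, all)
  keep_r <- apply(as.matrix(motion[rc]) <= rot_max, 1, all)
  unname(keep_t & keep_r)
}

#' Nuisance regression of region-wise series
#'
#' Replaces each region's series by the residuals of an ordinary
#' least-squares regression on an intercept, a linear trend and the given
#' nuisance regressors (e.g. motion parameters, global/white-matter/CSF
#' signals). Output columns are mean-zero and orthogonal to every
#' regressor.
#'
#' @param series a [region_series()].
#' @param nuisance optional timepoints x m numeric matrix; with `NULL` the
#'   series is only detrended and demeaned.
#' @return A `region_series` of residuals.
#' @export
nuisance_regress <- function(series, nuisance = NULL) {
  stopifnot(inherits(series, "region_series"))
  nt <- nrow(series$mat)
  x <- cbind(intercept = 1, trend = seq_len(nt))
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != nt)
      stop("nuisance rows must equal the number of timepoints")
    if (is.null(colnames(nuisance)))
      colnames(nuisance) <- paste0("nuis", seq_len(ncol(nuisance)))
    x <- cbind(x, nuisance)
  }
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    bad <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    stop("rank-deficient nuisance design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  res <- qr.resid(qx, series$mat)
  region_series(res, tr = series$tr, subject_id = series$subject_id,
                n_discarded_initial = series$n_discarded_initial)
}

# band bin indices k with low <= k/(N*tr) <= high (inclusive, with a small
# tolerance against floating-point representation of the endpoints)
band_bins <- function(n, tr, band) {
  k <- seq_len(floor((n - 1) / 2))
  f <- k / (n * tr)
  k[f >= band[1] - 1e-12 & f <= band[2] + 1e-12]
}

#' Amplitude of low-frequency fluctuation (ALFF)
#'
#' Computes per-region ALFF from the periodogram of the (already
#' nuisance-cleaned) series: the mean of the square root of spectral power
#' over the Fourier frequencies k/(N tr) inside `band`, endpoints
#' inclusive. Power is scaled so that a pure in-band sinusoid of amplitude
#' A at an exact Fourier frequency contributes sqrt(power) = A at its bin;
#' a tone of amplitude A therefore yields ALFF = A / n_band_bins, and ALFF
#' is positively homogeneous of degree one in signal amplitude.
#'
#' @param series a [region_series()], or a timepoints x regions matrix
#'   (then `tr` must be given).
#' @param band frequency band in Hz, default `c(0.01, 0.08)`; the upper
#'   endpoint must be below the Nyquist frequency 1/(2 tr).
#' @param tr repetition time in seconds (ignored when `series` is a
#'   `region_series`).
#' @return An object of class `alff_vector`: list with `subject`, `raw`
#'   (per-region ALFF, non-negative), `normalized` (`NULL` until
#'   [normalize_alff()]), `band`, `n_bins`.
#' @export
compute_alff <- function(series, band = c(0.01, 0.08), tr = NULL) {
  if (inherits(series, "region_series")) {
    mat <- series$mat; tr <- series$tr; subject <- series$subject_id
  } else {
    if (is.null(tr)) stop("tr must be supplied for a plain matrix")
    mat <- as.matrix(series); subject <- NULL
  }
  stopifnot(tr > 0, length(band) == 2, band[1] < band[2])
  if (band[2] >= 1 / (2 * tr))
    stop("band upper endpoint must be below the Nyquist frequency 1/(2 tr)")
  n <- nrow(mat)
  bins <- band_bins(n, tr, band)
  if (!length(bins))
    stop(sprintf("no Fourier frequencies in [%g, %g] Hz for N = %d, tr = %g",
                 band[1], band[2], n, tr))
  amp <- 2 * Mod(stats::mvfft(mat)[bins + 1L, , drop = FALSE]) / n
  raw <- colMeans(amp)
  structure(list(subject = subject, raw = raw, normalized = NULL,
                 band = band, n_bins = length(bins)),
            class = "alff_vector")
}

#' Normalize ALFF by the subject's within-brain mean
#'
#' Divides each region's raw ALFF by the mean raw ALFF across the 90
#' regions, so normalized values average exactly 1 per subject.
#'
#' @param alff an `alff_vector` from [compute_alff()].
#' @return The `alff_vector` with its `normalized` element filled.
#' @export
normalize_alff <- function(alff) {
  stopifnot(inherits(alff, "alff_vector"))
  m <- mean(alff$raw)
  if (m <= 0) stop("all-zero ALFF vector cannot be normalized")
  alff$normalized <- alff$raw / m
  alff
}

#' Normalized ALFF matrix for a set of subjects
#'
#' Runs [nuisance_regress()] (detrend/demean only unless nuisance
#' regressors are supplied per subject), [compute_alff()] and
#' [normalize_alff()] for each series and stacks the normalized vectors.
#'
#' @param series_list named list of [region_series()].
#' @param band frequency band in Hz.
#' @param nuisance optional named list of per-subject nuisance matrices.
#' @return subjects x 90 matrix of normalized ALFF values.
#' @export
cohort_alff <- function(series_list, band = c(0.01, 0.08), nuisance = NULL) {
  out <- t(vapply(seq_along(series_list), function(i) {
    s <- series_list[[i]]
    nu <- if (is.null(nuisance)) NULL else nuisance[[i]]
    normalize_alff(compute_alff(nuisance_regress(s, nu), band = band))$normalized
  }, numeric(90)))
  rownames(out) <- names(series_list)
  colnames(out) <- paste0("region", 1:90)
  out
}
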