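#' Read GWAS summary statistics from TSV
#'
#' Expects columns SNP, CHR, BP, A1, A2, BETA (or OR), P. With
#' `or_to_beta = TRUE` an OR column is log-transformed onto the effect
#' scale.
#'
#' @param file path to a tab-separated file with a header.
#' @param or_to_beta logical; read an `OR` column and log-transform it.
#' @return Summary-statistic data.frame (`snp`, `chr`, `pos`, `A1`, `A2`,
#'   `beta`, `p`).
#' @export
read_summary_stats <- function(file, or_to_beta = FALSE) {
  x <- utils::read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  names(x) <- toupper(names(x))
  eff <- if (or_to_beta) {
    if (!"OR" %in% names(x)) stop("no OR column to transform")
    log(x$OR)
  } else x$BETA
  need <- c("SNP", "CHR", "BP", "A1", "A2", "P")
  if (!all(need %in% names(x)))
    stop("missing columns: ", paste(setdiff(need, names(x)), collapse = ", "))
  out <- data.frame(snp = x$SNP, chr = x$CHR, pos = x$BP, A1 = x$A1,
                    A2 = x$A2, beta = eff, p = x$P, stringsAsFactors = FALSE)
  if (anyDuplicated(out$snp)) stop("duplicate SNP ids in summary statistics")
  if (any(out$p <= 0 | out$p > 1)) stop("P values must lie in (0, 1]")
  out
}

#' Write GWAS summary statistics to TSV
#'
#' @param stats summary-statistic data.frame.
#' @param file output path.
#' @export
write_summary_stats <- function(stats, file) {
  utils::write.table(
    data.frame(SNP = stats$snp, CHR = stats$chr, BP = stats$pos,
               A1 = stats$A1, A2 = stats$A2, BETA = stats$beta, P = stats$p),
    file, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a dosage matrix as TSV (values + map sidecar)
#'
#' The value file is subjects x SNPs with a `subject` column and SNP-id
#' header; the map sidecar carries SNP, CHR, BP, A1, A2.
#'
#' @param dosages a [dosage_matrix()].
#' @param file output path for the value table.
#' @param map_file output path for the map (default `<file>.map`).
#' @export
write_dosage_tsv <- function(dosages, file, map_file = paste0(file, ".map")) {
  stopifnot(inherits(dosages, "dosage_matrix"))
  df <- data.frame(subject = dosages$subject_ids, dosages$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(SNP = dosages$map$snp, CHR = dosages$map$chr,
               BP = dosages$map$pos, A1 = dosages$map$A1, A2 = dosages$map$A2),
    map_file, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a dosage matrix from TSV
#'
#' @param file value table written by [write_dosage_tsv()].
#' @param map_file map sidecar path (default `<file>.map`).
#' @return A [dosage_matrix()].
#' @export
read_dosage_tsv <- function(file, map_file = paste0(file, ".map")) {
  df <- utils::read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  mp <- utils::read.delim(map_file, stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  dosage_matrix(values, subject_ids = df$subject,
                map = data.frame(snp = mp$SNP, chr = mp$CHR, pos = mp$BP,
                                 A1 = mp$A1, A2 = mp$A2,
                                 stringsAsFactors = FALSE))
}

#' Read dosages from a VCF with a DS (dosage) FORMAT field
#'
#' @param file path to a VCF (plain or gzipped).
#' @return A [dosage_matrix()] (A1 = the ALT allele whose dosage DS counts).
#' @export
read_dosage_vcf <- function(file) {
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  fix <- vcfR::getFIX(v)
  map <- data.frame(snp = fix[, "ID"], chr = fix[, "CHROM"],
                    pos = as.integer(fix[, "POS"]), A1 = fix[, "ALT"],
                    A2 = fix[, "REF"], stringsAsFactors = FALSE)
  dosage_matrix(t(ds), subject_ids = colnames(ds), map = map)
}

#' Write a dosage matrix as a minimal VCF with a DS FORMAT field
#'
#' @param dosages a [dosage_matrix()]; A1 is written as ALT.
#' @param file output path (plain text).
#' @export
write_dosage_vcf <- function(dosages, file) {
  stopifnot(inherits(dosages, "dosage_matrix"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", dosages$subject_ids),
                     collapse = "\t")), con)
  vals <- t(dosages$values)
  body <- apply(cbind(dosages$map$chr, dosages$map$pos, dosages$map$snp,
                      dosages$map$A2, dosages$map$A1, ".", "PASS", ".", "DS",
                      format(vals, trim = TRUE, digits = 6)),
                1, paste, collapse = "\t")
  writeLines(body, con)
}

#' Read a BED-like gene-interval table
#'
#' Columns chr, start, end, gene (no header). With `zero_based = TRUE`
#' (the BED dialect) starts are converted to 1-based inclusive
#' coordinates; with `FALSE` the intervals are taken as already 1-based
#' inclusive.
#'
#' @param file path to the table.
#' @param zero_based logical; input uses BED 0-based half-open starts.
#' @return data.frame with columns `gene`, `chr`, `start`, `end`.
#' @export
read_gene_intervals <- function(file, zero_based = TRUE) {
  x <- utils::read.table(file, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (ncol(x) < 4) stop("expected at least 4 columns: chr, start, end, gene")
  out <- data.frame(gene = x[[4]], chr = x[[1]],
                    start = x[[2]] + if (zero_based) 1L else 0L,
                    end = x[[3]], stringsAsFactors = FALSE)
  if (any(out$start > out$end)) stop("interval start > end after conversion")
  out
}

#' Read gene sets from a GMT file
#'
#' @param file path to a GMT file (set name, description, genes...).
#' @return Named list of gene-symbol character vectors.
#' @export
read_gmt <- function(file) {
  sets <- fgsea::gmtPathways(file)
  if (any(!lengths(sets))) stop("GMT contains an empty set")
  sets
}

#' Write a synthetic cohort to a directory
#'
#' Emits the pipeline's on-disk interchange formats: dosage TSV + map,
#' summary-statistic TSVs, a covariates+emotion CSV, one region-series CSV
#' per subject, a motion TSV, and the planted truth as JSON.
#'
#' @param cohort a `synthetic_cohort` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_dosage_tsv(cohort$dosages, file.path(dir, "dosages.tsv"))
  write_summary_stats(cohort$asd_stats, file.path(dir, "asd_sumstats.tsv"))
  if (!is.null(cohort$scz_stats))
    write_summary_stats(cohort$scz_stats, file.path(dir, "scz_sumstats.tsv"))
  utils::write.csv(merge(cohort$covariates, cohort$emotion, by = "subject"),
                   file.path(dir, "phenotypes.csv"), row.names = FALSE)
  utils::write.table(cohort$motion, file.path(dir, "motion.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sdir <- file.path(dir, "series")
  dir.create(sdir, showWarnings = FALSE)
  for (id in names(cohort$series))
    utils::write.csv(cohort$series[[id]]$mat,
                     file.path(sdir, paste0(id, ".csv")), row.names = FALSE)
  truth <- cohort$truth
  truth$score <- as.numeric(truth$score)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read one region-series CSV
#'
#' @param file CSV with timepoints in rows and 90 region columns.
#' @param tr repetition time, seconds.
#' @param subject_id optional subject id.
#' @param n_discarded_initial initial volumes to drop from the top of the
#'   file before constructing the series (0 when the file is already
#'   post-discard).
#' @return A [region_series()].
#' @export
read_region_series_csv <- function(file, tr, subject_id = NULL,
                                   n_discarded_initial = 0L) {
  mat <- as.matrix(utils::read.csv(file))
  if (n_discarded_initial > 0)
    mat <- mat[-seq_len(n_discarded_initial), , drop = FALSE]
  region_series(mat, tr = tr, subject_id = subject_id,
                n_discarded_initial = n_discarded_initial)
}
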