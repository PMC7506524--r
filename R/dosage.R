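#' Allele-dosage matrix
#'
#' Container for target-sample genotypes as expected effect-allele counts.
#' Rows are subjects, columns are SNPs; values lie in \[0, 2\] (fractional
#' after imputation) with \code{NA} marking missing genotypes. A per-SNP map
#' carries chromosome, 1-based position and the two alleles, with \code{A1}
#' the allele whose dosage is stored.
#'
#' @param values numeric matrix, subjects x SNPs, entries in \[0, 2\] or `NA`.
#' @param subject_ids character vector of unique subject identifiers
#'   (defaults to rownames of `values`).
#' @param map data.frame with columns `snp`, `chr`, `pos`, `A1`, `A2`
#'   (one row per column of `values`; `snp` defaults to colnames).
#'
#' @return An object of class `dosage_matrix`: a list with elements
#'   `values`, `subject_ids`, `snp_ids`, `map`.
#' @export
dosage_matrix <- function(values, subject_ids = rownames(values), map = NULL) {
  values <- as.matrix(values)
  if (is.null(subject_ids))
    subject_ids <- sprintf("S%04d", seq_len(nrow(values)))
  subject_ids <- as.character(subject_ids)
  if (anyDuplicated(subject_ids))
    stop("duplicate subject ids")
  if (is.null(map)) {
    snp <- colnames(values)
    if (is.null(snp)) snp <- sprintf("snp%05d", seq_len(ncol(values)))
    map <- data.frame(snp = snp, chr = 1L, pos = seq_len(ncol(values)),
                      A1 = "A", A2 = "G", stringsAsFactors = FALSE)
  }
  map <- as.data.frame(map)
  need <- c("snp", "chr", "pos", "A1", "A2")
  if (!all(need %in% names(map)))
    stop("map must have columns ", paste(need, collapse = ", "))
  if (nrow(map) != ncol(values))
    stop("map rows must match value columns")
  if (anyDuplicated(map$snp))
    stop("duplicate SNP ids")
  rng <- range(values, na.rm = TRUE)
  if (any(is.finite(rng)) && (rng[1] < 0 || rng[2] > 2))
    stop("dosage values must lie in [0, 2]")
  dimnames(values) <- list(subject_ids, map$snp)
  structure(list(values = values, subject_ids = subject_ids,
                 snp_ids = map$snp, map = map),
            class = "dosage_matrix")
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat(sprintf("dosage_matrix: %d subjects x %d SNPs (%d chromosome(s), %.1f%% missing)\n",
              nrow(x$values), ncol(x$values), length(unique(x$map$chr)),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.dosage_matrix <- function(x) dim(x$values)

#' Subset a dosage matrix by subjects and/or SNPs
#'
#' @param dosages a [dosage_matrix()].
#' @param subjects character vector of subject ids to keep (default all).
#' @param snps character vector of SNP ids to keep (default all).
#' @return A `dosage_matrix` restricted to the requested rows/columns.
#' @export
subset_dosages <- function(dosages, subjects = NULL, snps = NULL) {
  stopifnot(inherits(dosages, "dosage_matrix"))
  keep_s <- if (is.null(subjects)) dosages$subject_ids else subjects
  keep_v <- if (is.null(snps)) dosages$snp_ids else snps
  miss_s <- setdiff(keep_s, dosages$subject_ids)
  miss_v <- setdiff(keep_v, dosages$snp_ids)
  if (length(miss_s)) stop("unknown subjects: ", paste(miss_s, collapse = ", "))
  if (length(miss_v)) stop("unknown SNPs: ", paste(miss_v, collapse = ", "))
  dosage_matrix(dosages$values[keep_s, keep_v, drop = FALSE],
                subject_ids = keep_s,
                map = dosages$map[match(keep_v, dosages$map$snp), , drop = FALSE])
}

#' AAL-90 atlas region table
#'
#' The standard automated anatomical labeling (AAL) parcellation order for
#' the 90 cerebral regions (45 per hemisphere) used throughout the pipeline.
#' Region 41 is the left amygdala.
#'
#' @return data.frame with columns `index` (1-90) and `name`.
#' @export
aal_regions <- function() {
  base <- c("Precentral", "Frontal_Sup", "Frontal_Sup_Orb", "Frontal_Mid",
            "Frontal_Mid_Orb", "Frontal_Inf_Oper", "Frontal_Inf_Tri",
            "Frontal_Inf_Orb", "Rolandic_Oper", "Supp_Motor_Area", "Olfactory",
            "Frontal_Sup_Medial", "Frontal_Med_Orb", "Rectus", "Insula",
            "Cingulum_Ant", "Cingulum_Mid", "Cingulum_Post", "Hippocampus",
            "ParaHippocampal", "Amygdala", "Calcarine", "Cuneus", "Lingual",
            "Occipital_Sup", "Occipital_Mid", "Occipital_Inf", "Fusiform",
            "Postcentral", "Parietal_Sup", "Parietal_Inf", "SupraMarginal",
            "Angular", "Precuneus", "Paracentral_Lobule", "Caudate", "Putamen",
            "Pallidum", "Thalamus", "Heschl", "Temporal_Sup",
            "Temporal_Pole_Sup", "Temporal_Mid", "Temporal_Pole_Mid",
            "Temporal_Inf")
  name <- as.vector(rbind(paste0(base, "_L"), paste0(base, "_R")))
  data.frame(index = 1:90, name = name, stringsAsFactors = FALSE)
}
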