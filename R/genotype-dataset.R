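#' Genotype dataset container
#'
#' The pipeline's universal input: a subjects x variants matrix of alternate
#' allele dosages (0, 1, 2 or `NA` for a missing call) together with variant
#' and subject metadata.
#'
#' @param dosages numeric matrix, subjects in rows and variants in columns;
#'   entries in `{0, 1, 2, NA}`. Row and column names are set from the
#'   metadata identifiers.
#' @param variant_meta data frame with columns `id`, `chrom`, `pos`, `ref`,
#'   `alt` (one row per variant, in column order of `dosages`). Additional
#'   columns are carried along (the simulator stores its generating minor
#'   allele frequency and LD block there).
#' @param subject_meta data frame with columns `id` and optionally
#'   `phenotype` (`"case"`/`"control"` or `NA`), `age` (years) and `sex`
#'   (`"female"`/`"male"`).
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(dosages, variant_meta, subject_meta) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  stopifnot(is.data.frame(variant_meta), is.data.frame(subject_meta))
  if (nrow(variant_meta) != ncol(dosages))
    stop("variant_meta rows must match dosage columns")
  if (nrow(subject_meta) != nrow(dosages))
    stop("subject_meta rows must match dosage rows")
  bad <- !(dosages %in% c(0, 1, 2) | is.na(dosages))
  if (any(bad))
    stop("dosage entries must be 0, 1, 2 or NA")
  if (anyDuplicated(variant_meta$id))
    stop("duplicate variant identifiers")
  if (anyDuplicated(subject_meta$id))
    stop("duplicate subject identifiers")
  for (chr in unique(variant_meta$chrom)) {
    p <- variant_meta$pos[variant_meta$chrom == chr]
    if (any(diff(p) <= 0))
      stop(sprintf("positions not strictly increasing on chromosome %s", chr))
  }
  if (!is.null(subject_meta$phenotype)) {
    ph <- subject_meta$phenotype
    if (!all(is.na(ph) | ph %in% c("case", "control")))
      stop("phenotype must be 'case', 'control' or NA")
  }
  rownames(dosages) <- subject_meta$id
  colnames(dosages) <- variant_meta$id
  structure(
    list(dosages = dosages,
         variant_meta = as.data.frame(variant_meta, stringsAsFactors = FALSE),
         subject_meta = as.data.frame(subject_meta, stringsAsFactors = FALSE)),
    class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  n_case <- sum(x$subject_meta$phenotype == "case", na.rm = TRUE)
  n_ctrl <- sum(x$subject_meta$phenotype == "control", na.rm = TRUE)
  cat(sprintf("<genotype_dataset> %d subjects x %d variants\n",
              nrow(x$dosages), ncol(x$dosages)))
  if (n_case + n_ctrl > 0)
    cat(sprintf("  phenotype: %d cases / %d controls\n", n_case, n_ctrl))
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$dosages)

# Subset a dataset by subject and/or variant indices or identifiers.
#' Subset a genotype dataset
#'
#' @param geno a [genotype_dataset()].
#' @param subjects,variants indices, logical masks or identifier vectors;
#'   `NULL` keeps everything.
#' @return A `genotype_dataset` restricted to the selection.
#' @export
subset_genotypes <- function(geno, subjects = NULL, variants = NULL) {
  si <- seq_len(nrow(geno$dosages))
  vi <- seq_len(ncol(geno$dosages))
  if (!is.null(subjects)) {
    si <- if (is.character(subjects)) match(subjects, geno$subject_meta$id) else si[subjects]
    if (anyNA(si)) stop("unknown subject identifiers")
  }
  if (!is.null(variants)) {
    vi <- if (is.character(variants)) match(variants, geno$variant_meta$id) else vi[variants]
    if (anyNA(vi)) stop("unknown variant identifiers")
  }
  genotype_dataset(geno$dosages[si, vi, drop = FALSE],
                   geno$variant_meta[vi, , drop = FALSE],
                   geno$subject_meta[si, , drop = FALSE])
}

# Minor allele frequency per variant from observed (non-missing) dosages.
variant_maf <- function(geno) {
  alt <- colMeans(geno$dosages, na.rm = TRUE) / 2
  pmin(alt, 1 - alt)
}

# Per-variant call rate.
variant_call_rate <- function(geno) {
  colMeans(!is.na(geno$dosages))
}
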