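# Plain-text interchange formats: minimal VCF 4.2 (GT-only, unphased),
# TSV dosage matrix (rows = variants), PLINK-style phenotype/covariate TSV
# (phenotype 1 = control / 2 = case; sex 1 = male / 2 = female).

#' Write a genotype dataset as minimal VCF 4.2
#'
#' GT-only, unphased; missing calls written as `./.`.
#'
#' @param geno a [genotype_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path) {
  gt <- matrix(c("0/0", "0/1", "1/1")[geno$dosages + 1],
               nrow = nrow(geno$dosages))
  gt[is.na(gt)] <- "./."
  vm <- geno$variant_meta
  body <- data.table::data.table(
    CHROM = vm$chrom, POS = as.integer(vm$pos), ID = vm$id,
    REF = vm$ref, ALT = vm$alt, QUAL = ".", FILTER = "PASS", INFO = ".",
    FORMAT = "GT")
  body <- cbind(body, data.table::as.data.table(t(gt)))
  data.table::setnames(body, c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                               "FILTER", "INFO", "FORMAT",
                               geno$subject_meta$id))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=elgwas",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             path)
  data.table::fwrite(body, path, sep = "\t", append = TRUE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Write a genotype dataset as a TSV dosage matrix
#'
#' Rows are variants (with `variant_id`, `chrom`, `pos`, `ref`, `alt`
#' leading columns), columns are subjects; missing calls are `NA`.
#'
#' @inheritParams write_vcf
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(geno, path) {
  vm <- geno$variant_meta
  tab <- data.table::data.table(variant_id = vm$id, chrom = vm$chrom,
                                pos = as.integer(vm$pos), ref = vm$ref,
                                alt = vm$alt)
  tab <- cbind(tab, data.table::as.data.table(t(geno$dosages)))
  data.table::setnames(tab, c("variant_id", "chrom", "pos", "ref", "alt",
                              geno$subject_meta$id))
  data.table::fwrite(tab, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Write a PLINK-style phenotype/covariate TSV
#'
#' Columns: `subject_id`, `phenotype` (1 = control, 2 = case), `age`,
#' `sex` (1 = male, 2 = female).
#'
#' @inheritParams write_vcf
#' @return `path`, invisibly.
#' @export
write_phenotype_tsv <- function(geno, path) {
  sm <- geno$subject_meta
  tab <- data.frame(
    subject_id = sm$id,
    phenotype = ifelse(is.na(sm$phenotype), NA_integer_,
                       ifelse(sm$phenotype == "case", 2L, 1L)),
    age = sm$age,
    sex = ifelse(is.na(sm$sex), NA_integer_,
                 ifelse(sm$sex == "female", 2L, 1L)))
  data.table::fwrite(tab, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a phenotype/covariate TSV
#'
#' @param path file written by [write_phenotype_tsv()] (or matching layout).
#' @return A `subject_meta` data frame (`id`, `phenotype`, `age`, `sex`).
#' @export
load_phenotypes <- function(path) {
  tab <- data.table::fread(path, sep = "\t", data.table = FALSE)
  need <- c("subject_id", "phenotype", "age", "sex")
  if (!all(need %in% names(tab)))
    stop("phenotype file must have columns ", paste(need, collapse = ", "))
  data.frame(id = as.character(tab$subject_id),
             phenotype = c("control", "case")[tab$phenotype],
             age = as.numeric(tab$age),
             sex = c("male", "female")[tab$sex],
             stringsAsFactors = FALSE)
}

# Structural pre-validation of a VCF so parse failures carry a line number.
validate_vcf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !startsWith(lines[1], "##fileformat=VCF"))
    stop("not a VCF: missing ##fileformat header (line 1)")
  hdr <- which(startsWith(lines, "#CHROM"))
  if (length(hdr) != 1)
    stop("malformed VCF: expected exactly one #CHROM header line")
  n_fields <- length(strsplit(lines[hdr], "\t", fixed = TRUE)[[1]])
  if (n_fields < 10)
    stop(sprintf("malformed VCF header (line %d): no sample columns", hdr))
  body <- lines[seq.int(hdr + 1L, length.out = length(lines) - hdr)]
  cnt <- lengths(strsplit(body, "\t", fixed = TRUE))
  bad <- which(cnt != n_fields)
  if (length(bad))
    stop(sprintf("malformed VCF record at line %d: %d fields, expected %d",
                 hdr + bad[1], cnt[bad[1]], n_fields))
  invisible(TRUE)
}

load_genotypes_vcf <- function(path) {
  validate_vcf_lines(path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dos <- matrix(NA_real_, nrow = ncol(gt), ncol = nrow(gt))
  gtv <- gsub("|", "/", t(gt), fixed = TRUE)
  dos[gtv %in% c("0/0")] <- 0
  dos[gtv %in% c("0/1", "1/0")] <- 1
  dos[gtv %in% c("1/1")] <- 2
  unknown <- !is.na(gtv) & !(gtv %in% c("0/0", "0/1", "1/0", "1/1", "./."))
  if (any(unknown))
    stop("unsupported genotype encodings: ",
         paste(utils::head(unique(gtv[unknown]), 3), collapse = ", "))
  variant_meta <- data.frame(id = fix$ID, chrom = fix$CHROM,
                             pos = as.numeric(fix$POS),
                             ref = fix$REF, alt = fix$ALT,
                             stringsAsFactors = FALSE)
  subject_meta <- data.frame(id = colnames(gt), phenotype = NA_character_,
                             age = NA_real_, sex = NA_character_,
                             stringsAsFactors = FALSE)
  genotype_dataset(dos, variant_meta, subject_meta)
}

load_genotypes_tsv <- function(path) {
  tab <- data.table::fread(path, sep = "\t", data.table = FALSE,
                           check.names = FALSE)
  need <- c("variant_id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(tab)))
    stop("dosage TSV must start with columns ", paste(need, collapse = ", "))
  subj <- setdiff(names(tab), need)
  if (length(subj) == 0) stop("dosage TSV has no subject columns")
  dos <- t(as.matrix(tab[, subj, drop = FALSE]))
  bad <- which(!(dos %in% c(0, 1, 2) | is.na(dos)), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("invalid dosage for variant at line %d (values must be 0/1/2/NA)",
                 bad[1, 2] + 1L))
  variant_meta <- data.frame(id = as.character(tab$variant_id),
                             chrom = as.character(tab$chrom),
                             pos = as.numeric(tab$pos),
                             ref = tab$ref, alt = tab$alt,
                             stringsAsFactors = FALSE)
  subject_meta <- data.frame(id = subj, phenotype = NA_character_,
                             age = NA_real_, sex = NA_character_,
                             stringsAsFactors = FALSE)
  genotype_dataset(dos, variant_meta, subject_meta)
}

#' Load genotypes from VCF or TSV
#'
#' Dosage is the alternate allele count; `./.` (VCF) or `NA` (TSV) becomes a
#' missing call. Optionally attaches phenotypes/covariates from a
#' [write_phenotype_tsv()]-style file.
#'
#' @param path genotype file path.
#' @param format `"vcf"` or `"tsv"`.
#' @param phenotype_path optional phenotype/covariate TSV.
#' @return A [genotype_dataset()].
#' @export
load_genotypes <- function(path, format = c("vcf", "tsv"),
                           phenotype_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  geno <- switch(format, vcf = load_genotypes_vcf(path),
                 tsv = load_genotypes_tsv(path))
  if (!is.null(phenotype_path)) {
    ph <- load_phenotypes(phenotype_path)
    ix <- match(geno$subject_meta$id, ph$id)
    if (anyNA(ix))
      stop("phenotype file lacks subjects: ",
           paste(utils::head(geno$subject_meta$id[is.na(ix)], 3),
                 collapse = ", "))
    geno$subject_meta <- ph[ix, , drop = FALSE]
    rownames(geno$subject_meta) <- NULL
  }
  geno
}
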