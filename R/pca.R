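# Coefficient-weighted PCA of association signals and the +/-1 binarization
# of PC scores that defines each subject's state vector.

#' Coefficient-weighted PCA of selected variants
#'
#' Dosages of the selected variants are mean-imputed per variant,
#' standardized to zero mean / unit variance, multiplied column-wise by
#' their GWAS coefficients, and decomposed by SVD. The sign of each loading
#' column is fixed so its largest-magnitude entry is positive.
#'
#' @param geno a [genotype_dataset()].
#' @param variants selected variant identifiers.
#' @param weights their log-odds coefficients (same length/order).
#' @param n_components number of components N retained (default 7, giving a
#'   2^7 state space).
#' @param standardize set `FALSE` to skip unit-variance scaling (weighting
#'   then acts on centered dosages).
#' @return A list of class `pca_encoding`: `variants`, `weights`,
#'   `column_means`, `column_sds`, `loadings` (variants x N, orthonormal),
#'   `scores` (subjects x N), `explained` (variance fractions),
#'   `thresholds` (`NULL` until [binarize_scores()]).
#' @export
weighted_pca <- function(geno, variants, weights, n_components = 7L,
                         standardize = TRUE) {
  stopifnot(length(variants) == length(weights))
  ix <- match(variants, geno$variant_meta$id)
  if (anyNA(ix))
    stop("variants absent from dataset: ",
         paste(utils::head(variants[is.na(ix)], 3), collapse = ", "))
  if (all(weights == 0)) stop("all weights are zero; weighted matrix is degenerate")
  X <- geno$dosages[, ix, drop = FALSE]
  cm <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- cm[j]
  csd <- apply(X, 2, stats::sd)
  keep <- csd > 0
  if (!all(keep)) {
    warning(sprintf("dropping %d zero-variance variant(s) after imputation",
                    sum(!keep)))
    X <- X[, keep, drop = FALSE]
    variants <- variants[keep]; weights <- weights[keep]
    cm <- cm[keep]; csd <- csd[keep]
  }
  if (ncol(X) == 0) stop("no variants left after dropping zero variance")
  Xs <- sweep(X, 2, cm)
  if (standardize) Xs <- sweep(Xs, 2, csd, "/")
  Xw <- sweep(Xs, 2, weights, "*")
  sv <- svd(Xw)
  pos <- sv$d > max(dim(Xw)) * .Machine$double.eps * sv$d[1]
  if (n_components > sum(pos))
    stop(sprintf("n_components = %d exceeds the rank (%d) of the weighted matrix",
                 n_components, sum(pos)))
  N <- n_components
  loadings <- sv$v[, seq_len(N), drop = FALSE]
  scores <- sv$u[, seq_len(N), drop = FALSE] %*% diag(sv$d[seq_len(N)], N)
  # sign convention: largest-magnitude loading entry positive
  for (k in seq_len(N)) {
    s <- sign(loadings[which.max(abs(loadings[, k])), k])
    if (s < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  rownames(scores) <- geno$subject_meta$id
  rownames(loadings) <- variants
  structure(list(variants = variants, weights = weights,
                 column_means = cm, column_sds = csd,
                 standardize = standardize,
                 loadings = loadings, scores = scores,
                 explained = sv$d[seq_len(N)]^2 / sum(sv$d^2),
                 n_components = N, thresholds = NULL),
            class = "pca_encoding")
}

#' Project new subjects onto a fitted encoding
#'
#' Applies the stored imputation means, standardization constants and
#' weights, then the stored loadings. All encoding variants must be present.
#'
#' @param enc a `pca_encoding`.
#' @param geno dataset holding (at least) the encoding's variants.
#' @return Subjects x N score matrix.
#' @export
project_scores <- function(enc, geno) {
  ix <- match(enc$variants, geno$variant_meta$id)
  if (anyNA(ix))
    stop("dataset lacks encoding variants: ",
         paste(utils::head(enc$variants[is.na(ix)], 3), collapse = ", "))
  X <- geno$dosages[, ix, drop = FALSE]
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- enc$column_means[j]
  Xs <- sweep(X, 2, enc$column_means)
  if (enc$standardize) Xs <- sweep(Xs, 2, enc$column_sds, "/")
  Xw <- sweep(Xs, 2, enc$weights, "*")
  sc <- Xw %*% enc$loadings
  rownames(sc) <- geno$subject_meta$id
  sc
}

#' Binarize PC scores to +/-1 states
#'
#' The threshold of component k is the across-subject mean of its scores;
#' a score at or above the threshold maps to +1, below to -1. Thresholds
#' are stored on the encoding so validation subjects are binarized with the
#' training rule.
#'
#' @param enc a `pca_encoding` with scores.
#' @return The encoding with `thresholds` filled and `states` (subjects x N
#'   matrix of +/-1) attached.
#' @export
binarize_scores <- function(enc) {
  enc$thresholds <- colMeans(enc$scores)
  enc$states <- apply_thresholds(enc, enc$scores)
  enc
}

#' Apply stored binarization thresholds to scores
#'
#' @param enc a `pca_encoding` with `thresholds` set (see
#'   [binarize_scores()]).
#' @param scores subjects x N score matrix.
#' @return Subjects x N matrix of +/-1 states.
#' @export
apply_thresholds <- function(enc, scores) {
  if (is.null(enc$thresholds)) stop("no stored thresholds; run binarize_scores()")
  stopifnot(ncol(scores) == length(enc$thresholds))
  st <- ifelse(sweep(scores, 2, enc$thresholds) >= 0, 1, -1)
  rownames(st) <- rownames(scores)
  st
}
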