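# Covariate-adjusted logistic association, one fit per variant:
#   logit P(case) = b0 + b1*age + b2*sex + b3*dosage
# fit by iteratively reweighted least squares with Wald inference on b3,
# matching PLINK --logistic output semantics.

# IRLS for a logistic model. Returns coefficients, standard errors and a
# status flag; never throws on degenerate fits.
logistic_irls <- function(X, y, tol = 1e-8, max_iter = 50L) {
  beta <- numeric(ncol(X))
  sep_tol <- 1e-10
  for (it in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    score <- as.vector(crossprod(X, y - mu))
    if (max(abs(score)) < tol) {
      XtWX <- crossprod(X * w, X)
      cov <- tryCatch(solve(XtWX), error = function(e) NULL)
      if (is.null(cov))
        return(list(flag = "singular", beta = beta, se = rep(NA_real_, ncol(X))))
      # complete separation: converged score with saturated fitted values
      carriers <- X[, ncol(X)] > 0
      if (all(mu[carriers] > 1 - sep_tol) || all(mu[carriers] < sep_tol))
        return(list(flag = "separation", beta = beta,
                    se = rep(NA_real_, ncol(X))))
      return(list(flag = "ok", beta = beta, se = sqrt(diag(cov))))
    }
    XtWX <- crossprod(X * w, X)
    step <- tryCatch(solve(XtWX, score), error = function(e) NULL)
    if (is.null(step))
      return(list(flag = "singular", beta = beta, se = rep(NA_real_, ncol(X))))
    beta <- beta + step
    if (max(abs(beta)) > 30)
      return(list(flag = "separation", beta = beta,
                  se = rep(NA_real_, ncol(X))))
  }
  list(flag = "no_convergence", beta = beta, se = rep(NA_real_, ncol(X)))
}

#' Per-variant covariate-adjusted logistic GWAS
#'
#' For every variant, fits `logit P(case) = b0 + b1*age + b2*sex + b3*dosage`
#' by IRLS on subjects with a non-missing dosage (complete-case, PLINK
#' style) and reports Wald statistics for the dosage coefficient `b3`.
#' Sex enters coded 1 = male / 2 = female, centered; age in years,
#' uncentered. Degenerate fits (separation, non-convergence, monomorphic
#' dosage) are flagged with `p = NA`, never an error.
#'
#' @param geno a [genotype_dataset()] with phenotype, age and sex filled.
#' @param covariates which covariates to adjust for (default age and sex;
#'   an empty vector fits the unadjusted model).
#' @return A data frame of class `gwas_result`: one row per variant with
#'   `variant`, `chrom`, `pos`, `beta`, `se`, `or_`, `l95`, `u95`, `p`,
#'   `n_used`, `flag`.
#' @export
logistic_gwas <- function(geno, covariates = c("age", "sex")) {
  sm <- geno$subject_meta
  if (any(is.na(sm$phenotype)))
    stop("all subjects need a phenotype; attach one with load_genotypes()")
  y_all <- as.numeric(sm$phenotype == "case")
  if (sum(y_all == 1) < 2 || sum(y_all == 0) < 2)
    stop("need at least 2 subjects per phenotype class")
  covs <- NULL
  if ("age" %in% covariates) covs <- cbind(covs, age = sm$age)
  if ("sex" %in% covariates) {
    sex12 <- ifelse(sm$sex == "female", 2, 1)
    covs <- cbind(covs, sex = sex12 - mean(sex12, na.rm = TRUE))
  }
  cov_ok <- if (is.null(covs)) rep(TRUE, length(y_all)) else
    stats::complete.cases(covs)
  nv <- ncol(geno$dosages)
  out <- data.frame(variant = geno$variant_meta$id,
                    chrom = geno$variant_meta$chrom,
                    pos = geno$variant_meta$pos,
                    beta = NA_real_, se = NA_real_, or_ = NA_real_,
                    l95 = NA_real_, u95 = NA_real_, p = NA_real_,
                    n_used = NA_integer_, flag = "ok",
                    stringsAsFactors = FALSE)
  for (j in seq_len(nv)) {
    g <- geno$dosages[, j]
    use <- cov_ok & !is.na(g)
    out$n_used[j] <- sum(use)
    gj <- g[use]
    if (stats::var(gj) == 0 || sum(use) < 4) {
      out$flag[j] <- "monomorphic"
      next
    }
    X <- cbind(1, if (is.null(covs)) NULL else covs[use, , drop = FALSE], gj)
    fit <- logistic_irls(X, y_all[use])
    out$flag[j] <- fit$flag
    k <- ncol(X)
    out$beta[j] <- fit$beta[k]
    if (fit$flag == "ok") {
      out$se[j] <- fit$se[k]
      out$or_[j] <- exp(fit$beta[k])
      out$l95[j] <- exp(fit$beta[k] - 1.959964 * fit$se[k])
      out$u95[j] <- exp(fit$beta[k] + 1.959964 * fit$se[k])
      out$p[j] <- 2 * stats::pnorm(-abs(fit$beta[k] / fit$se[k]))
    } else {
      out$beta[j] <- NA_real_
    }
  }
  class(out) <- c("gwas_result", "data.frame")
  out
}

#' Select association signals for the landscape
#'
#' Returns the variants with unflagged Wald `p < p_threshold` together with
#' their log-odds coefficients, in dataset variant order. These weighted
#' signals are the input to [weighted_pca()].
#'
#' @param results a `gwas_result` from [logistic_gwas()].
#' @param p_threshold inclusion threshold (default 0.01).
#' @return A list with `variants` (identifiers) and `weights` (b3 values).
#' @export
select_signals <- function(results, p_threshold = 0.01) {
  if (nrow(results) == 0) stop("empty GWAS result")
  sel <- results$flag == "ok" & !is.na(results$p) & results$p < p_threshold
  if (!any(sel))
    stop(sprintf("no variants at p < %g; the landscape cannot be built",
                 p_threshold))
  list(variants = results$variant[sel], weights = results$beta[sel])
}

#' Write a GWAS association table
#'
#' TSV with PLINK-like columns CHR, POS, SNP, A1, A2, OR, L95, U95, BETA,
#' SE, P, N, FLAG.
#'
#' @param results a `gwas_result`.
#' @param geno the dataset the results came from (for alleles).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gwas_tsv <- function(results, geno, path) {
  vm <- geno$variant_meta[match(results$variant, geno$variant_meta$id), ]
  tab <- data.frame(CHR = results$chrom, POS = results$pos,
                    SNP = results$variant, A1 = vm$alt, A2 = vm$ref,
                    OR = results$or_, L95 = results$l95, U95 = results$u95,
                    BETA = results$beta, SE = results$se, P = results$p,
                    N = results$n_used, FLAG = results$flag)
  data.table::fwrite(tab, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}
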