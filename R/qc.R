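# PLINK-style marker and sample quality control.
#
# Filter order is fixed: variants (call rate -> MAF -> HWE), then samples
# (missingness -> heterozygosity F -> relatedness PI_HAT), then LD pruning.

#' Quality-control thresholds
#'
#' Defaults mirror the usual PLINK flags: `--geno 0.95`, `--maf 0.001`,
#' `--hwe 0.001`, `--mind 0.05`, `--het 0.1`, PI_HAT > 0.25,
#' `--indep-pairwise 50 5 0.1`.
#'
#' @param geno_call_rate minimum per-variant call rate.
#' @param maf_min minimum minor allele frequency.
#' @param hwe_p_min minimum Hardy-Weinberg exact-test p-value.
#' @param sample_missing_max maximum per-subject missingness.
#' @param het_f_max maximum |F| (method-of-moments inbreeding coefficient).
#' @param pihat_max maximum pairwise PI_HAT; one member of each offending
#'   pair is removed.
#' @param prune_window,prune_step,prune_r2 LD pruning window (variants),
#'   step and r^2 threshold.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(geno_call_rate = 0.95, maf_min = 0.001,
                          hwe_p_min = 0.001, sample_missing_max = 0.05,
                          het_f_max = 0.1, pihat_max = 0.25,
                          prune_window = 50L, prune_step = 5L,
                          prune_r2 = 0.1) {
  thr <- list(geno_call_rate = geno_call_rate, maf_min = maf_min,
              hwe_p_min = hwe_p_min, sample_missing_max = sample_missing_max,
              het_f_max = het_f_max, pihat_max = pihat_max,
              prune_window = as.integer(prune_window),
              prune_step = as.integer(prune_step), prune_r2 = prune_r2)
  with(thr, {
    if (geno_call_rate < 0 || geno_call_rate > 1)
      stop_field("geno_call_rate", "must lie in [0, 1]")
    if (maf_min < 0 || maf_min > 0.5)
      stop_field("maf_min", "must lie in [0, 0.5]")
    if (hwe_p_min < 0 || hwe_p_min > 1)
      stop_field("hwe_p_min", "must lie in [0, 1]")
    if (sample_missing_max < 0 || sample_missing_max > 1)
      stop_field("sample_missing_max", "must lie in [0, 1]")
    if (het_f_max < 0) stop_field("het_f_max", "must be non-negative")
    if (pihat_max < 0 || pihat_max > 1)
      stop_field("pihat_max", "must lie in [0, 1]")
    if (prune_window < 1 || prune_step < 1 || prune_step > prune_window)
      stop_field("prune_step", "needs 1 <= prune_step <= prune_window")
    if (prune_r2 < 0 || prune_r2 > 1)
      stop_field("prune_r2", "must lie in [0, 1]")
  })
  class(thr) <- "qc_thresholds"
  thr
}

new_qc_report <- function() {
  structure(list(removals = data.frame(stage = character(), type = character(),
                                       id = character(), reason = character(),
                                       stringsAsFactors = FALSE),
                 counts = data.frame(stage = character(),
                                     n_variants = integer(),
                                     n_subjects = integer(),
                                     stringsAsFactors = FALSE)),
            class = "qc_report")
}

qc_record <- function(report, stage, type, ids, reason, geno) {
  if (length(ids))
    report$removals <- rbind(report$removals,
                             data.frame(stage = stage, type = type, id = ids,
                                        reason = reason,
                                        stringsAsFactors = FALSE))
  report$counts <- rbind(report$counts,
                         data.frame(stage = stage,
                                    n_variants = ncol(geno$dosages),
                                    n_subjects = nrow(geno$dosages),
                                    stringsAsFactors = FALSE))
  report
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  print(x$counts, row.names = FALSE)
  if (nrow(x$removals))
    cat(sprintf("  %d removals (%s)\n", nrow(x$removals),
                paste(sprintf("%s: %d", names(table(x$removals$stage)),
                              table(x$removals$stage)), collapse = ", ")))
  else cat("  no removals\n")
  invisible(x)
}

#' Hardy-Weinberg exact test
#'
#' Exact test of Hardy-Weinberg proportions: conditioning on the allele
#' counts, the p-value sums the exact probabilities of every heterozygote
#' count whose probability does not exceed that of the observed table.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (reference homozygote,
#'   heterozygote, alternate homozygote).
#' @return The exact two-sided p-value.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be non-negative")
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("at least one genotype count must be positive")
  rare <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)   # rare allele count
  hets <- seq.int(rare %% 2, rare, by = 2)        # attainable het counts
  # log P(het = h | allele counts): conditional distribution
  lp <- vapply(hets, function(h) {
    hom_rare <- (rare - h) / 2
    hom_common <- n - h - hom_rare
    lfactorial(n) - lfactorial(h) - lfactorial(hom_rare) -
      lfactorial(hom_common) + h * log(2) +
      lfactorial(rare) + lfactorial(2 * n - rare) - lfactorial(2 * n)
  }, 0)
  p <- exp(lp - logsumexp(lp))
  obs <- p[match(n_Aa, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

# Per-variant HWE p-values on a dosage matrix.
hwe_pvalues <- function(dos) {
  apply(dos, 2, function(g) {
    g <- g[!is.na(g)]
    if (!length(g)) return(NA_real_)
    hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
  })
}

#' Marker quality-control filters
#'
#' Removes, in order: variants with call rate below `geno_call_rate`, minor
#' allele frequency below `maf_min`, and Hardy-Weinberg exact p below
#' `hwe_p_min`. HWE is computed in controls only when phenotypes are present
#' (standard practice, so true case-enriched signals are not discarded);
#' set `hwe_scope = "all"` to use every subject.
#'
#' @param geno a [genotype_dataset()].
#' @param thr a [qc_thresholds()].
#' @param hwe_scope `"controls"` (default) or `"all"`.
#' @return A list with the filtered `geno` and a `qc_report`.
#' @export
filter_variants <- function(geno, thr = qc_thresholds(),
                            hwe_scope = c("controls", "all")) {
  hwe_scope <- match.arg(hwe_scope)
  if (ncol(geno$dosages) == 0) stop("dataset has no variants")
  report <- new_qc_report()
  report <- qc_record(report, "input", "variant", character(), "", geno)

  cr <- variant_call_rate(geno)
  drop <- geno$variant_meta$id[cr < thr$geno_call_rate]
  geno <- subset_genotypes(geno, variants = setdiff(geno$variant_meta$id, drop))
  report <- qc_record(report, "call_rate", "variant", drop,
                      sprintf("call rate < %g", thr$geno_call_rate), geno)

  maf <- variant_maf(geno)
  drop <- geno$variant_meta$id[is.na(maf) | maf < thr$maf_min]
  geno <- subset_genotypes(geno, variants = setdiff(geno$variant_meta$id, drop))
  report <- qc_record(report, "maf", "variant", drop,
                      sprintf("MAF < %g", thr$maf_min), geno)

  ph <- geno$subject_meta$phenotype
  hwe_rows <- if (hwe_scope == "controls" && any(ph == "control", na.rm = TRUE))
    which(ph == "control") else seq_len(nrow(geno$dosages))
  hp <- hwe_pvalues(geno$dosages[hwe_rows, , drop = FALSE])
  drop <- geno$variant_meta$id[!is.na(hp) & hp < thr$hwe_p_min]
  geno <- subset_genotypes(geno, variants = setdiff(geno$variant_meta$id, drop))
  report <- qc_record(report, "hwe", "variant", drop,
                      sprintf("HWE exact p < %g", thr$hwe_p_min), geno)

  if (ncol(geno$dosages) == 0)
    stop("all variants removed by marker QC")
  list(geno = geno, report = report)
}

# Method-of-moments inbreeding coefficient per subject (PLINK --het):
# F = 1 - O(het)/E(het), expectations from per-variant 2*p*(1-p).
heterozygosity_f <- function(dos) {
  p <- colMeans(dos, na.rm = TRUE) / 2
  eh <- 2 * p * (1 - p)
  eh[is.na(eh)] <- 0
  o <- rowSums(dos == 1, na.rm = TRUE)
  e <- as.vector((!is.na(dos)) %*% eh)
  1 - o / pmax(e, .Machine$double.eps)
}

# Method-of-moments PI_HAT for all subject pairs from IBS sharing
# (PLINK --genome): PI_HAT = P(IBD=1)/2 + P(IBD=2).
pihat_matrix <- function(dos) {
  keep <- !is.na(colMeans(dos, na.rm = TRUE))
  x <- dos[, keep, drop = FALSE]
  x[is.na(x)] <- NA
  a0 <- (!is.na(x)) & x == 0; a1 <- (!is.na(x)) & x == 1
  a2 <- (!is.na(x)) & x == 2
  m0 <- matrix(as.numeric(a0), nrow(x)); m1 <- matrix(as.numeric(a1), nrow(x))
  m2 <- matrix(as.numeric(a2), nrow(x))
  seen <- matrix(as.numeric(!is.na(x)), nrow(x))
  n_obs <- seen %*% t(seen)                       # co-observed variants
  ibs0 <- m0 %*% t(m2) + m2 %*% t(m0)
  ibs2 <- m0 %*% t(m0) + m1 %*% t(m1) + m2 %*% t(m2)
  ibs1 <- n_obs - ibs0 - ibs2
  p <- colMeans(x, na.rm = TRUE) / 2
  q <- 1 - p
  # expected IBS probabilities per variant given IBD state
  e0_ibd0 <- 2 * p^2 * q^2
  e1_ibd0 <- 4 * p^3 * q + 4 * p * q^3
  e2_ibd0 <- 1 - e0_ibd0 - e1_ibd0
  e1_ibd1 <- 2 * p * q
  e2_ibd1 <- 1 - e1_ibd1
  # per-pair expectations restricted to co-observed variants: approximate
  # with panel-wide means (adequate at the low missing rates QC tolerates)
  s0_0 <- mean(e0_ibd0); s1_0 <- mean(e1_ibd0); s2_0 <- mean(e2_ibd0)
  s1_1 <- mean(e1_ibd1); s2_1 <- mean(e2_ibd1)
  p0 <- ibs0 / (n_obs * s0_0)
  p1 <- (ibs1 / n_obs - p0 * s1_0) / s1_1
  p2 <- (ibs2 / n_obs - p0 * s2_0 - p1 * s2_1)
  p0 <- pmin(pmax(p0, 0), 1); p1 <- pmin(pmax(p1, 0), 1)
  p2 <- pmin(pmax(p2, 0), 1)
  tot <- p0 + p1 + p2
  pihat <- (p1 / 2 + p2) / tot
  diag(pihat) <- 0
  pihat
}

#' Sample quality-control filters
#'
#' Removes, in order: subjects with genotype missingness above
#' `sample_missing_max`; subjects with |F| above `het_f_max`, where F is the
#' method-of-moments inbreeding coefficient `1 - O(het)/E(het)`; and one
#' member (the one with higher missingness, ties by later order) of each
#' pair with method-of-moments PI_HAT above `pihat_max`.
#'
#' @inheritParams filter_variants
#' @param relatedness set `FALSE` to skip the O(n^2) PI_HAT scan (e.g. for
#'   cohorts known to be unrelated by construction).
#' @return A list with the filtered `geno` and a `qc_report`.
#' @export
filter_samples <- function(geno, thr = qc_thresholds(), relatedness = TRUE) {
  if (nrow(geno$dosages) == 0) stop("dataset has no subjects")
  report <- new_qc_report()
  report <- qc_record(report, "input", "subject", character(), "", geno)

  miss <- rowMeans(is.na(geno$dosages))
  drop <- geno$subject_meta$id[miss > thr$sample_missing_max]
  geno <- subset_genotypes(geno, subjects = setdiff(geno$subject_meta$id, drop))
  report <- qc_record(report, "missingness", "subject", drop,
                      sprintf("missingness > %g", thr$sample_missing_max), geno)

  f <- heterozygosity_f(geno$dosages)
  drop <- geno$subject_meta$id[abs(f) > thr$het_f_max]
  geno <- subset_genotypes(geno, subjects = setdiff(geno$subject_meta$id, drop))
  report <- qc_record(report, "heterozygosity", "subject", drop,
                      sprintf("|F| > %g", thr$het_f_max), geno)

  if (relatedness && nrow(geno$dosages) >= 2) {
    ph <- pihat_matrix(geno$dosages)
    miss <- rowMeans(is.na(geno$dosages))
    drop_ix <- integer()
    repeat {
      ph_live <- ph
      if (length(drop_ix)) ph_live[drop_ix, ] <- ph_live[, drop_ix] <- 0
      mx <- which(ph_live == max(ph_live), arr.ind = TRUE)[1, ]
      if (ph_live[mx[1], mx[2]] <= thr$pihat_max) break
      pair <- c(mx[1], mx[2])
      victim <- pair[order(-miss[pair], -pair)][1]
      drop_ix <- c(drop_ix, victim)
    }
    drop <- geno$subject_meta$id[drop_ix]
    geno <- subset_genotypes(geno,
                             subjects = setdiff(geno$subject_meta$id, drop))
    report <- qc_record(report, "relatedness", "subject", drop,
                        sprintf("PI_HAT > %g", thr$pihat_max), geno)
  }
  if (nrow(geno$dosages) < 2)
    stop("fewer than 2 subjects remain after sample QC")
  list(geno = geno, report = report)
}

#' PLINK-style LD pruning
#'
#' Slides a `prune_window`-variant window along each chromosome in
#' `prune_step` increments; within a window, while any kept pair has
#' r^2 above `prune_r2`, removes one member of the worst pair (the one with
#' the lower MAF; ties broken by later position). r^2 is the squared
#' dosage correlation over pairwise-complete subjects.
#'
#' @inheritParams filter_variants
#' @return Character vector of kept variant identifiers (dataset order).
#' @export
ld_prune <- function(geno, thr = qc_thresholds()) {
  vm <- geno$variant_meta
  if (nrow(vm) == 0) return(character())
  keep <- rep(TRUE, nrow(vm))
  maf <- variant_maf(geno)
  for (chr in unique(vm$chrom)) {
    idx <- which(vm$chrom == chr)
    idx <- idx[order(vm$pos[idx])]
    nv <- length(idx)
    starts <- unique(c(seq(1L, max(1L, nv - 1L), by = thr$prune_step)))
    for (w0 in starts) {
      win <- idx[w0:min(w0 + thr$prune_window - 1L, nv)]
      live <- win[keep[win]]
      if (length(live) < 2) next
      # r^2 between surviving pairs does not change when a third variant is
      # removed, so the window correlation is computed once
      r2 <- suppressWarnings(
        stats::cor(geno$dosages[, live, drop = FALSE],
                   use = "pairwise.complete.obs"))^2
      r2[!is.finite(r2)] <- 0
      diag(r2) <- 0
      repeat {
        mx <- max(r2)
        if (mx <= thr$prune_r2) break
        pr <- which(r2 == mx, arr.ind = TRUE)[1, ]
        a <- live[pr[1]]; b <- live[pr[2]]
        victim <- if (maf[a] < maf[b]) a
          else if (maf[b] < maf[a]) b
          else if (vm$pos[a] > vm$pos[b]) a else b
        keep[victim] <- FALSE
        vix <- which(live == victim)
        r2[vix, ] <- r2[, vix] <- 0
      }
    }
  }
  vm$id[keep]
}

#' Run the full QC pipeline
#'
#' Marker filters, then sample filters, then LD pruning; reports every
#' removal with its stage and reason.
#'
#' @inheritParams filter_samples
#' @inheritParams filter_variants
#' @return A list with the QC'd pruned `geno`, the `variant_report`,
#'   `sample_report` and the `pruned` identifiers kept.
#' @export
run_qc <- function(geno, thr = qc_thresholds(),
                   hwe_scope = c("controls", "all"), relatedness = TRUE) {
  fv <- filter_variants(geno, thr, hwe_scope = match.arg(hwe_scope))
  fs <- filter_samples(fv$geno, thr, relatedness = relatedness)
  kept <- ld_prune(fs$geno, thr)
  list(geno = subset_genotypes(fs$geno, variants = kept),
       variant_report = fv$report, sample_report = fs$report,
       pruned = kept)
}
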