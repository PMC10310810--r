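# Downstream statistics on the two landscape groups: representative-cluster
# association scans with Bonferroni correction, exact contingency tests on
# risk-allele counts, landscape-wide Kendall correlation, biomarker
# comparisons with Benjamini-Hochberg FDR, and eQTL linear regression.

#' Representative clusters of each group
#'
#' Per group, the minima whose case/control frequency difference exceeds the
#' threshold in absolute value (strict inequality), with their basin
#' subjects.
#'
#' @param landscape an `energy_landscape` (needs per-subject assignments).
#' @param threshold frequency-difference cutoff (default 0.05).
#' @return A list with one `cluster_selection` per group: `group`, `minima`,
#'   `subjects` (identifiers), `n_case`, `n_control`, `threshold`.
#' @export
select_representative <- function(landscape, threshold = 0.05) {
  ns <- landscape$node_summary
  subj <- landscape$subjects
  if (is.null(subj)) stop("landscape carries no subject assignments")
  lapply(sort(unique(landscape$groups)), function(g) {
    mins <- ns$minimum[ns$group == g & abs(ns$freq_diff) > threshold]
    if (!length(mins))
      warning(sprintf("group %d has no representative clusters at |diff| > %g",
                      g, threshold))
    rows <- subj$basin %in% mins
    structure(list(group = g, minima = mins,
                   subjects = subj$id[rows],
                   n_case = sum(rows & subj$phenotype == "case"),
                   n_control = sum(rows & subj$phenotype == "control"),
                   threshold = threshold),
              class = "cluster_selection")
  })
}

#' Within-cluster association scan
#'
#' Re-runs the covariate-adjusted logistic GWAS restricted to the selected
#' subjects and applies a Bonferroni correction over the number of variants
#' actually tested in the selection.
#'
#' @param geno the QC'd [genotype_dataset()].
#' @param selection a `cluster_selection` from [select_representative()].
#' @param alpha significance level on the corrected p-values (default 0.05).
#' @return A data frame of class `association_table`: the `gwas_result`
#'   columns plus `p_bonferroni` and `significant`; the number of tests is
#'   in attribute `m`.
#' @export
cluster_association <- function(geno, selection, alpha = 0.05) {
  if (!length(selection$subjects)) stop("empty cluster selection")
  sub <- subset_genotypes(geno, subjects = selection$subjects)
  res <- logistic_gwas(sub)
  m <- sum(res$flag == "ok")
  res$p_bonferroni <- pmin(1, m * res$p)
  res$significant <- !is.na(res$p_bonferroni) & res$p_bonferroni < alpha
  attr(res, "m") <- m
  class(res) <- c("association_table", "data.frame")
  res
}

# Exact Fisher-Freeman-Halton p for a 2 x c table by full enumeration over
# all tables with the observed margins; probabilities from the multivariate
# hypergeometric in log space.
ffh_two_row <- function(tab) {
  cs <- colSums(tab); n <- sum(tab); r1 <- sum(tab[1, ])
  ord <- order(cs)                     # enumerate all but the largest column
  free <- ord[-length(ord)]
  big <- ord[length(ord)]
  grids <- lapply(free, function(j) 0:min(cs[j], r1))
  g <- as.matrix(expand.grid(grids))
  rest <- r1 - rowSums(g)
  ok <- rest >= 0 & rest <= cs[big]
  g <- g[ok, , drop = FALSE]; rest <- rest[ok]
  lp <- lchoose(cs[big], rest) - lchoose(n, r1)
  for (k in seq_along(free)) lp <- lp + lchoose(cs[free[k]], g[, k])
  lobs <- lchoose(cs[big], tab[1, big]) - lchoose(n, r1) +
    sum(lchoose(cs[free], tab[1, free]))
  min(1, sum(exp(lp[lp <= lobs + 1e-7])))
}

#' Fisher-Freeman-Halton exact test for an r x c table
#'
#' Two-sided exact p-value: the sum of the probabilities of all tables with
#' the observed margins whose conditional probability does not exceed that
#' of the observed table. Two-row tables (the genotype-category comparisons
#' this analysis makes) are evaluated by full enumeration; larger tables
#' fall back to the network algorithm of [stats::fisher.test()].
#'
#' @param tab matrix of non-negative integer counts with positive margins.
#' @return The exact p-value.
#' @export
fisher_exact_rxc <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("table must hold non-negative integer counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("table has a zero margin")
  if (nrow(tab) > ncol(tab)) tab <- t(tab)
  if (nrow(tab) == 1) return(1)
  if (nrow(tab) == 2) return(ffh_two_row(tab))
  stats::fisher.test(tab, workspace = 2e7)$p.value
}

#' Percentage of risk-allele carriers
#'
#' `100 * (n1 + n2) / (n0 + n1 + n2)` from genotype-category counts
#' (0/1/2 copies), reported to 2 decimals.
#'
#' @param n0,n1,n2 subject counts with 0, 1, 2 copies of the allele.
#' @return Carrier percentage rounded to 2 decimals.
#' @export
carrier_percentage <- function(n0, n1, n2) {
  total <- n0 + n1 + n2
  if (total <= 0) stop("total count must be positive")
  round(100 * (n1 + n2) / total, 2)
}

#' Kendall correlation across landscape nodes
#'
#' Kendall's tau-b (tie-corrected) between per-node case frequencies and
#' per-node carrier frequencies, with p by exact enumeration for n <= 8
#' untied nodes and by normal approximation otherwise.
#'
#' @param x,y per-node values (length >= 3).
#' @return A list with `tau` and `p`.
#' @export
kendall_tau_nodes <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 nodes with defined values")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("tau undefined: all-tied input")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "kendall", exact = length(x) <= 8))
  list(tau = unname(ct$estimate), p = ct$p.value)
}

#' Biomarker comparisons between cases and controls within groups
#'
#' Per landscape group and marker, a two-sided Wilcoxon rank-sum test of
#' cases vs controls (exact enumeration when both arms have <= 10 subjects
#' and no ties; otherwise normal approximation with tie and continuity
#' correction), with Benjamini-Hochberg q-values across the five kidney
#' markers within each group. HbA1c is tested separately, uncorrected.
#'
#' @param markers data frame from [simulate_biomarkers()] (or matching
#'   layout, keyed by `subject_id`).
#' @param subjects per-subject data frame with `id` and `phenotype`.
#' @param group_assignment named group vector (or the landscape `subjects`
#'   table) mapping subject id to group.
#' @return A data frame of class `biomarker_comparison`: `group`, `marker`,
#'   `n_case`, `n_control`, `wilcoxon_p`, `fdr_q` (`NA` for HbA1c).
#' @export
wilcoxon_biomarkers <- function(markers, subjects, group_assignment) {
  if (is.data.frame(group_assignment))
    group_assignment <- stats::setNames(group_assignment$group,
                                        group_assignment$id)
  kidney <- c("creatinine", "cystatin_c", "egfr", "albumin", "hemoglobin")
  all_markers <- c(kidney, "hba1c")
  out <- list()
  for (g in sort(unique(group_assignment))) {
    ids <- names(group_assignment)[group_assignment == g]
    sm <- subjects[subjects$id %in% ids, ]
    mk <- markers[match(sm$id, markers$subject_id), ]
    rows <- data.frame(group = g, marker = all_markers,
                       n_case = NA_integer_, n_control = NA_integer_,
                       wilcoxon_p = NA_real_, fdr_q = NA_real_)
    for (i in seq_along(all_markers)) {
      m <- all_markers[i]
      xc <- mk[[m]][sm$phenotype == "case"]
      xk <- mk[[m]][sm$phenotype == "control"]
      xc <- xc[!is.na(xc)]; xk <- xk[!is.na(xk)]
      rows$n_case[i] <- length(xc); rows$n_control[i] <- length(xk)
      if (length(xc) < 2 || length(xk) < 2) {
        warning(sprintf("group %d, %s: an arm has < 2 subjects; skipped", g, m))
        next
      }
      exact <- length(xc) <= 10 && length(xk) <= 10 &&
        !anyDuplicated(c(xc, xk))
      p <- suppressWarnings(
        stats::wilcox.test(xc, xk, exact = exact, correct = TRUE)$p.value)
      rows$wilcoxon_p[i] <- if (is.finite(p)) p else 1  # fully tied samples
    }
    ik <- match(kidney, rows$marker)
    rows$fdr_q[ik] <- stats::p.adjust(rows$wilcoxon_p[ik], method = "BH")
    out[[length(out) + 1L]] <- rows
  }
  out <- do.call(rbind, out)
  class(out) <- c("biomarker_comparison", "data.frame")
  out
}

#' eQTL linear regression
#'
#' Ordinary least squares of expression on dosage adjusted for age and sex,
#' with a t-test on the dosage coefficient.
#'
#' @param expression per-subject expression values.
#' @param dosage per-subject dosages in `{0, 1, 2}` (missing allowed;
#'   complete cases are used).
#' @param age,sex covariates (`sex` as `"female"`/`"male"` or numeric).
#' @return A list with `beta`, `se`, `p` and `n_used`.
#' @export
eqtl_linear <- function(expression, dosage, age, sex) {
  if (is.character(sex) || is.factor(sex))
    sex <- as.numeric(as.character(sex) == "female")
  df <- data.frame(expression = expression, dosage = dosage, age = age,
                   sex = sex)
  df <- df[stats::complete.cases(df), ]
  if (nrow(df) < 4) stop("need at least 4 complete observations")
  if (stats::var(df$dosage) == 0)
    stop("degenerate predictor: dosage has zero variance")
  fit <- stats::lm(expression ~ dosage + age + sex, data = df)
  co <- summary(fit)$coefficients["dosage", ]
  list(beta = unname(co[1]), se = unname(co[2]), p = unname(co[4]),
       n_used = nrow(df))
}
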