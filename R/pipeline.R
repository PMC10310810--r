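# End-to-end convenience: QC -> GWAS -> landscape on a discovery cohort,
# optionally followed by the neural-network predictor evaluated on a
# validation cohort.

#' Run the subtype-discovery pipeline on a discovery cohort
#'
#' Marker QC and LD pruning, covariate-adjusted logistic GWAS, and the
#' energy-landscape fit with the two-group split.
#'
#' @param geno discovery [genotype_dataset()] with phenotypes.
#' @param thr [qc_thresholds()].
#' @param p_threshold,n_components,lr,tol,max_iter landscape controls (see
#'   [fit_landscape()]).
#' @param sample_qc run sample filters (missingness / heterozygosity /
#'   relatedness); the relatedness scan is quadratic in subjects, so
#'   cohorts unrelated by construction may set this `FALSE`.
#' @return A list: `landscape`, `geno` (post-QC), `gwas`, `qc` reports.
#' @export
run_subtyping <- function(geno, thr = qc_thresholds(), p_threshold = 0.01,
                          n_components = 7L, lr = 0.1, tol = 1e-6,
                          max_iter = 1e5, sample_qc = FALSE) {
  fv <- filter_variants(geno, thr)
  g <- fv$geno
  sample_report <- NULL
  if (sample_qc) {
    fs <- filter_samples(g, thr)
    g <- fs$geno
    sample_report <- fs$report
  }
  kept <- ld_prune(g, thr)
  g <- subset_genotypes(g, variants = kept)
  gwas <- logistic_gwas(g)
  landscape <- fit_landscape(g, gwas, p_threshold = p_threshold,
                             n_components = n_components, lr = lr,
                             tol = tol, max_iter = max_iter)
  list(landscape = landscape, geno = g, gwas = gwas,
       qc = list(variant_report = fv$report, sample_report = sample_report))
}

#' Train and evaluate the subtype predictor across cohorts
#'
#' Trains the PC-score network on the discovery cohort (inputs restricted
#' to variants present in both cohorts), then maps validation subjects onto
#' the landscape via predicted states and scores node accuracy. Validation
#' "true groups" are the basin groups of the directly binarized PCA
#' projection of each validation subject (the training thresholds applied
#' to projected scores), computable because the encoding variants are
#' shared.
#'
#' @param fit output of [run_subtyping()].
#' @param validation validation [genotype_dataset()] with phenotypes.
#' @param cfg a [net_config()].
#' @return A list: `model`, `discovery` and `validation`
#'   `prediction_assessment`s, plus the predicted validation states.
#' @export
evaluate_predictor <- function(fit, validation, cfg = net_config()) {
  landscape <- fit$landscape
  enc_vars <- landscape$encoding$variants
  common <- intersect(enc_vars, validation$variant_meta$id)
  if (length(common) < 2)
    stop("validation cohort shares too few encoding variants")
  if (!all(enc_vars %in% common))
    message(sprintf("encoding restricted to %d/%d variants shared with validation",
                    length(common), length(enc_vars)))
  model <- train_pc_predictor(fit$geno, landscape$encoding$scores, common,
                              cfg, landscape = landscape)
  disc_states <- predict_states(model, fit$geno)
  disc_assess <- assess_predictions(
    landscape, disc_states, fit$geno$subject_meta$phenotype,
    true_groups = landscape$subjects$group)
  val_states <- predict_states(model, validation)
  val_truth <- tryCatch(
    assign_subjects(landscape, geno = validation)$group,
    error = function(e) NULL)
  val_assess <- assess_predictions(
    landscape, val_states, validation$subject_meta$phenotype,
    true_groups = val_truth)
  list(model = model, discovery = disc_assess, validation = val_assess,
       validation_states = val_states, validation_true_groups = val_truth)
}
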