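#' Synthetic cohort configuration
#'
#' Parameters of the generative model behind the synthetic discovery and
#' validation cohorts. Defaults emulate the study conditions the pipeline
#' targets: a case-control cohort of elderly subjects with two latent case
#' subtypes driven by disjoint causal-variant sets plus one strong shared
#' risk locus (an APOE4-like allele) enriched in subtype 1, cases older and
#' more often female than controls.
#'
#' @param n_cases,n_controls subject quotas (defaults 1947 / 2192).
#' @param n_variants number of variants on the array (default 5000; the
#'   simulated panel stands in for a pruned genome-wide set).
#' @param maf_range range the per-block generating minor allele frequency is
#'   drawn from, within (0, 0.5].
#' @param ld_block_size variants per correlated LD block; within a block each
#'   variant is a copy of its predecessor with per-entry resampling
#'   probability `ld_resample_prob`, so pairwise r^2 decays with distance.
#' @param ld_resample_prob per-entry probability of redrawing a genotype from
#'   Hardy-Weinberg when copying along an LD block.
#' @param n_subtypes number of latent case subtypes (default 2).
#' @param causal_per_subtype causal variants per subtype (disjoint sets).
#' @param effect_size_range range of causal log-odds per alternate allele
#'   (default 2.5-3.5, odds ratios ~12-33: the scale reported for subtype
#'   drivers in this design, chosen for detectability at cohort scale
#'   rather than genome-wide realism).
#' @param apoe_like_effect log-odds per allele of the shared strong risk
#'   locus (default 1.2, an odds ratio of ~3.3 per allele).
#' @param apoe_like_subtype1_enrichment extra odds multiplier per allele of
#'   the strong locus applied to the subtype-1 pathway (default 4).
#' @param age_mean_case,age_mean_control,age_sd age model in years; the
#'   liability slope for age is `(age_mean_case - age_mean_control)/age_sd^2`
#'   so that conditional age distributions match the configured means.
#' @param female_odds_case,female_odds_control odds of being female; the
#'   liability coefficient for sex is the log of their ratio.
#' @param missing_rate fraction of genotype calls masked as missing.
#' @param population_prevalence disease prevalence among candidate draws;
#'   the case quota is then filled by oversampling cases, as in a
#'   case-control design (default 0.02, an age-specific late-onset
#'   dementia incidence scale; low prevalence sharpens the selection
#'   differential that separates case subtypes).
#' @param b0 liability intercept; `NULL` (default) calibrates it so the
#'   expected candidate case fraction matches `population_prevalence`.
#' @param seed integer seed; all generation is deterministic given the seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_cases = 1947, n_controls = 2192,
                          n_variants = 5000,
                          maf_range = c(0.1, 0.4),
                          ld_block_size = 10,
                          ld_resample_prob = 0.1,
                          n_subtypes = 2,
                          causal_per_subtype = 20,
                          effect_size_range = c(2.5, 3.5),
                          apoe_like_effect = 1.2,
                          apoe_like_subtype1_enrichment = 4,
                          age_mean_case = 79.1, age_mean_control = 70.8,
                          age_sd = 6,
                          female_odds_case = 2.13, female_odds_control = 1.19,
                          missing_rate = 0.01,
                          population_prevalence = 0.02,
                          b0 = NULL,
                          seed = 1L) {
  cfg <- list(n_cases = n_cases, n_controls = n_controls,
              n_variants = n_variants, maf_range = maf_range,
              ld_block_size = ld_block_size,
              ld_resample_prob = ld_resample_prob,
              n_subtypes = n_subtypes,
              causal_per_subtype = causal_per_subtype,
              effect_size_range = effect_size_range,
              apoe_like_effect = apoe_like_effect,
              apoe_like_subtype1_enrichment = apoe_like_subtype1_enrichment,
              age_mean_case = age_mean_case,
              age_mean_control = age_mean_control, age_sd = age_sd,
              female_odds_case = female_odds_case,
              female_odds_control = female_odds_control,
              missing_rate = missing_rate,
              population_prevalence = population_prevalence,
              b0 = b0, seed = as.integer(seed))
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  chk_count <- function(field) {
    v <- cfg[[field]]
    if (length(v) != 1 || !is.finite(v) || v < 1 || v != round(v))
      stop_field(field, "must be a single positive integer")
  }
  for (f in c("n_cases", "n_controls", "n_variants", "ld_block_size",
              "n_subtypes", "causal_per_subtype"))
    chk_count(f)
  mr <- cfg$maf_range
  if (length(mr) != 2 || any(mr <= 0) || any(mr > 0.5) || mr[1] > mr[2])
    stop_field("maf_range", "must be an increasing pair within (0, 0.5]")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop_field("missing_rate", "must lie in [0, 1)")
  if (cfg$ld_resample_prob <= 0 || cfg$ld_resample_prob > 1)
    stop_field("ld_resample_prob", "must lie in (0, 1]")
  es <- cfg$effect_size_range
  if (length(es) != 2 || es[1] > es[2])
    stop_field("effect_size_range", "must be an increasing pair (log-odds)")
  if (cfg$age_sd <= 0)
    stop_field("age_sd", "must be positive")
  if (cfg$female_odds_case <= 0 || cfg$female_odds_control <= 0)
    stop_field("female_odds_case", "odds must be positive")
  if (cfg$apoe_like_subtype1_enrichment <= 0)
    stop_field("apoe_like_subtype1_enrichment", "odds multiplier must be positive")
  if (cfg$population_prevalence <= 0 || cfg$population_prevalence >= 1)
    stop_field("population_prevalence", "must lie in (0, 1)")
  if (cfg$causal_per_subtype * cfg$n_subtypes + 1 > cfg$n_variants)
    stop_field("n_variants",
               "needs causal_per_subtype * n_subtypes + 1 <= n_variants")
  invisible(cfg)
}
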