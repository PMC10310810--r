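# Synthetic cohort generator: determinism, allele-frequency recovery,
# liability calibration, biomarkers, expression, cohort pairs.

small_cfg <- function(...) {
  defaults <- list(n_cases = 60, n_controls = 60, n_variants = 40,
                   causal_per_subtype = 3, ld_block_size = 2,
                   missing_rate = 0.02, seed = 5)
  do.call(cohort_config, utils::modifyList(defaults, list(...)))
}

test_that("generation is deterministic given the seed", {
  cfg <- small_cfg()
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$geno$dosages, b$geno$dosages)
  expect_identical(a$geno$subject_meta, b$geno$subject_meta)
  expect_identical(a$truth$subtype, b$truth$subtype)
  c2 <- simulate_cohort(small_cfg(seed = 6))
  expect_false(identical(a$geno$dosages, c2$geno$dosages))
})

test_that("dosages recover the generating allele frequency under HW", {
  cfg <- cohort_config(n_cases = 1000, n_controls = 1000, n_variants = 3,
                       causal_per_subtype = 1, maf_range = c(0.3, 0.3),
                       ld_block_size = 1, missing_rate = 0, seed = 2)
  geno <- simulate_genotypes(cfg)
  expect_false(anyNA(geno$dosages))
  se <- sqrt(2 * 0.3 * 0.7 / 2000)
  for (j in 1:3)
    expect_lt(abs(mean(geno$dosages[, j]) - 0.6), 3 * se)
})

test_that("empirical MAF stays within 4 SE of the generating MAF", {
  cfg <- cohort_config(n_cases = 1200, n_controls = 1200, n_variants = 60,
                       causal_per_subtype = 2, ld_block_size = 3,
                       missing_rate = 0.01, seed = 9)
  geno <- simulate_genotypes(cfg)
  maf_gen <- geno$variant_meta$maf_gen
  alt <- colMeans(geno$dosages, na.rm = TRUE) / 2
  se <- sqrt(maf_gen * (1 - maf_gen) / (2 * 2400))
  expect_true(all(abs(alt - maf_gen) < 4 * se))
})

test_that("HWE exact p-values are approximately uniform absent LD and missingness", {
  cfg <- cohort_config(n_cases = 250, n_controls = 250, n_variants = 1000,
                       causal_per_subtype = 2, ld_block_size = 1,
                       missing_rate = 0, seed = 13)
  geno <- simulate_genotypes(cfg)
  p <- elgwas:::hwe_pvalues(geno$dosages)
  # exact-test p-values are discrete, so compare quantile-level coverage
  expect_gt(mean(p > 0.5), 0.35)
  expect_lt(mean(p < 0.05), 0.10)
})

test_that("missing_rate = 0 gives complete data and rates scale as configured", {
  g0 <- simulate_genotypes(small_cfg(missing_rate = 0))
  expect_false(anyNA(g0$dosages))
  g1 <- simulate_genotypes(cohort_config(n_cases = 500, n_controls = 500,
                                         n_variants = 100,
                                         causal_per_subtype = 2,
                                         missing_rate = 0.05, seed = 3))
  expect_lt(abs(mean(is.na(g1$dosages)) - 0.05), 0.005)
})

test_that("invalid configurations are rejected naming the offending field", {
  expect_error(cohort_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(cohort_config(missing_rate = 1), "missing_rate")
  expect_error(cohort_config(n_cases = 0), "n_cases")
  expect_error(cohort_config(n_variants = 10, causal_per_subtype = 10),
               "n_variants")
  expect_error(cohort_config(population_prevalence = 0),
               "population_prevalence")
})

test_that("a null architecture accepts candidates at rate logistic(b0)", {
  cfg <- cohort_config(n_cases = 150, n_controls = 350, n_variants = 10,
                       causal_per_subtype = 1,
                       effect_size_range = c(0, 0), apoe_like_effect = 0,
                       apoe_like_subtype1_enrichment = 1,
                       age_mean_case = 75, age_mean_control = 75,
                       female_odds_case = 1, female_odds_control = 1,
                       b0 = qlogis(0.3), seed = 17)
  sim <- simulate_cohort(cfg)
  rate <- attr(sim$truth, "candidate_case_rate")
  expect_lt(abs(rate - 0.3), 3 * sqrt(0.3 * 0.7 / 1000))
  # null subtype assignment is a fair coin
  expect_gt(mean(sim$truth$subtype == 1), 0.38)
  expect_lt(mean(sim$truth$subtype == 1), 0.62)
})

test_that("phenotype quotas are exact and confounding runs as configured", {
  cfg <- cohort_config(n_cases = 400, n_controls = 400, n_variants = 60,
                       causal_per_subtype = 3, seed = 21)
  sim <- simulate_cohort(cfg)
  sm <- sim$geno$subject_meta
  expect_equal(sum(sm$phenotype == "case"), 400)
  expect_equal(sum(sm$phenotype == "control"), 400)
  expect_gt(mean(sm$age[sm$phenotype == "case"]),
            mean(sm$age[sm$phenotype == "control"]))
  expect_gt(mean(sm$sex[sm$phenotype == "case"] == "female"),
            mean(sm$sex[sm$phenotype == "control"] == "female"))
  # APOE4-like carriers enriched among cases
  j <- match(sim$truth$apoe_variant, sim$geno$variant_meta$id)
  carrier <- sim$geno$dosages[, j] > 0
  expect_gt(mean(carrier[sm$phenotype == "case"], na.rm = TRUE),
            mean(carrier[sm$phenotype == "control"], na.rm = TRUE))
})

test_that("unreachable quotas error after the bounded number of attempts", {
  cfg <- cohort_config(n_cases = 500, n_controls = 100, n_variants = 10,
                       causal_per_subtype = 1,
                       effect_size_range = c(0, 0), apoe_like_effect = 0,
                       apoe_like_subtype1_enrichment = 1,
                       b0 = qlogis(1e-4), seed = 3)
  expect_error(simulate_cohort(cfg), "quota unreachable")
})

test_that("biomarkers are positive with the configured subtype-2 depression", {
  subjects <- data.frame(id = sprintf("s%04d", 1:700),
                         phenotype = rep(c("case", "control"), c(350, 350)),
                         stringsAsFactors = FALSE)
  truth <- structure(list(subtype = setNames(rep(c(2L, 1L), 350),
                                             subjects$id)),
                     class = "truth_labels")
  bm <- simulate_biomarkers(truth, subjects, seed = 5)
  expect_true(all(as.matrix(bm[, -1]) > 0))
  # subtype-2 cases (the case arm here) sit lower on albumin and hemoglobin
  sub2case <- subjects$phenotype == "case" & truth$subtype == 2L
  expect_lt(mean(bm$albumin[sub2case]), mean(bm$albumin[!sub2case]))
  expect_lt(mean(bm$hemoglobin[sub2case]), mean(bm$hemoglobin[!sub2case]))
  # no phenotype effect markers are centred alike
  expect_lt(abs(mean(bm$egfr[sub2case]) - mean(bm$egfr[!sub2case])), 3)
})

test_that("a -0.5 SD albumin shift is detectable by Wilcoxon in most seeds", {
  subjects <- data.frame(id = sprintf("s%04d", 1:700),
                         phenotype = rep(c("case", "control"), c(350, 350)),
                         stringsAsFactors = FALSE)
  truth <- structure(list(subtype = setNames(rep(2L, 700), subjects$id)),
                     class = "truth_labels")
  hits <- 0
  for (s in 1:20) {
    bm <- simulate_biomarkers(truth, subjects, shift_albumin = -0.5, seed = s)
    p <- wilcox.test(bm$albumin[subjects$phenotype == "case"],
                     bm$albumin[subjects$phenotype == "control"])$p.value
    hits <- hits + (p < 0.05)
  }
  expect_gte(hits, 16)
})

test_that("expression follows the eQTL dosage effect deterministically", {
  cfg <- small_cfg(missing_rate = 0)
  sim <- simulate_cohort(cfg)
  v <- sim$geno$variant_meta$id[10]
  e1 <- simulate_expression(sim$geno, v, beta = 1, noise_sd = 0.1, seed = 4)
  e2 <- simulate_expression(sim$geno, v, beta = 1, noise_sd = 0.1, seed = 4)
  expect_identical(e1, e2)
  fit <- eqtl_linear(e1, sim$geno$dosages[, 10], sim$geno$subject_meta$age,
                     sim$geno$subject_meta$sex)
  expect_lt(abs(fit$beta - 1), 2 * fit$se)
  expect_error(simulate_expression(sim$geno, "nope", 1, 0.1), "unknown variant")
})

test_that("cohort pairs share exactly the configured variant overlap", {
  cfg_d <- cohort_config(n_cases = 80, n_controls = 80, n_variants = 100,
                         causal_per_subtype = 3, seed = 31)
  cfg_v <- cohort_config(n_cases = 50, n_controls = 50, n_variants = 100,
                         causal_per_subtype = 3, seed = 32)
  pair <- make_cohort_pair(cfg_d, cfg_v, variant_overlap = 0.8)
  shared <- intersect(pair$discovery$geno$variant_meta$id,
                      pair$validation$geno$variant_meta$id)
  expect_length(shared, 80)
  expect_length(intersect(pair$discovery$geno$subject_meta$id,
                          pair$validation$geno$subject_meta$id), 0)
  # causal architecture identical across cohorts
  expect_identical(pair$discovery$truth$causal, pair$validation$truth$causal)
  expect_true(all(unlist(lapply(pair$validation$truth$causal,
                                `[[`, "variant")) %in% shared))
  full <- make_cohort_pair(cfg_d, cfg_v, variant_overlap = 1)
  expect_setequal(full$discovery$geno$variant_meta$id,
                  full$validation$geno$variant_meta$id)
  expect_error(make_cohort_pair(cfg_d, cfg_v, variant_overlap = 0), "overlap")
})
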