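# Synthetic cohort generator.
#
# Generative model, in the order the pipeline assumes it:
#   1. a variant panel in LD blocks; each block has one generating MAF and
#      genotypes chain-copied along the block with a fixed per-entry
#      resampling probability, so r^2 decays with distance;
#   2. a latent subtype per subject: the pathway of greatest genetic
#      predisposition, argmax_s of the per-subtype liabilities (a null
#      architecture therefore reduces to a fair coin);
#   3. case status from the chosen pathway's logistic liability
#        logit P(case) = b0 + b_age*age + b_sex*female + beta_apoe*g_apoe
#                        + [subtype == 1] log(enrichment)*g_apoe
#                        + sum over the subtype's causal set of beta_v * g_v
#      with exact case/control quotas filled by rejection sampling
#      (cases oversampled relative to the population prevalence, as in a
#      case-control design);
#   4. missing calls masked uniformly at the configured rate.

# Variant panel: id, chrom, pos, ref, alt, maf_gen, block.
make_variant_panel <- function(cfg, id_prefix = "snp") {
  nv <- cfg$n_variants
  n_chrom <- min(22L, nv)
  chrom_of <- sort(rep_len(seq_len(n_chrom), nv))
  pos <- unlist(lapply(split(seq_len(nv), chrom_of), function(ix) {
    cumsum(sample.int(10000L, length(ix), replace = TRUE)) + 1e6
  }), use.names = FALSE)
  # blocks never span chromosomes
  block <- unlist(lapply(split(seq_len(nv), chrom_of), function(ix) {
    ceiling(seq_along(ix) / cfg$ld_block_size)
  }), use.names = FALSE)
  block_id <- paste0("c", chrom_of, "b", block)
  maf_block <- stats::runif(length(unique(block_id)),
                            cfg$maf_range[1], cfg$maf_range[2])
  names(maf_block) <- unique(block_id)
  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, nv, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1), "")
  data.frame(id = sprintf("%s%06d", id_prefix, seq_len(nv)),
             chrom = as.character(chrom_of), pos = pos,
             ref = ref, alt = unname(alt),
             maf_gen = unname(maf_block[block_id]), block = block_id,
             stringsAsFactors = FALSE)
}

# Draw n complete genotype rows for a panel (no missingness). Within an LD
# block each variant copies the previous one, resampling each entry from
# Hardy-Weinberg with probability resample_prob.
draw_genotype_rows <- function(panel, n, resample_prob) {
  nv <- nrow(panel)
  out <- matrix(0, n, nv)
  new_block <- !duplicated(panel$block)
  for (j in seq_len(nv)) {
    hw <- stats::rbinom(n, 2L, panel$maf_gen[j])
    if (new_block[j]) {
      out[, j] <- hw
    } else {
      keep <- stats::runif(n) >= resample_prob
      out[, j] <- ifelse(keep, out[, j - 1L], hw)
    }
  }
  out
}

apply_missingness <- function(dosages, rate) {
  if (rate > 0) {
    mask <- stats::runif(length(dosages)) < rate
    dosages[mask] <- NA_real_
  }
  dosages
}

#' Simulate genotypes for a synthetic cohort
#'
#' Draws a subjects x variants dosage matrix from Hardy-Weinberg proportions
#' at block-level minor allele frequencies, with LD within blocks produced by
#' chain-copying (see [cohort_config()]). Phenotypes are left unassigned;
#' see [simulate_phenotypes()].
#'
#' @param config a [cohort_config()].
#' @return A [genotype_dataset()] with `n_cases + n_controls` subjects; the
#'   variant metadata carries the generating MAF (`maf_gen`) and LD block.
#' @export
simulate_genotypes <- function(config) {
  validate_cohort_config(config)
  with_seed(config$seed, {
    panel <- make_variant_panel(config)
    n <- config$n_cases + config$n_controls
    dos <- draw_genotype_rows(panel, n, config$ld_resample_prob)
    dos <- apply_missingness(dos, config$missing_rate)
    subj <- data.frame(id = sprintf("S%05d", seq_len(n)),
                       phenotype = NA_character_,
                       age = NA_real_, sex = NA_character_,
                       stringsAsFactors = FALSE)
    geno <- genotype_dataset(dos, panel, subj)
    attr(geno, "config") <- config
    geno
  })
}

# Pick the causal architecture: one APOE4-like shared locus plus disjoint
# per-subtype causal sets with log-odds drawn from the configured range.
# The sets carry the same effect-size multiset on MAF-matched variants, so
# the pathways are exchangeable (no subtype dominates by construction).
draw_truth_architecture <- function(panel, cfg) {
  # causal loci and the APOE4-like locus are LD-block seeds: MAF-adjacent
  # slot members are never block-mates (pathway burdens stay independent)
  # and candidate liabilities depend only on independent Hardy-Weinberg
  # draws, which keeps rejection sampling cheap
  reps <- panel$id[!duplicated(panel$block)]
  apoe <- reps[which.min(abs(panel$maf_gen[match(reps, panel$id)] - 0.2))]
  pool <- setdiff(reps, apoe)
  if (length(pool) < cfg$causal_per_subtype * cfg$n_subtypes)
    pool <- setdiff(panel$id, apoe)   # few blocks: fall back to all variants
  pool <- pool[order(panel$maf_gen[match(pool, panel$id)])]
  K <- cfg$n_subtypes
  k <- cfg$causal_per_subtype
  n_slots <- length(pool) %/% K
  slots <- sort(sample.int(n_slots, k))
  betas <- stats::runif(k, cfg$effect_size_range[1],
                        cfg$effect_size_range[2])
  causal <- vector("list", K)
  for (s in seq_len(K)) {
    # member s of each MAF-adjacent slot of K variants
    ids <- pool[(slots - 1L) * K + s]
    causal[[s]] <- data.frame(variant = ids, beta = betas,
                              stringsAsFactors = FALSE)
  }
  list(apoe_variant = apoe, causal = causal)
}

# Per-pathway linear predictors (without intercept): column s holds the
# liability of the subtype-s pathway for every candidate.
candidate_etas <- function(dos, panel, arch, age, female, cfg) {
  b_age <- (cfg$age_mean_case - cfg$age_mean_control) / cfg$age_sd^2
  b_sex <- log(cfg$female_odds_case / cfg$female_odds_control)
  g_apoe <- dos[, match(arch$apoe_variant, panel$id)]
  base <- b_age * age + b_sex * female + cfg$apoe_like_effect * g_apoe
  etas <- matrix(base, nrow(dos), cfg$n_subtypes)
  etas[, 1] <- etas[, 1] + log(cfg$apoe_like_subtype1_enrichment) * g_apoe
  for (s in seq_len(cfg$n_subtypes)) {
    ix <- match(arch$causal[[s]]$variant, panel$id)
    etas[, s] <- etas[, s] +
      as.vector(dos[, ix, drop = FALSE] %*% arch$causal[[s]]$beta)
  }
  etas
}

# Expected subtype-specific liability contribution of pathway s under the
# generating allele frequencies, used to centre pathway comparison.
pathway_means <- function(panel, arch, cfg) {
  mu <- vapply(seq_len(cfg$n_subtypes), function(s) {
    maf <- panel$maf_gen[match(arch$causal[[s]]$variant, panel$id)]
    sum(arch$causal[[s]]$beta * 2 * maf)
  }, 0)
  maf_apoe <- panel$maf_gen[match(arch$apoe_variant, panel$id)]
  mu[1] <- mu[1] + log(cfg$apoe_like_subtype1_enrichment) * 2 * maf_apoe
  mu
}

# The latent subtype is the pathway of greatest genetic predisposition
# relative to its population mean (exact ties broken uniformly at random,
# so a null architecture reduces to a fair coin); a candidate's case
# liability is then that pathway's eta.
draw_candidates <- function(m, panel, arch, cfg) {
  # candidates only need the columns entering the liability; when all of
  # them are LD-block seeds (the generator's own architectures always are)
  # they are plain Hardy-Weinberg draws and the full panel is completed
  # later, conditionally, for accepted subjects only
  arch_ids <- c(arch$apoe_variant,
                unlist(lapply(arch$causal, `[[`, "variant")))
  seeds <- panel$id[!duplicated(panel$block)]
  if (all(arch_ids %in% seeds)) {
    panel <- panel[match(arch_ids, panel$id), , drop = FALSE]
    dos <- vapply(panel$maf_gen,
                  function(p) stats::rbinom(m, 2L, p), numeric(m))
    if (m == 1L) dos <- matrix(dos, nrow = 1L)
  } else {
    dos <- draw_genotype_rows(panel, m, cfg$ld_resample_prob)
  }
  prev <- cfg$population_prevalence
  is_case_age <- stats::runif(m) < prev   # marginal mixture components
  age <- stats::rnorm(m, ifelse(is_case_age, cfg$age_mean_case,
                                cfg$age_mean_control), cfg$age_sd)
  p_f <- ifelse(stats::runif(m) < prev,
                cfg$female_odds_case / (1 + cfg$female_odds_case),
                cfg$female_odds_control / (1 + cfg$female_odds_control))
  female <- as.integer(stats::runif(m) < p_f)
  etas <- candidate_etas(dos, panel, arch, age, female, cfg)
  centred <- sweep(etas, 2, pathway_means(panel, arch, cfg))
  jitter <- matrix(stats::runif(length(etas)) * 1e-9, nrow(etas))
  subtype <- max.col(centred + jitter)
  eta <- etas[cbind(seq_len(m), subtype)]
  list(dos = dos, panel = panel, subtype = subtype, age = age,
       female = female, eta = eta)
}

# Complete full panel rows for accepted subjects, conditional on their
# stored liability-column genotypes (all LD-block seeds): other block seeds
# are fresh Hardy-Weinberg draws and block members chain-copy as usual.
complete_genotype_rows <- function(panel, stored_ids, stored_dos,
                                   resample_prob) {
  n <- nrow(stored_dos)
  nv <- nrow(panel)
  out <- matrix(0, n, nv)
  new_block <- !duplicated(panel$block)
  stored_at <- match(panel$id, stored_ids)
  for (j in seq_len(nv)) {
    if (!is.na(stored_at[j])) {
      out[, j] <- stored_dos[, stored_at[j]]
    } else if (new_block[j]) {
      out[, j] <- stats::rbinom(n, 2L, panel$maf_gen[j])
    } else {
      hw <- stats::rbinom(n, 2L, panel$maf_gen[j])
      keep <- stats::runif(n) >= resample_prob
      out[, j] <- ifelse(keep, out[, j - 1L], hw)
    }
  }
  out
}

#' Assign phenotypes, covariates and latent subtypes
#'
#' Fills the dataset with subjects drawn from the logistic liability model
#' until the configured case and control quotas are met exactly (rejection
#' sampling, capped at 100x the requested totals). Genotype rows are redrawn
#' from the same generative law as [simulate_genotypes()] because case status
#' and genotype are dependent under the liability.
#'
#' @param geno a dataset from [simulate_genotypes()] (defines the panel and
#'   the subject count).
#' @param config the [cohort_config()] used to generate `geno`.
#' @param reuse_truth optionally a `truth_labels` object from another cohort;
#'   its causal sets and APOE4-like locus are reused (all identifiers must
#'   exist in this panel), making the two cohorts share one architecture.
#' @param id_prefix prefix for subject identifiers (cohort pairs use
#'   disjoint prefixes).
#' @return A list with `geno` (phenotypes, ages and sexes filled; genotypes
#'   redrawn; missingness re-applied) and `truth` (a `truth_labels` object:
#'   per-subject latent `subtype`, per-subtype `causal` data frames,
#'   `apoe_variant`). The attribute `candidate_case_rate` on `truth` records
#'   the fraction of candidate draws that became cases, and `b0` the
#'   intercept used.
#' @export
simulate_phenotypes <- function(geno, config, reuse_truth = NULL,
                                id_prefix = "S") {
  validate_cohort_config(config)
  panel <- geno$variant_meta
  if (is.null(panel$maf_gen) || is.null(panel$block))
    stop("dataset lacks generator metadata; use simulate_genotypes()")
  n_total <- config$n_cases + config$n_controls
  with_seed(config$seed + 1L, {
    arch <- if (is.null(reuse_truth)) {
      draw_truth_architecture(panel, config)
    } else {
      ids <- c(reuse_truth$apoe_variant,
               unlist(lapply(reuse_truth$causal, `[[`, "variant")))
      if (!all(ids %in% panel$id))
        stop("reuse_truth names variants absent from this panel")
      list(apoe_variant = reuse_truth$apoe_variant,
           causal = reuse_truth$causal)
    }
    b0 <- config$b0
    if (is.null(b0)) {
      cal <- draw_candidates(4000L, panel, arch, config)
      target <- config$population_prevalence
      b0 <- stats::uniroot(function(b) mean(stats::plogis(b + cal$eta)) - target,
                           c(-max(cal$eta) - 40, -min(cal$eta) + 40))$root
    }
    cap <- 100L * n_total
    arch_ids <- c(arch$apoe_variant,
                  unlist(lapply(arch$causal, `[[`, "variant")))
    fast <- all(arch_ids %in% panel$id[!duplicated(panel$block)])
    batch_cap <- if (fast) 500000L else 20000L
    drawn <- 0L; n_case_drawn <- 0L
    need_case <- config$n_cases; need_ctrl <- config$n_controls
    keep <- list()
    while (need_case > 0 || need_ctrl > 0) {
      if (drawn >= cap)
        stop("case/control quota unreachable within 100x the requested totals; ",
             "check b0 and effect sizes")
      m <- min(max(1000L,
                   2L * need_ctrl +
                     as.integer(2 * need_case / config$population_prevalence)),
               cap - drawn, batch_cap)
      cand <- draw_candidates(m, panel, arch, config)
      is_case <- stats::runif(m) < stats::plogis(b0 + cand$eta)
      drawn <- drawn + m
      n_case_drawn <- n_case_drawn + sum(is_case)
      take_case <- which(is_case)[seq_len(min(need_case, sum(is_case)))]
      take_ctrl <- which(!is_case)[seq_len(min(need_ctrl, sum(!is_case)))]
      need_case <- need_case - length(take_case)
      need_ctrl <- need_ctrl - length(take_ctrl)
      sel <- c(take_case, take_ctrl)
      keep[[length(keep) + 1L]] <- list(
        dos = cand$dos[sel, , drop = FALSE],
        subtype = cand$subtype[sel], age = cand$age[sel],
        female = cand$female[sel],
        phenotype = rep(c("case", "control"),
                        c(length(take_case), length(take_ctrl))))
      cand_panel <- cand$panel
    }
    dos <- do.call(rbind, lapply(keep, `[[`, "dos"))
    if (nrow(cand_panel) < nrow(panel))
      dos <- complete_genotype_rows(panel, cand_panel$id, dos,
                                    config$ld_resample_prob)
    subtype <- unlist(lapply(keep, `[[`, "subtype"))
    age <- unlist(lapply(keep, `[[`, "age"))
    female <- unlist(lapply(keep, `[[`, "female"))
    phenotype <- unlist(lapply(keep, `[[`, "phenotype"))
    perm <- sample.int(n_total)
    ids <- sprintf("%s%05d", id_prefix, seq_len(n_total))
    subj <- data.frame(id = ids,
                       phenotype = phenotype[perm],
                       age = round(age[perm], 1),
                       sex = ifelse(female[perm] == 1L, "female", "male"),
                       stringsAsFactors = FALSE)
    dos <- apply_missingness(dos[perm, , drop = FALSE], config$missing_rate)
    out <- genotype_dataset(dos, panel, subj)
    attr(out, "config") <- config
    truth <- structure(
      list(subtype = stats::setNames(subtype[perm], ids),
           causal = arch$causal,
           apoe_variant = arch$apoe_variant),
      class = "truth_labels")
    attr(truth, "candidate_case_rate") <- n_case_drawn / drawn
    attr(truth, "b0") <- b0
    list(geno = out, truth = truth)
  })
}

#' Simulate a synthetic cohort end to end
#'
#' Convenience wrapper: [simulate_genotypes()] then [simulate_phenotypes()].
#'
#' @inheritParams simulate_phenotypes
#' @param config a [cohort_config()].
#' @return As [simulate_phenotypes()].
#' @export
simulate_cohort <- function(config, reuse_truth = NULL, id_prefix = "S") {
  geno <- simulate_genotypes(config)
  simulate_phenotypes(geno, config, reuse_truth = reuse_truth,
                      id_prefix = id_prefix)
}

# Marker reference distributions: mean, SD, units as measured in routine
# blood tests of elderly subjects.
biomarker_reference <- data.frame(
  marker = c("creatinine", "cystatin_c", "egfr", "albumin", "hemoglobin",
             "hba1c"),
  mean = c(0.85, 1.05, 65, 4.2, 13.5, 5.8),
  sd = c(0.25, 0.25, 15, 0.35, 1.5, 0.6),
  stringsAsFactors = FALSE)

#' Simulate routine blood-test biomarkers
#'
#' Albumin and hemoglobin means are shifted down for subtype-2 cases (the
#' kidney-associated subtype); creatinine, cystatin C, eGFR and HbA1c carry
#' no phenotype effect. All values are truncated to stay positive.
#'
#' @param truth `truth_labels` from [simulate_phenotypes()].
#' @param subjects the dataset's `subject_meta` (needs `id`, `phenotype`).
#' @param shift_albumin,shift_hemoglobin shifts in SD units applied to
#'   subtype-2 cases (defaults -0.5).
#' @param seed integer seed.
#' @return A data frame keyed by `subject_id` with one column per marker.
#' @export
simulate_biomarkers <- function(truth, subjects,
                                shift_albumin = -0.5,
                                shift_hemoglobin = -0.5,
                                seed = 1L) {
  stopifnot(inherits(truth, "truth_labels"))
  n <- nrow(subjects)
  subtype <- truth$subtype[subjects$id]
  if (anyNA(subtype)) stop("subjects absent from truth labels")
  shifted <- subjects$phenotype == "case" & subtype == 2L
  with_seed(seed, {
    out <- data.frame(subject_id = subjects$id, stringsAsFactors = FALSE)
    for (k in seq_len(nrow(biomarker_reference))) {
      m <- biomarker_reference$marker[k]
      mu <- rep(biomarker_reference$mean[k], n)
      sdv <- biomarker_reference$sd[k]
      if (m == "albumin") mu <- mu + shifted * shift_albumin * sdv
      if (m == "hemoglobin") mu <- mu + shifted * shift_hemoglobin * sdv
      out[[m]] <- pmax(stats::rnorm(n, mu, sdv), 1e-6)
    }
    out
  })
}

#' Simulate expression for a cis-eQTL variant
#'
#' Expression = intercept + beta x dosage + small age and sex nuisance terms
#' + Gaussian noise; missing dosages contribute through their panel mean.
#'
#' @param geno a [genotype_dataset()] with ages and sexes filled.
#' @param eqtl_variant variant identifier driving expression.
#' @param beta expression units per alternate allele.
#' @param noise_sd residual SD in expression units.
#' @param seed integer seed.
#' @return Named numeric vector of per-subject expression values.
#' @export
simulate_expression <- function(geno, eqtl_variant, beta, noise_sd,
                                seed = 1L) {
  j <- match(eqtl_variant, geno$variant_meta$id)
  if (is.na(j)) stop(sprintf("unknown variant identifier '%s'", eqtl_variant))
  g <- geno$dosages[, j]
  g[is.na(g)] <- mean(g, na.rm = TRUE)
  age <- geno$subject_meta$age
  age <- if (all(is.na(age))) rep(0, length(g)) else age - mean(age, na.rm = TRUE)
  female <- as.numeric(geno$subject_meta$sex == "female")
  female[is.na(female)] <- 0
  with_seed(seed, {
    expr <- 5 + beta * g + 0.02 * age + 0.1 * female +
      stats::rnorm(length(g), 0, noise_sd)
    stats::setNames(expr, geno$subject_meta$id)
  })
}

#' Simulate a discovery / validation cohort pair
#'
#' The validation cohort is drawn from the same generative model with the
#' same causal architecture; its variant panel shares exactly
#' `round(variant_overlap * n_variants)` identifiers with the discovery
#' panel (validation `n_variants`), mirroring genotyping on two different
#' arrays. Subject identifiers are disjoint by construction.
#'
#' @param config_discovery,config_validation [cohort_config()]s for the two
#'   cohorts.
#' @param variant_overlap fraction of the validation panel shared with the
#'   discovery panel, in (0, 1].
#' @return A list: `discovery`, `validation` (each as returned by
#'   [simulate_cohort()]) and `shared_variants`.
#' @export
make_cohort_pair <- function(config_discovery, config_validation,
                             variant_overlap = 0.8) {
  if (length(variant_overlap) != 1 || variant_overlap <= 0 ||
      variant_overlap > 1)
    stop("variant_overlap must lie in (0, 1]")
  disc <- simulate_cohort(config_discovery, id_prefix = "D")
  n_shared <- round(variant_overlap * config_validation$n_variants)
  if (n_shared > config_discovery$n_variants)
    stop("overlap asks for more shared variants than the discovery panel has")
  arch_ids <- c(disc$truth$apoe_variant,
                unlist(lapply(disc$truth$causal, `[[`, "variant")))
  if (n_shared < length(arch_ids))
    stop("overlap too small to share the causal architecture")
  panel_d <- disc$geno$variant_meta
  with_seed(config_validation$seed + 2L, {
    shared <- c(arch_ids,
                sample(setdiff(panel_d$id, arch_ids),
                       n_shared - length(arch_ids)))
    shared_panel <- panel_d[match(shared, panel_d$id), , drop = FALSE]
    shared_panel$block <- paste0("s", seq_len(nrow(shared_panel)))
    n_new <- config_validation$n_variants - n_shared
    if (n_new > 0) {
      cfg_new <- config_validation
      cfg_new$n_variants <- n_new
      # suspend count checks that only apply to a full panel
      cfg_new$causal_per_subtype <- 1L
      new_panel <- make_variant_panel(cfg_new, id_prefix = "vsnp")
      new_panel$pos <- new_panel$pos + 5e8   # keep positions disjoint
      panel_v <- rbind(shared_panel, new_panel)
    } else {
      panel_v <- shared_panel
    }
    panel_v <- panel_v[order(as.integer(panel_v$chrom), panel_v$pos), ,
                       drop = FALSE]
    rownames(panel_v) <- NULL
  })
  n_v <- config_validation$n_cases + config_validation$n_controls
  geno_v <- with_seed(config_validation$seed, {
    dos <- draw_genotype_rows(panel_v, n_v, config_validation$ld_resample_prob)
    subj <- data.frame(id = sprintf("V%05d", seq_len(n_v)),
                       phenotype = NA_character_, age = NA_real_,
                       sex = NA_character_, stringsAsFactors = FALSE)
    genotype_dataset(dos, panel_v, subj)
  })
  valid <- simulate_phenotypes(geno_v, config_validation,
                               reuse_truth = disc$truth, id_prefix = "V")
  list(discovery = disc, validation = valid, shared_variants = shared)
}
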