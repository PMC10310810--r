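# Downstream subtype statistics: exact contingency tests, carrier rates,
# Kendall correlation, biomarker FDR, eQTL regression, cluster scans.

test_that("Fisher exact test handles canonical small tables", {
  expect_equal(fisher_exact_rxc(matrix(c(10, 10, 10, 10), 2)), 1)
  expect_equal(fisher_exact_rxc(matrix(c(2, 0, 0, 2), 2)), 1 / 3,
               tolerance = 1e-12)
  expect_error(fisher_exact_rxc(matrix(c(0, 0, 3, 4), 2)), "zero margin")
  expect_error(fisher_exact_rxc(matrix(c(1.5, 1, 2, 2), 2)), "integer")
})

test_that("two-row enumeration agrees with the network algorithm", {
  set.seed(14)
  for (i in 1:60) {
    nc <- sample(2:3, 1)
    tab <- matrix(rpois(2 * nc, sample(2:10, 1)), nrow = 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_rxc(tab),
                 stats::fisher.test(tab, workspace = 2e7)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("carrier percentages reproduce genotype-count arithmetic", {
  expect_equal(carrier_percentage(457, 383, 78), 50.22)
  expect_equal(carrier_percentage(1112, 179, 6), 14.26)
  expect_equal(carrier_percentage(100, 0, 0), 0)
  expect_error(carrier_percentage(0, 0, 0), "positive")
})

test_that("Kendall tau across nodes matches hand-counted concordances", {
  expect_equal(kendall_tau_nodes(1:5, 2 * (1:5))$tau, 1)
  expect_equal(kendall_tau_nodes(1:5, 5:1)$tau, -1)
  # x = (1,2,3), y = (1,3,2): 2 concordant, 1 discordant of 3 pairs
  expect_equal(kendall_tau_nodes(c(1, 2, 3), c(1, 3, 2))$tau, 1 / 3,
               tolerance = 1e-12)
  expect_error(kendall_tau_nodes(c(1, 1, 1), c(1, 2, 3)), "tied")
  expect_error(kendall_tau_nodes(c(1, 2), c(1, 2)), "3 nodes")
})

test_that("biomarker comparisons use exact Wilcoxon and per-group BH", {
  set.seed(44)
  subjects <- data.frame(id = sprintf("s%02d", 1:8),
                         phenotype = rep(c("case", "control"), each = 4),
                         stringsAsFactors = FALSE)
  grp <- setNames(rep(1L, 8), subjects$id)
  markers <- data.frame(subject_id = subjects$id,
                        creatinine = c(1, 2, 1.5, 1.8, 3, 4, 3.5, 3.8),
                        cystatin_c = rep(1, 8), egfr = rep(60, 8),
                        albumin = c(3, 3.1, 3.2, 3.3, 4.5, 4.6, 4.7, 4.8),
                        hemoglobin = rnorm(8, 13, 1),
                        hba1c = rnorm(8, 5.8, 0.2))
  out <- wilcoxon_biomarkers(markers, subjects, grp)
  # both arms completely separated: two-sided exact p = 2/C(8,4)
  cr <- out[out$marker == "creatinine", ]
  expect_equal(cr$wilcoxon_p, 2 / choose(8, 4), tolerance = 1e-12)
  alb <- out[out$marker == "albumin", ]
  expect_equal(alb$wilcoxon_p, 2 / choose(8, 4), tolerance = 1e-12)
  # ties: identical samples give p = 1
  expect_equal(out$wilcoxon_p[out$marker == "cystatin_c"], 1)
  # BH within the kidney family only; HbA1c uncorrected
  kidney <- out[out$marker != "hba1c", ]
  expect_true(all(kidney$fdr_q >= kidney$wilcoxon_p - 1e-12))
  expect_equal(kidney$fdr_q,
               p.adjust(kidney$wilcoxon_p, "BH"))
  expect_true(is.na(out$fdr_q[out$marker == "hba1c"]))
})

test_that("the exact two-sample example {1,2} vs {3,4} gives p = 1/3", {
  p <- suppressWarnings(wilcox.test(c(1, 2), c(3, 4), exact = TRUE)$p.value)
  markers <- data.frame(subject_id = sprintf("s%d", 1:4),
                        creatinine = c(1, 2, 3, 4), cystatin_c = 1:4,
                        egfr = 1:4, albumin = 1:4, hemoglobin = 1:4,
                        hba1c = 1:4)
  subjects <- data.frame(id = sprintf("s%d", 1:4),
                         phenotype = c("case", "case", "control", "control"),
                         stringsAsFactors = FALSE)
  out <- wilcoxon_biomarkers(markers, subjects, setNames(rep(1L, 4),
                                                         subjects$id))
  expect_equal(out$wilcoxon_p[out$marker == "creatinine"], 1 / 3,
               tolerance = 1e-12)
  expect_equal(p, 1 / 3, tolerance = 1e-12)
})

test_that("eQTL regression recovers effects and rejects degenerate dosage", {
  set.seed(15)
  n <- 150
  dosage <- rbinom(n, 2, 0.3)
  age <- rnorm(n, 75, 6)
  sex <- sample(c("female", "male"), n, TRUE)
  noiseless <- 1 + 2 * dosage
  fit0 <- suppressWarnings(eqtl_linear(noiseless, dosage, age, sex))
  expect_equal(fit0$beta, 2, tolerance = 1e-10)
  expect_lt(fit0$p, 1e-12)
  noisy <- 1 + dosage + 0.02 * age + rnorm(n, 0, 0.5)
  fit1 <- eqtl_linear(noisy, dosage, age, sex)
  expect_lt(abs(fit1$beta - 1), 2 * fit1$se)
  expect_error(eqtl_linear(noisy, rep(2, n), age, sex), "zero variance")
})

test_that("representative clusters respect the strict 5% rule", {
  ns <- data.frame(minimum = 1:4, index = c(0, 3, 5, 9),
                   energy = c(-1, -0.5, -0.4, -0.2),
                   group = c(1L, 1L, 2L, 2L),
                   n_case = c(50, 5, 40, 10), n_control = c(20, 6, 60, 9),
                   case_frequency = c(0.5, 0.05, 0.38, 0.07),
                   control_frequency = c(0.21, 0.09, 0.58, 0.12),
                   freq_diff = c(0.29, -0.04, -0.20, -0.05),
                   color = c("red", "green", "green", "green"))
  subj <- data.frame(id = sprintf("s%03d", 1:200),
                     basin = rep(1:4, each = 50),
                     phenotype = rep(c("case", "control"), 100),
                     group = rep(c(1L, 1L, 2L, 2L), each = 50),
                     stringsAsFactors = FALSE)
  L <- structure(list(node_summary = ns, subjects = subj,
                      groups = c(1L, 1L, 2L, 2L)),
                 class = "energy_landscape")
  sel <- select_representative(L, threshold = 0.05)
  # |diff| 0.04 and 0.05 excluded (strict), -0.20 kept as control-majority
  expect_equal(sel[[1]]$minima, 1L)
  expect_equal(sel[[2]]$minima, 3L)
  expect_equal(length(sel[[1]]$subjects), 50)
  expect_equal(sel[[1]]$n_case + sel[[1]]$n_control, 50)
})

test_that("cluster association over the whole cohort equals the plain GWAS", {
  set.seed(16)
  n <- 120
  ph <- rep(c("case", "control"), n / 2)
  geno <- toy_dataset(random_dosages(n, 6, seed = 16), phenotype = ph,
                      age = rnorm(n, 75, 5),
                      sex = sample(c("female", "male"), n, TRUE))
  selection <- structure(list(group = 1L, minima = 1L,
                              subjects = geno$subject_meta$id,
                              n_case = n / 2, n_control = n / 2,
                              threshold = 0.05),
                         class = "cluster_selection")
  tab <- cluster_association(geno, selection)
  ref <- logistic_gwas(geno)
  expect_equal(tab$beta, ref$beta)
  expect_equal(tab$p, ref$p)
  m <- attr(tab, "m")
  expect_equal(tab$p_bonferroni, pmin(1, m * tab$p))
  # the Bonferroni arithmetic of a large scan
  expect_equal(min(1, 20000 * 2.53e-8), 5.06e-4)
})

test_that("association tables are invariant to subject order", {
  set.seed(18)
  n <- 80
  ph <- rep(c("case", "control"), n / 2)
  geno <- toy_dataset(random_dosages(n, 4, seed = 18), phenotype = ph,
                      age = rnorm(n, 75, 5),
                      sex = sample(c("female", "male"), n, TRUE))
  perm <- sample(n)
  geno2 <- subset_genotypes(geno, subjects = perm)
  r1 <- logistic_gwas(geno)
  r2 <- logistic_gwas(geno2)
  expect_equal(r1$beta, r2$beta, tolerance = 1e-10)
  expect_equal(r1$p, r2$p, tolerance = 1e-10)
})
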