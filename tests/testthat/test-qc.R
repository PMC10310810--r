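# Marker/sample QC: HWE exact test, filters, relatedness, LD pruning.

test_that("HWE exact test matches known values and an enumeration oracle", {
  expect_equal(hwe_exact_test(100, 0, 0), 1)
  expect_equal(hwe_exact_test(25, 50, 25), 1)
  expect_lt(hwe_exact_test(0, 100, 0), 1e-6)
  expect_error(hwe_exact_test(-1, 2, 3), "non-negative")
  # oracle: direct summation over the conditional distribution, written as
  # an unnormalized loop over all attainable heterozygote counts
  oracle <- function(aa, ab, bb) {
    n <- aa + ab + bb
    rare <- min(2 * aa + ab, 2 * bb + ab)
    hs <- seq(rare %% 2, rare, by = 2)
    pr <- sapply(hs, function(h) {
      hr <- (rare - h) / 2
      exp(lgamma(n + 1) - lgamma(h + 1) - lgamma(hr + 1) -
            lgamma(n - h - hr + 1) + h * log(2) +
            lgamma(rare + 1) + lgamma(2 * n - rare + 1) - lgamma(2 * n + 1))
    })
    pr <- pr / sum(pr)
    sum(pr[pr <= pr[hs == ab] * (1 + 1e-12)])
  }
  set.seed(12)
  for (i in 1:50) {
    n <- sample(3:200, 1)
    ab <- sample(0:n, 1)
    aa <- sample(0:(n - ab), 1)
    bb <- n - ab - aa
    expect_equal(hwe_exact_test(aa, ab, bb), oracle(aa, ab, bb),
                 tolerance = 1e-12)
  }
})

test_that("marker filters remove by call rate, MAF and HWE in order", {
  set.seed(21)
  dos <- random_dosages(100, 5, maf = 0.3, seed = 21)
  dos[1:6, 1] <- NA                      # call rate 0.94 < 0.95
  dos[, 2] <- 0; dos[1, 2] <- 1          # MAF 0.005, above 0.001
  geno <- toy_dataset(dos, phenotype = rep(c("case", "control"), 50))
  out <- filter_variants(geno, qc_thresholds())
  expect_true("v001" %in% out$report$removals$id)
  expect_false("v002" %in% out$report$removals$id)
  expect_true(all(diff(out$report$counts$n_variants) <= 0))
  # one alt allele among 2000 subjects: MAF 0.00025 < 0.001
  dos2 <- matrix(0, 2000, 2)
  dos2[1, 1] <- 1
  dos2[, 2] <- rbinom(2000, 2, 0.3)
  g2 <- toy_dataset(dos2)
  out2 <- filter_variants(g2, qc_thresholds())
  expect_equal(out2$report$removals$id, "v001")
  # an all-passing matrix reports zero removals
  g3 <- toy_dataset(random_dosages(200, 4, maf = 0.25, seed = 3))
  expect_equal(nrow(filter_variants(g3)$report$removals), 0)
})

test_that("HWE-violating variants are removed using controls only", {
  set.seed(31)
  n <- 300
  dos <- cbind(rep(1, n), rbinom(n, 2, 0.3))   # all-het column fails HWE hard
  ph <- rep(c("case", "control"), each = n / 2)
  geno <- toy_dataset(dos, phenotype = ph)
  out <- filter_variants(geno)
  expect_true("v001" %in%
                out$report$removals$id[out$report$removals$stage == "hwe"])
  # a case-only violation survives the controls-only test
  dos2 <- cbind(c(rep(1, 150), rbinom(150, 2, 0.3)), rbinom(n, 2, 0.3))
  g2 <- toy_dataset(dos2, phenotype = ph)
  expect_false("v001" %in% filter_variants(g2)$report$removals$id)
  expect_true("v001" %in%
                filter_variants(g2, hwe_scope = "all")$report$removals$id)
})

test_that("sample filters catch missingness, duplicates, and spare the unrelated", {
  set.seed(41)
  dos <- random_dosages(40, 1000, maf = 0.3, seed = 41)
  dos[2, 1:100] <- NA                    # 10% missing > 5%
  dos[5, ] <- dos[4, ]                   # duplicated subject, PI_HAT ~ 1
  geno <- toy_dataset(dos)
  out <- filter_samples(geno, qc_thresholds())
  rem <- out$report$removals
  expect_true("s002" %in% rem$id[rem$stage == "missingness"])
  dup_removed <- rem$id[rem$stage == "relatedness"]
  expect_length(dup_removed, 1)
  expect_true(dup_removed %in% c("s004", "s005"))
  # no unrelated pair is flagged by the relatedness scan
  expect_true(all(rem$id[rem$stage == "relatedness"] %in% c("s004", "s005")))
})

test_that("heterozygosity outliers are flagged by |F|", {
  set.seed(51)
  n <- 60; m <- 2000
  dos <- matrix(rbinom(n * m, 2, 0.3), n, m)
  # subject 1: 80% heterozygous calls vs ~42% expected -> strongly negative F
  dos[1, ] <- ifelse(runif(m) < 0.8, 1, 2 * rbinom(m, 1, 0.3))
  geno <- toy_dataset(dos)
  f <- elgwas:::heterozygosity_f(dos)
  expect_gt(abs(f[1]), 0.1)
  expect_lt(max(abs(f[-1])), 0.1)
  out <- filter_samples(geno, qc_thresholds(), relatedness = FALSE)
  expect_true("s001" %in% out$report$removals$id)
})

test_that("LD pruning removes duplicates, keeps independents, and is idempotent", {
  set.seed(61)
  base <- rbinom(200, 2, 0.3)
  dos <- cbind(base, base, rbinom(200, 2, 0.3), rbinom(200, 2, 0.4))
  geno <- toy_dataset(dos)
  kept <- ld_prune(geno, qc_thresholds())
  expect_length(setdiff(c("v001", "v002"), kept), 1)   # exactly one of the pair
  expect_true(all(c("v003", "v004") %in% kept))
  # mutually independent variants all survive
  g2 <- toy_dataset(random_dosages(400, 10, maf = 0.3, seed = 62))
  expect_equal(ld_prune(g2, qc_thresholds()), g2$variant_meta$id)
  # idempotence and the r^2 invariant
  g3 <- toy_dataset(sapply(1:8, function(j) {
    if (j %% 2 == 0) base else rbinom(200, 2, 0.35)
  }))
  k1 <- ld_prune(g3, qc_thresholds())
  g3p <- subset_genotypes(g3, variants = k1)
  expect_equal(ld_prune(g3p, qc_thresholds()), k1)
  r2 <- suppressWarnings(cor(g3p$dosages))^2
  diag(r2) <- 0
  expect_lt(max(r2), 0.1 + 1e-12)
})

test_that("greedy pruning follows the documented tie-break walkthrough", {
  # a correlation chain v1~v2~v3 with v4, v5 independent; the oracle is an
  # independent re-implementation of the greedy rule on the r^2 matrix
  set.seed(71)
  n <- 500
  v1 <- rbinom(n, 2, 0.25)
  flip <- function(x, p, maf) ifelse(runif(n) < p, rbinom(n, 2, maf), x)
  v2 <- flip(v1, 0.15, 0.25)
  v3 <- flip(v2, 0.15, 0.25)
  v4 <- rbinom(n, 2, 0.45)
  v5 <- rbinom(n, 2, 0.10)
  dos <- cbind(v1, v2, v3, v4, v5)
  geno <- toy_dataset(dos)
  thr <- qc_thresholds()
  kept <- ld_prune(geno, thr)
  maf <- elgwas:::variant_maf(geno)
  r2 <- suppressWarnings(cor(dos))^2; diag(r2) <- 0
  alive <- rep(TRUE, 5)
  repeat {
    r2a <- r2; r2a[!alive, ] <- 0; r2a[, !alive] <- 0
    if (max(r2a) <= thr$prune_r2) break
    pr <- which(r2a == max(r2a), arr.ind = TRUE)[1, ]
    victim <- if (maf[pr[1]] < maf[pr[2]]) pr[1]
      else if (maf[pr[2]] < maf[pr[1]]) pr[2]
      else max(pr)
    alive[victim] <- FALSE
  }
  expect_equal(kept, geno$variant_meta$id[alive])
})
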