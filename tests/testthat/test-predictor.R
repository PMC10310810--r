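# Neural-network PC-score predictor: learnability, determinism, state
# prediction and node-based assessment.

tiny_net <- function(...) {
  net_config(n_hidden_layers = 2L, width = 32L, dropout = 0.1,
             batch_size = 16L, epoch_grid = c(40L, 80L), n_outputs = 2L,
             learning_rate = 3e-3, seed = 3L, ...)
}

test_that("a noiseless linear map is learned to high R-squared", {
  set.seed(31)
  n <- 200; m <- 20
  dos <- random_dosages(n, m, maf = 0.3, seed = 31)
  geno <- toy_dataset(dos)
  W <- matrix(rnorm(m * 2, sd = 0.5), m, 2)
  targets <- scale(dos, scale = FALSE) %*% W
  model <- train_pc_predictor(geno, targets, geno$variant_meta$id, tiny_net())
  pred <- predict_scores(model, geno)
  r2 <- 1 - colSums((pred - targets)^2) / colSums(scale(targets, scale = FALSE)^2)
  expect_true(all(r2 > 0.95))
})

test_that("permuted targets do not generalize (no leakage)", {
  # the net can memorize shuffled targets in-sample, so the null check is
  # out-of-sample: train on one half, score on the other
  set.seed(32)
  n <- 300; m <- 20
  dos <- random_dosages(n, m, maf = 0.3, seed = 32)
  W <- matrix(rnorm(m * 2, sd = 0.5), m, 2)
  targets <- (scale(dos, scale = FALSE) %*% W)[sample(n), ]
  train <- 1:150; test <- 151:300
  geno_tr <- toy_dataset(dos[train, ])
  model <- train_pc_predictor(geno_tr, targets[train, ],
                              geno_tr$variant_meta$id, tiny_net())
  geno_te <- toy_dataset(dos[test, ])
  pred <- predict_scores(model, geno_te)
  r2 <- 1 - colSums((pred - targets[test, ])^2) /
    colSums(scale(targets[test, ], scale = FALSE)^2)
  expect_true(all(r2 < 0.3))
})

test_that("training is deterministic given the seed", {
  dos <- random_dosages(60, 10, seed = 33)
  geno <- toy_dataset(dos)
  targets <- matrix(rnorm(120), 60, 2)
  cfg <- net_config(n_hidden_layers = 1L, width = 8L, dropout = 0.3,
                    batch_size = 16L, epoch_grid = c(5L, 10L),
                    n_outputs = 2L, seed = 9L)
  m1 <- train_pc_predictor(geno, targets, geno$variant_meta$id, cfg)
  m2 <- train_pc_predictor(geno, targets, geno$variant_meta$id, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
})

test_that("prediction enforces variant order and names missing inputs", {
  dos <- random_dosages(50, 8, seed = 34)
  geno <- toy_dataset(dos)
  targets <- matrix(rnorm(100), 50, 2)
  cfg <- net_config(n_hidden_layers = 1L, width = 8L, epoch_grid = c(5L),
                    n_outputs = 2L, seed = 2L)
  model <- train_pc_predictor(geno, targets, geno$variant_meta$id, cfg)
  # same data with the variant columns stored in a different order
  perm <- sample(8)
  shuffled <- genotype_dataset(
    geno$dosages[, perm],
    data.frame(id = geno$variant_meta$id[perm], chrom = "1",
               pos = seq_len(8) * 50, ref = "A", alt = "G",
               stringsAsFactors = FALSE),
    geno$subject_meta)
  expect_equal(predict_scores(model, shuffled), predict_scores(model, geno))
  expect_error(predict_scores(model, subset_genotypes(geno, variants = 1:4)),
               "v005")
})

test_that("network config invariants are enforced", {
  expect_error(net_config(dropout = 1), "dropout")
  expect_error(net_config(epoch_grid = c(100, 100)), "epoch_grid")
  expect_error(net_config(n_hidden_layers = 0), "n_hidden_layers")
})

test_that("states binarize with stored thresholds under the >= rule", {
  dos <- random_dosages(40, 6, seed = 35)
  geno <- toy_dataset(dos)
  targets <- matrix(rnorm(80), 40, 2)
  cfg <- net_config(n_hidden_layers = 1L, width = 8L, epoch_grid = c(5L),
                    n_outputs = 2L, seed = 4L)
  model <- train_pc_predictor(geno, targets, geno$variant_meta$id, cfg)
  model$thresholds <- c(-Inf, Inf)   # force both sides of the rule
  model$n_components <- 2L
  st <- predict_states(model, geno)
  expect_true(all(st[, 1] == 1))     # score >= -Inf
  expect_true(all(st[, 2] == -1))
  model$thresholds <- NULL
  expect_error(predict_states(model, geno), "thresholds")
})

test_that("node accuracy scores color and group agreement", {
  # two-well landscape: basin 1 red group 1, basin 2 green group 2
  m <- manual_model(c(0, 2, 2, 0.5))
  mins <- find_local_minima(m)
  basins <- basin_map(m, mins)
  states <- rbind(c(-1, -1), c(-1, -1), c(1, 1), c(1, 1))
  ph <- c("case", "case", "control", "control")
  ns <- summarize_nodes(mins, basins, c(1L, 2L), states, ph)
  L <- structure(list(model = m, minima = mins, basins = basins,
                      groups = c(1L, 2L), node_summary = ns),
                 class = "energy_landscape")
  # all cases sit in the red basin of group 1, controls in green of group 2
  a <- assess_predictions(L, states, ph, true_groups = c(1L, 1L, 2L, 2L))
  expect_equal(a$accuracy, 1)
  expect_equal(sum(a$by_group$n_correct), a$n_correct)
  # swapped states: every subject lands on the wrong color
  a2 <- assess_predictions(L, states[c(3, 4, 1, 2), ], ph)
  expect_equal(a2$accuracy, 0)
  # gray basins never score
  ns_gray <- ns; ns_gray$color <- "gray"
  Lg <- L; Lg$node_summary <- ns_gray
  expect_equal(assess_predictions(Lg, states, ph)$accuracy, 0)
  # invariance to subject order
  perm <- c(2, 4, 1, 3)
  a3 <- assess_predictions(L, states[perm, ], ph[perm],
                           true_groups = c(1L, 2L, 1L, 2L))
  expect_equal(a3$accuracy, a$accuracy)
})
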