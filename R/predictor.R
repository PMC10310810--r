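# Feed-forward neural network that regresses PC scores on standardized
# genotype dosages, so new subjects can be placed on a fitted landscape
# from genotypes alone. Written as plain matrix code: hidden layers with
# randomized leaky ReLU (RReLU) activation, inverted dropout during
# training, mini-batch Adam on a mean-squared-error loss, checkpointing on
# an epoch grid with the checkpoint of highest discovery-cohort node
# accuracy retained.

#' Network configuration for the PC-score predictor
#'
#' Defaults follow the reference architecture: six hidden layers of 512
#' neurons, RReLU activation, 50% dropout, batch size 32, checkpoints every
#' 100 epochs up to 1500. Reduced widths/grids train in minutes on a CPU at
#' synthetic scale.
#'
#' @param n_hidden_layers hidden layer count (>= 1).
#' @param width neurons per hidden layer.
#' @param dropout dropout fraction in `[0, 1)` (training only).
#' @param batch_size mini-batch size.
#' @param epoch_grid strictly increasing checkpoint epochs.
#' @param n_outputs PC scores predicted (default 7, the landscape N; a
#'   10-output mode is supported — only the first N outputs are binarized).
#' @param learning_rate Adam step size.
#' @param rrelu_range lower/upper of the uniform negative-slope draw
#'   (evaluation uses their mean).
#' @param seed integer seed; training is deterministic given the seed.
#' @return A list of class `net_config`.
#' @export
net_config <- function(n_hidden_layers = 6L, width = 512L, dropout = 0.5,
                       batch_size = 32L,
                       epoch_grid = seq(100L, 1500L, by = 100L),
                       n_outputs = 7L, learning_rate = 1e-3,
                       rrelu_range = c(1 / 8, 1 / 3), seed = 1L) {
  if (n_hidden_layers < 1) stop_field("n_hidden_layers", "must be >= 1")
  if (dropout < 0 || dropout >= 1) stop_field("dropout", "must lie in [0, 1)")
  if (any(diff(epoch_grid) <= 0) || any(epoch_grid < 1))
    stop_field("epoch_grid", "must be strictly increasing positive epochs")
  if (batch_size < 1) stop_field("batch_size", "must be >= 1")
  structure(list(n_hidden_layers = as.integer(n_hidden_layers),
                 width = as.integer(width), dropout = dropout,
                 batch_size = as.integer(batch_size),
                 epoch_grid = as.integer(epoch_grid),
                 n_outputs = as.integer(n_outputs),
                 learning_rate = learning_rate,
                 rrelu_range = rrelu_range, seed = as.integer(seed)),
            class = "net_config")
}

mlp_init <- function(n_in, cfg) {
  sizes <- c(n_in, rep(cfg$width, cfg$n_hidden_layers), cfg$n_outputs)
  lapply(seq_len(length(sizes) - 1L), function(l) {
    list(W = matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                                 sd = sqrt(2 / sizes[l])),
                    sizes[l], sizes[l + 1L]),
         b = numeric(sizes[l + 1L]))
  })
}

# Forward pass. In training mode samples RReLU slopes and dropout masks and
# keeps the caches needed for backprop; in eval mode the activation uses
# the mean slope and dropout is off.
mlp_forward <- function(params, X, cfg, training = FALSE) {
  L <- length(params)
  a <- X
  cache <- vector("list", L)
  slope_eval <- mean(cfg$rrelu_range)
  for (l in seq_len(L)) {
    z <- sweep(a %*% params[[l]]$W, 2, params[[l]]$b, "+")
    if (l < L) {
      if (training) {
        slope <- matrix(stats::runif(length(z), cfg$rrelu_range[1],
                                     cfg$rrelu_range[2]), nrow(z))
        act_grad <- ifelse(z > 0, 1, slope)
        h <- z * act_grad
        if (cfg$dropout > 0) {
          keep <- matrix(stats::runif(length(h)) >= cfg$dropout, nrow(h))
          h <- h * keep / (1 - cfg$dropout)
          act_grad <- act_grad * keep / (1 - cfg$dropout)
        }
      } else {
        act_grad <- NULL
        h <- ifelse(z > 0, z, slope_eval * z)
      }
      cache[[l]] <- list(a_in = a, act_grad = act_grad)
      a <- h
    } else {
      cache[[l]] <- list(a_in = a, act_grad = NULL)
      a <- z
    }
  }
  list(out = a, cache = cache)
}

# Backprop of the MSE loss; returns per-layer gradients.
mlp_backward <- function(params, fw, Y) {
  L <- length(params)
  n <- nrow(Y)
  delta <- 2 * (fw$out - Y) / (n * ncol(Y))
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    ca <- fw$cache[[l]]
    grads[[l]] <- list(W = crossprod(ca$a_in, delta), b = colSums(delta))
    if (l > 1) {
      delta <- (delta %*% t(params[[l]]$W)) * fw$cache[[l - 1L]]$act_grad
    }
  }
  grads
}

adam_init <- function(params) {
  lapply(params, function(p) list(mW = p$W * 0, vW = p$W * 0,
                                  mb = p$b * 0, vb = p$b * 0))
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in seq_along(params)) {
    st <- state[[l]]; g <- grads[[l]]
    st$mW <- beta1 * st$mW + (1 - beta1) * g$W
    st$vW <- beta2 * st$vW + (1 - beta2) * g$W^2
    st$mb <- beta1 * st$mb + (1 - beta1) * g$b
    st$vb <- beta2 * st$vb + (1 - beta2) * g$b^2
    mhW <- st$mW / (1 - beta1^t); vhW <- st$vW / (1 - beta2^t)
    mhb <- st$mb / (1 - beta1^t); vhb <- st$vb / (1 - beta2^t)
    params[[l]]$W <- params[[l]]$W - lr * mhW / (sqrt(vhW) + eps)
    params[[l]]$b <- params[[l]]$b - lr * mhb / (sqrt(vhb) + eps)
    state[[l]] <- st
  }
  list(params = params, state = state)
}

# Standardized, mean-imputed input matrix in the model's variant order.
predictor_inputs <- function(geno, variants, centers = NULL, scales = NULL) {
  ix <- match(variants, geno$variant_meta$id)
  if (anyNA(ix))
    stop("dataset lacks predictor variants: ",
         paste(utils::head(variants[is.na(ix)], 5), collapse = ", "))
  X <- geno$dosages[, ix, drop = FALSE]
  if (is.null(centers)) {
    centers <- colMeans(X, na.rm = TRUE)
    centers[is.nan(centers)] <- 0
  }
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- centers[j]
  if (is.null(scales)) {
    scales <- apply(X, 2, stats::sd)
    scales[scales == 0] <- 1
  }
  X <- sweep(sweep(X, 2, centers), 2, scales, "/")
  list(X = X, centers = centers, scales = scales)
}

#' Train the PC-score predictor network
#'
#' Mean-squared-error regression of PC scores on standardized, mean-imputed
#' genotype dosages of the variants shared between cohorts. Training is
#' mini-batch Adam; at every `epoch_grid` point the network is checkpointed
#' and, when a landscape is supplied, scored by discovery-cohort node
#' accuracy ([assess_predictions()]); the best checkpoint is retained
#' (falling back to lowest training loss without a landscape).
#'
#' @param geno discovery [genotype_dataset()].
#' @param targets subjects x n_outputs matrix of PC scores, row-aligned with
#'   `geno` (e.g. `landscape$encoding$scores`).
#' @param common_variants identifiers of the input variants (those shared
#'   with the validation cohort).
#' @param cfg a [net_config()].
#' @param landscape optional `energy_landscape` used for checkpoint
#'   selection and to copy binarization thresholds.
#' @return A list of class `trained_predictor`: `params`, `cfg`, `variants`,
#'   `centers`, `scales`, `thresholds`, `history` (per-checkpoint loss and
#'   node accuracy), `best_epoch`.
#' @export
train_pc_predictor <- function(geno, targets, common_variants, cfg,
                               landscape = NULL) {
  targets <- as.matrix(targets)
  if (nrow(targets) != nrow(geno$dosages))
    stop("targets are not row-aligned with the dataset subjects")
  if (ncol(targets) != cfg$n_outputs)
    stop(sprintf("targets have %d columns, cfg$n_outputs is %d",
                 ncol(targets), cfg$n_outputs))
  inp <- predictor_inputs(geno, common_variants)
  X <- inp$X
  n <- nrow(X)
  with_seed(cfg$seed, {
    params <- mlp_init(ncol(X), cfg)
    opt <- adam_init(params)
    t <- 0L
    history <- data.frame(epoch = integer(), loss = numeric(),
                          node_accuracy = numeric())
    best <- list(score = -Inf, params = params, epoch = 0L)
    n_epochs <- max(cfg$epoch_grid)
    for (epoch in seq_len(n_epochs)) {
      perm <- sample.int(n)
      for (b0 in seq(1L, n, by = cfg$batch_size)) {
        rows <- perm[b0:min(b0 + cfg$batch_size - 1L, n)]
        fw <- mlp_forward(params, X[rows, , drop = FALSE], cfg,
                          training = TRUE)
        if (!all(is.finite(fw$out))) stop("non-finite loss during training")
        grads <- mlp_backward(params, fw, targets[rows, , drop = FALSE])
        t <- t + 1L
        upd <- adam_step(params, grads, opt, cfg$learning_rate, t)
        params <- upd$params; opt <- upd$state
      }
      if (epoch %in% cfg$epoch_grid) {
        pred <- mlp_forward(params, X, cfg, training = FALSE)$out
        loss <- mean((pred - targets)^2)
        acc <- NA_real_
        score <- -loss
        if (!is.null(landscape)) {
          Nl <- landscape$model$n_components
          states <- apply_thresholds(landscape$encoding,
                                     pred[, seq_len(Nl), drop = FALSE])
          acc <- assess_predictions(landscape, states,
                                    geno$subject_meta$phenotype)$accuracy
          score <- acc
        }
        history <- rbind(history, data.frame(epoch = epoch, loss = loss,
                                             node_accuracy = acc))
        if (score > best$score)
          best <- list(score = score, params = params, epoch = epoch)
      }
    }
    structure(list(params = best$params, cfg = cfg,
                   variants = common_variants,
                   centers = inp$centers, scales = inp$scales,
                   thresholds = if (!is.null(landscape))
                     landscape$encoding$thresholds,
                   n_components = if (!is.null(landscape))
                     landscape$model$n_components else cfg$n_outputs,
                   history = history, best_epoch = best$epoch),
              class = "trained_predictor")
  })
}

#' Predict PC scores for new subjects
#'
#' @param model a `trained_predictor`.
#' @param geno dataset holding the model's input variants (column order is
#'   enforced internally; missing variants are an error naming them).
#' @return Subjects x n_outputs matrix of estimated PC scores.
#' @export
predict_scores <- function(model, geno) {
  inp <- predictor_inputs(geno, model$variants, model$centers, model$scales)
  out <- mlp_forward(model$params, inp$X, model$cfg, training = FALSE)$out
  rownames(out) <- geno$subject_meta$id
  out
}

#' Predict +/-1 states for new subjects
#'
#' Network outputs are thresholded with the landscape's stored per-component
#' binarization thresholds (never re-estimated on new data).
#'
#' @param model a `trained_predictor` trained with a landscape.
#' @param geno dataset holding the model's input variants.
#' @return Subjects x N matrix of +/-1 states.
#' @export
predict_states <- function(model, geno) {
  if (is.null(model$thresholds))
    stop("predictor was trained without a landscape; no stored thresholds")
  sc <- predict_scores(model, geno)
  N <- model$n_components
  st <- ifelse(sweep(sc[, seq_len(N), drop = FALSE], 2,
                     model$thresholds) >= 0, 1, -1)
  rownames(st) <- geno$subject_meta$id
  st
}

#' Node-based accuracy of predicted states
#'
#' Each predicted state descends to its basin; a case counts as correct iff
#' the basin's color is red (cases over-represented) and — when true groups
#' are supplied — the basin's group matches the subject's; a control iff
#' the color is green and the group matches. Gray basins are never correct.
#'
#' @param landscape an `energy_landscape`.
#' @param states subjects x N matrix of +/-1 predicted states.
#' @param phenotype per-subject `"case"`/`"control"`.
#' @param true_groups optional per-subject group labels; when `NULL` only
#'   the color criterion scores.
#' @return A list of class `prediction_assessment`: `n_correct`, `n_total`,
#'   `accuracy`, `by_group` (counts per basin group).
#' @export
assess_predictions <- function(landscape, states, phenotype,
                               true_groups = NULL) {
  if (ncol(states) != landscape$model$n_components)
    stop("state dimension does not match the landscape")
  if (nrow(states) != length(phenotype))
    stop("states and phenotype differ in length")
  basin <- landscape$basins[state_index(states) + 1L]
  color <- landscape$node_summary$color[basin]
  group <- landscape$groups[basin]
  ok_color <- (phenotype == "case" & color == "red") |
    (phenotype == "control" & color == "green")
  ok <- if (is.null(true_groups)) ok_color else
    ok_color & group == true_groups
  by_group <- do.call(rbind, lapply(sort(unique(landscape$groups)),
    function(g) data.frame(group = g, n_correct = sum(ok[group == g]),
                           n_total = sum(group == g))))
  structure(list(n_correct = sum(ok), n_total = length(ok),
                 accuracy = sum(ok) / length(ok), by_group = by_group),
            class = "prediction_assessment")
}

#' @export
print.prediction_assessment <- function(x, ...) {
  cat(sprintf("<prediction_assessment> accuracy %.3f (%d/%d)\n",
              x$accuracy, x$n_correct, x$n_total))
  for (r in seq_len(nrow(x$by_group)))
    cat(sprintf("  group %d: %d/%d = %.3f\n", x$by_group$group[r],
                x$by_group$n_correct[r], x$by_group$n_total[r],
                x$by_group$n_correct[r] / max(1, x$by_group$n_total[r])))
  invisible(x)
}
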