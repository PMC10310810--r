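# Energy-landscape analysis: local minima of the fitted Ising energy,
# steepest-descent basins, the disconnectivity tree of barrier energies,
# and the two-group split at the highest barrier.
#
# Tie-breaking is by state/component index throughout and is fixed by tests:
# on an energy plateau only the lowest state index counts as a minimum, and
# descent prefers the lowest flip index.

# 2^N x N matrix of 0-based neighbor indices (single bit flips).
neighbor_indices <- function(N) {
  k <- 0:(2^N - 1)
  vapply(seq_len(N), function(i) bitwXor(k, bitwShiftL(1L, i - 1L)),
         integer(length(k)))
}

#' Local minima of the energy landscape
#'
#' A state is a local minimum iff its energy is lower than all N single-flip
#' neighbours; on exact ties only the lowest state index of the tied plateau
#' qualifies.
#'
#' @param model a `maxent_model`.
#' @return A data frame: `minimum` (1..M), `index` (0-based state index),
#'   `energy`; the +/-1 vectors are in the `sigma` attribute (M x N).
#' @export
find_local_minima <- function(model) {
  E <- model$energies
  N <- model$n_components
  nb <- neighbor_indices(N)
  is_min <- rep(TRUE, length(E))
  k <- seq_along(E) - 1L
  for (i in seq_len(N)) {
    En <- E[nb[, i] + 1L]
    ok <- (En > E) | (En == E & nb[, i] > k)
    is_min <- is_min & ok
  }
  idx <- which(is_min) - 1L
  out <- data.frame(minimum = seq_along(idx), index = idx,
                    energy = E[idx + 1L])
  attr(out, "sigma") <- state_space(N)[idx + 1L, , drop = FALSE]
  out
}

# Single steepest-descent step; returns the same index at a local minimum.
descend_step <- function(E, nb, k) {
  nbi <- nb[k + 1L, ]
  En <- E[nbi + 1L]
  best <- min(En)
  if (best < E[k + 1L]) return(nbi[which(En == best)[1]])  # lowest flip index
  # plateau: move to an equal-energy neighbour with a lower state index
  tie <- nbi[En == E[k + 1L] & nbi < k]
  if (length(tie)) return(min(tie))
  k
}

#' Steepest-descent basin of a state
#'
#' Repeatedly flips the bit giving the lowest-energy neighbour (ties: lowest
#' component index; plateaus: lowest state index) until a local minimum is
#' reached.
#'
#' @param model a `maxent_model`.
#' @param sigma a +/-1 state vector (or its 0-based index).
#' @param minima optional output of [find_local_minima()] (recomputed if
#'   missing).
#' @return The row number in `minima` of the terminal minimum.
#' @export
descend <- function(model, sigma, minima = find_local_minima(model)) {
  k <- if (length(sigma) == 1 && sigma >= 0 && sigma == round(sigma) &&
           !all(sigma %in% c(-1, 1))) as.integer(sigma) else state_index(sigma)
  nb <- neighbor_indices(model$n_components)
  repeat {
    k2 <- descend_step(model$energies, nb, k)
    if (k2 == k) break
    k <- k2
  }
  m <- match(k, minima$index)
  if (is.na(m)) stop("descent terminated off the minima list")
  m
}

#' Basin assignment for every state
#'
#' @param model a `maxent_model`.
#' @param minima output of [find_local_minima()].
#' @return Integer vector of length 2^N: basin (row in `minima`) of each
#'   state index (position k+1 holds state k).
#' @export
basin_map <- function(model, minima = find_local_minima(model)) {
  E <- model$energies
  N <- model$n_components
  nb <- neighbor_indices(N)
  n <- length(E)
  basin <- integer(n)
  # process states from the bottom of the landscape up: the descent target
  # of a state is always processed earlier
  ord <- order(E, seq_len(n))
  for (k1 in ord) {
    k <- k1 - 1L
    k2 <- descend_step(E, nb, k)
    basin[k1] <- if (k2 == k) match(k, minima$index) else basin[k2 + 1L]
  }
  basin
}

#' Disconnectivity tree over local minima
#'
#' States are inserted in order of increasing energy (ties by index) into a
#' union-find over the single-flip adjacency graph; the first time an
#' insertion connects components holding distinct minima, a merge is
#' recorded at the inserted state's energy. The resulting binary tree has
#' minima as leaves (heights = their energies) and internal nodes at the
#' barrier energies (the min-over-paths of the max energy en route).
#'
#' @param model a `maxent_model`.
#' @param minima output of [find_local_minima()].
#' @return A list of class `disconnectivity_tree`: `merges` (data frame
#'   `node_a`, `node_b`, `height`, `node`; leaves are nodes 1..M, internal
#'   nodes M+1, ...), `leaf_heights`, `n_minima`.
#' @export
build_disconnectivity <- function(model, minima = find_local_minima(model)) {
  E <- model$energies
  N <- model$n_components
  n <- length(E)
  nb <- neighbor_indices(N)
  M <- nrow(minima)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  cluster <- rep(NA_integer_, n)   # tree node carried by each component root
  inserted <- rep(FALSE, n)
  next_node <- M
  merges <- data.frame(node_a = integer(), node_b = integer(),
                       height = numeric(), node = integer())
  ord <- order(E, seq_len(n))
  is_min_at <- rep(NA_integer_, n)
  is_min_at[minima$index + 1L] <- minima$minimum
  for (k1 in ord) {
    k <- k1 - 1L
    inserted[k1] <- TRUE
    if (!is.na(is_min_at[k1])) cluster[find(k1)] <- is_min_at[k1]
    for (i in seq_len(N)) {
      nb1 <- nb[k1, i] + 1L
      if (!inserted[nb1]) next
      ra <- find(k1); rb <- find(nb1)
      if (ra == rb) next
      ca <- cluster[ra]; cb <- cluster[rb]
      parent[ra] <- rb
      r <- find(rb)
      if (!is.na(ca) && !is.na(cb)) {
        next_node <- next_node + 1L
        merges <- rbind(merges,
                        data.frame(node_a = ca, node_b = cb,
                                   height = E[k1], node = next_node))
        cluster[r] <- next_node
      } else {
        cluster[r] <- if (is.na(ca)) cb else ca
      }
    }
  }
  structure(list(merges = merges,
                 leaf_heights = minima$energy,
                 n_minima = M),
            class = "disconnectivity_tree")
}

# Leaves (minimum ids) under a tree node.
leaves_under <- function(tree, node) {
  if (node <= tree$n_minima) return(node)
  row <- tree$merges[tree$merges$node == node, ]
  c(leaves_under(tree, row$node_a), leaves_under(tree, row$node_b))
}

#' Pairwise barrier energies between minima
#'
#' @param tree a `disconnectivity_tree`.
#' @return M x M matrix; entry (i, j) is the height of the lowest internal
#'   node joining minima i and j (diagonal = leaf energies).
#' @export
barrier_matrix <- function(tree) {
  M <- tree$n_minima
  B <- matrix(NA_real_, M, M)
  diag(B) <- tree$leaf_heights
  membership <- lapply(seq_len(M), function(i) i)
  for (r in seq_len(nrow(tree$merges))) {
    mg <- tree$merges[r, ]
    la <- leaves_under(tree, mg$node_a)
    lb <- leaves_under(tree, mg$node_b)
    B[la, lb] <- mg$height
    B[lb, la] <- mg$height
  }
  B
}

#' Split minima into two groups at the highest barrier
#'
#' Cuts the disconnectivity tree at its root; the two subtrees define the
#' groups. Group 1 is the side containing the lower-energy global minimum
#' (ties broken by lower state index via the minima ordering).
#'
#' @param tree a `disconnectivity_tree`.
#' @return Integer vector of length M with entries in `{1, 2}`.
#' @export
split_groups <- function(tree) {
  M <- tree$n_minima
  if (M < 2) stop("cannot split: landscape has a single minimum")
  root <- tree$merges[nrow(tree$merges), ]
  side_a <- leaves_under(tree, root$node_a)
  side_b <- leaves_under(tree, root$node_b)
  global_min <- which.min(tree$leaf_heights)
  groups <- integer(M)
  if (global_min %in% side_a) {
    groups[side_a] <- 1L; groups[side_b] <- 2L
  } else {
    groups[side_a] <- 2L; groups[side_b] <- 1L
  }
  groups
}

#' Case/control summaries per landscape node
#'
#' Each subject is assigned to the basin of its state; per minimum the case
#' and control counts, the frequencies relative to all cases / all controls,
#' their difference, and the display color (red: cases over-represented;
#' green: controls; gray: equal).
#'
#' @param minima output of [find_local_minima()].
#' @param basins length-2^N basin map from [basin_map()].
#' @param groups group labels from [split_groups()] (optional).
#' @param states subjects x N matrix of +/-1.
#' @param phenotype per-subject `"case"`/`"control"`.
#' @return Data frame with one row per minimum.
#' @export
summarize_nodes <- function(minima, basins, groups = NULL, states, phenotype) {
  if (ncol(states) != round(log2(length(basins))))
    stop("state dimension does not match the landscape")
  subj_basin <- basins[state_index(states) + 1L]
  n_case_tot <- sum(phenotype == "case")
  n_ctrl_tot <- sum(phenotype == "control")
  n_case <- vapply(minima$minimum,
                   function(m) sum(subj_basin == m & phenotype == "case"), 0)
  n_ctrl <- vapply(minima$minimum,
                   function(m) sum(subj_basin == m & phenotype == "control"), 0)
  cf <- n_case / n_case_tot
  gf <- n_ctrl / n_ctrl_tot
  fd <- cf - gf
  out <- data.frame(minimum = minima$minimum, index = minima$index,
                    energy = minima$energy,
                    group = if (is.null(groups)) NA_integer_ else groups,
                    n_case = n_case, n_control = n_ctrl,
                    case_frequency = cf, control_frequency = gf,
                    freq_diff = fd,
                    color = ifelse(fd > 0, "red",
                                   ifelse(fd < 0, "green", "gray")))
  out
}

#' Fit the full energy landscape from a genotype dataset
#'
#' Runs the landscape stage end to end: select GWAS signals below
#' `p_threshold`, coefficient-weighted PCA to `n_components` scores,
#' binarize at the per-component score means, fit the pairwise
#' maximum-entropy model to the empirical state distribution, locate local
#' minima, basins and the disconnectivity tree, split at the highest
#' barrier, and summarize case/control occupancy per node.
#'
#' @param geno a QC'd [genotype_dataset()] with phenotypes.
#' @param gwas a `gwas_result` (computed with [logistic_gwas()] if `NULL`).
#' @param p_threshold signal-selection threshold (default 0.01).
#' @param n_components number of binarized components N (default 7).
#' @param lr,tol,max_iter maximum-entropy fit controls (see [fit_maxent()]).
#' @param standardize passed to [weighted_pca()].
#' @return An object of class `energy_landscape`: `encoding`, `model`,
#'   `minima`, `basins`, `tree`, `groups`, `node_summary`, `subjects`
#'   (per-subject state index, basin, group, phenotype) and `gwas`.
#' @export
fit_landscape <- function(geno, gwas = NULL, p_threshold = 0.01,
                          n_components = 7L, lr = 0.1, tol = 1e-6,
                          max_iter = 1e5, standardize = TRUE) {
  if (is.null(gwas)) gwas <- logistic_gwas(geno)
  sig <- select_signals(gwas, p_threshold)
  enc <- weighted_pca(geno, sig$variants, sig$weights,
                      n_components = n_components, standardize = standardize)
  enc <- binarize_scores(enc)
  p_emp <- empirical_distribution(enc$states)
  model <- fit_maxent(p_emp, lr = lr, tol = tol, max_iter = max_iter)
  minima <- find_local_minima(model)
  basins <- basin_map(model, minima)
  tree <- build_disconnectivity(model, minima)
  groups <- if (nrow(minima) >= 2) split_groups(tree) else
    rep(1L, nrow(minima))
  phenotype <- geno$subject_meta$phenotype
  node_summary <- summarize_nodes(minima, basins, groups, enc$states,
                                  phenotype)
  sidx <- state_index(enc$states)
  subjects <- data.frame(id = geno$subject_meta$id,
                         state_index = sidx,
                         basin = basins[sidx + 1L],
                         group = groups[basins[sidx + 1L]],
                         phenotype = phenotype,
                         stringsAsFactors = FALSE)
  structure(list(encoding = enc, model = model, minima = minima,
                 basins = basins, tree = tree, groups = groups,
                 node_summary = node_summary, subjects = subjects,
                 gwas = gwas, p_threshold = p_threshold),
            class = "energy_landscape")
}

#' Map subjects onto a fitted landscape
#'
#' Binarizes states (given directly or via PCA projection of a dataset with
#' the stored thresholds) and assigns basin and group.
#'
#' @param landscape an `energy_landscape`.
#' @param states subjects x N matrix of +/-1, or `NULL` to project `geno`.
#' @param geno dataset to project when `states` is `NULL`.
#' @return Data frame `id`, `state_index`, `basin`, `group`.
#' @export
assign_subjects <- function(landscape, states = NULL, geno = NULL) {
  if (is.null(states)) {
    if (is.null(geno)) stop("provide states or a dataset to project")
    sc <- project_scores(landscape$encoding, geno)
    states <- apply_thresholds(landscape$encoding, sc)
  }
  sidx <- state_index(states)
  basin <- landscape$basins[sidx + 1L]
  data.frame(id = rownames(states) %||% seq_len(nrow(states)),
             state_index = sidx, basin = basin,
             group = landscape$groups[basin], stringsAsFactors = FALSE)
}

#' @export
print.energy_landscape <- function(x, ...) {
  cat(sprintf("<energy_landscape> N = %d components, %d signals, %d minima, %d groups\n",
              x$model$n_components, length(x$encoding$variants),
              nrow(x$minima), length(unique(x$groups))))
  print(x$node_summary[, c("minimum", "energy", "group", "n_case",
                           "n_control", "freq_diff", "color")],
        row.names = FALSE, digits = 3)
  invisible(x)
}
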