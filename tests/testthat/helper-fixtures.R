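# Shared fixture builders; everything is generated in code at test time.

# Small fully-typed dataset with known dosages.
toy_dataset <- function(dosages, phenotype = NULL, age = NULL, sex = NULL) {
  n <- nrow(dosages)
  m <- ncol(dosages)
  genotype_dataset(
    dosages,
    data.frame(id = sprintf("v%03d", seq_len(m)), chrom = "1",
               pos = seq_len(m) * 100, ref = "A", alt = "G",
               stringsAsFactors = FALSE),
    data.frame(id = sprintf("s%03d", seq_len(n)),
               phenotype = phenotype %||% rep(NA_character_, n),
               age = age %||% rep(NA_real_, n),
               sex = sex %||% rep(NA_character_, n),
               stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random complete dosage matrix under Hardy-Weinberg.
random_dosages <- function(n, m, maf = 0.3, seed = 1) {
  withr::with_seed(seed, matrix(rbinom(n * m, 2, maf), n, m))
}

# A maxent_model with prescribed energies (bypassing the fit), for
# landscape-topology tests.
manual_model <- function(energies) {
  N <- as.integer(round(log2(length(energies))))
  structure(list(h = numeric(N), J = matrix(0, N, N), energies = energies,
                 logZ = elgwas:::logsumexp(-energies), n_components = N,
                 n_iter = 0L, max_gap = 0),
            class = "maxent_model")
}

# Independent brute-force minima oracle: plain loop over all states,
# checking every neighbour explicitly (same tie rule, independent code).
brute_minima <- function(energies) {
  N <- as.integer(round(log2(length(energies))))
  idx <- integer()
  for (k in 0:(length(energies) - 1)) {
    ok <- TRUE
    for (i in seq_len(N)) {
      nb <- bitwXor(k, bitwShiftL(1L, i - 1L))
      En <- energies[nb + 1]; Ek <- energies[k + 1]
      if (En < Ek || (En == Ek && nb < k)) { ok <- FALSE; break }
    }
    if (ok) idx <- c(idx, k)
  }
  idx
}

# Independent minimax-path barrier oracle via igraph: barrier(u, v) is the
# max node energy along the path minimizing that max; on a graph with edge
# weight max(E_u, E_v) this equals the largest edge on the minimum spanning
# tree path.
brute_barriers <- function(energies, minima_idx) {
  N <- as.integer(round(log2(length(energies))))
  n <- length(energies)
  edges <- NULL
  w <- NULL
  for (k in 0:(n - 1)) for (i in seq_len(N)) {
    nb <- bitwXor(k, bitwShiftL(1L, i - 1L))
    if (nb > k) {
      edges <- rbind(edges, c(k + 1, nb + 1))
      w <- c(w, max(energies[k + 1], energies[nb + 1]))
    }
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- w
  mst <- igraph::mst(g)
  M <- length(minima_idx)
  B <- matrix(NA_real_, M, M)
  for (a in seq_len(M)) for (b in seq_len(M)) {
    if (a == b) { B[a, b] <- energies[minima_idx[a] + 1]; next }
    p <- igraph::shortest_paths(mst, from = minima_idx[a] + 1,
                                to = minima_idx[b] + 1, weights = NA,
                                output = "epath")
    B[a, b] <- max(igraph::E(mst)$weight[p$epath[[1]]])
  }
  B
}

# Independent brute-force steepest-descent oracle (loop form).
brute_descend <- function(energies, k) {
  N <- as.integer(round(log2(length(energies))))
  repeat {
    nbs <- vapply(seq_len(N), function(i) bitwXor(k, bitwShiftL(1L, i - 1L)),
                  integer(1))
    En <- energies[nbs + 1]
    if (min(En) < energies[k + 1]) {
      k <- nbs[which.min(En)]
    } else {
      tie <- nbs[En == energies[k + 1] & nbs < k]
      if (!length(tie)) return(k)
      k <- min(tie)
    }
  }
}
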