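# Pairwise maximum-entropy (Ising / Boltzmann) model over +/-1 state
# vectors, fitted by gradient ascent on the exact log-likelihood with full
# enumeration of the 2^N states (feasible for the N <= 20 this analysis
# uses; the default landscape has N = 7).
#
# Conventions: component i of a state is bit i-1 of its index (component 1
# = least significant bit); bit set <=> sigma = +1. Energy
# E(V) = -sum_i h_i sigma_i - sum_{i<j} J_ij sigma_i sigma_j, so lower
# energy means higher Boltzmann probability.

#' Enumerate the +/-1 state space
#'
#' @param n_components N.
#' @return 2^N x N matrix; row k+1 is the state with index k.
#' @export
state_space <- function(n_components) {
  stopifnot(n_components >= 1, n_components <= 20)
  k <- 0:(2^n_components - 1)
  vapply(seq_len(n_components),
         function(i) ifelse(bitwAnd(k, bitwShiftL(1L, i - 1L)) > 0, 1, -1),
         numeric(length(k)))
}

#' State index of a +/-1 vector
#'
#' @param sigma +/-1 vector, or a matrix of such rows.
#' @return Integer index/indices in `[0, 2^N)`.
#' @export
state_index <- function(sigma) {
  if (is.matrix(sigma))
    return(as.integer(round(((sigma + 1) / 2) %*% 2^(seq_len(ncol(sigma)) - 1))))
  as.integer(sum(((sigma + 1) / 2) * 2^(seq_along(sigma) - 1)))
}

# Columns sigma_i * sigma_j for i < j, aligned with J's upper triangle.
pair_products <- function(S) {
  N <- ncol(S)
  if (N < 2) return(matrix(0, nrow(S), 0))
  pairs <- which(upper.tri(diag(N)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 2], pairs[, 1]), , drop = FALSE]
  S[, pairs[, 1], drop = FALSE] * S[, pairs[, 2], drop = FALSE]
}

upper_to_matrix <- function(jvec, N) {
  J <- matrix(0, N, N)
  J[upper.tri(J)] <- jvec
  J + t(J)
}

#' Empirical state distribution
#'
#' Relative frequency of each state index over subjects.
#'
#' @param states subjects x N matrix of +/-1.
#' @return Probability vector of length 2^N (sums to 1).
#' @export
empirical_distribution <- function(states) {
  stopifnot(is.matrix(states), nrow(states) >= 1)
  N <- ncol(states)
  idx <- state_index(states)
  tabulate(idx + 1L, nbins = 2^N) / nrow(states)
}

#' Fit the pairwise maximum-entropy model
#'
#' Gradient ascent on the exact log-likelihood: at each step the fields move
#' by `lr` times the gap between empirical and model first moments, the
#' couplings by the gap between second moments; convergence when every gap
#' is below `tol`. Empirical moments exactly at +/-1 (a component constant
#' in the data) are shrunk by 1e-6 toward 0 so finite parameters exist.
#'
#' @param p_emp probability vector over the 2^N states (sums to 1).
#' @param lr gradient step size (default 0.1).
#' @param tol moment-matching tolerance (default 1e-6).
#' @param max_iter iteration cap; exceeding it is an error that carries the
#'   final moment gap.
#' @return A list of class `maxent_model`: `h` (length N), `J` (N x N
#'   symmetric, zero diagonal), `energies` (length 2^N), `logZ`,
#'   `n_components`, `n_iter`, `max_gap`.
#' @export
fit_maxent <- function(p_emp, lr = 0.1, tol = 1e-6, max_iter = 1e5) {
  N <- as.integer(round(log2(length(p_emp))))
  if (2^N != length(p_emp)) stop("p_emp length must be a power of 2")
  if (N > 20) stop("N > 20 exceeds exact enumeration")
  if (abs(sum(p_emp) - 1) > 1e-8 || any(p_emp < 0))
    stop("p_emp must be a probability vector")
  S <- state_space(N)
  SP <- pair_products(S)
  m1_emp <- as.vector(crossprod(S, p_emp))
  m2_emp <- as.vector(crossprod(SP, p_emp))
  clamp <- function(m) sign(m) * pmin(abs(m), 1 - 1e-6)
  m1_emp <- clamp(m1_emp); m2_emp <- clamp(m2_emp)
  h <- numeric(N)
  jvec <- numeric(ncol(SP))
  gap <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    logp <- S %*% h + if (ncol(SP)) SP %*% jvec else 0
    logp <- logp - logsumexp(logp)
    p <- exp(logp)
    g1 <- m1_emp - as.vector(crossprod(S, p))
    g2 <- m2_emp - as.vector(crossprod(SP, p))
    gap <- max(abs(c(g1, g2)))
    if (gap < tol) break
    h <- h + lr * g1
    jvec <- jvec + lr * g2
  }
  if (gap >= tol) {
    e <- simpleError(sprintf(
      "maximum-entropy fit did not converge in %g iterations (moment gap %.3g)",
      max_iter, gap))
    e$max_gap <- gap
    stop(e)
  }
  J <- upper_to_matrix(jvec, N)
  energies <- as.vector(-(S %*% h) - (if (ncol(SP)) SP %*% jvec else 0))
  structure(list(h = h, J = J, energies = energies,
                 logZ = logsumexp(-energies), n_components = N,
                 n_iter = it, max_gap = gap),
            class = "maxent_model")
}

#' Energy of a state
#'
#' `E(V) = -sum_i h_i sigma_i - sum_{i<j} J_ij sigma_i sigma_j`.
#'
#' @param model a `maxent_model`.
#' @param sigma +/-1 vector of length N.
#' @return The energy.
#' @export
state_energy <- function(model, sigma) {
  if (length(sigma) != model$n_components)
    stop(sprintf("state has %d components, model expects %d",
                 length(sigma), model$n_components))
  -sum(model$h * sigma) - sum(model$J[upper.tri(model$J)] *
                                pair_products(matrix(sigma, 1)))
}

#' Boltzmann probabilities of a model
#'
#' @param model a `maxent_model`.
#' @return Length-2^N probability vector `exp(-E - logZ)`.
#' @export
boltzmann_probabilities <- function(model) {
  exp(-model$energies - model$logZ)
}

#' Sample states from a maximum-entropy model
#'
#' Exact sampling by enumeration of the Boltzmann distribution.
#'
#' @param model a `maxent_model`.
#' @param n number of draws.
#' @param seed integer seed.
#' @return n x N matrix of +/-1 states.
#' @export
sample_states <- function(model, n, seed = 1L) {
  S <- state_space(model$n_components)
  p <- boltzmann_probabilities(model)
  with_seed(seed, {
    S[sample.int(nrow(S), n, replace = TRUE, prob = p), , drop = FALSE]
  })
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("<maxent_model> N = %d, fitted in %d iterations (gap %.2g)\n",
              x$n_components, x$n_iter, x$max_gap))
  invisible(x)
}
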