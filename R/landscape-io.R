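# Landscape serialization (JSON) and the 2-D disconnectivity plot.

#' Serialize a fitted landscape to JSON
#'
#' Stores fields, couplings, minima, merge tree, groups, node summaries and
#' the PCA encoding (loadings, standardization constants, thresholds) —
#' enough to re-map new subjects without refitting.
#'
#' @param landscape an `energy_landscape`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_landscape_json <- function(landscape, path) {
  enc <- landscape$encoding
  payload <- list(
    n_components = landscape$model$n_components,
    h = landscape$model$h,
    J = landscape$model$J,
    logZ = landscape$model$logZ,
    minima = landscape$minima,
    merges = landscape$tree$merges,
    groups = landscape$groups,
    node_summary = landscape$node_summary,
    p_threshold = landscape$p_threshold,
    encoding = list(variants = enc$variants, weights = enc$weights,
                    column_means = enc$column_means,
                    column_sds = enc$column_sds,
                    standardize = enc$standardize,
                    loadings = enc$loadings,
                    thresholds = enc$thresholds))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a landscape serialized by [write_landscape_json()]
#'
#' Energies, the basin map and Boltzmann normalization are reconstructed
#' from the stored fields and couplings.
#'
#' @param path JSON file.
#' @return An `energy_landscape` (without the per-subject table and GWAS of
#'   the original fit).
#' @export
read_landscape_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  N <- x$n_components
  S <- state_space(N)
  SP <- pair_products(S)
  J <- matrix(unlist(x$J), N, N)
  jvec <- J[upper.tri(J)]
  energies <- as.vector(-(S %*% x$h) - (if (ncol(SP)) SP %*% jvec else 0))
  model <- structure(list(h = x$h, J = J, energies = energies,
                          logZ = logsumexp(-energies), n_components = N,
                          n_iter = NA_integer_, max_gap = NA_real_),
                     class = "maxent_model")
  enc <- x$encoding
  enc$loadings <- matrix(unlist(x$encoding$loadings),
                         ncol = N, dimnames = list(x$encoding$variants, NULL))
  class(enc) <- "pca_encoding"
  minima <- as.data.frame(x$minima)
  tree <- structure(list(merges = as.data.frame(x$merges),
                         leaf_heights = minima$energy,
                         n_minima = nrow(minima)),
                    class = "disconnectivity_tree")
  structure(list(encoding = enc, model = model, minima = minima,
                 basins = basin_map(model, minima), tree = tree,
                 groups = x$groups,
                 node_summary = as.data.frame(x$node_summary),
                 subjects = NULL, gwas = NULL,
                 p_threshold = x$p_threshold),
            class = "energy_landscape")
}

# x position of each leaf/internal node for plotting: leaves evenly spaced
# in tree order, internal nodes at the midpoint of their children.
tree_layout <- function(tree) {
  M <- tree$n_minima
  if (nrow(tree$merges) == 0) {
    return(list(x = stats::setNames(1, 1), order = 1))
  }
  root <- tree$merges$node[nrow(tree$merges)]
  leaf_order <- leaves_under(tree, root)
  xs <- numeric(M + nrow(tree$merges))
  xs[leaf_order] <- seq_along(leaf_order)
  for (r in seq_len(nrow(tree$merges))) {
    mg <- tree$merges[r, ]
    xs[mg$node] <- mean(c(xs[mg$node_a], xs[mg$node_b]))
  }
  list(x = xs, order = leaf_order)
}

#' 2-D disconnectivity plot
#'
#' Vertical axis is energy; leaves are local minima drawn as circles whose
#' area scales with |case frequency - control frequency| and whose color is
#' red (cases over-represented), green (controls) or gray (equal); internal
#' joins are drawn at their barrier energies.
#'
#' @param landscape an `energy_landscape`.
#' @param cex_max circle size for the largest |frequency difference|.
#' @param ... passed to [graphics::plot()].
#' @return The landscape, invisibly.
#' @export
plot_disconnectivity <- function(landscape, cex_max = 4, ...) {
  tree <- landscape$tree
  ns <- landscape$node_summary
  lay <- tree_layout(tree)
  heights <- c(tree$leaf_heights, tree$merges$height)
  graphics::plot(NA, xlim = range(lay$x[seq_len(tree$n_minima)]) + c(-0.5, 0.5),
                 ylim = range(heights) + c(-0.1, 0.1) * diff(range(heights)),
                 xlab = "", ylab = "energy", xaxt = "n", ...)
  node_h <- c(tree$leaf_heights,
              if (nrow(tree$merges)) tree$merges$height)
  for (r in seq_len(nrow(tree$merges))) {
    mg <- tree$merges[r, ]
    for (child in c(mg$node_a, mg$node_b)) {
      graphics::segments(lay$x[child], node_h[child], lay$x[child], mg$height)
    }
    graphics::segments(lay$x[mg$node_a], mg$height, lay$x[mg$node_b],
                       mg$height)
  }
  sz <- if (all(ns$freq_diff == 0)) rep(0.5, nrow(ns)) else
    0.5 + (cex_max - 0.5) * sqrt(abs(ns$freq_diff) / max(abs(ns$freq_diff)))
  cols <- c(red = "#d62728", green = "#2ca02c", gray = "grey60")[ns$color]
  graphics::points(lay$x[ns$minimum], ns$energy, pch = 21, bg = cols,
                   cex = sz)
  invisible(landscape)
}
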