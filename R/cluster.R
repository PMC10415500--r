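#' Wasserstein neighborhood graph of a pattern collection
#'
#' Connects two patterns whenever the squared Wasserstein distance between
#' their resistance distance histograms is at most `tau` (default 0.05, in
#' squared bins) and returns the connected components: clusters of
#' qualitatively similar patterns.
#'
#' @param H matrix of histograms, one per row (rows of equal bin count).
#' @param tau adjacency threshold on the squared distance.
#' @return list with `membership` (component id per pattern), `sizes`
#'   (component sizes, descending), `n_components` and the dense `d2`
#'   distance matrix.
#' @export
neighborhood_graph <- function(H, tau = 0.05) {
  H <- as.matrix(H)
  n <- nrow(H)
  d2 <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i) d2[i, j] <- d2[j, i] <- wasserstein_sq(H[i, ], H[j, ])
    }
  }
  adj <- d2 <= tau
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  list(membership = comp$membership,
       sizes = sort(comp$csize, decreasing = TRUE),
       n_components = comp$no, d2 = d2)
}

#' Cluster-coverage report
#'
#' @param graph result of [neighborhood_graph()] (or any list with a
#'   `membership` vector).
#' @param k number of largest components to aggregate.
#' @return list with `sizes` (descending), `fraction_in_top_k` and `k`.
#' @examples
#' g <- list(membership = c(1, 1, 1, 2, 2, 3))
#' cluster_report(g, k = 2)$fraction_in_top_k  # 5/6
#' @export
cluster_report <- function(graph, k = 6) {
  stopifnot(k >= 1)
  sizes <- sort(tabulate(graph$membership), decreasing = TRUE)
  top <- sum(sizes[seq_len(min(k, length(sizes)))])
  list(sizes = sizes, fraction_in_top_k = top / sum(sizes), k = k)
}
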