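#' Weighted pattern graph of a single-species field
#'
#' Thresholds the field at its mean and assigns every torus edge weight 1
#' when both endpoints lie on the same side of the mean (both `>=` or both
#' `<`) and a small weight `eps_w` when the edge crosses the mean.  Paths
#' that stay inside a high- or low-concentration region are thus cheap
#' while crossings are penalised, so effective resistances encode the
#' nonlocal geometry of the pattern.
#'
#' @param field numeric `n_r x n_r` matrix (species-1 concentrations).
#' @param eps_w crossing-edge weight, `0 < eps_w << 1` (default 0.003).
#' @return object of class `pattern_graph` with per-edge weight matrices
#'   `w_right` (edge to the cyclic right neighbour) and `w_down` (cyclic
#'   down), the grid side `n_r` and the threshold `u_bar`.
#' @examples
#' g <- pattern_graph(matrix(c(2, 2, 0, 0), 2, 4))
#' table(c(g$w_right, g$w_down))
#' @export
pattern_graph <- function(field, eps_w = 0.003) {
  stopifnot(is.matrix(field), all(is.finite(field)), nrow(field) >= 4,
            nrow(field) == ncol(field), eps_w > 0)
  n <- nrow(field)
  high <- field >= mean(field)
  right <- high[, c(2:n, 1)]
  down <- high[c(2:n, 1), ]
  w_right <- ifelse(high == right, 1, eps_w)
  w_down <- ifelse(high == down, 1, eps_w)
  structure(list(n_r = n, w_right = w_right, w_down = w_down,
                 eps_w = eps_w, u_bar = mean(field)),
            class = "pattern_graph")
}

# sparse graph Laplacian of a pattern graph (column-major node ids)
pattern_laplacian <- function(g) {
  n <- g$n_r; m <- n * n
  idx <- matrix(seq_len(m), n, n)
  right <- idx[, c(2:n, 1)]
  down <- idx[c(2:n, 1), ]
  ii <- c(idx, idx); jj <- c(right, down); ww <- c(g$w_right, g$w_down)
  A <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(ww, ww),
                            dims = c(m, m))
  Matrix::Diagonal(m, Matrix::rowSums(A)) - A
}

#' Effective-resistance matrix of a weighted connected graph
#'
#' Computes the Gram matrix `K = (J_m + L_G)^{-1}` (with `J_m` the all-ones
#' matrix and `L_G` the weighted graph Laplacian) and from it the
#' resistance distances `R_vv' = K_vv + K_v'v' - 2 K_vv'`, identical to the
#' classical Laplacian-pseudoinverse construction.  Pattern graphs use a
#' grounded-node Cholesky factorisation instead of the dense `J_m + L_G`
#' solve; the two routes agree to numerical precision.
#'
#' @param graph either a symmetric nonnegative adjacency matrix (dense or
#'   sparse, zero diagonal) or a [pattern_graph()].
#' @return symmetric `m x m` matrix of resistance distances with zero
#'   diagonal (class `resistance_data`, a plain matrix with an attribute
#'   recording the construction).
#' @examples
#' A <- matrix(1, 3, 3) - diag(3)          # unit triangle
#' resistance_matrix(A)[1, 2]               # 2/3 by series-parallel reduction
#' @export
resistance_matrix <- function(graph) {
  if (inherits(graph, "pattern_graph")) {
    # ground node 1: inv(M) gives resistances among nodes 2..m and to node 1
    Minv <- grounded_inverse(graph)
    d <- c(0, diag(Minv))
    K <- rbind(0, cbind(0, Minv))
    # R[v, v'] = d_v + d_v' - 2 K_vv', assembled by two vectorised passes
    R <- -2 * K + d
    R <- t(R) + d
  } else {
    A <- as.matrix(graph)
    stopifnot(isSymmetric(A, tol = 1e-12), all(A >= 0))
    m <- nrow(A)
    if (!igraph::is_connected(igraph::graph_from_adjacency_matrix(
      A > 0, mode = "undirected")))
      stop("graph is disconnected; resistance distances are undefined")
    L <- diag(rowSums(A)) - A
    K <- solve(matrix(1, m, m) + L)
    dK <- diag(K)
    R <- outer(dK, dK, "+") - 2 * K
  }
  diag(R) <- 0
  structure((R + t(R)) / 2, class = c("resistance_data", "matrix"),
            construction = if (inherits(graph, "pattern_graph")) "grounded" else "gram")
}

# toroidal minimal-image offsets (di, dj) with Euclidean length <= r,
# excluding (0, 0); returned as an integer matrix of 0-based shifts
radius_offsets <- function(n_r, r) {
  d <- 0:(n_r - 1)
  md <- pmin(d, n_r - d)              # minimal-image magnitude per shift
  keep <- which(outer(md^2, md^2, "+") <= r^2, arr.ind = TRUE)
  keep <- keep[!(keep[, 1] == 1 & keep[, 2] == 1), , drop = FALSE]
  cbind(di = keep[, 1] - 1L, dj = keep[, 2] - 1L)
}

#' Collect resistance values within a spatial radius
#'
#' Gathers `R_vv'` for every source node `v` in the undersampled node set
#' (every `t`-th row and column) and every node `v'` within toroidal
#' Euclidean distance `r` of `v` (excluding `v` itself).  These multisets
#' are the raw material of resistance distance histograms and of the
#' `R_max` calibration.
#'
#' @param res a `resistance_data` matrix from [resistance_matrix()].
#' @param grid a [grid_spec()] matching the matrix.
#' @param r radius in grid units.
#' @param t undersampling factor (1 keeps every node).
#' @return numeric vector of resistance values.
#' @export
collect_resistances <- function(res, grid, r, t = 1) {
  n <- grid$n_r
  stopifnot(nrow(res) == n * n, r > 0, t >= 1)
  offs <- radius_offsets(n, r)
  src_rc <- as.matrix(expand.grid(i = seq(1, n, by = t), j = seq(1, n, by = t)))
  src <- src_rc[, 1] + (src_rc[, 2] - 1) * n
  vals <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    ti <- (src_rc[, 1] - 1 + offs[k, 1]) %% n + 1
    tj <- (src_rc[, 2] - 1 + offs[k, 2]) %% n + 1
    vals[[k]] <- res[cbind(src, ti + (tj - 1) * n)]
  }
  unlist(vals, use.names = FALSE)
}

#' Resistance distance histogram (RDH)
#'
#' Normalised `B`-bin histogram of the resistance values collected within
#' radius `r` (see [collect_resistances()]), binned uniformly on
#' `[0, R_max]` with half-open bins (last bin closed); values above `R_max`
#' are dropped before normalisation.  The result is a point in the
#' probability simplex and is exactly invariant under cyclic shifts,
#' transposition and quarter-turn rotations of the underlying field.
#'
#' @inheritParams collect_resistances
#' @param B number of bins (default 12).
#' @param R_max upper histogram edge; calibrate across a batch of patterns
#'   with [calibrate_rmax()].
#' @return object of class `rdh`: list with `hist` (length-`B`, sums to 1),
#'   `r`, `t`, `B`, `R_max` and the number of retained values `n_values`.
#' @export
rdh <- function(res, grid, r, t = 1, B = 12, R_max) {
  stopifnot(B >= 1, R_max > 0)
  vals <- collect_resistances(res, grid, r, t)
  rdh_from_values(vals, r = r, t = t, B = B, R_max = R_max)
}

#' @rdname rdh
#' @param values precomputed resistance value multiset (alternative entry
#'   point used by the two-pass batch featurisation).
#' @export
rdh_from_values <- function(values, r, t = 1, B = 12, R_max) {
  keep <- values[values <= R_max]
  if (length(keep) == 0)
    stop("all resistance values exceed R_max; the histogram edge is miscalibrated")
  bin <- pmin(floor(keep / (R_max / B)) + 1, B)  # half-open bins, last closed
  h <- tabulate(bin, nbins = B)
  structure(list(hist = h / sum(h), r = r, t = t, B = B, R_max = R_max,
                 n_values = length(keep)),
            class = "rdh")
}

#' Calibrate the histogram edge across a batch of patterns
#'
#' For each pattern's multiset of collected resistance values the 99%
#' quantile is taken, and the maximum of these quantiles over the batch is
#' returned.  Rare very large resistances (typically numerical artefacts of
#' the PDE solve) are thereby excluded from the histogram support without
#' discarding the bulk of any pattern's values.
#'
#' @param value_sets list of numeric vectors, one multiset per pattern.
#' @param prob quantile level (default 0.99).
#' @return scalar `R_max`.
#' @export
calibrate_rmax <- function(value_sets, prob = 0.99) {
  if (length(value_sets) == 0) stop("no patterns supplied")
  max(vapply(value_sets, stats::quantile, numeric(1),
             probs = prob, names = FALSE))
}

#' Maximal plateau concentration of a pattern
#'
#' Bins the field's values into 25 equal-width bins over `[min, max]`; a
#' peak is a bin whose count is a local maximum and holds at least 1% of
#' the pixels (which discards isolated numerical outliers).  Returns the
#' centre of the right-most peak bin, i.e. the concentration level of the
#' highest plateau.  Constant fields return their value.
#'
#' @param field numeric matrix of concentrations.
#' @param bins number of histogram bins.
#' @param peak_floor minimum pixel fraction for a bin to qualify as a peak.
#' @return scalar concentration `c_m`.
#' @export
max_concentration <- function(field, bins = 25, peak_floor = 0.01) {
  v <- as.vector(field)
  stopifnot(all(is.finite(v)))
  lo <- min(v); hi <- max(v)
  if (hi == lo) return(lo)
  w <- (hi - lo) / bins
  counts <- tabulate(pmin(floor((v - lo) / w) + 1, bins), nbins = bins)
  padded <- c(-1, counts, -1)
  local_max <- counts >= padded[seq_len(bins)] & counts >= padded[seq_len(bins) + 2]
  peak <- local_max & counts >= peak_floor * length(v)
  if (!any(peak)) peak <- local_max & counts == max(counts)
  i <- max(which(peak))
  lo + (i - 0.5) * w
}

#' Number of high-concentration connected components
#'
#' Keeps only the nodes with concentration at or above the field mean and
#' the torus edges between two such nodes, and counts the connected
#' components of that subgraph.  Together with the maximal concentration
#' this breaks the range-reflection symmetry of resistance distance
#' histograms (inverting a pattern about its mean leaves the RDH unchanged
#' but swaps spots for holes).
#'
#' @param field numeric `n_r x n_r` matrix.
#' @return integer count `n_c` (0 if no node reaches the mean, which can
#'   only happen for empty tie-breaking corner cases).
#' @export
connected_components_feature <- function(field) {
  n <- nrow(field)
  high <- field >= mean(field)
  m <- sum(high)
  if (m == 0) return(0L)
  id <- matrix(0L, n, n)
  id[high] <- seq_len(m)
  right <- cbind(as.vector(id), as.vector(id[, c(2:n, 1)]))
  down <- cbind(as.vector(id), as.vector(id[c(2:n, 1), ]))
  e <- rbind(right, down)
  e <- e[e[, 1] > 0 & e[, 2] > 0, , drop = FALSE]
  g <- igraph::make_empty_graph(n = m, directed = FALSE)
  if (nrow(e) > 0) g <- igraph::add_edges(g, t(e))
  igraph::components(g)$no
}

# grounded inverse of the pattern-graph Laplacian (node 1 removed),
# solved per 1024-column chunk through the supernodal CHOLMOD factor
grounded_inverse <- function(g) {
  L <- pattern_laplacian(g)
  m <- nrow(L)
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(L[-1, -1]),
                         LDL = FALSE, super = TRUE)
  Minv <- matrix(0, m - 1, m - 1)
  chunk <- 512L
  for (s in seq(1L, m - 1L, by = chunk)) {
    e <- min(s + chunk - 1L, m - 1L)
    B <- matrix(0, m - 1L, e - s + 1L)
    B[cbind(s:e, seq_len(e - s + 1L))] <- 1
    Minv[, s:e] <- as.matrix(Matrix::solve(ch, B))
  }
  Minv
}

# resistance multiset of a pattern graph without assembling the full m x m
# resistance matrix (or even the full grounded inverse): inverse columns are
# produced 512 at a time through the sparse Cholesky factor and the entries
# needed for R_vv' = d_v + d_v' - 2 K_vv' (row/column 1 of K is zero) are
# gathered immediately, so no allocation exceeds a few tens of megabytes
pattern_resistance_values <- function(g, r, t = 1) {
  n <- g$n_r; m <- n * n
  L <- pattern_laplacian(g)
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(L[-1, -1]),
                         LDL = FALSE, super = TRUE)
  offs <- radius_offsets(n, r)
  noff <- nrow(offs)
  src_rc <- as.matrix(expand.grid(i = seq(1, n, by = t), j = seq(1, n, by = t)))
  src <- src_rc[, 1] + (src_rc[, 2] - 1) * n
  S <- length(src)
  TGT <- matrix(0L, S, noff)
  for (k in seq_len(noff)) {
    ti <- (src_rc[, 1] - 1 + offs[k, 1]) %% n + 1
    tj <- (src_rc[, 2] - 1 + offs[k, 2]) %% n + 1
    TGT[, k] <- as.integer(ti + (tj - 1) * n)
  }
  kv <- matrix(0, S, noff)
  dvec <- numeric(m)
  chunk <- 512L
  for (s in seq(1L, m - 1L, by = chunk)) {
    e <- min(s + chunk - 1L, m - 1L)
    B <- matrix(0, m - 1L, e - s + 1L)
    B[cbind(s:e, seq_len(e - s + 1L))] <- 1
    Mc <- as.matrix(Matrix::solve(ch, B))
    dvec[(s + 1):(e + 1)] <- Mc[cbind(s:e, seq_len(e - s + 1L))]
    for (k in seq_len(noff)) {
      tc <- TGT[, k] - 1L                       # grounded column index
      sel <- which(tc >= s & tc <= e & src > 1L)
      if (length(sel))
        kv[sel, k] <- Mc[cbind(src[sel] - 1L, tc[sel] - s + 1L)]
    }
  }
  vals <- vector("list", noff)
  for (k in seq_len(noff))
    vals[[k]] <- dvec[src] + dvec[TGT[, k]] - 2 * kv[, k]
  unlist(vals, use.names = FALSE)
}

#' Featurise a single pattern
#'
#' Convenience wrapper: pattern graph, resistance matrix, value collection
#' and (optionally) histogram binning for one simulated pattern.  For
#' batches with shared `R_max` calibration use [featurize_dataset()].
#'
#' @param pattern a `pattern` from [simulate_pattern()] (or a bare matrix).
#' @param r histogram radius.
#' @param t undersampling factor.
#' @param B bin count.
#' @param R_max histogram edge; if `NULL`, only the value multiset is
#'   returned (for later calibration).
#' @param eps_w crossing-edge weight of the pattern graph.
#' @return an [rdh()] object, or the value multiset when `R_max` is `NULL`.
#' @export
pattern_features <- function(pattern, r = 8, t = 1, B = 12, R_max = NULL,
                             eps_w = 0.003) {
  field <- if (inherits(pattern, "pattern")) pattern$field[, , 1] else pattern
  g <- pattern_graph(field, eps_w)
  vals <- pattern_resistance_values(g, r = r, t = t)
  if (is.null(R_max)) return(vals)
  rdh_from_values(vals, r = r, t = t, B = B, R_max = R_max)
}
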