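# shared fixture builders and independent oracles

random_simplex <- function(B, rng = NULL) {
  x <- stats::runif(B)
  x / sum(x)
}

# random connected weighted graph on n nodes (ring plus random chords)
random_weighted_graph <- function(n, extra = n) {
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i %% n + 1
    A[i, j] <- A[j, i] <- stats::runif(1, 0.1, 2)
  }
  for (k in seq_len(extra)) {
    ij <- sample(n, 2)
    w <- stats::runif(1, 0.1, 2)
    A[ij[1], ij[2]] <- A[ij[2], ij[1]] <- w
  }
  A
}

# LP oracle for the discrete optimal transport problem with cost (i-j)^2,
# solved with the simplex method (column-major transport-plan variables)
ot_lp_oracle <- function(x, xp) {
  B <- length(x)
  C <- outer(seq_len(B), seq_len(B), function(i, j) (i - j)^2)
  rowA <- matrix(0, B, B * B)
  colA <- matrix(0, B, B * B)
  for (i in seq_len(B)) rowA[i, i + B * (0:(B - 1))] <- 1
  for (j in seq_len(B)) colA[j, (j - 1) * B + seq_len(B)] <- 1
  res <- boot::simplex(a = as.vector(C),
                       A3 = rbind(rowA, colA[-B, , drop = FALSE]),
                       b3 = c(x, xp[-B]), maxi = FALSE)
  unname(res$value)
}

# generic convex-QP oracle for the epsilon-insensitive SVR primal
# (variables alpha and slacks xi), via an interior-point solver
svr_qp_oracle <- function(K, y, lam, epsilon) {
  n <- length(y)
  H <- matrix(0, 2 * n, 2 * n)
  H[1:n, 1:n] <- lam * K + 1e-10 * diag(n)
  cvec <- c(rep(0, n), rep(1, n))
  Amat <- rbind(cbind(K, diag(n)), cbind(-K, diag(n)))
  bvec <- c(y - epsilon, -y - epsilon)
  sol <- kernlab::ipop(cvec, H, Amat, bvec,
                       l = c(rep(-1e3, n), rep(0, n)), u = rep(1e3, 2 * n),
                       r = rep(1e6, 2 * n), sigf = 9, maxiter = 400)
  z <- kernlab::primal(sol)
  alpha <- z[1:n]
  f <- as.vector(K %*% alpha)
  sum(pmax(0, abs(y - f) - epsilon)) + lam / 2 * sum(alpha * f)
}

# dense Kronecker-system oracle for the operator-valued-kernel solve
kron_dense_oracle <- function(K, Tn, lam) {
  n <- nrow(K)
  A <- kronecker(K, Tn) + n * lam * diag(n * n)
  solve(A, as.vector(diag(n)))
}

# cyclic shift of a matrix by (di, dj)
shift_mat <- function(x, di, dj) {
  n <- nrow(x)
  x[(seq_len(n) - 1 - di) %% n + 1, (seq_len(n) - 1 - dj) %% n + 1]
}

# a small simulated pattern cache shared across test files
pattern_cache <- new.env(parent = emptyenv())
cached_pattern <- function(key = "default", n_r = 64, seed = 11,
                           params = c(a = 0.02, b = 1, c = 0.5,
                                      delta = 100, s = 0.25)) {
  if (is.null(pattern_cache[[key]])) {
    m <- gm_model(params[["a"]], params[["b"]], params[["c"]],
                  params[["delta"]], params[["s"]])
    pattern_cache[[key]] <- simulate_pattern(m, grid_spec(n_r), sim_config(),
                                             seed = seed)
  }
  pattern_cache[[key]]
}
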