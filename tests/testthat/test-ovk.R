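random_psd <- function(n) {
  A <- matrix(stats::rnorm(n * n), n)
  crossprod(A) / n
}

test_that("context matrix reduces to closed forms and the dense inverse", {
  L <- random_psd(3)
  expect_equal(compute_Tn(matrix(0, 3, 3), L, eps_reg = 0.1), L)
  expect_equal(compute_Tn(diag(2), diag(2), eps_reg = 0.5), 0.5 * diag(2))
  set.seed(41)
  K <- random_psd(4); L <- random_psd(4)
  e <- 1e-3
  dense <- L - solve(K + 4 * e * diag(4)) %*% K %*% L
  expect_equal(compute_Tn(K, L, e), dense, tolerance = 1e-10)
})

test_that("matrix-free Kronecker solve agrees with the dense oracle", {
  set.seed(42)
  for (n in c(3, 5)) {
    K <- random_psd(n); Tn <- compute_Tn(K, random_psd(n), 1e-3)
    lam <- 0.05
    u <- solve_kron_system(K, Tn, lam, tol = 1e-10)
    expect_equal(as.vector(u), kron_dense_oracle(K, Tn, lam), tolerance = 1e-8)
    # residual re-verified by direct application
    r <- turingfit:::kron_apply(u, K, Tn, lam) - as.vector(diag(n))
    expect_lte(sqrt(sum(r^2)) / sqrt(n), 1e-8)
  }
  # K = 0 gives the diagonal system u = vec(I)/(n lam)
  n <- 4; lam <- 0.2
  u0 <- solve_kron_system(matrix(0, n, n), random_psd(n), lam)
  expect_equal(as.vector(u0), as.vector(diag(n)) / (n * lam), tolerance = 1e-10)
})

test_that("context vector equals the explicit Kronecker contraction", {
  set.seed(43)
  n <- 4
  Tn <- matrix(stats::rnorm(n * n), n)
  u <- stats::rnorm(n * n)
  kx <- stats::rnorm(n)
  v <- context_vector(u, Tn, kx)
  expect_equal(v, as.vector((t(kx) %x% Tn) %*% u), tolerance = 1e-12)
  # u = vec(I), kx = e_j picks the j-th column of Tn
  expect_equal(context_vector(as.vector(diag(n)), Tn, c(0, 1, 0, 0)), Tn[, 2])
  expect_equal(context_vector(u, Tn, numeric(n)), numeric(n))
})

test_that("pre-image descent finds the dominant target and beats a grid", {
  Y <- matrix(c(0.2, 0.8, 0.5, 0.1, 0.9, 0.4), 3, 2)
  v <- c(0, 1, 0)
  out <- preimage_predict(v, Y, gamma_out = 0.1)
  expect_equal(out$y, Y[2, ], tolerance = 1e-6)
  # symmetric two-target case in d = 1 stays at the midpoint
  sym <- preimage_predict(c(0.5, 0.5), matrix(c(-1, 1), 2, 1),
                          gamma_out = 10, init = 0)
  expect_equal(sym$y, 0, tolerance = 1e-8)
  # random instance: objective at the optimum below a 200x200 grid search
  set.seed(44)
  Y3 <- matrix(stats::runif(6), 3, 2)
  v3 <- stats::runif(3, 0.1, 1)
  opt <- preimage_predict(v3, Y3, gamma_out = 0.3)
  obj <- function(y1, y2) 1 - 2 * sum(v3 * exp(-((Y3[, 1] - y1)^2 +
                                                 (Y3[, 2] - y2)^2) / 0.3))
  gr <- seq(min(Y3) - 0.2, max(Y3) + 0.2, length.out = 200)
  grid_best <- min(outer(gr, gr, Vectorize(obj)))
  expect_lte(opt$objective, grid_best + 1e-8)
})

test_that("joint prediction recovers training targets in the small-ridge limit", {
  set.seed(45)
  n <- 10
  # well-separated histograms: bumps at distinct locations
  X <- t(vapply(seq(0.05, 0.95, length.out = n), function(ci) {
    h <- stats::dnorm(1:12, mean = 1 + 10 * ci, sd = 1); h / sum(h)
  }, numeric(12)))
  Y <- cbind(stats::runif(n, 0.2, 1), stats::runif(n, 0.2, 1))
  fit <- ovk_fit(X, Y, kernel_spec("wasserstein", gamma = 5),
                 gamma_out = 0.05, lam = 1e-6, eps_reg = 1e-4)
  pred <- predict_ovk(fit, X[c(2, 7), , drop = FALSE])
  expect_lt(max(abs(pred - Y[c(2, 7), ])), 0.05)
  # n = 1: the single target is always recovered
  one <- ovk_fit(X[1, , drop = FALSE], Y[1, , drop = FALSE],
                 kernel_spec("wasserstein", gamma = 5),
                 gamma_out = 0.2, lam = 0.01)
  expect_equal(as.vector(predict_ovk(one, X[5, , drop = FALSE])), Y[1, ],
               tolerance = 1e-6)
})

test_that("joint and scalar predictions agree in rank on a 1-D toy problem", {
  set.seed(46)
  n <- 12
  c_true <- stats::runif(n, 0.1, 1)
  X <- t(vapply(c_true, function(ci) {
    h <- stats::dnorm(1:12, mean = 2 + 8 * ci, sd = 1.2); h / sum(h)
  }, numeric(12)))
  tr <- 1:8; te <- 9:12
  spec <- kernel_spec("wasserstein", gamma = 3)
  sv <- svr_fit(X[tr, ], c_true[tr], spec, lam = 1e-3, epsilon = 0.01)
  ps <- predict_svr(sv, X[te, ])
  ov <- ovk_fit(X[tr, ], matrix(c_true[tr], ncol = 1), spec,
                gamma_out = 0.1, lam = 1e-3)
  po <- as.vector(predict_ovk(ov, X[te, ]))
  expect_gte(stats::cor(ps, po, method = "spearman"), 0.8)
})
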