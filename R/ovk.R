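#' Context matrix of the operator-valued-kernel predictor
#'
#' `T_n = L_n - (K_n + n e I)^{-1} K_n L_n`, the empirical conditional
#' covariance factor coupling the input Gram matrix `K_n` and the output
#' Gram matrix `L_n`; `e` is a small ridge regularising the inversion.
#'
#' @param K input Gram matrix (`n x n`, PSD).
#' @param L output Gram matrix (`n x n`, PSD).
#' @param eps_reg small positive regulariser.
#' @return `n x n` matrix `T_n`.
#' @export
compute_Tn <- function(K, L, eps_reg = 1e-4) {
  stopifnot(nrow(K) == nrow(L), eps_reg > 0)
  n <- nrow(K)
  L - solve(K + n * eps_reg * diag(n), K %*% L)
}

# operator of the Kronecker system applied matrix-free:
# (K %x% T + n lam I) vec(U) = vec(T U K) + n lam vec(U)   (K symmetric)
kron_apply <- function(u, K, Tn, lam) {
  n <- nrow(K)
  U <- matrix(u, n, n)
  as.vector(Tn %*% U %*% K) + n * lam * u
}

#' Solve the Kronecker-structured normal system by global GMRES
#'
#' Solves `(K_n (x) T_n + n lambda I) u = vec(I_n)` without ever forming
#' the `n^2 x n^2` Kronecker matrix: the operator is applied matrix-free as
#' `X -> T_n X K_n + n lambda X` on the `n x n` un-vectorisation of the
#' iterate, and a restarted GMRES (Arnoldi with modified Gram-Schmidt on
#' the vectorised Krylov matrices, i.e. the Frobenius inner product on
#' matrix space) reduces each cycle to a small least-squares problem.
#'
#' @param K input Gram matrix.
#' @param Tn context matrix from [compute_Tn()].
#' @param lam regularisation parameter `lambda > 0`.
#' @param tol relative residual tolerance.
#' @param restart Krylov cycle length.
#' @param max_restart maximum number of cycles.
#' @return length-`n^2` solution vector `u` with attribute
#'   `"residual"` (relative).
#' @export
solve_kron_system <- function(K, Tn, lam, tol = 1e-8, restart = 50,
                              max_restart = 200) {
  stopifnot(lam > 0)
  n <- nrow(K)
  b <- as.vector(diag(n))
  bnorm <- sqrt(sum(b^2))
  x <- numeric(n * n)
  for (cycle in seq_len(max_restart)) {
    r <- b - kron_apply(x, K, Tn, lam)
    beta <- sqrt(sum(r^2))
    if (beta <= tol * bnorm) break
    m <- restart
    V <- matrix(0, n * n, m + 1)
    H <- matrix(0, m + 1, m)
    V[, 1] <- r / beta
    k_used <- m
    for (j in seq_len(m)) {
      w <- kron_apply(V[, j], K, Tn, lam)
      for (i in seq_len(j)) {              # modified Gram-Schmidt
        H[i, j] <- sum(w * V[, i])
        w <- w - H[i, j] * V[, i]
      }
      H[j + 1, j] <- sqrt(sum(w^2))
      if (H[j + 1, j] < 1e-14) { k_used <- j; break }
      V[, j + 1] <- w / H[j + 1, j]
      k_used <- j
    }
    e1 <- c(beta, numeric(k_used))
    Hk <- H[seq_len(k_used + 1), seq_len(k_used), drop = FALSE]
    # SVD least squares: robust to the rank drop of a happy breakdown
    sv <- svd(Hk)
    dtol <- max(dim(Hk)) * max(sv$d) * .Machine$double.eps
    yls <- sv$v %*% (ifelse(sv$d > dtol, 1 / sv$d, 0) * (t(sv$u) %*% e1))
    x <- x + V[, seq_len(k_used), drop = FALSE] %*% yls
  }
  r <- b - kron_apply(x, K, Tn, lam)
  rel <- sqrt(sum(r^2)) / bnorm
  if (rel > tol)
    stop("global GMRES stagnated (relative residual ", signif(rel, 3), ")")
  structure(as.vector(x), residual = rel)
}

#' Context vector for a test point
#'
#' `v = vec(T_n unvec(u) k_x) = (k_x^T (x) T_n) u`; the length-`n` weight
#' vector defining the pre-image objective for a test input with kernel
#' column `k_x` against the training inputs.
#'
#' @param u Kronecker-system solution from [solve_kron_system()].
#' @param Tn context matrix.
#' @param kx length-`n` vector of input-kernel evaluations `k(x, x_i)`.
#' @return length-`n` numeric vector.
#' @export
context_vector <- function(u, Tn, kx) {
  n <- nrow(Tn)
  stopifnot(length(u) == n * n, length(kx) == n)
  as.vector(Tn %*% (matrix(u, n, n) %*% kx))
}

#' Pre-image of the embedded prediction
#'
#' Minimises `l(y, y) - 2 l_y^T v = 1 - 2 sum_i v_i exp(-||y - y_i||^2 /
#' gamma)` over the output space by gradient descent with backtracking
#' (Armijo) line search.  The default initialisation starts at the training
#' target with the largest context weight `v_i` (ties broken by lowest
#' index), the dominant bump of the Gaussian mixture.
#'
#' @param v context vector from [context_vector()].
#' @param Y training target matrix (`n x d`).
#' @param gamma_out output-kernel scale.
#' @param init `"best"` (dominant-weight target) or a numeric `d`-vector.
#' @param grad_tol gradient-norm stopping tolerance.
#' @param max_iter iteration cap; the best iterate found is returned.
#' @return list with the predicted vector `y`, final `objective` and
#'   `iterations`.
#' @export
preimage_predict <- function(v, Y, gamma_out, init = "best",
                             grad_tol = 1e-8, max_iter = 1000) {
  Y <- as.matrix(Y)
  stopifnot(length(v) == nrow(Y), gamma_out > 0)
  obj <- function(y) {
    e <- exp(-colSums((t(Y) - y)^2) / gamma_out)
    1 - 2 * sum(v * e)
  }
  grad <- function(y) {
    D <- t(t(Y) - y)                       # n x d rows y_i - y
    e <- exp(-rowSums(D^2) / gamma_out)
    -(4 / gamma_out) * colSums((v * e) * D)
  }
  y <- if (identical(init, "best")) Y[which.max(v), ] else as.numeric(init)
  fy <- obj(y)
  best_y <- y; best_f <- fy
  it <- 0
  for (it in seq_len(max_iter)) {
    g <- grad(y)
    gn2 <- sum(g^2)
    if (sqrt(gn2) <= grad_tol) break
    step <- 1
    repeat {
      cand <- y - step * g
      fc <- obj(cand)
      if (fc <= fy - 1e-4 * step * gn2) break
      step <- step / 2
      if (step < 1e-16) { cand <- y; fc <- fy; break }
    }
    if (identical(cand, y)) break
    y <- cand; fy <- fc
    if (fy < best_f) { best_f <- fy; best_y <- y }
  }
  list(y = best_y, objective = best_f, iterations = it)
}

#' Fit the operator-valued-kernel joint predictor
#'
#' Assembles the input Gram matrix (Wasserstein kernel on the feature
#' histograms by default), the Gaussian output Gram matrix on the
#' normalised targets, the context matrix and the Kronecker-system
#' solution; prediction for a new pattern then only requires its kernel
#' column, the context vector and the pre-image optimisation.
#'
#' @param X training feature matrix (`n` rows).
#' @param Y training target matrix (`n x d`, normalised to `[0, 1]`).
#' @param spec_in input [kernel_spec()].
#' @param gamma_out Gaussian output-kernel scale.
#' @param lam regularisation parameter of the least-squares fit.
#' @param eps_reg ridge of the context-matrix inversion.
#' @param ... passed to [solve_kron_system()].
#' @return object of class `ovk_fit`.
#' @export
ovk_fit <- function(X, Y, spec_in, gamma_out, lam, eps_reg = 1e-4, ...) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  K <- gram(X, spec_in)
  L <- gram(Y, kernel_spec("gaussian", gamma = gamma_out))
  Tn <- compute_Tn(K, L, eps_reg)
  u <- solve_kron_system(K, Tn, lam, ...)
  structure(list(X = X, Y = Y, spec_in = spec_in, gamma_out = gamma_out,
                 lam = lam, eps_reg = eps_reg, K = K, L = L, Tn = Tn, u = u),
            class = "ovk_fit")
}

#' Predict jointly with a fitted operator-valued-kernel model
#'
#' @param object an `ovk_fit`.
#' @param newX matrix of new feature vectors.
#' @return matrix of predicted target vectors (one row per input).
#' @export
predict_ovk <- function(object, newX) {
  newX <- as.matrix(newX)
  Kx <- cross_gram(newX, object$X, object$spec_in)
  out <- matrix(0, nrow(newX), ncol(object$Y))
  for (i in seq_len(nrow(newX))) {
    v <- context_vector(object$u, object$Tn, Kx[i, ])
    out[i, ] <- preimage_predict(v, object$Y, object$gamma_out)$y
  }
  out
}

#' @export
predict.ovk_fit <- function(object, newdata, ...) predict_ovk(object, newdata)

#' One-call fit and predict for joint parameter regression
#'
#' @inheritParams ovk_fit
#' @param testX feature matrix of test patterns.
#' @return matrix of predictions for `testX`.
#' @export
ovk_fit_predict <- function(X, Y, testX, spec_in, gamma_out, lam,
                            eps_reg = 1e-4, ...) {
  fit <- ovk_fit(X, Y, spec_in, gamma_out, lam, eps_reg, ...)
  predict_ovk(fit, testX)
}
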