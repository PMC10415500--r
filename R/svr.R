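#' Train epsilon-insensitive support vector regression (no offset)
#'
#' Solves the kernelised regression problem
#' \deqn{\min_{\alpha,\xi} \sum_i \xi_i + \tfrac{\lambda}{2}\alpha^\top K_n \alpha
#'   \quad \text{s.t.}\quad \xi \ge 0,\;
#'   \xi_i + (K_n\alpha)_i \ge y_i - \varepsilon,\;
#'   \xi_i - (K_n\alpha)_i \ge -y_i - \varepsilon,}
#' i.e. an epsilon-insensitive loss with RKHS-norm regularisation and no
#' bias term.  The solver works on the equivalent box-constrained dual
#' \deqn{\max_{d \in [-1,1]^n} -\tfrac{1}{2\lambda} d^\top K_n d
#'   + y^\top d - \varepsilon \lVert d\rVert_1,\qquad \alpha = d/\lambda,}
#' by exact soft-threshold coordinate updates, stopping on the duality gap.
#'
#' @param K symmetric positive semidefinite Gram matrix of the training
#'   inputs (a small negative jitter up to `-1e-8` on the spectrum is
#'   tolerated).
#' @param y numeric target vector.
#' @param lam regularisation parameter `lambda > 0`.
#' @param epsilon half-width of the insensitive tube (`>= 0`).
#' @param tol duality-gap stopping tolerance (relative).
#' @param max_pass maximum number of coordinate sweeps.
#' @return object of class `svr_model` with `alpha`, `xi`, `objective`
#'   (attained primal minimum), `dual_objective`, `gap`, `lam`, `epsilon`.
#' @examples
#' K <- diag(2)
#' m <- train_svr(K, c(1, -1), lam = 1, epsilon = 0.1)
#' m$alpha   # soft-thresholded targets
#' @export
train_svr <- function(K, y, lam, epsilon = 0.01, tol = 1e-8,
                      max_pass = 20000) {
  stopifnot(lam > 0, epsilon >= 0, nrow(K) == length(y))
  n <- length(y)
  ev_min <- min(eigen((K + t(K)) / 2, only.values = TRUE,
                      symmetric = TRUE)$values)
  if (ev_min < -1e-8 * max(1, max(abs(K))))
    stop("Gram matrix is indefinite beyond tolerance (min eigenvalue ",
         signif(ev_min, 3), ")")
  d <- numeric(n)
  g <- numeric(n)        # g = K d, maintained incrementally
  Kd <- diag(K)
  soft <- function(z, e) sign(z) * pmax(abs(z) - e, 0)
  for (pass in seq_len(max_pass)) {
    delta_max <- 0
    for (i in seq_len(n)) {
      r <- g[i] - Kd[i] * d[i]
      if (Kd[i] > 1e-12) {
        cand <- lam * soft(y[i] - r / lam, epsilon) / Kd[i]
        new <- min(1, max(-1, cand))
      } else {
        z <- y[i] - r / lam
        new <- if (z > epsilon) 1 else if (z < -epsilon) -1 else 0
      }
      ch <- new - d[i]
      if (ch != 0) {
        g <- g + K[, i] * ch
        d[i] <- new
        delta_max <- max(delta_max, abs(ch))
      }
    }
    alpha <- d / lam
    f <- g / lam                          # in-sample predictions K alpha
    xi <- pmax(0, abs(y - f) - epsilon)
    primal <- sum(xi) + lam / 2 * sum(alpha * f)
    dual <- -sum(d * g) / (2 * lam) + sum(y * d) - epsilon * sum(abs(d))
    gap <- primal - dual
    if (gap <= tol * (1 + abs(primal)) && delta_max <= sqrt(tol)) break
  }
  if (gap > 1e-4 * (1 + abs(primal)))
    stop("SVR solver did not converge (duality gap ", signif(gap, 3), ")")
  structure(list(alpha = alpha, xi = xi, objective = primal,
                 dual_objective = dual, gap = gap, lam = lam,
                 epsilon = epsilon),
            class = "svr_model")
}

#' Fit an SVR predictor on feature vectors
#'
#' Builds the Gram matrix for `spec`, trains via [train_svr()] and stores
#' the training inputs so the predictor `f(x) = sum_i alpha_i k(x_i, x)`
#' can be evaluated on new points.
#'
#' @param X training feature matrix (one histogram/feature vector per row).
#' @param y numeric targets.
#' @param spec a [kernel_spec()].
#' @inheritParams train_svr
#' @return object of class `svr_fit`.
#' @export
svr_fit <- function(X, y, spec, lam, epsilon = 0.01, ...) {
  X <- as.matrix(X)
  K <- gram(X, spec)
  model <- train_svr(K, y, lam = lam, epsilon = epsilon, ...)
  structure(list(model = model, X = X, spec = spec), class = "svr_fit")
}

#' Predict with a trained SVR model
#'
#' @param object an `svr_fit` (or an `svr_model` together with `K_new`).
#' @param newX matrix of new feature vectors (one per row).
#' @return numeric vector of predictions.
#' @export
predict_svr <- function(object, newX) {
  if (inherits(object, "svr_fit")) {
    Kx <- cross_gram(as.matrix(newX), object$X, object$spec)
    return(as.vector(Kx %*% object$model$alpha))
  }
  stop("object must be an svr_fit")
}

#' @export
predict.svr_fit <- function(object, newdata, ...) predict_svr(object, newdata)
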