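#' Normalise target columns by their maxima
#'
#' `y'_{ij} = y_{ij} / max_l y_{lj}`; the stored maxima provide the exact
#' inverse transform.  Normalised targets lie in `[0, 1]` with column
#' maximum 1, which keeps the offset-free SVR and the Gaussian output
#' kernel well scaled.
#'
#' @param Y nonnegative target matrix (`n x d`).
#' @return list with `Y` (normalised) and `maxima`.
#' @export
normalize_targets <- function(Y) {
  Y <- as.matrix(Y)
  mx <- apply(Y, 2, max)
  if (any(mx <= 0)) stop("every target column must have a positive maximum")
  list(Y = sweep(Y, 2, mx, "/"), maxima = mx)
}

#' @rdname normalize_targets
#' @param Yn normalised matrix.
#' @param maxima stored column maxima.
#' @export
denormalize_targets <- function(Yn, maxima) {
  sweep(as.matrix(Yn), 2, maxima, "*")
}

#' Normalised root-mean-square error
#'
#' `RMSE = sqrt(mean((pred - truth)^2))` over all entries, divided by the
#' mean of the (nonnegative) true values over the same entries.  Values
#' below 0.2 are considered good and below 0.05 excellent in terms of
#' visual pattern similarity.
#'
#' @param pred,truth matrices (or vectors) of equal shape.
#' @return scalar NRMSE.
#' @examples
#' nrmse(c(1, 3), c(2, 4))  # RMSE 1 over mean 3
#' @export
nrmse <- function(pred, truth) {
  pred <- as.matrix(pred); truth <- as.matrix(truth)
  stopifnot(all(dim(pred) == dim(truth)))
  mu <- mean(truth)
  if (mu <= 0) stop("NRMSE undefined: nonpositive mean of the true targets")
  sqrt(mean((pred - truth)^2)) / mu
}

#' Random train/validation/test partition
#'
#' Disjoint 60/20/20 split (validation and test sizes rounded down, the
#' training set takes the remainder), reproducible from `seed`.
#'
#' @param n number of samples (`>= 5`).
#' @param seed integer seed.
#' @param fractions length-3 vector (train, validation, test) summing to 1.
#' @return list of index vectors `train`, `validation`, `test`.
#' @export
split_dataset <- function(n, seed, fractions = c(0.6, 0.2, 0.2)) {
  stopifnot(n >= 5, abs(sum(fractions) - 1) < 1e-12)
  withr_seed(seed)
  perm <- sample.int(n)
  n_val <- floor(fractions[2] * n)
  n_test <- floor(fractions[3] * n)
  list(train = perm[seq_len(n - n_val - n_test)],
       validation = perm[n - n_val - n_test + seq_len(n_val)],
       test = perm[n - n_test + seq_len(n_test)])
}

#' Subset-averaged test NRMSE
#'
#' Implements the robustified evaluation protocol for small datasets: a
#' pool of `P` points is partitioned into `floor(P/m)` disjoint subsets of
#' size `m` (for `m <= 500`; a single subset of size `m` is drawn for
#' larger `m`), each subset is split 60/20/20, trained and tested
#' independently, and the mean of the test NRMSE values is returned.
#'
#' @param X feature matrix of the pool.
#' @param Y target matrix of the pool.
#' @param m subset size.
#' @param train_predict function `(Xtr, Ytr, Xval, Yval, Xte) -> test
#'   predictions`; it never sees the test targets.
#' @param seed integer seed driving subset selection and splits.
#' @return list with `mean_nrmse`, the per-subset values `nrmse`, and the
#'   number of subsets.
#' @export
averaged_nrmse <- function(X, Y, m, train_predict, seed = 1) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  P <- nrow(X)
  stopifnot(m <= P, m >= 5)
  withr_seed(seed)
  if (m <= 500) {
    k <- floor(P / m)
    if (k == 0) stop("pool smaller than the subset size")
    perm <- sample.int(P)
    subsets <- lapply(seq_len(k), function(i) perm[(i - 1) * m + seq_len(m)])
  } else {
    subsets <- list(sample.int(P, m))
  }
  vals <- vapply(seq_along(subsets), function(i) {
    idx <- subsets[[i]]
    sp <- split_dataset(m, seed = seed + 1000 + i)
    tr <- idx[sp$train]; va <- idx[sp$validation]; te <- idx[sp$test]
    pred <- train_predict(X[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                          X[va, , drop = FALSE], Y[va, , drop = FALSE],
                          X[te, , drop = FALSE])
    nrmse(pred, Y[te, , drop = FALSE])
  }, numeric(1))
  list(mean_nrmse = mean(vals), nrmse = vals, n_subsets = length(subsets))
}

#' Validation grid search over hyperparameters
#'
#' Trains one model per grid row, selects the row minimising the
#' validation NRMSE (ties broken by the first row in grid order) and
#' returns that model; the test split is never consulted.  An optional
#' refinement pass re-runs the search on a finer grid centred at the
#' winner of the first pass.
#'
#' @param Xtr,Ytr,Xval,Yval train and validation splits.
#' @param grid data frame of hyperparameter combinations (one per row).
#' @param fit function `(Xtr, Ytr, hyper) -> model` where `hyper` is a
#'   one-row list of the grid row.
#' @param predict_fn function `(model, X) -> predictions`.
#' @return list with `model`, `best` (grid row), `val_nrmse` and the full
#'   vector of validation scores.
#' @export
grid_search <- function(Xtr, Ytr, Xval, Yval, grid, fit, predict_fn) {
  stopifnot(nrow(grid) >= 1)
  scores <- rep(Inf, nrow(grid))
  models <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    hyper <- as.list(grid[i, , drop = FALSE])
    models[i] <- list(tryCatch(fit(Xtr, Ytr, hyper), error = function(e) NULL))
    if (!is.null(models[[i]]))
      scores[i] <- nrmse(predict_fn(models[[i]], Xval), Yval)
  }
  if (all(!is.finite(scores))) stop("every grid point failed to train")
  best <- which.min(scores)   # ties: first in grid order
  list(model = models[[best]], best = grid[best, , drop = FALSE],
       val_nrmse = scores[best], scores = scores)
}

#' Default hyperparameter grids
#'
#' Kernel scales must live on the scale of the squared distances they
#' exponentiate: squared Wasserstein distances between `B`-bin histograms
#' are measured in squared bins (up to `(B-1)^2`), so the input-kernel
#' grid spans `0.01` to `30`; regularisation and the output-kernel scale
#' (normalised targets in `[0,1]^d`) use shorter log-spaced grids.
#'
#' @param lambda,gamma,gamma_out optional overrides.
#' @return named list of numeric grids.
#' @export
default_grids <- function(gamma = c(0.01, 0.03, 0.1, 0.3, 1, 3, 10, 30),
                          lambda = 10^seq(-4, 0),
                          gamma_out = c(0.01, 0.03, 0.1, 0.3, 1)) {
  list(gamma = gamma, lambda = lambda, gamma_out = gamma_out)
}
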