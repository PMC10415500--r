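#' Kernel specification
#'
#' @param family one of `"chi2"` (symmetric chi-squared, no scale),
#'   `"exp_chi2"`, `"wasserstein"` (squared 1-D optimal transport distance
#'   with squared bin-index cost inside an exponential), or `"gaussian"`
#'   (squared Euclidean; the output-space kernel).
#' @param gamma positive scale of the exponential families.
#' @return object of class `kernel_spec`.
#' @export
kernel_spec <- function(family = c("wasserstein", "chi2", "exp_chi2", "gaussian"),
                        gamma = NULL) {
  family <- match.arg(family)
  if (family != "chi2") {
    stopifnot(!is.null(gamma), gamma > 0)
  }
  structure(list(family = family, gamma = gamma), class = "kernel_spec")
}

#' Symmetric chi-squared kernel on histograms
#'
#' `sum_i x_i x'_i / (x_i + x'_i)` with `0/0` summands contributing 0.
#' Equal distributions give 1/2.
#'
#' @param x,xp nonnegative vectors (histograms).
#' @return nonnegative scalar.
#' @export
chi2_kernel <- function(x, xp) {
  s <- x + xp
  ok <- s > 0
  sum(x[ok] * xp[ok] / s[ok])
}

#' Exponential chi-squared kernel
#'
#' `exp(-(1/gamma) sum_i (x_i - x'_i)^2 / (x_i + x'_i))`, `0/0 -> 0`.
#'
#' @inheritParams chi2_kernel
#' @param gamma positive scale.
#' @export
exp_chi2_kernel <- function(x, xp, gamma) {
  s <- x + xp
  ok <- s > 0
  exp(-sum((x[ok] - xp[ok])^2 / s[ok]) / gamma)
}

#' Squared 1-D Wasserstein distance between histograms
#'
#' Optimal transport with ground cost `C_ij = (i - j)^2` on bin indices.
#' On the line the optimum is the monotone coupling, evaluated exactly by
#' merging the two cumulative distributions and summing
#' `(mass of segment) * (index difference)^2` over the merged segments --
#' the quantile-function form of the transport cost.  Distances are in
#' units of squared bins.
#'
#' @param x,xp points of the probability simplex (renormalised if their
#'   sums deviate by at most `tol`; larger mass mismatch is an error).
#' @param tol mass-mismatch tolerance.
#' @return nonnegative scalar, the squared Wasserstein distance.
#' @examples
#' wasserstein_sq(c(0.5, 0.5, 0), c(0, 0.5, 0.5))  # each half moves one bin
#' @export
wasserstein_sq <- function(x, xp, tol = 1e-9) {
  stopifnot(length(x) == length(xp), all(x >= 0), all(xp >= 0))
  if (abs(sum(x) - 1) > tol || abs(sum(xp) - 1) > tol)
    stop("histograms must lie in the probability simplex (mass mismatch)")
  x <- x / sum(x); xp <- xp / sum(xp)
  i <- 1L; j <- 1L
  ri <- x[1]; rj <- xp[1]
  B <- length(x)
  w <- 0
  repeat {
    m <- min(ri, rj)
    w <- w + m * (i - j)^2
    ri <- ri - m; rj <- rj - m
    if (ri <= 1e-15) { i <- i + 1L; if (i > B) break; ri <- x[i] }
    if (rj <= 1e-15) { j <- j + 1L; if (j > B) break; rj <- xp[j] }
  }
  w
}

#' Wasserstein kernel on histograms
#'
#' `exp(-d_W^2(x, x') / gamma)` with the squared distance of
#' [wasserstein_sq()]; a valid (positive definite) kernel on the simplex.
#'
#' @inheritParams wasserstein_sq
#' @param gamma positive scale.
#' @export
wasserstein_kernel <- function(x, xp, gamma) {
  exp(-wasserstein_sq(x, xp) / gamma)
}

#' Gaussian kernel on vectors
#'
#' `exp(-||y - y'||^2 / gamma)`; used as the smooth output-space kernel of
#' the joint (operator-valued-kernel) predictor.
#'
#' @param y,yp numeric vectors of equal length.
#' @param gamma positive scale.
#' @export
gaussian_kernel <- function(y, yp, gamma) {
  exp(-sum((y - yp)^2) / gamma)
}

kernel_fun <- function(spec) {
  switch(spec$family,
         chi2 = function(x, y) chi2_kernel(x, y),
         exp_chi2 = function(x, y) exp_chi2_kernel(x, y, spec$gamma),
         wasserstein = function(x, y) wasserstein_kernel(x, y, spec$gamma),
         gaussian = function(x, y) gaussian_kernel(x, y, spec$gamma))
}

#' Gram matrix of a kernel on a point set
#'
#' @param X numeric matrix, one point per row (histograms or target
#'   vectors, depending on the kernel family).
#' @param spec a [kernel_spec()].
#' @return symmetric `n x n` kernel matrix.
#' @export
gram <- function(X, spec) {
  X <- as.matrix(X)
  n <- nrow(X)
  k <- kernel_fun(spec)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      K[i, j] <- K[j, i] <- k(X[i, ], X[j, ])
    }
  }
  K
}

#' Cross Gram matrix between two point sets
#'
#' @param X,Y numeric matrices with one point per row.
#' @param spec a [kernel_spec()].
#' @return `nrow(X) x nrow(Y)` matrix of kernel values.
#' @export
cross_gram <- function(X, Y, spec) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  k <- kernel_fun(spec)
  out <- matrix(0, nrow(X), nrow(Y))
  for (i in seq_len(nrow(X)))
    for (j in seq_len(nrow(Y)))
      out[i, j] <- k(X[i, ], Y[j, ])
  out
}
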