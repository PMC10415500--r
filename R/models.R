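#' Gierer-Meinhardt reaction rates
#'
#' Dimensionless two-species activator-inhibitor kinetics
#' \deqn{f_1(u) = a - b u_1 + u_1^2 / (u_2 (1 + c u_1^2)), \qquad
#'       f_2(u) = u_1^2 - u_2.}
#' Parameter `a` is the basal activator production, `b` its linear
#' degradation and `c` saturates the autocatalytic term.
#'
#' @param u numeric 2-vector of nonnegative concentrations (activator,
#'   inhibitor); `u[2]` must be positive.
#' @param a,b,c positive kinetic parameters (`c = 0` is allowed, removing
#'   saturation).
#' @return numeric 2-vector of reaction rates.
#' @examples
#' gm_reaction(c(1, 1), a = 0, b = 1, c = 0)   # equilibrium of the reduced model
#' @export
gm_reaction <- function(u, a, b, c) {
  stopifnot(length(u) == 2, all(is.finite(u)), u[1] >= 0)
  if (u[2] <= 0) stop("inhibitor concentration u[2] must be positive")
  c(a - b * u[1] + u[1]^2 / (u[2] * (1 + c * u[1]^2)),
    u[1]^2 - u[2])
}

#' Jacobian of the Gierer-Meinhardt kinetics
#'
#' @inheritParams gm_reaction
#' @return 2x2 numeric matrix of partial derivatives of [gm_reaction()].
#' @export
gm_jacobian <- function(u, a, b, c) {
  u1 <- u[1]; u2 <- u[2]
  s <- 1 + c * u1^2
  # d/du1 of u1^2/(u2 s) = (2 u1 s - u1^2 * 2 c u1) / (u2 s^2)
  j11 <- -b + (2 * u1 * s - 2 * c * u1^3) / (u2 * s^2)
  j12 <- -u1^2 / (u2^2 * s)
  matrix(c(j11, 2 * u1, j12, -1), 2, 2)
}

#' Construct a kinetic reaction-diffusion model
#'
#' Bundles species kinetics, their Jacobian, the diagonal diffusion
#' constants and the overall diffusion scale into a model object consumed by
#' the stability analysis and the simulator.  [gm_model()] is the shipped
#' Gierer-Meinhardt instance; `kinetic_model()` accepts arbitrary kinetics
#' for any number of species.
#'
#' @param n_species number of interacting species.
#' @param reaction function `u -> rates` (length-`n_species` in and out).
#' @param jacobian function `u -> n_species x n_species` matrix.
#' @param diffusion_diag nonnegative diffusion constants, one per species,
#'   before the overall scaling.
#' @param scale positive scalar multiplying the whole diffusion matrix; it
#'   sets the wavelength of emerging patterns without affecting whether an
#'   instability exists at some wavenumber.
#' @param params named numeric vector of the model parameters (metadata).
#' @return an object of class `kinetic_model`.
#' @export
kinetic_model <- function(n_species, reaction, jacobian, diffusion_diag,
                          scale = 1, params = numeric()) {
  stopifnot(n_species >= 1, length(diffusion_diag) == n_species,
            all(diffusion_diag >= 0), scale > 0)
  structure(list(n_species = n_species, reaction = reaction,
                 jacobian = jacobian, diffusion_diag = diffusion_diag,
                 scale = scale, params = params),
            class = "kinetic_model")
}

#' @rdname kinetic_model
#' @param a,b,c positive Gierer-Meinhardt kinetic parameters.
#' @param delta inhibitor/activator diffusion ratio (> 0); the activator
#'   diffusion constant is normalised to 1.
#' @param s overall diffusion scale (> 0).
#' @examples
#' m <- gm_model(a = 0.01, b = 1.2, c = 0.7, delta = 40, s = 1)
#' m$reaction(c(1, 1))
#' @export
gm_model <- function(a, b, c, delta, s = 1) {
  stopifnot(a > 0 || a == 0, b > 0, c >= 0, delta > 0, s > 0)
  kinetic_model(
    n_species = 2,
    reaction = function(u) gm_reaction(u, a, b, c),
    jacobian = function(u) gm_jacobian(u, a, b, c),
    diffusion_diag = c(1, delta),
    scale = s,
    params = c(a = a, b = b, c = c, delta = delta, s = s))
}

#' Homogeneous equilibrium of the Gierer-Meinhardt kinetics
#'
#' Eliminating the inhibitor (`u2* = u1*^2`) reduces the equilibrium
#' condition to the scalar equation `a - b u1 + 1/(1 + c u1^2) = 0`, whose
#' left-hand side is strictly decreasing for positive `u1`; the unique
#' positive root is bracketed and found with [stats::uniroot()] (Brent).
#'
#' @inheritParams gm_reaction
#' @param tol residual tolerance on the full kinetics at the returned point.
#' @return list with `u_star` (positive 2-vector) and `residual`.
#' @examples
#' gm_equilibrium(a = 0.02, b = 1, c = 0)  # closed form (1 + a)/b
#' @export
gm_equilibrium <- function(a, b, c, tol = 1e-12) {
  stopifnot(a >= 0, b > 0, c >= 0)
  g <- function(u1) a - b * u1 + 1 / (1 + c * u1^2)
  upper <- (1 + a) / b + 10      # the c = 0 root upper-bounds the general root
  u1 <- stats::uniroot(g, c(1e-12, upper), tol = tol)$root
  u_star <- c(u1, u1^2)
  res <- sqrt(sum(gm_reaction(u_star, a, b, c)^2))
  if (res > 1e-10) {  # polish with one Newton step on the scalar equation
    u1 <- u1 - g(u1) / (-b - 2 * c * u1 / (1 + c * u1^2)^2)
    u_star <- c(u1, u1^2)
    res <- sqrt(sum(gm_reaction(u_star, a, b, c)^2))
  }
  list(u_star = u_star, residual = res)
}

#' Equilibrium of a general kinetic model
#'
#' Dispatches to the closed reduction for Gierer-Meinhardt models; other
#' models must supply `u0` for a damped Newton solve.
#'
#' @param model a [kinetic_model()].
#' @param u0 optional starting point for non-GM models.
#' @return list with `u_star` and `residual`.
#' @export
equilibrium <- function(model, u0 = NULL) {
  p <- model$params
  if (all(c("a", "b", "c") %in% names(p)))
    return(gm_equilibrium(p[["a"]], p[["b"]], p[["c"]]))
  if (is.null(u0)) stop("u0 required for non-Gierer-Meinhardt models")
  u <- u0
  for (i in 1:200) {
    f <- model$reaction(u)
    if (sqrt(sum(f^2)) <= 1e-12) break
    u <- u - solve(model$jacobian(u), f)
  }
  list(u_star = u, residual = sqrt(sum(model$reaction(u)^2)))
}

#' Dispersion relation of the linearised reaction-diffusion system
#'
#' For each squared wavenumber the perturbation Jacobian is
#' `J(u*) - q^2 * s * D`, with `D = diag(diffusion_diag)`; its eigenvalue
#' real parts as a function of `q^2` form the dispersion relation.  A
#' homogeneous equilibrium that is stable without diffusion but has a
#' positive branch at finite `q^2` is diffusion-driven (Turing) unstable.
#'
#' @param model a [kinetic_model()].
#' @param eq equilibrium as returned by [equilibrium()]; computed if `NULL`.
#' @param q_squared nonnegative grid of squared wavenumbers.
#' @return list of class `dispersion_result` with elements `q_squared`,
#'   `real_parts` (length(q_squared) x N matrix, rows sorted decreasingly),
#'   `max_real`, `argmax_q_squared` and `stable_at_zero`.
#' @examples
#' m <- gm_model(0.01, 1.2, 0.7, delta = 40, s = 1)
#' d <- dispersion_relation(m)
#' d$max_real > 0
#' @export
dispersion_relation <- function(model, eq = NULL,
                                q_squared = default_qsq_grid()) {
  stopifnot(all(q_squared >= 0))
  if (is.null(eq)) eq <- equilibrium(model)
  J <- model$jacobian(eq$u_star)
  D <- model$scale * diag(model$diffusion_diag, model$n_species)
  re <- t(vapply(q_squared, function(q2) {
    ev <- eigen(J - q2 * D, only.values = TRUE)$values
    sort(Re(ev), decreasing = TRUE)
  }, numeric(model$n_species)))
  mx <- which.max(re[, 1])
  ev0 <- Re(eigen(J, only.values = TRUE)$values)
  structure(list(q_squared = q_squared, real_parts = re,
                 max_real = re[mx, 1], argmax_q_squared = q_squared[mx],
                 stable_at_zero = all(ev0 < 0), eq = eq),
            class = "dispersion_result")
}

#' Default squared-wavenumber grid
#'
#' Geometric grid of 400 points on `[1e-4, qsq_max]` plus zero; the upper
#' cutoff stands in for `q^2 -> Inf` when checking that short wavelengths
#' are damped, and covers all wavelengths resolvable on grids up to 128.
#'
#' @param qsq_max upper end of the grid.
#' @param n number of geometric points.
#' @export
default_qsq_grid <- function(qsq_max = 50, n = 400) {
  c(0, exp(seq(log(1e-4), log(qsq_max), length.out = n)))
}

#' Test for a Turing (diffusion-driven) instability
#'
#' The three conditions are checked on the dispersion relation: (i) the
#' non-spatial equilibrium is asymptotically stable, (ii) some finite
#' wavenumber has a positive real part, (iii) all real parts are negative
#' again at the short-wavelength end of the grid (automatic for strictly
#' positive diagonal diffusion, and asserted).
#'
#' @inheritParams dispersion_relation
#' @return list with logical `unstable`, the individual `conditions`, and
#'   the `dispersion` result.
#' @examples
#' is_turing_unstable(gm_model(0.02, 1, 1.2, delta = 50, s = 0.5))$unstable
#' @export
is_turing_unstable <- function(model, q_squared = default_qsq_grid()) {
  disp <- dispersion_relation(model, q_squared = q_squared)
  c1 <- disp$stable_at_zero
  pos <- disp$q_squared > 0
  c2 <- any(disp$real_parts[pos, 1] > 0)
  c3 <- disp$real_parts[which.max(disp$q_squared), 1] < 0
  if (all(model$diffusion_diag > 0) && !c3)
    warning("short-wavelength damping violated on the grid despite positive diffusion")
  list(unstable = c1 && c2 && c3,
       conditions = c(stable_without_diffusion = c1,
                      unstable_at_finite_q = c2,
                      damped_at_large_q = c3),
       dispersion = disp)
}
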