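#' Torus grid specification
#'
#' @param n_r grid side length (nodes per direction, spacing 1); at least 4
#'   so that the 4-neighbour torus has no duplicated edges.
#' @return object of class `grid_spec`.
#' @export
grid_spec <- function(n_r) {
  stopifnot(n_r >= 4, n_r == round(n_r))
  structure(list(n_r = as.integer(n_r), topology = "torus", spacing = 1),
            class = "grid_spec")
}

#' Simulation configuration
#'
#' Defaults follow the operating point of the integrator: step `h = 0.2`,
#' inner fixed-point tolerance `1e-3`, steady-state tolerance `1e-6`
#' checked every 100 time units, and a final time of 2000 for grids up to
#' 64 and 5000 for 128.
#'
#' @param h time step.
#' @param eps_inner relative tolerance of the inner fixed-point iteration.
#' @param eps_outer infinity-norm steady-state tolerance on the discrete
#'   right-hand side.
#' @param check_interval simulated time between steady-state checks.
#' @param t_final maximal simulated time; if `NULL`, chosen from the grid
#'   side when the pattern is simulated.
#' @param max_inner inner-iteration cap; exceeding it (or producing
#'   non-finite values) signals divergence and halves `h`.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(h = 0.2, eps_inner = 1e-3, eps_outer = 1e-6,
                       check_interval = 100, t_final = NULL, max_inner = 50) {
  stopifnot(h > 0, eps_inner > 0, eps_outer > 0, check_interval > 0,
            is.null(t_final) || t_final >= check_interval)
  structure(list(h = h, eps_inner = eps_inner, eps_outer = eps_outer,
                 check_interval = check_interval, t_final = t_final,
                 max_inner = max_inner),
            class = "sim_config")
}

default_t_final <- function(n_r) if (n_r <= 64) 2000 else 5000

#' Fourier symbol of the backward-Euler diffusion operator
#'
#' Eigenvalues of `I + h * delta * A` on the `n_r x n_r` torus, where `A` is
#' the negated 5-point Laplacian stencil; entry `(k, l)` (0-based
#' frequencies) equals
#' `1 + h * delta * (4 - 2 cos(2 pi k / n_r) - 2 cos(2 pi l / n_r))`.
#'
#' @param n_r grid side.
#' @param h time step.
#' @param delta effective diffusion constant of the species.
#' @return `n_r x n_r` matrix of symbol values, all `>= 1`.
#' @export
laplacian_symbol <- function(n_r, h, delta) {
  stopifnot(n_r >= 4, h > 0, delta >= 0)
  k <- 2 * pi * (seq_len(n_r) - 1) / n_r
  outer(k, k, function(x, y) 1 + h * delta * (4 - 2 * cos(x) - 2 * cos(y)))
}

#' Apply the 5-point torus Laplacian to a field
#'
#' Uses the sign convention of the reaction-diffusion right-hand side
#' `f(v) + delta * L v`: neighbour sum minus four times the centre.
#'
#' @param x numeric matrix (a single-species field).
#' @return matrix of the same shape.
#' @export
torus_laplacian <- function(x) {
  n <- nrow(x)
  up <- c(2:n, 1); dn <- c(n, 1:(n - 1))
  x[up, ] + x[dn, ] + x[, up] + x[, dn] - 4 * x
}

fft_solve <- function(rhs, symbol) {
  Re(stats::fft(stats::fft(rhs) / symbol, inverse = TRUE)) / length(rhs)
}

#' One implicit-Euler step (reference implementation)
#'
#' Advances the stacked species fields by one backward-Euler step via the
#' fixed-point iteration
#' `v <- (I - h delta_i L)^{-1} (v_old + h f(v))`, each linear solve being
#' an FFT, an elementwise division by the species' symbol and an inverse
#' FFT.  The iteration stops when the relative Euclidean change of the
#' stacked state drops below `eps_inner`.  Works for any [kinetic_model()]
#' and is the cross-check for the compiled Gierer-Meinhardt path.
#'
#' @param field `n_r x n_r x N` array of species fields.
#' @param model a [kinetic_model()].
#' @param config a [sim_config()].
#' @param symbols optional precomputed list of per-species symbols.
#' @return list with the updated `field`, the number of inner iterations
#'   `inner`, and `diverged` (inner cap exceeded or non-finite values).
#' @export
implicit_step <- function(field, model, config, symbols = NULL) {
  n_r <- dim(field)[1]; N <- dim(field)[3]
  deff <- model$scale * model$diffusion_diag
  if (is.null(symbols))
    symbols <- lapply(deff, function(d) laplacian_symbol(n_r, config$h, d))
  old <- field
  v <- field
  for (l in seq_len(config$max_inner)) {
    rates <- apply_rates(v, model)
    vn <- v
    for (i in seq_len(N))
      vn[, , i] <- fft_solve(old[, , i] + config$h * rates[, , i], symbols[[i]])
    if (!all(is.finite(vn)))
      return(list(field = v, inner = l, diverged = TRUE))
    rel <- sqrt(sum((vn - v)^2)) / sqrt(sum(v^2))
    v <- vn
    if (rel <= config$eps_inner)
      return(list(field = v, inner = l, diverged = FALSE))
  }
  list(field = v, inner = config$max_inner, diverged = TRUE)
}

# evaluate reaction rates on a full field, species-last array in/out
apply_rates <- function(field, model) {
  d <- dim(field)
  flat <- matrix(field, ncol = d[3])
  out <- t(apply(flat, 1, model$reaction))
  if (d[3] == 1) out <- matrix(out, ncol = 1)
  array(out, dim = d)
}

#' Random initial condition around the homogeneous equilibrium
#'
#' Each species and grid point is drawn independently and uniformly from
#' `[0.9 u_i*, 1.1 u_i*]`; the draw is reproducible from `seed`.
#'
#' @param model a [kinetic_model()] with a computable equilibrium.
#' @param grid a [grid_spec()].
#' @param seed integer seed.
#' @param noise half-width of the relative perturbation (default 0.1).
#' @return `n_r x n_r x N` array.
#' @export
initial_condition <- function(model, grid, seed, noise = 0.1) {
  eq <- equilibrium(model)
  n <- grid$n_r; N <- model$n_species
  withr_seed(seed)
  field <- array(0, dim = c(n, n, N))
  for (i in seq_len(N))
    field[, , i] <- matrix(stats::runif(n * n, (1 - noise) * eq$u_star[i],
                                        (1 + noise) * eq$u_star[i]), n, n)
  field
}

# seeded draws: functions taking a seed reset the global RNG (Mersenne-Twister)
withr_seed <- function(seed) set.seed(as.integer(seed))

#' Simulate a reaction-diffusion pattern to steady state
#'
#' Integrates the system with the implicit-Euler/fixed-point/FFT scheme
#' until the steady-state criterion
#' `max |f(v) + delta L v| <= eps_outer` is met (checked every
#' `check_interval` time units) or `t_final` is reached.  A diverging inner
#' iteration halves the step size and retries the step.  Gierer-Meinhardt
#' models run in the compiled core; any other [kinetic_model()] uses the R
#' reference path.
#'
#' @param model a [kinetic_model()].
#' @param grid a [grid_spec()].
#' @param config a [sim_config()].
#' @param seed integer seed for the random initial condition (ignored when
#'   `init` is given).
#' @param init optional explicit initial field (`n_r x n_r x N`).
#' @param engine `"auto"` (compiled for GM, reference otherwise),
#'   `"compiled"`, or `"reference"`.
#' @return object of class `pattern`: list with `field`, `params`, `seed`,
#'   `t_end`, `converged`, `amplitude` (max - min of species 1) and
#'   `h_final`.
#' @examples
#' \donttest{
#' m <- gm_model(0.01, 1.2, 0.7, delta = 40, s = 1)
#' p <- simulate_pattern(m, grid_spec(32), sim_config(t_final = 200), seed = 1)
#' p$amplitude
#' }
#' @export
simulate_pattern <- function(model, grid, config = sim_config(), seed = 1,
                             init = NULL, engine = c("auto", "compiled", "reference")) {
  engine <- match.arg(engine)
  n_r <- grid$n_r
  t_final <- if (is.null(config$t_final)) default_t_final(n_r) else config$t_final
  if (is.null(init)) init <- initial_condition(model, grid, seed)
  stopifnot(dim(init)[1] == n_r, dim(init)[3] == model$n_species)

  is_gm <- identical(sort(names(model$params)), sort(c("a", "b", "c", "delta", "s")))
  use_cpp <- engine == "compiled" || (engine == "auto" && is_gm)
  deff <- model$scale * model$diffusion_diag

  if (use_cpp) {
    if (!is_gm) stop("compiled engine supports only Gierer-Meinhardt kinetics")
    p <- model$params
    out <- .gm_simulate_cpp(init[, , 1], init[, , 2],
                            p[["a"]], p[["b"]], p[["c"]],
                            deff[1], deff[2],
                            config$h, config$eps_inner, config$eps_outer,
                            config$check_interval, t_final,
                            config$max_inner, 1e-8)
    field <- array(c(out$u1, out$u2), dim = c(n_r, n_r, 2))
    t_end <- out$t_end; converged <- out$converged; h <- out$h_final
  } else {
    field <- init
    h <- config$h
    t_end <- 0; converged <- FALSE
    next_check <- config$check_interval
    cfg <- config
    symbols <- lapply(deff, function(d) laplacian_symbol(n_r, h, d))
    while (t_end < t_final - 1e-12 && !converged) {
      cfg$h <- h
      st <- implicit_step(field, model, cfg, symbols)
      if (st$diverged) {
        h <- h / 2
        if (h < 1e-8) stop("step size underflow after repeated halving")
        symbols <- lapply(deff, function(d) laplacian_symbol(n_r, h, d))
        next
      }
      field <- st$field
      t_end <- t_end + h
      if (t_end >= next_check - 1e-12) {
        next_check <- next_check + config$check_interval
        if (steady_state_residual(field, model) <= config$eps_outer)
          converged <- TRUE
      }
    }
  }

  structure(list(field = field, params = model$params, seed = seed,
                 t_end = t_end, converged = converged,
                 amplitude = max(field[, , 1]) - min(field[, , 1]),
                 h_final = h),
            class = "pattern")
}

#' Steady-state residual of a field
#'
#' Infinity norm of `f(v) + delta L v` over the stacked species.
#'
#' @param field `n_r x n_r x N` array.
#' @param model a [kinetic_model()].
#' @export
steady_state_residual <- function(field, model) {
  rates <- apply_rates(field, model)
  deff <- model$scale * model$diffusion_diag
  res <- 0
  for (i in seq_len(model$n_species))
    res <- max(res, max(abs(rates[, , i] + deff[i] * torus_laplacian(field[, , i]))))
  res
}

#' Step-size bound of the implicit scheme
#'
#' Minimum of the invertibility bound `1 / (max(delta) * lambda_max(L))` and
#' the root of `h L_f / (1 - h max(delta) lambda_max(L)) = 1`, with
#' `lambda_max(L) = 8` for the unit-weight torus stencil.  In practice the
#' integrator uses a fixed `h` with adaptive halving instead, because
#' Lipschitz estimates for saturating kinetics are very loose.
#'
#' @param model a [kinetic_model()].
#' @param L_f Lipschitz estimate for the reaction term (> 0).
#' @param lambda_max largest Laplacian eigenvalue (8 on the torus).
#' @return largest admissible step size.
#' @export
step_size_bound <- function(model, L_f, lambda_max = 8) {
  stopifnot(L_f > 0)
  dmax <- max(model$scale * model$diffusion_diag)
  inv_bound <- 1 / (dmax * lambda_max)
  # h L_f / (1 - h dmax lambda_max) = 1  =>  h = 1 / (L_f + dmax lambda_max)
  contraction <- 1 / (L_f + dmax * lambda_max)
  min(inv_bound, contraction)
}
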