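test_that("Laplacian symbol matches dense eigenvalues on a small torus", {
  n <- 4; h <- 0.2; delta <- 3
  sym <- laplacian_symbol(n, h, delta)
  expect_equal(sym[1, 1], 1)
  expect_equal(max(sym), 1 + 8 * h * delta)
  # dense I - h delta L with L the (negative) 5-point torus stencil
  m <- n * n
  L <- matrix(0, m, m)
  id <- function(i, j) (i - 1) %% n + 1 + (((j - 1) %% n) * n)
  for (i in 1:n) for (j in 1:n) {
    v <- id(i, j)
    L[v, v] <- -4
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)))
      L[v, id(i + d[1], j + d[2])] <- L[v, id(i + d[1], j + d[2])] + 1
  }
  ev <- sort(eigen(diag(m) - h * delta * L, only.values = TRUE)$values)
  expect_equal(ev, sort(as.vector(sym)), tolerance = 1e-10)
})

test_that("one FFT inner iterate equals the dense linear solve", {
  set.seed(5)
  n <- 8; h <- 0.2; delta <- 2
  v <- matrix(stats::runif(n * n, 0.5, 1.5), n)
  f <- matrix(stats::rnorm(n * n), n)
  # dense operator
  m <- n * n
  L <- matrix(0, m, m)
  id <- function(i, j) (i - 1) %% n + 1 + (((j - 1) %% n) * n)
  for (i in 1:n) for (j in 1:n) {
    vv <- id(i, j)
    L[vv, vv] <- -4
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)))
      L[vv, id(i + d[1], j + d[2])] <- L[vv, id(i + d[1], j + d[2])] + 1
  }
  rhs <- v + h * f
  dense <- solve(diag(m) - h * delta * L, as.vector(rhs))
  ffts <- turingfit:::fft_solve(rhs, laplacian_symbol(n, h, delta))
  expect_equal(as.vector(ffts), dense, tolerance = 1e-10)
})

test_that("pure diffusion conserves mass and zero diffusion is the identity", {
  null_model <- kinetic_model(1, function(u) 0, function(u) matrix(0, 1, 1),
                              diffusion_diag = 1, scale = 2)
  set.seed(1)
  n <- 12
  field <- array(stats::runif(n * n), dim = c(n, n, 1))
  cfg <- sim_config(h = 0.5, max_inner = 5)
  x <- field
  for (k in 1:1000) {
    x <- implicit_step(x, null_model, cfg)$field
    expect_equal(mean(x), mean(field), tolerance = 1e-10)
  }
  # delta = 0: the map is the identity for f = 0
  frozen <- kinetic_model(1, function(u) 0, function(u) matrix(0, 1, 1),
                          diffusion_diag = 0, scale = 1)
  y <- implicit_step(field, frozen, cfg)$field
  expect_equal(y, field, tolerance = 1e-14)
})

test_that("initial conditions stay within ten percent of equilibrium, reproducibly", {
  m <- gm_model(0.01, 1.2, 0.7, 40, 1)
  eq <- equilibrium(m)
  g <- grid_spec(32)
  f1 <- initial_condition(m, g, seed = 3)
  f2 <- initial_condition(m, g, seed = 3)
  expect_identical(f1, f2)
  for (i in 1:2) {
    expect_true(all(f1[, , i] >= 0.9 * eq$u_star[i]))
    expect_true(all(f1[, , i] <= 1.1 * eq$u_star[i]))
  }
  # sample mean within 3 standard errors of the uniform's mean
  big <- initial_condition(m, grid_spec(128), seed = 9)
  for (i in 1:2) {
    se <- 0.1 * eq$u_star[i] / sqrt(3 * 128^2)
    expect_lt(abs(mean(big[, , i]) - eq$u_star[i]), 3 * se)
  }
})

test_that("the homogeneous equilibrium is a fixed point of the simulation", {
  m <- gm_model(0.01, 1.2, 0.7, 40, 1)
  eq <- equilibrium(m)
  n <- 16
  init <- array(rep(eq$u_star, each = n * n), dim = c(n, n, 2))
  p <- simulate_pattern(m, grid_spec(n), sim_config(t_final = 200), init = init)
  expect_true(p$converged)
  expect_lte(p$t_end, 101)   # first steady-state check already passes
  expect_lt(max(abs(p$field - init)), 1e-8)
})

test_that("compiled and reference engines agree step by step", {
  m <- gm_model(0.02, 1, 0.5, 100, 0.25)
  g <- grid_spec(16)
  init <- initial_condition(m, g, seed = 4)
  cfg <- sim_config(t_final = 100, check_interval = 100)
  pc <- simulate_pattern(m, g, cfg, init = init, engine = "compiled")
  pr <- simulate_pattern(m, g, cfg, init = init, engine = "reference")
  expect_equal(pc$field, pr$field, tolerance = 1e-9)
  expect_equal(pc$t_end, pr$t_end)
})

test_that("cyclic shifts of the initial field shift the final field identically", {
  m <- gm_model(0.02, 1, 0.5, 100, 0.25)
  g <- grid_spec(16)
  init <- initial_condition(m, g, seed = 8)
  cfg <- sim_config(t_final = 50, check_interval = 50)
  base <- simulate_pattern(m, g, cfg, init = init)$field
  di <- 3; dj <- 7
  shifted_init <- init
  for (s in 1:2) shifted_init[, , s] <- shift_mat(init[, , s], di, dj)
  shifted <- simulate_pattern(m, g, cfg, init = shifted_init)$field
  for (s in 1:2)
    expect_equal(shifted[, , s], shift_mat(base[, , s], di, dj), tolerance = 1e-9)
})

test_that("steady-state residual of converged patterns meets the tolerance", {
  m <- gm_model(0.01, 1.2, 0.7, 40, 1)
  eq <- equilibrium(m)
  n <- 16
  init <- array(rep(eq$u_star, each = n * n), dim = c(n, n, 2))
  p <- simulate_pattern(m, grid_spec(n), sim_config(t_final = 300), init = init)
  expect_true(p$converged)
  expect_lte(steady_state_residual(p$field, m), 1e-6)
})

test_that("step-size bound reproduces the closed-form cases", {
  m1 <- kinetic_model(1, identity, function(u) matrix(1), 1, scale = 1)
  expect_equal(step_size_bound(m1, L_f = 1e-12), 1 / 8, tolerance = 1e-9)
  expect_equal(step_size_bound(m1, L_f = 1), 1 / 9)   # solve h/(1 - 8h) = 1
})
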