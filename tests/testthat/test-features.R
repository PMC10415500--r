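test_that("pattern-graph weights follow the mean-threshold rule", {
  # constant field: every node is >= its mean, all weights 1
  g <- pattern_graph(matrix(5, 6, 6))
  expect_true(all(g$w_right == 1) && all(g$w_down == 1))
  expect_equal(length(g$w_right) + length(g$w_down), 2 * 36)
  # checkerboard straddling the mean: every edge crosses
  cb <- outer(1:6, 1:6, function(i, j) ifelse((i + j) %% 2 == 0, 2, 0))
  g2 <- pattern_graph(cb, eps_w = 0.003)
  expect_true(all(g2$w_right == 0.003) && all(g2$w_down == 0.003))
  # half-and-half 4x4 field: exactly the vertical interfaces get eps
  f <- cbind(matrix(2, 4, 2), matrix(0, 4, 2))
  g3 <- pattern_graph(f, eps_w = 0.01)
  expect_equal(sum(g3$w_right == 0.01), 8)  # two interface columns (torus wrap)
  expect_true(all(g3$w_down == 1))
})

test_that("resistance matrix matches circuit theory and the pseudoinverse", {
  tri <- matrix(1, 3, 3) - diag(3)
  R <- resistance_matrix(tri)
  expect_equal(diag(R), rep(0, 3))
  expect_equal(R[1, 2], 2 / 3, tolerance = 1e-12)   # 1 || (1 + 1)
  expect_true(isSymmetric(unclass(R)))
  set.seed(10)
  for (rep in 1:5) {
    A <- random_weighted_graph(9)
    R <- resistance_matrix(A)
    L <- diag(rowSums(A)) - A
    Lp <- MASS::ginv(L)
    Rp <- outer(diag(Lp), diag(Lp), "+") - 2 * Lp
    expect_equal(unclass(R), Rp, tolerance = 1e-9, ignore_attr = TRUE)
  }
  expect_error(resistance_matrix(diag(0, 4)), "disconnected")
})

test_that("resistance is bounded by the resistive shortest path", {
  set.seed(11)
  for (rep in 1:20) {
    A <- random_weighted_graph(8)
    R <- resistance_matrix(A)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                             weighted = TRUE)
    D <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
    expect_true(all(R <= D + 1e-9))
  }
})

test_that("lowering the crossing weight never lowers any resistance", {
  set.seed(12)
  f <- matrix(stats::rnorm(64), 8)
  R1 <- resistance_matrix(pattern_graph(f, eps_w = 0.01))
  R2 <- resistance_matrix(pattern_graph(f, eps_w = 0.002))
  expect_true(all(R2 - R1 >= -1e-9))   # Rayleigh monotonicity
})

test_that("RDH is a normalized histogram and collapses correctly", {
  set.seed(13)
  f <- matrix(stats::rnorm(100), 10)
  g <- pattern_graph(f, eps_w = 0.1)
  res <- resistance_matrix(g)
  h <- rdh(res, grid_spec(10), r = 3, B = 12, R_max = max(res))
  expect_equal(sum(h$hist), 1)
  expect_true(all(h$hist >= 0))
  h1 <- rdh(res, grid_spec(10), r = 3, B = 1, R_max = max(res))
  expect_equal(h1$hist, 1)
  expect_error(rdh(res, grid_spec(10), r = 3, B = 12, R_max = 1e-12),
               "miscalibrated")
  # edge-transitive unit-weight torus: all radius-1 resistances equal
  cf <- matrix(1, 6, 6)
  rc <- resistance_matrix(pattern_graph(cf))
  hu <- rdh(rc, grid_spec(6), r = 1, B = 10, R_max = max(rc))
  expect_equal(sum(hu$hist == 1), 1)    # indicator vector on one bin
  vals <- collect_resistances(rc, grid_spec(6), r = 1)
  expect_lt(max(vals) - min(vals), 1e-10)
  expect_equal(length(vals), 4 * 36)    # four neighbours per source node
})

test_that("R_max calibration takes the maximal 99% quantile", {
  s1 <- 1:100; s2 <- seq(2, 200, by = 2)
  expect_equal(calibrate_rmax(list(s1)), stats::quantile(s1, 0.99, names = FALSE))
  q1 <- stats::quantile(s1, 0.99, names = FALSE)
  q2 <- stats::quantile(s2, 0.99, names = FALSE)
  expect_equal(calibrate_rmax(list(s1, s2)), max(q1, q2))
  set.seed(3)
  sets <- replicate(3, stats::rexp(500), simplify = FALSE)
  manual <- max(vapply(sets, function(v) {   # sort-based type-7 quantile
    x <- sort(v); h <- (length(x) - 1) * 0.99 + 1
    x[floor(h)] + (h - floor(h)) * (x[floor(h) + 1] - x[floor(h)])
  }, numeric(1)))
  expect_equal(calibrate_rmax(sets), manual, tolerance = 1e-12)
  expect_error(calibrate_rmax(list()), "no patterns")
})

test_that("maximal concentration picks the right-most qualifying peak", {
  expect_equal(max_concentration(matrix(5, 8, 8)), 5)
  # bimodal: half near 1, half near 3
  set.seed(4)
  v <- c(stats::rnorm(500, 1, 0.02), stats::rnorm(500, 3, 0.02))
  cm <- max_concentration(matrix(v, 40, 25))
  expect_lt(abs(cm - 3), (max(v) - min(v)) / 25)
  # a single outlying pixel fails the 1% peak floor
  f <- matrix(stats::rnorm(4096, 1, 0.01), 64)
  f[1, 1] <- 100
  expect_lt(abs(max_concentration(f) - 1), (100 - min(f)) / 25)
})

test_that("high-concentration component count matches constructed fields", {
  expect_equal(connected_components_feature(matrix(1, 8, 8)), 1)
  # two disjoint plateaus on a low background
  f <- matrix(0, 12, 12)
  f[2:4, 2:4] <- 2
  f[8:10, 8:10] <- 2
  expect_equal(connected_components_feature(f), 2)
  # a stripe wrapping around the torus stays one component
  s <- matrix(0, 10, 10)
  s[4:5, ] <- 2
  expect_equal(connected_components_feature(s), 1)
})

test_that("RDHs are invariant under shifts, rotations and range reflection", {
  p <- cached_pattern()
  f <- p$field[, , 1]
  n <- nrow(f)
  base_vals <- pattern_features(f, r = 8)
  R_max <- stats::quantile(base_vals, 0.99)
  base <- rdh_from_values(base_vals, r = 8, B = 12, R_max = R_max)$hist
  shifted <- pattern_features(shift_mat(f, 17, 5), r = 8)
  expect_equal(rdh_from_values(shifted, r = 8, B = 12, R_max = R_max)$hist,
               base, tolerance = 1e-10)
  rotated <- pattern_features(t(f[n:1, ]), r = 8)   # quarter turn
  expect_equal(rdh_from_values(rotated, r = 8, B = 12, R_max = R_max)$hist,
               base, tolerance = 1e-10)
  reflected <- pattern_features(2 * mean(f) - f, r = 8)
  expect_equal(rdh_from_values(reflected, r = 8, B = 12, R_max = R_max)$hist,
               base, tolerance = 1e-10)
  # the scalar features break the range-reflection symmetry by design
  expect_false(isTRUE(all.equal(max_concentration(f),
                                max_concentration(2 * mean(f) - f))))
})
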