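test_that("target normalisation divides by column maxima and round-trips", {
  Y <- cbind(a = c(1, 2, 4), b = c(3, 6, 12))
  nm <- normalize_targets(Y)
  expect_equal(unname(nm$Y[, 1]), c(0.25, 0.5, 1))
  expect_equal(unname(nm$maxima), c(4, 12))
  expect_equal(denormalize_targets(nm$Y, nm$maxima), unname(Y),
               ignore_attr = TRUE, tolerance = 1e-15)
  expect_equal(unname(normalize_targets(matrix(c(2, 5), 1))$Y[1, ]), c(1, 1))
  expect_error(normalize_targets(cbind(c(0, 0))), "positive maximum")
})

test_that("NRMSE matches hand arithmetic and is scale invariant", {
  expect_equal(nrmse(c(2, 4), c(2, 4)), 0)
  expect_equal(nrmse(c(1, 3), c(2, 4)), 1 / 3)
  set.seed(61)
  p <- matrix(stats::runif(20), 10); y <- matrix(stats::runif(20, 1, 2), 10)
  expect_equal(nrmse(p, y), nrmse(5.5 * p, 5.5 * y), tolerance = 1e-12)
  expect_error(nrmse(c(1), c(0)), "mean")
})

test_that("splits are disjoint, covering, sized 60/20/20 and seeded", {
  for (n in c(10, 100, 37)) {
    sp <- split_dataset(n, seed = 4)
    all_idx <- sort(c(sp$train, sp$validation, sp$test))
    expect_equal(all_idx, 1:n)
    expect_equal(length(sp$validation), floor(0.2 * n))
    expect_equal(length(sp$test), floor(0.2 * n))
  }
  expect_identical(split_dataset(50, seed = 7), split_dataset(50, seed = 7))
  expect_equal(lengths(split_dataset(10, seed = 1))[c("train", "validation", "test")],
               c(train = 6L, validation = 2L, test = 2L))
})

test_that("subset averaging matches the mean-predictor closed form", {
  set.seed(62)
  P <- 100
  X <- matrix(stats::runif(P * 3), P)
  Y <- matrix(stats::runif(P, 0.5, 1.5), P, 1)
  mean_predictor <- function(Xtr, Ytr, Xval, Yval, Xte)
    matrix(mean(Ytr), nrow(Xte), 1)
  res <- averaged_nrmse(X, Y, m = 20, mean_predictor, seed = 3)
  expect_equal(res$n_subsets, 5)
  # oracle recomputation of each subset's mean-predictor NRMSE
  withr_seed <- function(s) set.seed(as.integer(s))
  withr_seed(3)
  perm <- sample.int(P)
  manual <- vapply(1:5, function(i) {
    idx <- perm[(i - 1) * 20 + 1:20]
    sp <- split_dataset(20, seed = 3 + 1000 + i)
    mu <- mean(Y[idx[sp$train], ])
    truth <- Y[idx[sp$test], ]
    sqrt(mean((mu - truth)^2)) / mean(truth)
  }, numeric(1))
  expect_equal(res$nrmse, manual, tolerance = 1e-12)
  # m = P: a single run, no averaging
  res1 <- averaged_nrmse(X, Y, m = P, mean_predictor, seed = 3)
  expect_equal(res1$n_subsets, 1)
})

test_that("grid search selects the validation minimiser deterministically", {
  set.seed(63)
  Xtr <- matrix(stats::runif(40), 20, 2); Ytr <- matrix(Xtr[, 1])
  Xval <- matrix(stats::runif(20), 10, 2); Yval <- matrix(Xval[, 1])
  # fits "predict constant h$w * column means" -- only w = 1 is right
  grid <- data.frame(w = c(0.2, 1, 5))
  gs <- grid_search(Xtr, Ytr, Xval, Yval, grid,
                    fit = function(X, Y, h) h$w,
                    predict_fn = function(mod, X) matrix(mod * X[, 1]))
  expect_equal(gs$best$w, 1)
  # exhaustive oracle re-check
  manual <- vapply(grid$w, function(w) nrmse(matrix(w * Xval[, 1]), Yval),
                   numeric(1))
  expect_equal(gs$scores, manual)
  expect_equal(which.min(manual), 2L)
  # ties break to the first grid row
  tie <- grid_search(Xtr, Ytr, Xval, Yval, data.frame(w = c(1, 1)),
                     fit = function(X, Y, h) h$w,
                     predict_fn = function(mod, X) matrix(mod * X[, 1]))
  expect_equal(rownames(tie$best), "1")
  expect_error(grid_search(Xtr, Ytr, Xval, Yval, data.frame(w = 1),
                           fit = function(X, Y, h) stop("boom"),
                           predict_fn = function(mod, X) X), "failed")
})
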