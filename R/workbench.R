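#' Parameter sweep specification
#'
#' Each Gierer-Meinhardt parameter is either fixed (a scalar) or sampled
#' uniformly from a range (a length-2 vector).  Two sweeps recur
#' throughout: the single-parameter study `c ~ U[0, 1.15]` with
#' `a = 0.02, b = 1, delta = 100, s = 0.25`, and the four-parameter study
#' `a ~ U[0.01, 0.7], b ~ U[0.4, 2], c ~ U[0.02, 7], delta ~ U[20, 200]`
#' with `s = 0.4` assumed known.
#'
#' @param a,b,c,delta,s scalar (fixed) or length-2 range.
#' @param n_requested number of accepted parameter vectors.
#' @param n_r grid side for the simulations.
#' @param base_seed integer base seed; candidate draws, initial conditions
#'   and everything downstream derive from it.
#' @return object of class `sweep_spec`.
#' @export
sweep_spec <- function(a = 0.02, b = 1, c = c(0, 1.15), delta = 100,
                       s = 0.25, n_requested = 100, n_r = 64,
                       base_seed = 1) {
  structure(list(ranges = list(a = a, b = b, c = c, delta = delta, s = s),
                 n_requested = as.integer(n_requested),
                 n_r = as.integer(n_r),
                 base_seed = as.integer(base_seed)),
            class = "sweep_spec")
}

#' @rdname sweep_spec
#' @export
sweep_spec_4param <- function(n_requested = 100, n_r = 64, base_seed = 1) {
  sweep_spec(a = c(0.01, 0.7), b = c(0.4, 2), c = c(0.02, 7),
             delta = c(20, 200), s = 0.4,
             n_requested = n_requested, n_r = n_r, base_seed = base_seed)
}

draw_params <- function(ranges) {
  vapply(ranges, function(r) {
    if (length(r) == 1) r else stats::runif(1, r[1], r[2])
  }, numeric(1))
}

#' Generate a pattern dataset with Turing rejection
#'
#' Repeatedly samples parameter vectors from the sweep, discards those
#' without a Turing instability (linear stability test), simulates the
#' accepted ones to steady state and records the patterns.  Candidate
#' parameters are drawn from a single seeded stream; pattern `j` uses the
#' initial-condition seed `base_seed + j`, so the whole dataset is
#' reproducible from the sweep alone.
#'
#' @param sweep a [sweep_spec()].
#' @param config a [sim_config()].
#' @param max_draw_factor give up after `max_draw_factor * n_requested`
#'   candidate draws (guards against sweeps with no unstable region).
#' @param progress print one line per accepted pattern.
#' @return manifest: list with `patterns` (list of `pattern`), `params`
#'   (accepted matrix), `seeds`, `converged`, `amplitude`, `n_draws` and
#'   the sweep.
#' @export
generate_dataset <- function(sweep, config = sim_config(),
                             max_draw_factor = 10, progress = FALSE) {
  n_req <- sweep$n_requested
  stopifnot(n_req >= 1)
  max_draws <- max_draw_factor * n_req
  withr_seed(sweep$base_seed)
  candidates <- t(vapply(seq_len(max_draws), function(i) draw_params(sweep$ranges),
                         numeric(5)))
  colnames(candidates) <- names(sweep$ranges)
  grid <- grid_spec(sweep$n_r)
  patterns <- vector("list", n_req)
  accepted <- matrix(0, n_req, 5, dimnames = list(NULL, colnames(candidates)))
  n_acc <- 0
  for (i in seq_len(max_draws)) {
    p <- candidates[i, ]
    model <- gm_model(p[["a"]], p[["b"]], p[["c"]], p[["delta"]], p[["s"]])
    ok <- tryCatch(is_turing_unstable(model)$unstable, error = function(e) FALSE)
    if (!ok) next
    n_acc <- n_acc + 1
    pat <- simulate_pattern(model, grid, config, seed = sweep$base_seed + n_acc)
    patterns[[n_acc]] <- pat
    accepted[n_acc, ] <- p
    if (progress)
      message(sprintf("pattern %d/%d (draw %d): amplitude %.3g", n_acc, n_req,
                      i, pat$amplitude))
    if (n_acc == n_req) break
  }
  if (n_acc < n_req)
    stop("only ", n_acc, " of ", n_req, " parameter vectors accepted within ",
         max_draws, " draws; the sweep may have no Turing-unstable region")
  list(patterns = patterns, params = accepted,
       seeds = sweep$base_seed + seq_len(n_req),
       converged = vapply(patterns, `[[`, logical(1), "converged"),
       amplitude = vapply(patterns, `[[`, numeric(1), "amplitude"),
       n_draws = i, sweep = sweep)
}

#' Featurise a pattern dataset
#'
#' Two-pass batch featurisation: first the resistance value multisets of
#' all patterns are collected and the shared histogram edge `R_max` is
#' calibrated (99% quantile rule, [calibrate_rmax()]), then every pattern
#' is binned into its RDH; optional scalar features (maximal concentration
#' `c_m`, high-component count `n_c`) are appended as extra columns.
#'
#' @param manifest output of [generate_dataset()].
#' @param r RDH radius.
#' @param t undersampling factor.
#' @param B bin count.
#' @param eps_w crossing-edge weight.
#' @param R_max histogram edge; calibrated from the batch when `NULL`.
#' @param extras character subset of `c("cm", "nc")`.
#' @param progress print a line per pattern.
#' @return list with `features` (matrix, `B` histogram columns plus
#'   extras), `R_max`, and the feature configuration.
#' @export
featurize_dataset <- function(manifest, r = 8, t = 1, B = 12,
                              eps_w = 0.003, R_max = NULL,
                              extras = character(0), progress = FALSE) {
  pats <- manifest$patterns
  n <- length(pats)
  value_sets <- vector("list", n)
  for (i in seq_len(n)) {
    value_sets[[i]] <- pattern_features(pats[[i]], r = r, t = t, B = B,
                                        R_max = NULL, eps_w = eps_w)
    if (progress) message("collected resistances for pattern ", i, "/", n)
  }
  if (is.null(R_max)) R_max <- calibrate_rmax(value_sets)
  H <- t(vapply(value_sets, function(v)
    rdh_from_values(v, r = r, t = t, B = B, R_max = R_max)$hist, numeric(B)))
  colnames(H) <- paste0("bin", seq_len(B))
  if ("cm" %in% extras)
    H <- cbind(H, cm = vapply(pats, function(p) max_concentration(p$field[, , 1]),
                              numeric(1)))
  if ("nc" %in% extras)
    H <- cbind(H, nc = vapply(pats, function(p)
      connected_components_feature(p$field[, , 1]), numeric(1)))
  list(features = H, R_max = R_max,
       config = list(r = r, t = t, B = B, eps_w = eps_w, extras = extras))
}

#' Grid-searched SVR train/predict closure
#'
#' Builds the `(gamma, lambda)` grid-search training function consumed by
#' [averaged_nrmse()]: Wasserstein(-family) kernel SVR per target column,
#' hyperparameters selected on the validation split.
#'
#' @param family input-kernel family.
#' @param gamma_grid,lambda_grid hyperparameter grids
#'   (see [default_grids()]).
#' @param epsilon SVR tube half-width (on normalised targets).
#' @param B number of leading feature columns forming the histogram; the
#'   kernel is evaluated on these columns only (defaults to all columns).
#' @return function `(Xtr, Ytr, Xval, Yval, Xte) -> predictions`.
#' @export
svr_train_predict <- function(family = "wasserstein",
                              gamma_grid = default_grids()$gamma,
                              lambda_grid = default_grids()$lambda,
                              epsilon = 0.01, B = NULL) {
  function(Xtr, Ytr, Xval, Yval, Xte) {
    Bi <- if (is.null(B)) ncol(Xtr) else B
    cols <- seq_len(Bi)
    Ytr <- as.matrix(Ytr); Yval <- as.matrix(Yval)
    grid <- expand.grid(gamma = gamma_grid, lambda = lambda_grid)
    if (family == "chi2") grid <- expand.grid(gamma = NA_real_, lambda = lambda_grid)
    preds <- matrix(0, nrow(Xte), ncol(Ytr))
    for (j in seq_len(ncol(Ytr))) {
      gs <- grid_search(
        Xtr[, cols, drop = FALSE], Ytr[, j], Xval[, cols, drop = FALSE],
        Yval[, j, drop = FALSE], grid,
        fit = function(X, y, hyper) {
          spec <- if (family == "chi2") kernel_spec("chi2")
                  else kernel_spec(family, gamma = hyper$gamma)
          svr_fit(X, as.numeric(y), spec, lam = hyper$lambda, epsilon = epsilon)
        },
        predict_fn = function(model, X) predict_svr(model, X[, seq_len(Bi), drop = FALSE]))
      preds[, j] <- predict_svr(gs$model, Xte[, cols, drop = FALSE])
    }
    preds
  }
}

#' Run a complete learning experiment
#'
#' Orchestrates dataset generation, featurisation, target normalisation,
#' subset splitting/averaging and grid-searched training for one method,
#' and reports the mean test NRMSE together with the trivial
#' mean-predictor baseline.
#'
#' @param sweep a [sweep_spec()].
#' @param targets character vector of parameter names to predict.
#' @param method `"svr"`, `"ovk"` or `"ffnn"`.
#' @param m training-set (subset) size.
#' @param r,B,eps_w feature configuration.
#' @param config a [sim_config()].
#' @param seed seed of the evaluation protocol (subsets/splits; the
#'   dataset itself derives from `sweep$base_seed`).
#' @param manifest optionally reuse a previously generated dataset.
#' @param hidden hidden widths when `method = "ffnn"`.
#' @param steps,patience FFNN schedule override (defaults to
#'   [ffnn_schedule()] for the subset's training size).
#' @return report list with `mean_nrmse`, per-subset values, the baseline
#'   NRMSE, and the manifest/features for reuse.
#' @export
run_experiment <- function(sweep, targets = "c", method = c("svr", "ovk", "ffnn"),
                           m = 20, r = 8, B = 12, eps_w = 0.003,
                           config = sim_config(), seed = 1,
                           manifest = NULL, hidden = c(16),
                           steps = NULL, patience = NULL) {
  method <- match.arg(method)
  if (is.null(manifest)) manifest <- generate_dataset(sweep, config)
  feats <- featurize_dataset(manifest, r = r, B = B, eps_w = eps_w)
  Y <- manifest$params[, targets, drop = FALSE]
  norm <- normalize_targets(Y)
  grids <- default_grids()

  tp <- switch(method,
    svr = svr_train_predict(),
    ovk = function(Xtr, Ytr, Xval, Yval, Xte) {
      grid <- expand.grid(gamma = grids$gamma, gamma_out = grids$gamma_out,
                          lambda = grids$lambda)
      gs <- grid_search(Xtr, Ytr, Xval, Yval, grid,
        fit = function(X, Yt, hyper)
          ovk_fit(X, Yt, kernel_spec("wasserstein", gamma = hyper$gamma),
                  gamma_out = hyper$gamma_out, lam = hyper$lambda),
        predict_fn = predict_ovk)
      predict_ovk(gs$model, Xte)
    },
    ffnn = function(Xtr, Ytr, Xval, Yval, Xte) {
      sched <- ffnn_schedule(nrow(Xtr))
      cfg <- ffnn_config(max_steps = if (is.null(steps)) sched[["max_steps"]] else steps,
                         patience = if (is.null(patience)) sched[["patience"]] else patience,
                         seed = seed)
      fit <- train_ffnn(Xtr, Ytr, Xval, Yval, hidden = hidden, config = cfg)
      predict_ffnn(fit, Xte)
    })

  res <- averaged_nrmse(feats$features, norm$Y, m = m, train_predict = tp,
                        seed = seed)
  baseline <- averaged_nrmse(feats$features, norm$Y, m = m,
                             train_predict = function(Xtr, Ytr, Xval, Yval, Xte)
                               matrix(colMeans(as.matrix(Ytr)), nrow(Xte),
                                      ncol(as.matrix(Ytr)), byrow = TRUE),
                             seed = seed)
  list(method = method, targets = targets, m = m,
       mean_nrmse = res$mean_nrmse, nrmse = res$nrmse,
       baseline_nrmse = baseline$mean_nrmse,
       R_max = feats$R_max, manifest = manifest, features = feats)
}
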