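#' Feedforward network specification
#'
#' Architectures are written by their hidden widths, e.g. `c(10, 20, 5)`;
#' `integer(0)` denotes a purely affine map (no hidden layers).  All
#' hidden layers use ReLU activations, the output layer is linear.
#'
#' @param input_dim input dimension.
#' @param hidden integer vector of hidden-layer widths (possibly empty).
#' @param output_dim output dimension.
#' @return object of class `ffnn_spec`.
#' @export
ffnn_spec <- function(input_dim, hidden = integer(0), output_dim = 1) {
  stopifnot(input_dim >= 1, output_dim >= 1, all(hidden >= 1))
  structure(list(input_dim = as.integer(input_dim),
                 hidden = as.integer(hidden),
                 output_dim = as.integer(output_dim)),
            class = "ffnn_spec")
}

#' Initialise network weights
#'
#' He-scaled Gaussian weights and zero biases, reproducible from `seed`.
#'
#' @param spec an [ffnn_spec()].
#' @param seed integer seed.
#' @return list of layers, each with matrices `W` and bias vectors `b`;
#'   the last layer is the linear output layer.
#' @export
ffnn_init <- function(spec, seed = 1) {
  withr_seed(seed)
  dims <- c(spec$input_dim, spec$hidden, spec$output_dim)
  lapply(seq_len(length(dims) - 1), function(j) {
    fan_in <- dims[j]
    list(W = matrix(stats::rnorm(dims[j + 1] * fan_in, sd = sqrt(2 / fan_in)),
                    dims[j + 1], fan_in),
         b = numeric(dims[j + 1]))
  })
}

#' Forward pass of a feedforward network
#'
#' Hidden layers compute `ReLU(W x + b)`, the final layer is affine.
#'
#' @param weights layer list from [ffnn_init()] (or trained weights).
#' @param X input matrix, one sample per row.
#' @return output matrix, one row per sample.
#' @export
ffnn_forward <- function(weights, X) {
  A <- t(as.matrix(X))
  L <- length(weights)
  for (j in seq_len(L)) {
    A <- weights[[j]]$W %*% A + weights[[j]]$b
    if (j < L) A <- pmax(A, 0)
  }
  t(A)
}

# forward with cached pre-activations, then backprop of the MSE gradient
ffnn_grad <- function(weights, X, Y) {
  Xt <- t(X); n <- ncol(Xt)
  L <- length(weights)
  acts <- vector("list", L + 1)
  acts[[1]] <- Xt
  for (j in seq_len(L)) {
    Z <- weights[[j]]$W %*% acts[[j]] + weights[[j]]$b
    acts[[j + 1]] <- if (j < L) pmax(Z, 0) else Z
  }
  delta <- 2 * (acts[[L + 1]] - t(Y)) / (n * nrow(acts[[L + 1]]))
  grads <- vector("list", L)
  for (j in L:1) {
    grads[[j]] <- list(W = delta %*% t(acts[[j]]), b = rowSums(delta))
    if (j > 1) {
      delta <- t(weights[[j]]$W) %*% delta
      delta[acts[[j]] <= 0] <- 0           # ReLU mask
    }
  }
  grads
}

#' Training configuration for feedforward networks
#'
#' The step/patience schedule follows the protocol used for the study's
#' dataset sizes: `(4e5, 1e5)` for 20-50 points, `(2e5, 5e4)` for
#' 100-2000, `(1e5, 2e4)` for 5000 and beyond; one step is one minibatch
#' update of batch size 32.
#'
#' @param max_steps total training steps `T_f`.
#' @param patience early-stopping patience `T_e` (steps without validation
#'   improvement).
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param eval_every validation-evaluation period in steps.
#' @param seed integer seed for initialisation and batch sampling.
#' @return object of class `ffnn_config`.
#' @export
ffnn_config <- function(max_steps = 2e5, patience = 5e4, batch_size = 32,
                        lr = 1e-3, eval_every = 50, seed = 1) {
  stopifnot(patience < max_steps, batch_size >= 1, lr > 0)
  structure(list(max_steps = max_steps, patience = patience,
                 batch_size = batch_size, lr = lr, eval_every = eval_every,
                 seed = seed),
            class = "ffnn_config")
}

#' @rdname ffnn_config
#' @param n_train training-set size used to pick the published schedule.
#' @export
ffnn_schedule <- function(n_train) {
  if (n_train <= 50) c(max_steps = 4e5, patience = 1e5)
  else if (n_train < 5000) c(max_steps = 2e5, patience = 5e4)
  else c(max_steps = 1e5, patience = 2e4)
}

#' Train a feedforward network with Adam and early stopping
#'
#' Minimises the mean squared error by minibatch Adam; the validation loss
#' is evaluated every `eval_every` steps and the weight snapshot with the
#' lowest validation loss along the trajectory is returned.  Training
#' stops early when the validation loss has not improved for `patience`
#' steps.  Inputs are standardised per feature with training-split
#' statistics inside the returned predictor.
#'
#' @param X,Y training inputs/targets (matrices, one sample per row).
#' @param Xval,Yval validation split.
#' @param hidden hidden-layer widths (see [ffnn_spec()]).
#' @param config an [ffnn_config()].
#' @return object of class `ffnn_fit` with the best `weights`,
#'   `val_loss`, input standardisation and the architecture.
#' @export
train_ffnn <- function(X, Y, Xval, Yval, hidden = integer(0),
                       config = ffnn_config()) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  Xval <- as.matrix(Xval); Yval <- as.matrix(Yval)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd); sdv[sdv < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  Xvs <- sweep(sweep(Xval, 2, mu), 2, sdv, "/")

  spec <- ffnn_spec(ncol(X), hidden, ncol(Y))
  w <- ffnn_init(spec, seed = config$seed)
  mth <- rapply(w, function(x) x * 0, how = "replace")  # Adam moments
  vth <- mth
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  n <- nrow(Xs)

  val_loss <- function(w) mean((ffnn_forward(w, Xvs) - Yval)^2)
  best <- list(w = w, loss = val_loss(w), step = 0)

  for (step in seq_len(config$max_steps)) {
    idx <- sample.int(n, min(config$batch_size, n), replace = n < config$batch_size)
    g <- ffnn_grad(w, Xs[idx, , drop = FALSE], Y[idx, , drop = FALSE])
    for (j in seq_along(w)) {
      for (nm in c("W", "b")) {
        mth[[j]][[nm]] <- b1 * mth[[j]][[nm]] + (1 - b1) * g[[j]][[nm]]
        vth[[j]][[nm]] <- b2 * vth[[j]][[nm]] + (1 - b2) * g[[j]][[nm]]^2
        mhat <- mth[[j]][[nm]] / (1 - b1^step)
        vhat <- vth[[j]][[nm]] / (1 - b2^step)
        w[[j]][[nm]] <- w[[j]][[nm]] - config$lr * mhat / (sqrt(vhat) + eps)
      }
    }
    if (!all(vapply(w, function(l) all(is.finite(l$W)) && all(is.finite(l$b)),
                    logical(1))))
      stop("training diverged (non-finite weights)")
    if (step %% config$eval_every == 0) {
      loss <- val_loss(w)
      if (loss < best$loss) best <- list(w = w, loss = loss, step = step)
      if (step - best$step >= config$patience) break
    }
  }
  structure(list(weights = best$w, val_loss = best$loss,
                 best_step = best$step, spec = spec,
                 center = mu, scale = sdv),
            class = "ffnn_fit")
}

#' Predict with a trained feedforward network
#'
#' @param object an `ffnn_fit`.
#' @param newX input matrix.
#' @return prediction matrix.
#' @export
predict_ffnn <- function(object, newX) {
  Xs <- sweep(sweep(as.matrix(newX), 2, object$center), 2, object$scale, "/")
  ffnn_forward(object$weights, Xs)
}

#' @export
predict.ffnn_fit <- function(object, newdata, ...) predict_ffnn(object, newdata)
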