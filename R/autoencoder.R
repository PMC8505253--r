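# Fully connected autoencoder, implemented in vectorised matrix algebra.
# The encoder follows a halving layer schedule down to a d-dimensional
# bottleneck; the decoder mirrors it. Training minimises reconstruction MSE
# with Adam on minibatches; all randomness (init, batch order) is governed by
# a single seed, so training is bit-reproducible on a given platform.

#' Layer schedule for the stacked autoencoder
#'
#' For 2175 input voxels the encoder is `2175-2048-1024-512-256-128-64-32-d`.
#' In general the hidden sizes start at the largest power of two strictly
#' below the input dimension and halve down to 32 (stopping early if the next
#' halving would be no larger than `d`), followed by the bottleneck `d`.
#'
#' @param input_dim number of input features.
#' @param d bottleneck dimension, `1 <= d < input_dim`.
#' @return Integer vector of strictly decreasing layer sizes, starting at
#'   `input_dim` and ending at `d`.
#' @export
#' @examples
#' build_layer_schedule(2175, 5)
#' build_layer_schedule(300, 3)
build_layer_schedule <- function(input_dim, d) {
  input_dim <- as.integer(input_dim)
  d <- as.integer(d)
  if (d < 1 || d >= input_dim) {
    abort("need 1 <= d < input_dim")
  }
  sizes <- input_dim
  cur <- as.integer(2^floor(log2(input_dim - 1e-9)))
  if (cur >= input_dim) cur <- cur %/% 2L
  while (cur > d) {
    sizes <- c(sizes, cur)
    nxt <- cur %/% 2L
    if (nxt < 32L || nxt <= d) break
    cur <- nxt
  }
  c(sizes, d)
}

ae_activations <- function(schedule, activation) {
  # per-layer activation over encoder+decoder transitions; bottleneck and
  # output layers are linear, hidden layers use `activation`
  n_enc <- length(schedule) - 1L
  n_all <- 2L * n_enc
  acts <- rep(activation, n_all)
  acts[n_enc] <- "linear"
  acts[n_all] <- "linear"
  acts
}

ae_forward <- function(params, X, acts) {
  A <- list(X)
  for (l in seq_along(params$W)) {
    Z <- A[[l]] %*% params$W[[l]]
    Z <- sweep(Z, 2, params$b[[l]], "+")
    A[[l + 1]] <- if (acts[l] == "relu") pmax(Z, 0) else Z
  }
  A
}

ae_backward <- function(params, A, X, acts) {
  L <- length(params$W)
  dW <- vector("list", L)
  db <- vector("list", L)
  dA <- 2 * (A[[L + 1]] - X) / length(X)
  for (l in rev(seq_len(L))) {
    dZ <- if (acts[l] == "relu") dA * (A[[l + 1]] > 0) else dA
    dW[[l]] <- crossprod(A[[l]], dZ)
    db[[l]] <- colSums(dZ)
    if (l > 1) dA <- tcrossprod(dZ, params$W[[l]])
  }
  list(W = dW, b = db)
}

ae_init <- function(dims, acts) {
  L <- length(dims) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    fan_in <- dims[l]
    sd <- if (acts[l] == "relu") sqrt(2 / fan_in) else sqrt(1 / fan_in)
    W[[l]] <- matrix(stats::rnorm(fan_in * dims[l + 1], sd = sd),
      fan_in, dims[l + 1])
    b[[l]] <- numeric(dims[l + 1])
  }
  list(W = W, b = b)
}

ae_mse <- function(params, X, acts) {
  A <- ae_forward(params, X, acts)
  mean((A[[length(A)]] - X)^2)
}

#' Train an autoencoder on a feature matrix
#'
#' Compresses a subjects-by-voxels matrix to `d` dimensions through a
#' symmetric encoder/decoder pair following [build_layer_schedule()]. Hidden
#' layers use ReLU (configurable), the bottleneck and output layers are
#' linear. Features are z-scored per column before training by default and
#' the stored transform is re-applied at encode time. The loss is the mean
#' squared reconstruction error, minimised with Adam; the epoch-wise loss
#' trace is recorded, and the returned weights are the checkpoint with the
#' lowest full-data MSE (so the final recorded MSE never exceeds the initial
#' one).
#'
#' @param features numeric matrix (subjects x features), e.g. a
#'   `feature_matrix`.
#' @param d bottleneck dimension.
#' @param layer_sizes optional explicit schedule (from `input_dim` to `d`).
#' @param activation `"relu"` (default) or `"linear"` for the hidden layers.
#' @param epochs,batch_size,learning_rate Adam training hyperparameters
#'   (`epochs` is an upper bound when early stopping is active).
#' @param patience early-stopping patience: stop when the full-data MSE has
#'   not improved by a relative `rel_tol` for this many epochs (0 disables).
#' @param rel_tol relative improvement counted as progress (default 1e-4).
#' @param seed RNG seed controlling initialisation and batch order.
#' @param standardize z-score columns before training.
#' @param on_constant `"error"` (default) or `"drop"`: what to do with
#'   zero-variance columns when standardizing.
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference
#'   implementation in plain matrix algebra).
#' @return An object of class `autoencoder` with the latent matrix
#'   (`$latent`), loss trace, stored transform and weights.
#' @export
train_autoencoder <- function(features, d, layer_sizes = NULL,
                              activation = c("relu", "linear"),
                              epochs = 200, batch_size = 32,
                              learning_rate = 1e-3, patience = 10,
                              rel_tol = 0.01, seed = 1L,
                              standardize = TRUE,
                              on_constant = c("error", "drop"),
                              engine = c("cpp", "r")) {
  activation <- match.arg(activation)
  on_constant <- match.arg(on_constant)
  engine <- match.arg(engine)
  stopifnot(epochs >= 1, batch_size >= 1)
  X <- unclass(features)
  if (!is.matrix(X) || nrow(X) == 0 || ncol(X) == 0) {
    abort("features must be a non-empty numeric matrix")
  }
  n_raw <- ncol(X)
  keep_cols <- seq_len(ncol(X))
  center <- rep(0, ncol(X))
  scale <- rep(1, ncol(X))
  if (standardize) {
    center <- colMeans(X)
    scale <- apply(X, 2, stats::sd)
    const <- scale < 1e-12
    if (any(const)) {
      if (on_constant == "error") {
        abort(paste0(sum(const), " constant feature columns; set ",
          "on_constant = \"drop\" or standardize = FALSE"))
      }
      keep_cols <- which(!const)
      X <- X[, keep_cols, drop = FALSE]
      center <- center[keep_cols]
      scale <- scale[keep_cols]
    }
    X <- sweep(sweep(X, 2, center, "-"), 2, scale, "/")
  }
  if (is.null(layer_sizes)) layer_sizes <- build_layer_schedule(ncol(X), d)
  if (layer_sizes[1] != ncol(X) || layer_sizes[length(layer_sizes)] != d ||
    any(diff(layer_sizes) > 0)) {
    abort("layer_sizes must be non-increasing from ncol(features) to d")
  }
  dims <- c(layer_sizes, rev(layer_sizes)[-1])
  acts <- ae_activations(layer_sizes, activation)

  set.seed(seed)
  if (engine == "cpp") {
    fit <- .ae_train_cpp(X, as.integer(dims), as.integer(acts == "relu"),
      as.integer(epochs), as.integer(batch_size), learning_rate,
      as.integer(patience), rel_tol)
    if (!is.null(fit$error)) {
      abort(paste0("non-finite loss at epoch ", fit$error,
        "; try a lower learning_rate"))
    }
    best_params <- list(W = fit$W, b = fit$b)
    n_enc <- length(layer_sizes) - 1L
    latent <- ae_forward(best_params, X, acts)[[n_enc + 1L]]
    rownames(latent) <- rownames(features)
    colnames(latent) <- paste0("dim_", seq_len(d))
    return(structure(
      list(
        latent = latent, d = d, seed = seed,
        schedule = layer_sizes, activation = activation,
        params = best_params, acts = acts, n_enc = n_enc,
        center = center, scale = scale, keep_cols = keep_cols,
        standardize = standardize, input_dim_raw = n_raw,
        n_input = ncol(X),
        initial_mse = fit$initial_mse, final_mse = fit$final_mse,
        loss_trace = tibble(epoch = 0:fit$epochs_run,
          mse = c(fit$initial_mse, fit$trace))
      ),
      class = "autoencoder"
    ))
  }

  params <- ae_init(dims, acts)
  adam <- list(
    mW = lapply(params$W, function(w) w * 0),
    vW = lapply(params$W, function(w) w * 0),
    mb = lapply(params$b, function(b) b * 0),
    vb = lapply(params$b, function(b) b * 0),
    t = 0
  )
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8

  n <- nrow(X)
  initial_mse <- ae_mse(params, X, acts)
  best_mse <- initial_mse
  best_params <- params
  best_epoch <- 0L
  trace <- numeric(epochs)
  last_epoch <- 0L
  for (epoch in seq_len(epochs)) {
    ord <- sample.int(n)
    starts <- seq(1, n, by = batch_size)
    for (s in starts) {
      rows <- ord[s:min(s + batch_size - 1, n)]
      Xb <- X[rows, , drop = FALSE]
      A <- ae_forward(params, Xb, acts)
      grads <- ae_backward(params, A, Xb, acts)
      adam$t <- adam$t + 1
      c1 <- 1 - beta1^adam$t
      c2 <- 1 - beta2^adam$t
      for (l in seq_along(params$W)) {
        adam$mW[[l]] <- beta1 * adam$mW[[l]] + (1 - beta1) * grads$W[[l]]
        adam$vW[[l]] <- beta2 * adam$vW[[l]] + (1 - beta2) * grads$W[[l]]^2
        params$W[[l]] <- params$W[[l]] - learning_rate *
          (adam$mW[[l]] / c1) / (sqrt(adam$vW[[l]] / c2) + eps)
        adam$mb[[l]] <- beta1 * adam$mb[[l]] + (1 - beta1) * grads$b[[l]]
        adam$vb[[l]] <- beta2 * adam$vb[[l]] + (1 - beta2) * grads$b[[l]]^2
        params$b[[l]] <- params$b[[l]] - learning_rate *
          (adam$mb[[l]] / c1) / (sqrt(adam$vb[[l]] / c2) + eps)
      }
    }
    trace[epoch] <- ae_mse(params, X, acts)
    if (!is.finite(trace[epoch])) {
      abort(paste0("non-finite loss at epoch ", epoch,
        "; try a lower learning_rate"))
    }
    if (trace[epoch] < best_mse * (1 - rel_tol)) best_epoch <- epoch
    if (trace[epoch] < best_mse) {
      best_mse <- trace[epoch]
      best_params <- params
    }
    last_epoch <- epoch
    if (patience > 0 && epoch - best_epoch >= patience) break
  }
  trace <- trace[seq_len(last_epoch)]

  n_enc <- length(layer_sizes) - 1L
  A <- ae_forward(best_params, X, acts)
  latent <- A[[n_enc + 1L]]
  rownames(latent) <- rownames(features)
  colnames(latent) <- paste0("dim_", seq_len(d))
  structure(
    list(
      latent = latent, d = d, seed = seed,
      schedule = layer_sizes, activation = activation,
      params = best_params, acts = acts, n_enc = n_enc,
      center = center, scale = scale, keep_cols = keep_cols,
      standardize = standardize, input_dim_raw = n_raw,
      n_input = ncol(X),
      initial_mse = initial_mse, final_mse = best_mse,
      loss_trace = tibble(epoch = 0:last_epoch, mse = c(initial_mse, trace))
    ),
    class = "autoencoder"
  )
}

#' @export
print.autoencoder <- function(x, ...) {
  cat(sprintf(
    "<autoencoder> schedule %s, seed %d, MSE %.4g -> %.4g over %d epochs\n",
    paste(x$schedule, collapse = "-"), x$seed, x$initial_mse, x$final_mse,
    nrow(x$loss_trace) - 1))
  invisible(x)
}

#' Encode subjects into the latent space of a trained autoencoder
#'
#' Deterministic forward pass through the encoder half, applying the
#' training-time standardization first.
#'
#' @param model a trained `autoencoder`.
#' @param features matrix with the same columns the model was trained on.
#' @return Subjects x d latent matrix.
#' @export
encode <- function(model, features) {
  stopifnot(inherits(model, "autoencoder"))
  X <- unclass(features)
  if (!is.matrix(X)) X <- as.matrix(X)
  if (model$standardize) {
    if (ncol(X) != model$input_dim_raw && ncol(X) != model$n_input) {
      abort(sprintf("feature count mismatch: model expects %d columns, got %d",
        model$input_dim_raw, ncol(X)))
    }
    if (ncol(X) == model$input_dim_raw && length(model$keep_cols) < ncol(X)) {
      X <- X[, model$keep_cols, drop = FALSE]
    }
    X <- sweep(sweep(X, 2, model$center, "-"), 2, model$scale, "/")
  } else if (ncol(X) != model$n_input) {
    abort(sprintf("feature count mismatch: model expects %d columns, got %d",
      model$n_input, ncol(X)))
  }
  A <- ae_forward(model$params, X, model$acts)
  latent <- A[[model$n_enc + 1L]]
  rownames(latent) <- rownames(features)
  colnames(latent) <- paste0("dim_", seq_len(model$d))
  latent
}

#' @export
predict.autoencoder <- function(object, newdata, ...) {
  encode(object, newdata)
}

#' Train the family of per-dimension autoencoders
#'
#' Trains one independent autoencoder per target dimension `d` (default
#' `2:10`, giving the nine low-dimensional representations that feed the
#' clustering ensemble), each with its own seed.
#'
#' @param features subjects x voxels matrix.
#' @param d_range bottleneck dimensions.
#' @param seeds integer vector, one per `d` (default derived from `seed`).
#' @param seed master seed used when `seeds` is NULL.
#' @param ... passed to [train_autoencoder()].
#' @return Named list of `autoencoder` objects (`"d2"`, `"d3"`, ...).
#' @export
train_embeddings <- function(features, d_range = 2:10, seeds = NULL,
                             seed = 1L, ...) {
  if (is.null(seeds)) seeds <- derive_seeds(seed, length(d_range))
  stopifnot(length(seeds) == length(d_range))
  models <- purrr::map2(d_range, seeds, function(d, s) {
    train_autoencoder(features, d = d, seed = s, ...)
  })
  names(models) <- paste0("d", d_range)
  models
}
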