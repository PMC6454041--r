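# Autoencoder dimensionality reduction.
#
# An encoder maps each n-dimensional gene vector x to an m-dimensional code
# y (m < n); a decoder mirroring the encoder widths maps y back to a
# reconstruction z. Both are trained jointly by mini-batch gradient descent
# on the mean squared reconstruction error ||x - z||^2. The code-layer
# output is the reduced representation fed to the classifier.

#' Autoencoder hyperparameters
#'
#' @param layer_sizes integer vector of encoder widths from the input width
#'   n down to the code width m, strictly decreasing (default `c(512, 200)`:
#'   a single code layer).
#' @param activation hidden-layer nonlinearity: one of `"sigmoid"`,
#'   `"identity"`, `"relu"`, `"tanh"` (output layer is always identity).
#' @param epochs training epochs (default 200).
#' @param batch_size mini-batch rows (default 32).
#' @param learning_rate fixed gradient-descent step size (default 1e-3).
#' @param standardize if `TRUE`, columns are centred/scaled before training
#'   and the transform is stored in the encoder (default `FALSE`).
#' @param seed integer RNG seed (weight init and batch shuffling).
#' @return an `ae_params` list.
#' @export
ae_params <- function(layer_sizes = c(512, 200), activation = "sigmoid",
                      epochs = 200, batch_size = 32, learning_rate = 1e-3,
                      standardize = FALSE, seed = 1L) {
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2L || any(diff(layer_sizes) >= 0))
    abort_validation("layer_sizes must be strictly decreasing with length >= 2 (code width m < input width n)")
  activation <- match.arg(activation, c("sigmoid", "identity", "relu", "tanh"))
  check_positive_scalar(learning_rate, "learning_rate")
  list(layer_sizes = layer_sizes, activation = activation,
       epochs = check_count(epochs, "epochs"),
       batch_size = check_count(batch_size, "batch_size"),
       learning_rate = learning_rate,
       standardize = isTRUE(standardize),
       seed = check_count(seed, "seed", min = 0L))
}

act_fun <- function(name) switch(name,
  identity = list(f = function(z) z,            df = function(a) 1),
  sigmoid  = list(f = function(z) 1 / (1 + exp(-z)), df = function(a) a * (1 - a)),
  relu     = list(f = function(z) pmax(z, 0),   df = function(a) (a > 0) * 1),
  tanh     = list(f = tanh,                     df = function(a) 1 - a^2))

glorot_init <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

ae_forward <- function(weights, biases, acts, X) {
  A <- list(X)
  for (l in seq_along(weights)) {
    Z <- A[[l]] %*% weights[[l]]
    Z <- sweep(Z, 2, biases[[l]], `+`)
    A[[l + 1L]] <- acts[[l]]$f(Z)
  }
  A
}

#' Train an autoencoder on a feature matrix
#'
#' The decoder mirrors the encoder widths in reverse; hidden layers use
#' `params$activation`, the output layer is linear. Training is plain
#' mini-batch gradient descent on the mean squared reconstruction error
#' (mean over rows of the squared Euclidean distance between input and
#' output), deterministic given `params$seed`.
#'
#' @param X numeric matrix, rows = genes, `params$layer_sizes[1]` columns,
#'   at least 2 rows, all finite.
#' @param params an [ae_params()].
#' @return an `autoencoder` object with `weights`, `biases`, encoder depth,
#'   code width `m`, per-epoch `loss_trace`, and the params used.
#' @export
train_autoencoder <- function(X, params) {
  X <- as.matrix(X)
  if (!is.numeric(X) || any(!is.finite(X)))
    abort_validation("X must be a finite numeric matrix")
  if (nrow(X) < 2L) abort_validation("X must have at least 2 rows")
  ls <- params$layer_sizes
  if (ncol(X) != ls[1])
    abort_validation(sprintf("X has %d columns but layer_sizes starts at %d",
                             ncol(X), ls[1]))
  center <- scale_sd <- NULL
  if (params$standardize) {
    center <- colMeans(X)
    scale_sd <- apply(X, 2, stats::sd)
    scale_sd[scale_sd == 0] <- 1
    X <- sweep(sweep(X, 2, center), 2, scale_sd, `/`)
    message("input columns standardized before autoencoder training")
  }
  widths <- c(ls, rev(ls)[-1])              # encoder then mirrored decoder
  n_layers <- length(widths) - 1L
  n_enc <- length(ls) - 1L
  act_names <- c(rep(params$activation, n_layers - 1L), "identity")
  acts <- lapply(act_names, act_fun)

  set.seed(params$seed)
  weights <- vector("list", n_layers)
  biases <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    weights[[l]] <- glorot_init(widths[l], widths[l + 1L])
    biases[[l]] <- rep(0, widths[l + 1L])
  }

  n <- nrow(X)
  bs <- min(params$batch_size, n)
  lr <- params$learning_rate
  loss_trace <- numeric(params$epochs)
  for (ep in seq_len(params$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (start in seq(1L, n, by = bs)) {
      rows <- ord[start:min(start + bs - 1L, n)]
      B <- X[rows, , drop = FALSE]
      A <- ae_forward(weights, biases, acts, B)
      Z <- A[[n_layers + 1L]]
      diff <- Z - B
      ep_loss <- ep_loss + sum(diff^2)
      delta <- 2 * diff / nrow(B)           # d(mean row SSE)/dZ
      for (l in n_layers:1) {
        if (l < n_layers) delta <- delta * acts[[l]]$df(A[[l + 1L]])
        gW <- crossprod(A[[l]], delta)
        gb <- colSums(delta)
        if (l > 1L) delta <- delta %*% t(weights[[l]])
        weights[[l]] <- weights[[l]] - lr * gW
        biases[[l]] <- biases[[l]] - lr * gb
      }
    }
    loss_trace[ep] <- ep_loss / n
    if (!is.finite(loss_trace[ep]))
      abort(sprintf("training diverged (non-finite loss) at epoch %d", ep),
            "n2asvm_training_error")
  }
  structure(list(weights = weights, biases = biases, n_enc = n_enc,
                 m = ls[length(ls)], widths = widths,
                 act_names = act_names, loss_trace = loss_trace,
                 center = center, scale_sd = scale_sd, params = params),
            class = "autoencoder")
}

#' @export
print.autoencoder <- function(x, ...) {
  cat(sprintf("autoencoder: %s | final loss %.4g\n",
              paste(x$widths, collapse = "-"),
              x$loss_trace[length(x$loss_trace)]))
  invisible(x)
}

ae_prepare <- function(encoder, X) {
  X <- as.matrix(X)
  if (ncol(X) != encoder$widths[1])
    abort_validation(sprintf("X has %d columns, encoder expects %d",
                             ncol(X), encoder$widths[1]))
  if (!is.null(encoder$center))
    X <- sweep(sweep(X, 2, encoder$center), 2, encoder$scale_sd, `/`)
  X
}

#' Encode features into the code layer
#'
#' Deterministic forward pass through the encoder half; row order is
#' preserved (row i of the output encodes row i of the input).
#'
#' @param encoder an `autoencoder` from [train_autoencoder()].
#' @param X numeric matrix with the encoder's input width.
#' @return numeric matrix with `encoder$m` columns (rownames preserved).
#' @export
encode <- function(encoder, X) {
  stopifnot(inherits(encoder, "autoencoder"))
  rn <- rownames(X)
  X <- ae_prepare(encoder, X)
  acts <- lapply(encoder$act_names, act_fun)
  A <- X
  for (l in seq_len(encoder$n_enc)) {
    Z <- sweep(A %*% encoder$weights[[l]], 2, encoder$biases[[l]], `+`)
    A <- acts[[l]]$f(Z)
  }
  rownames(A) <- rn
  A
}

#' Reconstruct inputs through the full autoencoder
#' @param encoder an `autoencoder`.
#' @param X input matrix.
#' @return reconstruction matrix, same shape as `X`.
#' @export
reconstruct <- function(encoder, X) {
  stopifnot(inherits(encoder, "autoencoder"))
  Xp <- ae_prepare(encoder, X)
  acts <- lapply(encoder$act_names, act_fun)
  A <- ae_forward(encoder$weights, encoder$biases, acts, Xp)
  Z <- A[[length(A)]]
  if (!is.null(encoder$center))
    Z <- sweep(sweep(Z, 2, encoder$scale_sd, `*`), 2, encoder$center, `+`)
  Z
}

#' Mean squared reconstruction error
#'
#' Mean over rows of the squared Euclidean distance between each input row
#' and its reconstruction.
#'
#' @param encoder an `autoencoder`.
#' @param X input matrix.
#' @return nonnegative scalar.
#' @export
reconstruction_error <- function(encoder, X) {
  Z <- reconstruct(encoder, X)
  mean(rowSums((as.matrix(X) - Z)^2))
}
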