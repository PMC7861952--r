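#' Stacked sparse-autoencoder settings
#'
#' Two-layer stack by default: 1200 hidden units then 900, L2 weight decay
#' lambda = 0.001, sparsity-penalty weight beta = 4 with target mean
#' activation rho = 0.05, and a purely linear encoder transfer — the
#' full-scale configuration. Test profiles shrink `hidden_sizes` and
#' `max_epochs`.
#'
#' @param hidden_sizes hidden-unit counts per layer (default `c(1200, 900)`).
#' @param l2_weight L2 penalty coefficient lambda on all weights
#'   (default 0.001).
#' @param sparsity_weight KL sparsity-penalty coefficient beta (default 4).
#' @param sparsity_proportion target mean activation rho in (0, 1)
#'   (default 0.05).
#' @param encoder_transfer `"linear"`, `"logistic"` or `"satlin"`
#'   (positive saturating linear).
#' @param max_epochs full-batch gradient steps per layer (default 200).
#' @param learning_rate initial step size; adapted by backtracking during
#'   training (default 0.05).
#' @param seed integer seed for weight initialization.
#' @return an object of class `autoencoder_spec`.
#' @export
autoencoder_spec <- function(hidden_sizes = c(1200, 900), l2_weight = 0.001,
                             sparsity_weight = 4, sparsity_proportion = 0.05,
                             encoder_transfer = c("linear", "logistic",
                                                  "satlin"),
                             max_epochs = 200, learning_rate = 0.05,
                             seed = 1L) {
  encoder_transfer <- match.arg(encoder_transfer)
  check_that(all(hidden_sizes >= 1), "hidden sizes must be positive")
  check_that(sparsity_proportion > 0 && sparsity_proportion < 1,
             "sparsity_proportion must lie in (0, 1)")
  check_that(l2_weight >= 0 && sparsity_weight >= 0,
             "penalty weights must be >= 0")
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 l2_weight = l2_weight, sparsity_weight = sparsity_weight,
                 sparsity_proportion = sparsity_proportion,
                 encoder_transfer = encoder_transfer,
                 max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "autoencoder_spec")
}

#' KL-divergence sparsity penalty
#'
#' `sum_j [rho*log(rho/rho_hat_j) + (1-rho)*log((1-rho)/(1-rho_hat_j))]` —
#' the Kullback-Leibler divergence between Bernoulli(rho) and
#' Bernoulli(rho_hat_j), summed over hidden units. Non-negative, and zero
#' exactly when every mean activation equals the target rho. Values of
#' `rho_hat` outside (0, 1) are clamped to `[1e-6, 1 - 1e-6]` with a
#' warning.
#'
#' @param rho_hat per-unit mean activation fractions.
#' @param rho target activation proportion in (0, 1).
#' @return the scalar penalty.
#' @export
kl_sparsity_penalty <- function(rho_hat, rho) {
  check_that(rho > 0 && rho < 1, "rho must lie in (0, 1)")
  if (any(rho_hat <= 0 | rho_hat >= 1)) {
    warning("mean activations outside (0,1) clamped to [1e-6, 1-1e-6]")
    rho_hat <- pmin(pmax(rho_hat, 1e-6), 1 - 1e-6)
  }
  sum(rho * log(rho / rho_hat) + (1 - rho) * log((1 - rho) / (1 - rho_hat)))
}

transfer_fun <- function(name) {
  switch(name,
    linear = list(f = function(z) z, df = function(z) 1),
    logistic = list(f = function(z) 1 / (1 + exp(-z)),
                    df = function(z) { s <- 1 / (1 + exp(-z)); s * (1 - s) }),
    satlin = list(f = function(z) pmin(pmax(z, 0), 1),
                  df = function(z) as.numeric(z > 0 & z < 1)))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

## full loss + gradients for one autoencoder layer.
## X: n x d. W1: h x d, b1: h, W2: d x h, b2: d.
## Mean activations for the KL term are computed on logistic-squashed
## encoder activations so the term stays defined for a linear transfer.
sae_loss_grad <- function(X, W1, b1, W2, b2, tf, lambda, beta, rho) {
  n <- nrow(X)
  Z1 <- sweep(X %*% t(W1), 2L, b1, `+`)      # n x h pre-activations
  A <- tf$f(Z1)                               # encoder activations
  Xhat <- sweep(A %*% t(W2), 2L, b2, `+`)
  E <- Xhat - X
  loss_rec <- sum(E^2) / n
  S <- sigmoid(A)
  rho_hat <- pmin(pmax(colMeans(S), 1e-6), 1 - 1e-6)
  kl <- sum(rho * log(rho / rho_hat) +
              (1 - rho) * log((1 - rho) / (1 - rho_hat)))
  loss <- loss_rec + lambda * (sum(W1^2) + sum(W2^2)) + beta * kl
  # gradients
  dXhat <- 2 * E / n
  gW2 <- t(dXhat) %*% A + 2 * lambda * W2
  gb2 <- colSums(dXhat)
  dA <- dXhat %*% W2
  dkl_drho <- -rho / rho_hat + (1 - rho) / (1 - rho_hat)
  dA <- dA + sweep(S * (1 - S), 2L, beta * dkl_drho / n, `*`)
  dZ1 <- dA * tf$df(Z1)
  gW1 <- t(dZ1) %*% X + 2 * lambda * W1
  gb1 <- colSums(dZ1)
  list(loss = loss, gW1 = gW1, gb1 = gb1, gW2 = gW2, gb2 = gb2)
}

#' Train one sparse-autoencoder layer
#'
#' Minimizes mean squared reconstruction error
#' `+ lambda * sum(weights^2) + beta * KL(rho || rho_hat)` by full-batch
#' gradient descent with a backtracking step size: a step that would
#' increase the loss is retried at half the step size, so the recorded loss
#' trace is monotone non-increasing. Deterministic given the seed.
#'
#' @param X numeric matrix (rows = samples), already standardized by the
#'   caller.
#' @param hidden number of hidden units.
#' @param spec an [autoencoder_spec()] supplying the penalties, transfer,
#'   epochs and learning rate.
#' @return an `sae_layer` with encoder weights `W`/`b`, decoder weights,
#'   the transfer name and the loss trace.
#' @export
train_sparse_autoencoder <- function(X, hidden, spec = autoencoder_spec()) {
  X <- as.matrix(X)
  check_that(nrow(X) > 0, "X must be non-empty")
  check_that(all(is.finite(X)), "X must be finite")
  d <- ncol(X)
  tf <- transfer_fun(spec$encoder_transfer)
  set.seed(spec$seed)
  r <- sqrt(6 / (d + hidden))
  W1 <- matrix(stats::runif(hidden * d, -r, r), hidden, d)
  b1 <- numeric(hidden)
  W2 <- matrix(stats::runif(d * hidden, -r, r), d, hidden)
  b2 <- numeric(d)
  lr <- spec$learning_rate
  trace <- numeric(spec$max_epochs + 1L)
  g <- sae_loss_grad(X, W1, b1, W2, b2, tf, spec$l2_weight,
                     spec$sparsity_weight, spec$sparsity_proportion)
  trace[1L] <- g$loss
  for (ep in seq_len(spec$max_epochs)) {
    repeat {
      W1n <- W1 - lr * g$gW1; b1n <- b1 - lr * g$gb1
      W2n <- W2 - lr * g$gW2; b2n <- b2 - lr * g$gb2
      gn <- sae_loss_grad(X, W1n, b1n, W2n, b2n, tf, spec$l2_weight,
                          spec$sparsity_weight, spec$sparsity_proportion)
      if (is.finite(gn$loss) && gn$loss <= g$loss + 1e-12) break
      lr <- lr / 2
      if (lr < 1e-12) { gn <- g; W1n <- W1; b1n <- b1; W2n <- W2; b2n <- b2; break }
    }
    W1 <- W1n; b1 <- b1n; W2 <- W2n; b2 <- b2n
    g <- gn
    trace[ep + 1L] <- g$loss
    lr <- lr * 1.05                     # cautious re-growth after backtracks
  }
  structure(list(W = W1, b = b1, W_dec = W2, b_dec = b2,
                 transfer = spec$encoder_transfer, loss_trace = trace,
                 hidden = hidden, input_dim = d),
            class = "sae_layer")
}

#' Encode data through one layer
#'
#' @param layer an `sae_layer`.
#' @param X matrix with `layer$input_dim` columns.
#' @return the activation matrix (rows x hidden).
#' @export
encode_layer <- function(layer, X) {
  X <- as.matrix(X)
  check_that(ncol(X) == layer$input_dim,
             sprintf("input has %d columns; layer expects %d", ncol(X),
                     layer$input_dim))
  tf <- transfer_fun(layer$transfer)
  tf$f(sweep(X %*% t(layer$W), 2L, layer$b, `+`))
}

#' Reconstruct data through one layer (encode then decode)
#'
#' @param layer an `sae_layer`.
#' @param X input matrix.
#' @return the reconstruction matrix, same shape as `X`.
#' @export
reconstruct_layer <- function(layer, X) {
  sweep(encode_layer(layer, X) %*% t(layer$W_dec), 2L, layer$b_dec, `+`)
}

#' Train a stacked encoder greedily
#'
#' Layer-wise training: layer 1 learns to reconstruct the input, layer 2
#' learns to reconstruct layer 1's codes, and so on. Each layer gets its
#' own derived seed so the stack is reproducible from the spec alone.
#'
#' @param X standardized feature matrix.
#' @param spec an [autoencoder_spec()]; one layer is trained per entry of
#'   `hidden_sizes`.
#' @return an `encoder_stack`.
#' @export
train_encoder_stack <- function(X, spec = autoencoder_spec()) {
  layers <- vector("list", length(spec$hidden_sizes))
  cur <- as.matrix(X)
  for (i in seq_along(spec$hidden_sizes)) {
    lspec <- spec
    lspec$seed <- derive_seed(spec$seed, i)
    layers[[i]] <- train_sparse_autoencoder(cur, spec$hidden_sizes[i], lspec)
    cur <- encode_layer(layers[[i]], cur)
  }
  structure(list(layers = layers, spec = spec), class = "encoder_stack")
}

#' Encode data through the whole stack
#'
#' Sequential application of each layer's `transfer(W x + b)`; the output
#' dimension is the last hidden size.
#'
#' @param stack an `encoder_stack`.
#' @param X matrix matching layer 1's input dimension.
#' @return the deep feature matrix.
#' @export
encode_stack <- function(stack, X) {
  cur <- as.matrix(X)
  for (layer in stack$layers) cur <- encode_layer(layer, cur)
  cur
}

#' @export
print.encoder_stack <- function(x, ...) {
  sizes <- vapply(x$layers, `[[`, 0L, "hidden")
  cat(sprintf("Encoder stack: %d -> %s (%s transfer)\n",
              x$layers[[1]]$input_dim, paste(sizes, collapse = " -> "),
              x$spec$encoder_transfer))
  invisible(x)
}

#' @export
predict.encoder_stack <- function(object, newdata, ...) {
  encode_stack(object, newdata)
}
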