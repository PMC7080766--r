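# Sparse autoencoder: single hidden layer, sigmoid activations on both
# layers, mean halved squared reconstruction error plus a KL-divergence
# sparsity penalty pulling each hidden unit's mean activation towards a
# small target rho. Trained by mini-batch gradient descent with adadelta
# per-parameter step sizes.

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Initialize a sparse autoencoder
#'
#' Weights drawn uniformly from `[-r, r]` with `r = sqrt(6 / (d_in + s2))`
#' (Glorot range for sigmoid units); biases start at zero.
#'
#' @param d_in Input width (e.g. 906 for a 593-drug/313-disease dataset).
#' @param s2 Hidden width (default 100).
#' @param seed Integer seed; the same seed reproduces the same model.
#' @return List of class `"sae_model"` with `W_encoder` (`s2 x d_in`),
#'   `b_encoder`, `W_decoder` (`d_in x s2`), `b_decoder`, `s2`, `d_in`.
#' @export
sae_init <- function(d_in, s2 = 100, seed = 1) {
  if (d_in < 1 || s2 < 1) stop("d_in and s2 must be >= 1")
  r <- sqrt(6 / (d_in + s2))
  with_seed(seed, {
    model <- list(
      W_encoder = matrix(runif(s2 * d_in, -r, r), s2, d_in),
      b_encoder = numeric(s2),
      W_decoder = matrix(runif(d_in * s2, -r, r), d_in, s2),
      b_decoder = numeric(d_in),
      s2 = as.integer(s2), d_in = as.integer(d_in))
    class(model) <- "sae_model"
    model
  })
}

#' Forward pass through the autoencoder
#'
#' `h = sigmoid(x W_enc' + b_enc)`, `y = sigmoid(h W_dec' + b_dec)`.
#'
#' @param model An [sae_init()] model.
#' @param x Numeric matrix `n x d_in` (rows are samples, values expected
#'   in \[0, 1\]).
#' @return List with hidden activations `h` (`n x s2`) and reconstruction
#'   `y` (`n x d_in`), both strictly inside (0, 1).
#' @export
sae_forward <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != model$d_in)
    stop(sprintf("input width %d does not match model d_in %d",
                 ncol(x), model$d_in))
  h <- sigmoid(sweep(x %*% t(model$W_encoder), 2, model$b_encoder, "+"))
  y <- sigmoid(sweep(h %*% t(model$W_decoder), 2, model$b_decoder, "+"))
  list(h = h, y = y)
}

#' Bernoulli KL divergence for the sparsity penalty
#'
#' `KL(rho || rho_hat) = rho*log(rho/rho_hat) +
#' (1-rho)*log((1-rho)/(1-rho_hat))`, elementwise over hidden units;
#' `rho_hat` is clipped to `[1e-12, 1 - 1e-12]` first. Zero exactly when
#' `rho_hat = rho`, strictly positive and increasing as `rho_hat` moves
#' away from `rho` in either direction.
#'
#' @param rho Sparsity target in (0, 1).
#' @param rho_hat Numeric vector of mean hidden activations.
#' @return Non-negative numeric vector.
#' @export
kl_divergence <- function(rho, rho_hat) {
  stopifnot(rho > 0, rho < 1)
  rho_hat <- pmin(pmax(rho_hat, 1e-12), 1 - 1e-12)
  rho * log(rho / rho_hat) + (1 - rho) * log((1 - rho) / (1 - rho_hat))
}

#' Sparse reconstruction cost and gradients
#'
#' Cost is `(1/n) * sum_i 0.5 * ||y_i - x_i||^2 + gamma * sum_t
#' KL(rho || rho_hat_t)` with `rho_hat_t` the batch mean activation of
#' hidden unit `t` (or the mean over `rho_data` when supplied, for
#' full-set sparsity accounting). Gradients are exact backpropagation,
#' including the KL term's path through the hidden layer.
#'
#' @param model An [sae_init()] model.
#' @param x Batch matrix `n x d_in`.
#' @param rho Sparsity target (default 0.05).
#' @param gamma Sparsity weight (default 1e-6).
#' @param rho_data Optional matrix over which `rho_hat` is computed instead
#'   of the batch.
#' @return List with `cost` (scalar) and `grads` (list of `W_encoder`,
#'   `b_encoder`, `W_decoder`, `b_decoder` matching the model shapes).
#' @export
sae_cost <- function(model, x, rho = 0.05, gamma = 1e-6, rho_data = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 1) stop("empty batch")
  fwd <- sae_forward(model, x)
  h <- fwd$h; y <- fwd$y
  if (is.null(rho_data)) {
    rho_hat <- colMeans(h)
    n_rho <- n
  } else {
    rho_hat <- colMeans(sae_forward(model, rho_data)$h)
    n_rho <- nrow(rho_data)
  }
  rho_hat_c <- pmin(pmax(rho_hat, 1e-12), 1 - 1e-12)
  recon <- sum((y - x)^2) / (2 * n)
  cost <- recon + gamma * sum(kl_divergence(rho, rho_hat))

  delta_y <- ((y - x) / n) * y * (1 - y)
  g_Wdec <- crossprod(delta_y, h)          # d_in x s2
  g_bdec <- colSums(delta_y)
  kl_grad <- gamma * (-rho / rho_hat_c + (1 - rho) / (1 - rho_hat_c)) / n_rho
  back <- delta_y %*% model$W_decoder      # n x s2
  if (is.null(rho_data)) {
    delta_h <- sweep(back, 2, kl_grad, "+") * h * (1 - h)
    g_Wenc <- crossprod(delta_h, x)
    g_benc <- colSums(delta_h)
  } else {
    # sparsity path flows through the activations on rho_data
    delta_h <- back * h * (1 - h)
    hr <- sae_forward(model, rho_data)$h
    delta_hr <- sweep(matrix(0, nrow(rho_data), model$s2), 2, kl_grad, "+") *
      hr * (1 - hr)
    g_Wenc <- crossprod(delta_h, x) + crossprod(delta_hr, as.matrix(rho_data))
    g_benc <- colSums(delta_h) + colSums(delta_hr)
  }
  list(cost = cost,
       grads = list(W_encoder = g_Wenc, b_encoder = g_benc,
                    W_decoder = g_Wdec, b_decoder = g_bdec))
}

#' Train a sparse autoencoder
#'
#' Mini-batch gradient descent with adadelta per-parameter step sizes
#' (running decay of squared gradients and squared updates); rows are
#' reshuffled every epoch under the given seed, so two runs with the same
#' seed produce identical weights. The mean batch cost per epoch is kept
#' in the returned model as `loss_history`. The inner loop runs in
#' compiled code; its gradients follow the same backpropagation as
#' [sae_cost()], which the test suite checks step for step.
#'
#' @param x Training matrix `n x d_in`, `n >= 2`.
#' @param s2 Hidden width (default 100).
#' @param rho,gamma Sparsity target and weight, see [sae_cost()].
#' @param epochs Number of passes over the data (default 100).
#' @param batch_size Mini-batch size (default 64).
#' @param adadelta_decay,adadelta_eps Adadelta accumulator decay (default
#'   0.95) and numerical floor (default 1e-6).
#' @param full_batch_rho When `TRUE`, the sparsity term uses mean
#'   activations over the full training set at every step instead of the
#'   mini-batch (slower, closer to a full-batch definition of the penalty).
#' @param seed Integer seed.
#' @return Trained `"sae_model"` with `loss_history` attached.
#' @export
sae_train <- function(x, s2 = 100, rho = 0.05, gamma = 1e-6, epochs = 100,
                      batch_size = 64, adadelta_decay = 0.95,
                      adadelta_eps = 1e-6, full_batch_rho = FALSE,
                      seed = 1) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) stop("need at least 2 training rows")
  stopifnot(rho > 0, rho < 1, gamma >= 0, epochs >= 1)
  model <- sae_init(ncol(x), s2, seed = derive_seed(seed, 0L))
  orders <- with_seed(derive_seed(seed, 1L),
                      vapply(seq_len(epochs), function(ep) sample.int(n) - 1L,
                             integer(n)))
  fit <- .sae_train_core(x, model$W_encoder, model$b_encoder,
                         model$W_decoder, model$b_decoder,
                         orders, as.integer(batch_size), rho, gamma,
                         adadelta_decay, adadelta_eps, full_batch_rho)
  model$W_encoder <- fit$W_encoder
  model$b_encoder <- as.numeric(fit$b_encoder)
  model$W_decoder <- fit$W_decoder
  model$b_decoder <- as.numeric(fit$b_decoder)
  model$loss_history <- as.numeric(fit$loss_history)
  model
}

#' Encode samples to the hidden representation
#'
#' @param model A trained [sae_train()] model.
#' @param x Matrix `n x d_in`.
#' @return Hidden activations `n x s2`, values in (0, 1).
#' @export
sae_encode <- function(model, x) sae_forward(model, x)$h

#' @export
print.sae_model <- function(x, ...) {
  cat(sprintf("sparse autoencoder: %d -> %d -> %d", x$d_in, x$s2, x$d_in))
  if (!is.null(x$loss_history))
    cat(sprintf(" | trained %d epochs, final loss %.6g",
                length(x$loss_history), x$loss_history[length(x$loss_history)]))
  cat("\n")
  invisible(x)
}
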