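# Minimal fully connected network in base R matrix code: linear layers with
# ReLU on the hidden layers, mean-squared-error or softmax cross-entropy
# loss, Adam optimizer. Dropout masks multiply the hidden activations, so a
# dropped unit emits zero forward and receives zero gradient through the
# product — the operational meaning of excluding it from both passes.
#
# Data layout: columns are samples (X is features x batch); weights W[[l]]
# are out x in. Initialization matches the common fan-in uniform scheme,
# U(-1/sqrt(fan_in), +1/sqrt(fan_in)) for weights and biases.

mlp_init <- function(layer_sizes, seed = NULL) {
  stopifnot(length(layer_sizes) >= 2L, all(layer_sizes >= 1L))
  n_layers <- length(layer_sizes) - 1L
  with_seed(seed, {
    W <- vector("list", n_layers)
    b <- vector("list", n_layers)
    for (l in seq_len(n_layers)) {
      fan_in <- layer_sizes[l]
      bound <- 1 / sqrt(fan_in)
      W[[l]] <- matrix(stats::runif(layer_sizes[l + 1L] * fan_in, -bound,
                                    bound),
                       nrow = layer_sizes[l + 1L])
      b[[l]] <- stats::runif(layer_sizes[l + 1L], -bound, bound)
    }
    list(W = W, b = b, sizes = layer_sizes, n_layers = n_layers)
  })
}

# Forward pass. masks: list over hidden layers (length n_layers - 1) of
# keep-multiplier vectors (numeric, 0 for dropped), or NULL entries / NULL.
# Returns the output matrix plus per-layer caches for backprop.
mlp_forward <- function(net, X, masks = NULL, training = FALSE) {
  a <- X
  hidden <- vector("list", net$n_layers - 1L)
  for (l in seq_len(net$n_layers - 1L)) {
    z <- net$W[[l]] %*% a + net$b[[l]]
    h <- z * (z > 0)                      # ReLU
    if (training && !is.null(masks) && !is.null(masks[[l]]))
      h <- h * masks[[l]]
    hidden[[l]] <- h
    a <- h
  }
  out <- net$W[[net$n_layers]] %*% a + net$b[[net$n_layers]]
  list(out = out, hidden = hidden, input = X)
}

# Loss and gradient at the output. For "mse", Y is a numeric matrix of
# targets; for "cross_entropy", Y is an integer vector of 1-based class
# labels and the loss is softmax cross-entropy averaged over the batch.
mlp_loss <- function(out, Y, loss = c("mse", "cross_entropy")) {
  loss <- match.arg(loss)
  if (loss == "mse") {
    d <- out - Y
    list(value = mean(d^2), grad = 2 * d / length(d))
  } else {
    m <- apply(out, 2L, max)
    ex <- exp(sweep(out, 2L, m))
    p <- sweep(ex, 2L, colSums(ex), "/")
    n <- ncol(out)
    picked <- p[cbind(Y, seq_len(n))]
    g <- p
    g[cbind(Y, seq_len(n))] <- g[cbind(Y, seq_len(n))] - 1
    list(value = -mean(log(pmax(picked, 1e-300))), grad = g / n,
         probs = p)
  }
}

# Backward pass given the output-gradient; returns gradients for W and b.
# Masked hidden units carry zero gradient (their activation is an exact 0
# produced by multiplication, and the mask multiplies the backward signal).
mlp_backward <- function(net, fwd, dout, masks = NULL) {
  nl <- net$n_layers
  gW <- vector("list", nl)
  gb <- vector("list", nl)
  delta <- dout
  for (l in nl:1) {
    a_prev <- if (l == 1L) fwd$input else fwd$hidden[[l - 1L]]
    gW[[l]] <- delta %*% t(a_prev)
    gb[[l]] <- rowSums(delta)
    if (l > 1L) {
      delta <- t(net$W[[l]]) %*% delta
      if (!is.null(masks) && !is.null(masks[[l - 1L]]))
        delta <- delta * masks[[l - 1L]]
      delta <- delta * (fwd$hidden[[l - 1L]] > 0)
    }
  }
  list(W = gW, b = gb)
}

adam_init <- function(net) {
  zero_like <- function(p) lapply(p, function(x) x * 0)
  list(mW = zero_like(net$W), vW = zero_like(net$W),
       mb = zero_like(net$b), vb = zero_like(net$b), t = 0L)
}

adam_step <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (l in seq_len(net$n_layers)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grads$W[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grads$W[[l]]^2
    net$W[[l]] <- net$W[[l]] -
      lr * (state$mW[[l]] / bc1) / (sqrt(state$vW[[l]] / bc2) + eps)
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$b[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$b[[l]]^2
    net$b[[l]] <- net$b[[l]] -
      lr * (state$mb[[l]] / bc1) / (sqrt(state$vb[[l]] / bc2) + eps)
  }
  list(net = net, state = state)
}
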