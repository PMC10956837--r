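# Minimal feed-forward machinery for the drug/target encoders: Xavier-
# initialized fully connected layers with ReLU activations and inverted
# dropout, trained with Adam. Everything operates on row-major matrices
# (one sample per row) through plain BLAS calls.

# Xavier-uniform initialization; `dims` is c(input, hidden..., latent)
mlpInit <- function(inputDim, hidden, latentDim) {
  dims <- c(inputDim, hidden, latentDim)
  W <- vector("list", length(dims) - 1L)
  b <- vector("list", length(dims) - 1L)
  for (l in seq_along(W)) {
    lim <- sqrt(6 / (dims[l] + dims[l + 1L]))
    W[[l]] <- matrix(
      stats::runif(dims[l] * dims[l + 1L], -lim, lim),
      dims[l], dims[l + 1L]
    )
    b[[l]] <- rep(0, dims[l + 1L])
  }
  list(W = W, b = b, dims = dims)
}

# forward pass; dropout (inverted) is applied after each hidden ReLU when
# training = TRUE. Returns the output and the cache needed for backprop.
mlpForward <- function(net, X, dropout = 0, training = FALSE) {
  L <- length(net$W)
  acts <- vector("list", L + 1L) # layer inputs
  masks <- vector("list", L)
  acts[[1L]] <- X
  H <- X
  for (l in seq_len(L)) {
    Z <- H %*% net$W[[l]]
    Z <- sweep(Z, 2L, net$b[[l]], "+")
    if (l < L) {
      H <- pmax(Z, 0)
      if (training && dropout > 0) {
        mask <- matrix(
          stats::rbinom(length(H), 1L, 1 - dropout) / (1 - dropout),
          nrow(H), ncol(H)
        )
        masks[[l]] <- mask
        H <- H * mask
      }
    } else {
      H <- Z
    }
    acts[[l + 1L]] <- H
  }
  list(out = H, acts = acts, masks = masks)
}

# backprop; dOut is dLoss/dOutput (n x latentDim). Returns weight/bias grads.
mlpBackward <- function(net, cache, dOut) {
  L <- length(net$W)
  dW <- vector("list", L)
  db <- vector("list", L)
  delta <- dOut
  for (l in rev(seq_len(L))) {
    dW[[l]] <- crossprod(cache$acts[[l]], delta)
    db[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- delta %*% t(net$W[[l]])
      if (!is.null(cache$masks[[l - 1L]])) delta <- delta * cache$masks[[l - 1L]]
      delta <- delta * (cache$acts[[l]] > 0) # ReLU gate (post-activation > 0)
    }
  }
  list(dW = dW, db = db)
}

adamInit <- function(net) {
  zero <- function(x) {
    if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else rep(0, length(x))
  }
  list(
    mW = lapply(net$W, zero), vW = lapply(net$W, zero),
    mb = lapply(net$b, zero), vb = lapply(net$b, zero), t = 0L
  )
}

adamStep <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (l in seq_along(net$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grads$dW[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grads$dW[[l]]^2
    net$W[[l]] <- net$W[[l]] -
      lr * (state$mW[[l]] / c1) / (sqrt(state$vW[[l]] / c2) + eps)
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$db[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$db[[l]]^2
    net$b[[l]] <- net$b[[l]] -
      lr * (state$mb[[l]] / c1) / (sqrt(state$vb[[l]] / c2) + eps)
  }
  list(net = net, state = state)
}
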