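# Recurrent network engine for one-step-ahead sequence regression.
#
# The network mirrors the standard stacked-LSTM regressor for short lag
# windows: batch-normalized scalar input sequence -> stacked LSTM layers
# (each followed by dropout during training) -> single linear output unit,
# trained with Adam on mean squared error. Everything is written in base R
# matrix operations: the sequence length equals the lag count (2-5), so the
# BPTT unroll is short and batched matrix products dominate.
#
# Gate layout: columns of the 4h-wide gate blocks are [input, forget, cell,
# output]. The forget-gate bias is initialized to 1. Gradients are validated
# against central finite differences in the test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

BN_EPS <- 1e-3
BN_MOMENTUM <- 0.99

# Initialize a network. Uses the current RNG stream (caller seeds it).
# widths: vector of LSTM layer sizes; lags: timesteps of the scalar input.
net_init <- function(lags, widths, dropout = 0.1) {
  stopifnot(length(widths) >= 1L, all(widths >= 1L))
  par <- list(bn_gamma = 1, bn_beta = 0)
  d_in <- 1L
  for (l in seq_along(widths)) {
    h <- widths[l]
    lim <- sqrt(6 / (d_in + 4 * h))                       # Glorot uniform
    W <- matrix(stats::runif(d_in * 4 * h, -lim, lim), d_in, 4 * h)
    U <- do.call(cbind, lapply(1:4, function(g) rand_orthogonal(h)))
    b <- rep(0, 4 * h)
    b[(h + 1):(2 * h)] <- 1                               # forget bias
    par[[paste0("W", l)]] <- W
    par[[paste0("U", l)]] <- U
    par[[paste0("b", l)]] <- b
    d_in <- h
  }
  h_last <- widths[length(widths)]
  lim <- sqrt(6 / (h_last + 1))
  par$dense_w <- matrix(stats::runif(h_last, -lim, lim), h_last, 1)
  par$dense_b <- 0
  list(lags = as.integer(lags), widths = as.integer(widths),
       dropout = dropout, par = par,
       running = list(mean = 0, var = 1))
}

rand_orthogonal <- function(h) {
  if (h == 1L) return(matrix(sample(c(-1, 1), 1), 1, 1))
  q <- qr.Q(qr(matrix(stats::rnorm(h * h), h, h)))
  q * sign(diag(q))[col(q)]   # fix sign convention for reproducibility
}

# Forward pass over a batch. X: n x lags matrix. Returns yhat (length n),
# and when training also the cache for backprop and updated running stats.
net_forward <- function(net, X, training = FALSE, keep_cache = training) {
  par <- net$par
  n <- nrow(X)
  L <- net$lags
  stopifnot(ncol(X) == L)

  if (training) {
    mu <- mean(X)
    v <- mean((X - mu)^2)
  } else {
    mu <- net$running$mean
    v <- net$running$var
  }
  inv_sd <- 1 / sqrt(v + BN_EPS)
  xhat <- (X - mu) * inv_sd
  Z <- par$bn_gamma * xhat + par$bn_beta

  drop_q <- if (training) net$dropout else 0
  cache <- if (keep_cache) list(xhat = xhat, inv_sd = inv_sd, layers = vector("list", length(net$widths)))
  inputs <- lapply(seq_len(L), function(t) Z[, t, drop = FALSE])

  for (l in seq_along(net$widths)) {
    h <- net$widths[l]
    W <- par[[paste0("W", l)]]
    U <- par[[paste0("U", l)]]
    b <- par[[paste0("b", l)]]
    h_prev <- matrix(0, n, h)
    c_prev <- matrix(0, n, h)
    steps <- vector("list", L)
    outs <- vector("list", L)
    for (t in seq_len(L)) {
      A <- inputs[[t]] %*% W + h_prev %*% U
      A <- sweep(A, 2L, b, "+")
      i_g <- sigmoid(A[, 1:h, drop = FALSE])
      f_g <- sigmoid(A[, (h + 1):(2 * h), drop = FALSE])
      g_g <- tanh(A[, (2 * h + 1):(3 * h), drop = FALSE])
      o_g <- sigmoid(A[, (3 * h + 1):(4 * h), drop = FALSE])
      c_t <- f_g * c_prev + i_g * g_g
      hc <- tanh(c_t)
      h_t <- o_g * hc
      mask <- if (drop_q > 0) {
        (matrix(stats::runif(n * h), n, h) >= drop_q) / (1 - drop_q)
      } else NULL
      out_t <- if (is.null(mask)) h_t else h_t * mask
      if (keep_cache) {
        steps[[t]] <- list(x = inputs[[t]], i = i_g, f = f_g, g = g_g, o = o_g,
                           c = c_t, hc = hc, c_prev = c_prev, h_prev = h_prev,
                           mask = mask)
      }
      outs[[t]] <- out_t
      h_prev <- h_t
      c_prev <- c_t
    }
    if (keep_cache) cache$layers[[l]] <- steps
    inputs <- outs
  }

  y <- inputs[[L]] %*% par$dense_w + par$dense_b
  res <- list(yhat = as.numeric(y))
  if (keep_cache) {
    cache$top_out <- inputs[[L]]
    res$cache <- cache
  }
  if (training) {
    m <- BN_MOMENTUM
    res$running <- list(mean = m * net$running$mean + (1 - m) * mu,
                        var = m * net$running$var + (1 - m) * v)
  }
  res
}

# Backward pass for MSE loss. dY: n-vector dLoss/dyhat. Returns gradients in
# the same named layout as net$par.
net_backward <- function(net, cache, dY) {
  par <- net$par
  L <- net$lags
  n <- length(dY)
  dY <- matrix(dY, n, 1)

  grads <- list()
  grads$dense_w <- t(cache$top_out) %*% dY
  grads$dense_b <- sum(dY)

  n_layers <- length(net$widths)
  # d_out[[t]]: gradient wrt the (post-dropout) output of the current layer
  # at timestep t. The top layer only feeds the dense head at t = L.
  d_out <- vector("list", L)
  d_out[[L]] <- dY %*% t(par$dense_w)

  for (l in rev(seq_len(n_layers))) {
    h <- net$widths[l]
    W <- par[[paste0("W", l)]]
    U <- par[[paste0("U", l)]]
    steps <- cache$layers[[l]]
    dW <- matrix(0, nrow(W), ncol(W))
    dU <- matrix(0, h, 4 * h)
    db <- rep(0, 4 * h)
    d_in <- vector("list", L)
    dh_carry <- matrix(0, n, h)
    dc_carry <- matrix(0, n, h)
    for (t in rev(seq_len(L))) {
      s <- steps[[t]]
      dh <- dh_carry
      if (!is.null(d_out[[t]])) {
        d_post <- d_out[[t]]
        dh <- dh + if (is.null(s$mask)) d_post else d_post * s$mask
      }
      do_ <- dh * s$hc
      dc <- dh * s$o * (1 - s$hc^2) + dc_carry
      di_ <- dc * s$g
      df_ <- dc * s$c_prev
      dg_ <- dc * s$i
      dc_carry <- dc * s$f
      dA <- cbind(di_ * s$i * (1 - s$i),
                  df_ * s$f * (1 - s$f),
                  dg_ * (1 - s$g^2),
                  do_ * s$o * (1 - s$o))
      dW <- dW + t(s$x) %*% dA
      dU <- dU + t(s$h_prev) %*% dA
      db <- db + colSums(dA)
      d_in[[t]] <- dA %*% t(W)
      dh_carry <- dA %*% t(U)
    }
    grads[[paste0("W", l)]] <- dW
    grads[[paste0("U", l)]] <- dU
    grads[[paste0("b", l)]] <- db
    d_out <- d_in
  }

  # Batch-norm backward (moments taken over all n*L elements).
  dZ <- do.call(cbind, d_out)
  xhat <- cache$xhat
  grads$bn_gamma <- sum(dZ * xhat)
  grads$bn_beta <- sum(dZ)
  # input gradient not needed (inputs are data), but computed cheaply for
  # completeness of the gradient check:
  dxhat <- dZ * par$bn_gamma
  grads$input <- cache$inv_sd * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat))
  grads
}

adam_init <- function(par) {
  list(m = lapply(par, function(p) p * 0),
       v = lapply(par, function(p) p * 0),
       t = 0L)
}

adam_step <- function(par, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(par)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    par[[nm]] <- par[[nm]] - lr * (state$m[[nm]] / bc1) /
      (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(par = par, state = state)
}

# MSE loss and gradient wrt predictions.
mse_loss <- function(yhat, y) mean((yhat - y)^2)
mse_grad <- function(yhat, y) 2 * (yhat - y) / length(y)

# Count trainable parameters.
net_n_params <- function(net) {
  sum(vapply(net$par, length, 1L))
}
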