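# Minimal fully connected network with tanh hidden layers and a linear
# output layer, with hand-written reverse-mode gradients.  tanh is used
# throughout because the gradient-penalty term requires a twice-
# differentiable activation (its parameter gradient involves phi'').
#
# A net is a list(W = list of in x out matrices, b = list of vectors,
# sizes = integer vector of layer widths).  Batches are row-major
# (samples in rows).

mlp_init <- function(sizes, seed = NULL) {
  with_seed(seed, {
    L <- length(sizes) - 1L
    W <- vector("list", L)
    b <- vector("list", L)
    for (l in seq_len(L)) {
      W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                                    sd = 1 / sqrt(sizes[l])),
                       sizes[l], sizes[l + 1L])
      b[[l]] <- rep(0, sizes[l + 1L])
    }
    list(W = W, b = b, sizes = as.integer(sizes))
  })
}

addb <- function(A, b) A + matrix(b, nrow(A), length(b), byrow = TRUE)

# Forward pass; returns list(out, h) where h[[1]] = input and
# h[[l + 1]] = activation after layer l (tanh except last, linear).
mlp_forward <- function(net, X) {
  L <- length(net$W)
  h <- vector("list", L + 1L)
  h[[1L]] <- X
  for (l in seq_len(L)) {
    A <- addb(h[[l]] %*% net$W[[l]], net$b[[l]])
    h[[l + 1L]] <- if (l < L) tanh(A) else A
  }
  list(out = h[[L + 1L]], h = h)
}

# Reverse pass from dout = dLoss/dout (B x out).  Returns parameter
# gradients and dLoss/dinput.
mlp_backward <- function(net, cache, dout) {
  L <- length(net$W)
  gW <- vector("list", L)
  gb <- vector("list", L)
  dA <- dout                                 # last layer is linear
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(cache$h[[l]], dA)
    gb[[l]] <- colSums(dA)
    dh <- dA %*% t(net$W[[l]])
    if (l > 1L) dA <- dh * (1 - cache$h[[l]]^2)
  }
  list(W = gW, b = gb, dx = dh)
}

# Gradient of the critic output (summed over the batch) with respect to
# its input, i.e. rows of d D(x)/dx.  Critic output must be B x 1.
mlp_input_grad <- function(net, cache) {
  L <- length(net$W)
  dA <- matrix(1, nrow(cache$h[[1L]]), 1L)
  for (l in rev(seq_len(L))) {
    dh <- dA %*% t(net$W[[l]])
    if (l > 1L) dA <- dh * (1 - cache$h[[l]]^2)
  }
  dh
}

# Gradient-penalty value and its gradient with respect to the critic
# parameters, by forward-over-reverse ("double backprop"):
#   P = mean_b (||g_b|| - 1)^2,  g_b = d D(xhat_b)/d xhat_b.
# dP/dtheta = d/dtheta sum_b <R_b, g_b(theta)> with R = dP/dg held
# fixed; the inner product is a directional derivative of D, computed by
# a tangent (dual-number) forward stream and differentiated by a reverse
# sweep through both streams.
mlp_penalty_grads <- function(net, xhat) {
  L <- length(net$W)
  B <- nrow(xhat)
  cache <- mlp_forward(net, xhat)
  h <- cache$h
  G <- mlp_input_grad(net, cache)
  norms <- sqrt(rowSums(G^2))
  P <- mean((norms - 1)^2)
  R <- (2 / B) * ((norms - 1) / pmax(norms, 1e-12)) * G

  # tangent forward: Td[[l + 1]] = d/d eps  h_l(xhat + eps R)
  Td <- vector("list", L + 1L)
  Adot <- vector("list", L)
  Td[[1L]] <- R
  for (l in seq_len(L)) {
    Adot[[l]] <- Td[[l]] %*% net$W[[l]]
    Td[[l + 1L]] <- if (l < L) (1 - h[[l + 1L]]^2) * Adot[[l]] else Adot[[l]]
  }

  # reverse sweep: alpha = adjoint of the primal pre-activation,
  # beta = adjoint of the tangent pre-activation
  gW <- vector("list", L)
  gb <- vector("list", L)
  alpha <- matrix(0, B, 1L)
  beta <- matrix(1, B, 1L)
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(h[[l]], alpha) + crossprod(Td[[l]], beta)
    gb[[l]] <- colSums(alpha)
    if (l > 1L) {
      p <- alpha %*% t(net$W[[l]])
      q <- beta %*% t(net$W[[l]])
      t_prev <- h[[l]]                       # tanh(a_{l-1})
      phi1 <- 1 - t_prev^2
      phi2 <- -2 * t_prev * phi1
      alpha <- p * phi1 + q * Adot[[l - 1L]] * phi2
      beta <- q * phi1
    }
  }
  list(penalty = P, W = gW, b = gb)
}

# RMSprop with the usual decaying mean of squared gradients.
rmsprop_init <- function(net) {
  list(W = lapply(net$W, function(w) w * 0),
       b = lapply(net$b, function(v) v * 0))
}

rmsprop_step <- function(net, grads, state, lr, rho = 0.9, eps = 1e-8) {
  for (l in seq_along(net$W)) {
    state$W[[l]] <- rho * state$W[[l]] + (1 - rho) * grads$W[[l]]^2
    state$b[[l]] <- rho * state$b[[l]] + (1 - rho) * grads$b[[l]]^2
    net$W[[l]] <- net$W[[l]] - lr * grads$W[[l]] / (sqrt(state$W[[l]]) + eps)
    net$b[[l]] <- net$b[[l]] - lr * grads$b[[l]] / (sqrt(state$b[[l]]) + eps)
  }
  list(net = net, state = state)
}

add_grads <- function(g1, g2, scale = 1) {
  list(W = Map(function(a, b) a + scale * b, g1$W, g2$W),
       b = Map(function(a, b) a + scale * b, g1$b, g2$b))
}
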