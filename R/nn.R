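# Minimal layer framework: stride-1 same-padded convolutions (2-D and 3-D,
# optional dilation) via compiled im2col, nearest-neighbor up/down sampling,
# dense layers, instance normalization and elementwise activations, each with
# an explicit backward pass. Feature maps are (H, W, C) or (D, H, W, C)
# arrays; network parameters live in flat named lists of arrays so the
# optimizers below can walk them generically. Gradient correctness is pinned
# by finite-difference tests.

init_mat <- function(nin, nout, scale = sqrt(2 / (nin + nout))) {
  matrix(rnorm(nin * nout, 0, scale), nin, nout)
}

conv2d_f <- function(x, W, b, k = 3L, dil = 1L) {
  d <- dim(x)
  cols <- im2col2d_cpp(x, d[1], d[2], d[3], k, dil)
  out <- cols %*% W
  out <- sweep(out, 2, b, "+")
  list(out = array(out, c(d[1], d[2], ncol(W))),
       cache = list(cols = cols, W = W, dims = d, k = k, dil = dil))
}

conv2d_b <- function(gout, cache) {
  d <- cache$dims
  gmat <- matrix(gout, d[1] * d[2], ncol(cache$W))
  dW <- crossprod(cache$cols, gmat)
  db <- colSums(gmat)
  dcols <- tcrossprod(gmat, cache$W)
  dx <- array(col2im2d_cpp(dcols, d[1], d[2], d[3], cache$k, cache$dil), d)
  list(dx = dx, dW = dW, db = db)
}

conv3d_f <- function(x, W, b, k = 3L, dil = 1L) {
  d <- dim(x)
  cols <- im2col3d_cpp(x, d[1], d[2], d[3], d[4], k, dil)
  out <- sweep(cols %*% W, 2, b, "+")
  list(out = array(out, c(d[1], d[2], d[3], ncol(W))),
       cache = list(cols = cols, W = W, dims = d, k = k, dil = dil))
}

conv3d_b <- function(gout, cache) {
  d <- cache$dims
  gmat <- matrix(gout, prod(d[1:3]), ncol(cache$W))
  dW <- crossprod(cache$cols, gmat)
  db <- colSums(gmat)
  dcols <- tcrossprod(gmat, cache$W)
  dx <- array(col2im3d_cpp(dcols, d[1], d[2], d[3], d[4], cache$k, cache$dil), d)
  list(dx = dx, dW = dW, db = db)
}

relu_f <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_b <- function(gout, cache) gout * cache

lrelu_f <- function(x, alpha = 0.1)
  list(out = ifelse(x > 0, x, alpha * x), cache = list(pos = x > 0, alpha = alpha))
lrelu_b <- function(gout, cache)
  gout * ifelse(cache$pos, 1, cache$alpha)

sigmoid_f <- function(x) {
  s <- sigmoid(x)
  list(out = s, cache = s)
}
sigmoid_b <- function(gout, cache) gout * cache * (1 - cache)

tanh_f <- function(x) {
  t <- tanh(x)
  list(out = t, cache = t)
}
tanh_b <- function(gout, cache) gout * (1 - cache^2)

odd <- function(n) seq(1L, n, 2L)

avgpool2_f <- function(x) {
  d <- dim(x)
  i <- odd(d[1]); j <- odd(d[2])
  out <- (x[i, j, , drop = FALSE] + x[i + 1L, j, , drop = FALSE] +
          x[i, j + 1L, , drop = FALSE] + x[i + 1L, j + 1L, , drop = FALSE]) / 4
  list(out = out, cache = d)
}

avgpool2_b <- function(gout, cache) {
  d <- cache
  dx <- array(0, d)
  i <- odd(d[1]); j <- odd(d[2])
  g4 <- gout / 4
  dx[i, j, ] <- g4; dx[i + 1L, j, ] <- g4
  dx[i, j + 1L, ] <- g4; dx[i + 1L, j + 1L, ] <- g4
  dx
}

upsample2_f <- function(x) {
  d <- dim(x)
  list(out = x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), ,
               drop = FALSE],
       cache = d)
}

upsample2_b <- function(gout, cache) {
  d <- dim(gout)
  i <- odd(d[1]); j <- odd(d[2])
  gout[i, j, , drop = FALSE] + gout[i + 1L, j, , drop = FALSE] +
    gout[i, j + 1L, , drop = FALSE] + gout[i + 1L, j + 1L, , drop = FALSE]
}

upsample3d_f <- function(x) {
  d <- dim(x)
  list(out = x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2),
               rep(seq_len(d[3]), each = 2), , drop = FALSE],
       cache = d)
}

upsample3d_b <- function(gout, cache) {
  d <- dim(gout)
  i <- odd(d[1]); j <- odd(d[2]); k <- odd(d[3])
  acc <- 0
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1)
    acc <- acc + gout[i + di, j + dj, k + dk, , drop = FALSE]
  acc
}

dense_f <- function(x, W, b) {
  x <- as.numeric(x)
  list(out = drop(x %*% W) + b, cache = list(x = x, W = W))
}

dense_b <- function(gout, cache) {
  gout <- as.numeric(gout)
  list(dx = drop(cache$W %*% gout), dW = outer(cache$x, gout), db = gout)
}

# Instance normalization over spatial positions, per channel, with affine
# scale/shift. `x` is any spatial array with channels last.
instnorm_f <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  C <- d[length(d)]
  n <- prod(d) / C
  xm <- matrix(x, n, C)
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  v <- colMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, inv, "*")
  y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(out = array(y, d),
       cache = list(xhat = xhat, inv = inv, gamma = gamma, d = d, n = n, C = C))
}

instnorm_b <- function(gout, cache) {
  gm <- matrix(gout, cache$n, cache$C)
  dgamma <- colSums(gm * cache$xhat)
  dbeta <- colSums(gm)
  dxhat <- sweep(gm, 2, cache$gamma, "*")
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * cache$xhat)
  dx <- sweep(dxhat, 2, m1) - sweep(cache$xhat, 2, m2, "*")
  dx <- sweep(dx, 2, cache$inv, "*")
  list(dx = array(dx, cache$d), dgamma = dgamma, dbeta = dbeta)
}

# ---- optimizers over flat named parameter lists ----------------------------

sgd_state <- function(params) tree_map(function(p) p * 0, params)

sgd_step <- function(params, grads, state, lr, momentum = 0, weight_decay = 0) {
  for (nm in names(params)) {
    g <- grads[[nm]] + weight_decay * params[[nm]]
    state[[nm]] <- momentum * state[[nm]] - lr * g
    params[[nm]] <- params[[nm]] + state[[nm]]
  }
  list(params = params, state = state)
}

adam_state <- function(params)
  list(m = tree_map(function(p) p * 0, params),
       v = tree_map(function(p) p * 0, params), t = 0L)

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]] + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / (1 - beta1^state$t)
    vh <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

# Elementwise gradient clamping keeps the hand-rolled training loops stable.
clamp_grads <- function(grads, limit = 5) {
  tree_map(function(g) pmax(pmin(g, limit), -limit), grads)
}

zero_like <- function(params) tree_map(function(p) p * 0, params)

add_grads <- function(a, b) tree_map2(`+`, a, b)
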