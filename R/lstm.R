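#' LSTM parameter set with diagonal cell-to-gate (peephole) weights
#'
#' Input, recurrent and bias weights for the input, forget, cell and output
#' gates, plus strictly diagonal cell-to-gate weights (stored as vectors
#' `wci`, `wcf`, `wco`) connecting the cell state to the three gates.
#'
#' @param input_dim Input dimension D.
#' @param hidden_dim Hidden dimension H.
#' @param scale Initialization scale for the weight matrices.
#' @return A flat named list of arrays (class `lstm_params`).
#' @export
lstm_params <- function(input_dim, hidden_dim, scale = 0.2) {
  D <- as.integer(input_dim); H <- as.integer(hidden_dim)
  p <- list()
  for (g in c("i", "f", "c", "o")) {
    p[[paste0("Wx", g)]] <- matrix(rnorm(D * H, 0, scale), D, H)
    p[[paste0("Wh", g)]] <- matrix(rnorm(H * H, 0, scale), H, H)
    p[[paste0("b", g)]] <- numeric(H)
  }
  for (g in c("i", "f", "o")) p[[paste0("wc", g)]] <- numeric(H)
  structure(p, input_dim = D, hidden_dim = H, class = "lstm_params")
}

#' Initial (zero) LSTM state
#' @param hidden_dim Hidden dimension.
#' @return List with `h` and `c`, both zero vectors.
#' @export
lstm_state <- function(hidden_dim) {
  list(h = numeric(hidden_dim), c = numeric(hidden_dim))
}

#' One LSTM step
#'
#' Gate equations with peephole terms: the input and forget gates see the
#' previous cell state through the diagonal weights, the output gate sees the
#' updated cell state; `h_t = o_t * tanh(c_t)`.
#'
#' @param x Input vector (length D).
#' @param state List with `h`, `c` (length H).
#' @param params An [lstm_params()] set.
#' @return Updated state: list with `h`, `c` and the gate activations
#'   (`i`, `f`, `g`, `o`) for inspection.
#' @export
lstm_step <- function(x, state, params) {
  D <- attr(params, "input_dim"); H <- attr(params, "hidden_dim")
  if (length(x) != D) stopf("input length %d != input_dim %d", length(x), D)
  if (length(state$h) != H || length(state$c) != H)
    stopf("state length mismatch")
  x <- as.numeric(x)
  i <- sigmoid(drop(x %*% params$Wxi) + drop(state$h %*% params$Whi) +
                 params$wci * state$c + params$bi)
  f <- sigmoid(drop(x %*% params$Wxf) + drop(state$h %*% params$Whf) +
                 params$wcf * state$c + params$bf)
  g <- tanh(drop(x %*% params$Wxc) + drop(state$h %*% params$Whc) + params$bc)
  c_new <- f * state$c + i * g
  o <- sigmoid(drop(x %*% params$Wxo) + drop(state$h %*% params$Who) +
                 params$wco * c_new + params$bo)
  list(h = o * tanh(c_new), c = c_new, i = i, f = f, g = g, o = o)
}

# Forward over a sequence with full caches for backpropagation through time.
lstm_seq_forward <- function(xs, params) {
  st <- lstm_state(attr(params, "hidden_dim"))
  caches <- vector("list", length(xs))
  hs <- matrix(0, length(xs), attr(params, "hidden_dim"))
  for (t in seq_along(xs)) {
    prev <- st
    st <- lstm_step(xs[[t]], st, params)
    caches[[t]] <- list(x = as.numeric(xs[[t]]), prev = prev, cur = st)
    hs[t, ] <- st$h
  }
  list(hs = hs, caches = caches, final = st)
}

# Backpropagation through time for the peephole LSTM. `dh_seq` is a T x H
# matrix of gradients w.r.t. each hidden output. Returns parameter gradients
# and gradients w.r.t. each input.
lstm_seq_backward <- function(params, caches, dh_seq) {
  H <- attr(params, "hidden_dim")
  grads <- zero_like(params)
  Tn <- length(caches)
  dxs <- vector("list", Tn)
  dh_next <- numeric(H); dc_next <- numeric(H)
  for (t in rev(seq_len(Tn))) {
    cc <- caches[[t]]
    s <- cc$cur; prev <- cc$prev
    tc <- tanh(s$c)
    dh <- dh_seq[t, ] + dh_next
    do <- dh * tc
    dao <- do * s$o * (1 - s$o)
    dc <- dh * s$o * (1 - tc^2) + dc_next + dao * params$wco
    df <- dc * prev$c
    di <- dc * s$g
    dg <- dc * s$i
    daf <- df * s$f * (1 - s$f)
    dai <- di * s$i * (1 - s$i)
    dag <- dg * (1 - s$g^2)
    grads$Wxi <- grads$Wxi + outer(cc$x, dai)
    grads$Wxf <- grads$Wxf + outer(cc$x, daf)
    grads$Wxc <- grads$Wxc + outer(cc$x, dag)
    grads$Wxo <- grads$Wxo + outer(cc$x, dao)
    grads$Whi <- grads$Whi + outer(prev$h, dai)
    grads$Whf <- grads$Whf + outer(prev$h, daf)
    grads$Whc <- grads$Whc + outer(prev$h, dag)
    grads$Who <- grads$Who + outer(prev$h, dao)
    grads$bi <- grads$bi + dai
    grads$bf <- grads$bf + daf
    grads$bc <- grads$bc + dag
    grads$bo <- grads$bo + dao
    grads$wci <- grads$wci + dai * prev$c
    grads$wcf <- grads$wcf + daf * prev$c
    grads$wco <- grads$wco + dao * s$c
    dxs[[t]] <- drop(params$Wxi %*% dai) + drop(params$Wxf %*% daf) +
      drop(params$Wxc %*% dag) + drop(params$Wxo %*% dao)
    dh_next <- drop(params$Whi %*% dai) + drop(params$Whf %*% daf) +
      drop(params$Whc %*% dag) + drop(params$Who %*% dao)
    dc_next <- dc * s$f + daf * params$wcf + dai * params$wci
  }
  list(grads = grads, dxs = dxs)
}

#' Spatial attention parameters
#' @param input_dim Feature dimension D of the N x D token matrix.
#' @param scale Initialization scale.
#' @return Flat named list with scoring weights `W` (D x 1) and bias `b`.
#' @export
attn_params <- function(input_dim, scale = 0.2) {
  list(W = matrix(rnorm(input_dim, 0, scale), input_dim, 1), b = 0)
}

#' Spatial attention over a token matrix
#'
#' Scores each of the N tokens (rows of `X`), softmaxes over tokens so the
#' weights sum to one, and returns the weighted sum of tokens: a length-D
#' summary emphasizing the informative rows.
#'
#' @param X N x D feature matrix.
#' @param params An [attn_params()] list.
#' @return List with `summary` (length D), `weights` (length N, sums to 1).
#' @export
spatial_attention <- function(X, params) {
  X <- as.matrix(X)
  if (ncol(X) != nrow(params$W)) stopf("feature dimension mismatch")
  scores <- drop(X %*% params$W) + params$b
  a <- softmax_vec(scores)
  list(summary = drop(crossprod(X, a)), weights = a)
}

# Backward pass of spatial attention given d(summary). Returns gradients for
# the scoring parameters and for X.
spatial_attention_b <- function(X, params, fwd, dsummary) {
  a <- fwd$weights
  da <- drop(X %*% dsummary)
  dscores <- a * (da - sum(a * da))
  list(dW = crossprod(X, dscores), db = sum(dscores),
       dX = tcrossprod(a, dsummary) + tcrossprod(dscores, drop(params$W)))
}

#' Transductive proximity weights
#'
#' Gaussian kernel weights `z_i` proportional to `exp(-d_i^2 / (2 sigma_k^2))`
#' where `d_i` is the Euclidean distance from training feature `i` to the test
#' feature; normalized to sum to one. As `sigma_k` grows the weights flatten
#' to uniform.
#'
#' @param train_features Matrix (one feature vector per row) or list of
#'   vectors.
#' @param test_feature Numeric vector.
#' @param sigma_k Kernel bandwidth (> 0).
#' @return Normalized weights (length = number of training samples).
#' @export
transductive_weights <- function(train_features, test_feature, sigma_k) {
  if (!(is.numeric(sigma_k) && length(sigma_k) == 1 && sigma_k > 0))
    stopf("`sigma_k` must be > 0")
  if (is.list(train_features))
    train_features <- do.call(rbind, train_features)
  train_features <- as.matrix(train_features)
  if (nrow(train_features) == 0) stopf("empty training feature set")
  d2 <- rowSums(sweep(train_features, 2, as.numeric(test_feature))^2)
  logw <- -d2 / (2 * sigma_k^2)
  w <- exp(logw - max(logw))
  w / sum(w)
}

#' Transductive configuration
#'
#' @param sigma_k Proximity kernel bandwidth (> 0); `Inf` gives uniform
#'   weights (global fine-tuning).
#' @param steps Number of adaptation gradient steps K (>= 0; 0 is a no-op).
#' @param learn_rate Adaptation learning rate.
#' @return An object of class `transductive_config`.
#' @export
transductive_config <- function(sigma_k = 5, steps = 0L, learn_rate = 1e-3) {
  if (!(is.numeric(sigma_k) && length(sigma_k) == 1 && sigma_k > 0))
    stopf("`sigma_k` must be > 0")
  check_number(steps, "steps", lower = 0)
  check_number(learn_rate, "learn_rate", lower = 0, strict_lower = TRUE)
  structure(list(sigma_k = sigma_k, steps = as.integer(steps),
                 learn_rate = learn_rate), class = "transductive_config")
}

#' Run an input sequence through attention and the LSTM
#'
#' When `attn` is provided each element of `sequence` must be an N x D token
#' matrix; spatial attention pools it to a length-D vector before the LSTM
#' step. Otherwise elements are used directly as input vectors. The recurrence
#' starts from the zero state.
#'
#' @param sequence Non-empty list of input vectors or token matrices.
#' @param params An [lstm_params()] set.
#' @param attn Optional [attn_params()] list.
#' @return Matrix of hidden states, one row per time step.
#' @export
run_sequence <- function(sequence, params, attn = NULL) {
  if (length(sequence) == 0) stopf("empty sequence")
  xs <- lapply(sequence, function(el) {
    if (is.null(attn)) as.numeric(el)
    else spatial_attention(as.matrix(el), attn)$summary
  })
  lstm_seq_forward(xs, params)$hs
}
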