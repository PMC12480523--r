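test_that("zero-parameter LSTM step gives zero state", {
  p <- lstm_params(2, 3, scale = 0)
  st <- lstm_step(c(1, -2), lstm_state(3), p)
  expect_equal(st$h, rep(0, 3))
  expect_equal(st$c, rep(0, 3))
  expect_true(all(st$i > 0 & st$i < 1))
  expect_error(lstm_step(c(1, 2, 3), lstm_state(3), p), "input length")
})

test_that("lstm_step matches the independent scalar oracle", {
  set.seed(6)
  for (k in 1:100) {
    H <- sample(1:3, 1); D <- sample(1:3, 1)
    p <- lstm_params(D, H, scale = 0.8)
    x <- rnorm(D)
    st0 <- list(h = rnorm(H), c = rnorm(H))
    got <- lstm_step(x, st0, p)
    ref <- oracle_lstm_step(x, st0$h, st0$c, p)
    expect_lt(max(abs(got$h - ref$h)), 1e-10)
    expect_lt(max(abs(got$c - ref$c)), 1e-10)
  }
})

test_that("gates stay strictly inside (0,1) for random draws", {
  set.seed(8)
  for (k in 1:20) {
    p <- lstm_params(2, 4, scale = 2)
    st <- lstm_step(rnorm(2), list(h = rnorm(4), c = rnorm(4)), p)
    expect_true(all(st$i > 0 & st$i < 1 & st$f > 0 & st$f < 1 &
                      st$o > 0 & st$o < 1))
  }
})

test_that("spatial attention normalizes, pools and is permutation-equivariant", {
  ap <- attn_params(3, scale = 0)
  X <- matrix(rnorm(12), 4, 3)
  out <- spatial_attention(X, ap)
  expect_equal(out$weights, rep(0.25, 4))          # softmax of constants
  expect_equal(out$summary, colMeans(X))
  set.seed(2)
  ap2 <- attn_params(3)
  o2 <- spatial_attention(X, ap2)
  expect_lt(abs(sum(o2$weights) - 1), 1e-12)
  # hand case: scores 0 and ln 3 -> weights 1/4 and 3/4
  ap3 <- list(W = matrix(c(log(3)), 1, 1), b = 0)
  X3 <- matrix(c(0, 1), 2, 1)
  o3 <- spatial_attention(X3, ap3)
  expect_equal(o3$weights, c(0.25, 0.75))
  expect_equal(o3$summary, 0.25 * 0 + 0.75 * 1)
  # permuting tokens permutes the weights identically
  perm <- c(3, 1, 4, 2)
  op <- spatial_attention(X[perm, ], ap2)
  expect_equal(op$weights, o2$weights[perm])
  expect_equal(op$summary, o2$summary)
})

test_that("transductive weights follow the Gaussian proximity kernel", {
  f <- rbind(c(0, 0), c(1, 0))
  w <- transductive_weights(f, c(0, 0), sigma_k = 1)
  hand <- c(1, exp(-0.5)) / (1 + exp(-0.5))
  expect_equal(w, hand)
  expect_equal(which.max(w), 1L)
  # flat kernel limit -> uniform
  wu <- transductive_weights(f, c(0, 0), sigma_k = 1e9)
  expect_equal(wu, c(0.5, 0.5), tolerance = 1e-9)
  # strictly decreasing in distance
  f3 <- rbind(c(0, 0), c(2, 0), c(5, 0))
  w3 <- transductive_weights(f3, c(0, 0), 2)
  expect_true(all(diff(w3) < 0))
  expect_error(transductive_weights(f, c(0, 0), -1), "sigma_k")
})

test_that("run_sequence folds attention and the recurrence over time", {
  p <- lstm_params(2, 3, scale = 0.3)
  xs <- lapply(1:4, function(t) rnorm(2))
  hs <- run_sequence(xs, p)
  expect_identical(dim(hs), c(4L, 3L))
  expect_equal(hs[1, ], lstm_step(xs[[1]], lstm_state(3), p)$h)
  expect_error(run_sequence(list(), p), "empty")
  p0 <- lstm_params(2, 3, scale = 0)
  expect_true(all(run_sequence(xs, p0) == 0))
  # with attention: token matrices pooled before the recurrence
  ap <- attn_params(2, scale = 0)
  toks <- lapply(1:3, function(t) matrix(rnorm(10), 5, 2))
  hs2 <- run_sequence(toks, p, attn = ap)
  manual <- run_sequence(lapply(toks, colMeans), p)
  expect_equal(hs2, manual)
})
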