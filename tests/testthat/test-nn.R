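# Finite-difference checks pin the analytic backward passes of the layer
# framework; everything downstream (U-Net, critics, 3-D generator) composes
# these primitives.

test_that("2-D convolution gradients match finite differences", {
  set.seed(1)
  x <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  W <- init_mat(9 * 2, 3); b <- rnorm(3)
  g <- array(rnorm(6 * 6 * 3), c(6, 6, 3))
  fwd <- lungrecon:::conv2d_f(x, W, b)
  bk <- lungrecon:::conv2d_b(g, fwd$cache)
  expect_lt(max(abs(num_grad(function(xx)
    sum(lungrecon:::conv2d_f(xx, W, b)$out * g), x) - as.numeric(bk$dx))), 1e-6)
  expect_lt(max(abs(num_grad(function(WW)
    sum(lungrecon:::conv2d_f(x, WW, b)$out * g), W) - as.numeric(bk$dW))), 1e-6)
  expect_lt(max(abs(num_grad(function(bb)
    sum(lungrecon:::conv2d_f(x, W, bb)$out * g), b) - bk$db)), 1e-6)
})

test_that("dilated 3-D convolution gradients match finite differences", {
  set.seed(2)
  x <- array(rnorm(4 * 4 * 4 * 2), c(4, 4, 4, 2))
  W <- init_mat(27 * 2, 2); b <- rnorm(2)
  g <- array(rnorm(4 * 4 * 4 * 2), c(4, 4, 4, 2))
  fwd <- lungrecon:::conv3d_f(x, W, b, dil = 2L)
  bk <- lungrecon:::conv3d_b(g, fwd$cache)
  expect_lt(max(abs(num_grad(function(xx)
    sum(lungrecon:::conv3d_f(xx, W, b, dil = 2L)$out * g), x) -
      as.numeric(bk$dx))), 1e-6)
  expect_lt(max(abs(num_grad(function(WW)
    sum(lungrecon:::conv3d_f(x, WW, b, dil = 2L)$out * g), W) -
      as.numeric(bk$dW))), 1e-6)
})

test_that("pooling, upsampling and instance-norm backward passes are exact", {
  set.seed(3)
  x <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  g2 <- array(rnorm(2 * 2 * 2), c(2, 2, 2))
  fp <- lungrecon:::avgpool2_f(x)
  expect_lt(max(abs(num_grad(function(xx)
    sum(lungrecon:::avgpool2_f(xx)$out * g2), x) -
      as.numeric(lungrecon:::avgpool2_b(g2, fp$cache)))), 1e-6)
  gu <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  fu <- lungrecon:::upsample2_f(x)
  expect_lt(max(abs(num_grad(function(xx)
    sum(lungrecon:::upsample2_f(xx)$out * gu), x) -
      as.numeric(lungrecon:::upsample2_b(gu, fu$cache)))), 1e-6)
  x3 <- array(rnorm(3 * 3 * 3 * 2), c(3, 3, 3, 2))
  gu3 <- array(rnorm(6 * 6 * 6 * 2), c(6, 6, 6, 2))
  fu3 <- lungrecon:::upsample3d_f(x3)
  expect_lt(max(abs(num_grad(function(xx)
    sum(lungrecon:::upsample3d_f(xx)$out * gu3), x3) -
      as.numeric(lungrecon:::upsample3d_b(gu3, fu3$cache)))), 1e-6)
  gm <- rnorm(2); bt <- rnorm(2)
  gi <- array(rnorm(length(x3)), dim(x3))
  fi <- lungrecon:::instnorm_f(x3, gm, bt)
  bi <- lungrecon:::instnorm_b(gi, fi$cache)
  expect_lt(max(abs(num_grad(function(xx)
    sum(lungrecon:::instnorm_f(xx, gm, bt)$out * gi), x3) -
      as.numeric(bi$dx))), 1e-5)
  expect_lt(max(abs(num_grad(function(gg)
    sum(lungrecon:::instnorm_f(x3, gg, bt)$out * gi), gm) - bi$dgamma)), 1e-6)
})

test_that("optimizers follow their update rules", {
  p <- list(w = matrix(1, 1, 1))
  g <- list(w = matrix(2, 1, 1))
  st <- lungrecon:::sgd_state(p)
  up <- lungrecon:::sgd_step(p, g, st, lr = 0.1, momentum = 0.5,
                             weight_decay = 0)
  expect_equal(as.numeric(up$params$w), 1 - 0.1 * 2)
  up2 <- lungrecon:::sgd_step(up$params, g, up$state, 0.1, 0.5, 0)
  # velocity: 0.5*(-0.2) - 0.1*2 = -0.3
  expect_equal(as.numeric(up2$params$w), 0.8 - 0.3)
  ad <- lungrecon:::adam_state(p)
  au <- lungrecon:::adam_step(p, g, ad, lr = 0.1, beta1 = 0.9, beta2 = 0.999)
  # first Adam step moves by ~lr in the gradient direction
  expect_equal(as.numeric(au$params$w), 1 - 0.1 * 2 / (2 + 1e-8),
               tolerance = 1e-6)
})

test_that("U-Net forward respects the contract and backward is exact", {
  cfg <- seg_config(depth = 2, channels = 4, seed = 3)
  m <- build_seg_generator(cfg)
  img <- matrix(rnorm(32 * 32), 32, 32)
  fwd <- lungrecon:::seg_forward(m$params, img, cfg)
  expect_identical(dim(fwd$prob), c(32L, 32L))
  expect_true(all(fwd$prob >= 0 & fwd$prob <= 1))
  # fixed seed, fixed input -> deterministic output
  expect_identical(fwd$prob,
                   lungrecon:::seg_forward(m$params, img, cfg)$prob)
  # odd image size errors with guidance
  expect_error(lungrecon:::seg_forward(m$params, matrix(0, 30, 30), cfg),
               "divisible")
  # parameter count grows monotonically with channels
  n1 <- n_params(build_seg_generator(seg_config(channels = 4)))
  n2 <- n_params(build_seg_generator(seg_config(channels = 8)))
  expect_gt(n2, n1)
  # spot-check full-network gradients
  set.seed(4)
  dp <- matrix(rnorm(1024), 32, 32)
  dv <- matrix(rnorm(1024), 32, 32)
  g <- lungrecon:::seg_backward(m$params, fwd, dp, dv, cfg)
  loss <- function(pp) {
    f <- lungrecon:::seg_forward(pp, img, cfg)
    sum(f$prob * dp) + sum(f$value * dv)
  }
  for (nm in c("enc1_W", "dec2_W", "out_W", "val_b")) {
    idx <- seq_len(min(4, length(m$params[[nm]])))
    gn <- vapply(idx, function(i) {
      eps <- 1e-6
      p1 <- m$params; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- m$params; p2[[nm]][i] <- p2[[nm]][i] - eps
      (loss(p1) - loss(p2)) / (2 * eps)
    }, numeric(1))
    expect_lt(max(abs(gn - g[[nm]][idx])), 1e-5)
  }
})
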