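test_that("feature extraction is per-slice and permutation-equivariant", {
  m <- build_reconstructor(tiny_recon_config())
  slices <- lapply(1:5, function(z) matrix(rnorm(256), 16, 16))
  f <- extract_features(slices, m$enc)
  expect_identical(dim(f), c(5L, 4L))
  expect_equal(f[2, ], extract_features(slices[2], m$enc)[1, ])
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(extract_features(slices[perm], m$enc), f[perm, ])
  # identical slices give identical rows
  same <- extract_features(list(slices[[1]], slices[[1]]), m$enc)
  expect_equal(same[1, ], same[2, ])
  expect_error(extract_features(list(), m$enc), "empty")
})

test_that("generator loss is MAE plus the weighted adversarial term", {
  gt <- array(rbinom(64, 1, 0.3), c(4, 4, 4))
  expect_equal(recon_gen_loss(gt, gt, 1, partial = 0.56), 0)
  pred <- pmin(pmax(gt + 0.1, 0), 1)
  expect_equal(recon_gen_loss(pred, gt, 1, partial = 0),
               mean(abs(pred - gt)))
  # MAE 0.2, d = e^-1, weight 0.56 -> 0.2 + 0.56
  p2 <- gt + 0.2 * ifelse(gt == 1, -1, 1)
  expect_equal(recon_gen_loss(p2, gt, exp(-1), partial = 0.56), 0.2 + 0.56)
  expect_error(recon_gen_loss(array(0, c(2, 2, 2)), gt, 1), "shape")
  expect_error(recon_gen_loss(gt, gt, 0), "d_score")
})

test_that("discriminator scores are in (0,1), deterministic and sensitive", {
  m <- build_reconstructor(tiny_recon_config())
  v <- array(runif(16^3), c(16, 16, 16))
  s <- recon_disc_score(m, v)
  expect_gt(s, 0); expect_lt(s, 1)
  expect_identical(s, recon_disc_score(m, v))
  v2 <- v; v2[1:8, , ] <- 1 - v2[1:8, , ]
  expect_gt(abs(recon_disc_score(m, v2) - s), 0)
  expect_error(recon_disc_score(m, matrix(0, 4, 4)), "3-D")
})

test_that("reconstruct obeys shape, range and determinism contracts", {
  m <- build_reconstructor(tiny_recon_config())
  slices <- lapply(1:16, function(z) matrix(rnorm(256), 16, 16))
  out <- reconstruct(m, slices)
  expect_identical(dim(out$prob), c(16L, 16L, 16L))
  expect_true(all(out$prob >= 0 & out$prob <= 1))
  expect_true(all(out$mask %in% c(0, 1)))
  expect_identical(out$prob, reconstruct(m, slices)$prob)
  expect_error(reconstruct(m, slices[1]), "minimum")
})

test_that("evaluate_reconstruction delegates to the surface metrics", {
  s1 <- rand_sphere_volume(3.2, 12, c(6, 6, 6))
  ev <- evaluate_reconstruction(s1, s1)
  expect_equal(ev$HD, 0)
  expect_equal(ev$ED, 0)
  s2 <- rand_sphere_volume(3.2, 12, c(7, 6, 6))
  ev2 <- evaluate_reconstruction(s1, s2)
  expect_equal(ev2$HD, hd(surface_points(s1), surface_points(s2)))
  expect_equal(ev2$ED, volume_ed(s1, s2))
  expect_gte(ev2$HD, ev2$ED)        # max dominates the mean
  expect_warning(ev3 <- evaluate_reconstruction(s1 * 0L, s1), "empty")
  expect_equal(ev3$HD, Inf)
})

test_that("transductive adaptation reduces correctly in its limits", {
  ds <- cube_phantom_dataset()
  cfg <- tiny_recon_config(epochs = 1)
  tr <- train_reconstructor(ds, cfg)
  model <- tr$model
  train_pairs <- lungrecon:::recon_collect(ds, "train")
  test_seq <- lungrecon:::recon_collect(ds, "test")[[1]]$slices
  # K = 0 is a bit-exact no-op
  m0 <- transductive_adapt(model, train_pairs, test_seq,
                           transductive_config(steps = 0), seed = 4)
  expect_identical(m0$gen, model$gen)
  expect_identical(m0$lstm, model$lstm)
  # sigma_k -> Inf equals uniformly-weighted fine-tuning under a shared seed
  minf <- transductive_adapt(model, train_pairs, test_seq,
                             transductive_config(sigma_k = Inf, steps = 2,
                                                 learn_rate = 1e-3), seed = 4)
  n <- length(train_pairs)
  uni <- model
  seeds <- derive_seeds(4, 2)
  for (k in 1:2) {
    g <- NULL
    for (i in seq_len(n)) {
      fwd <- lungrecon:::recon_forward(uni, train_pairs[[i]]$slices,
                                       train = TRUE, drop_masks = NULL)
      dpred <- (1 / n) * sign(fwd$pred - train_pairs[[i]]$volume) /
        length(fwd$pred)
      gi <- lungrecon:::recon_backward(uni, fwd, dpred)
      g <- if (is.null(g)) gi else list(
        attn = lungrecon:::add_grads(g$attn, gi$attn),
        lstm = Map(lungrecon:::add_grads, g$lstm, gi$lstm),
        head = lungrecon:::add_grads(g$head, gi$head),
        gen = lungrecon:::add_grads(g$gen, gi$gen))
    }
    step1 <- function(p, gr)
      lungrecon:::tree_map2(function(a, b) a - 1e-3 * b, p, gr)
    uni$attn <- step1(uni$attn, g$attn)
    for (l in seq_along(uni$lstm)) {
      at <- attributes(uni$lstm[[l]])
      uni$lstm[[l]] <- step1(uni$lstm[[l]], g$lstm[[l]])
      attributes(uni$lstm[[l]]) <- at
    }
    uni$head <- step1(uni$head, g$head)
    uni$gen <- step1(uni$gen, g$gen)
  }
  expect_lt(lungrecon:::tree_max_abs_diff(minf$gen, uni$gen), 1e-8)
  expect_lt(lungrecon:::tree_max_abs_diff(minf$lstm[[1]], uni$lstm[[1]]), 1e-8)
  # adaptation does not increase the weighted training loss for a small rate
  feats <- do.call(rbind, lapply(train_pairs, function(s)
    colMeans(extract_features(s$slices, model$enc))))
  w <- transductive_weights(feats,
                            colMeans(extract_features(test_seq, model$enc)),
                            sigma_k = 5)
  wloss <- function(mm) sum(w * vapply(seq_along(train_pairs), function(i)
    mean(abs(lungrecon:::recon_forward(mm, train_pairs[[i]]$slices)$pred -
               train_pairs[[i]]$volume)), numeric(1)))
  mk <- transductive_adapt(model, train_pairs, test_seq,
                           transductive_config(sigma_k = 5, steps = 3,
                                               learn_rate = 1e-3), seed = 4)
  expect_lte(wloss(mk), wloss(model) + 1e-8)
})

test_that("training is deterministic and reduces MAE (also without adversary)", {
  ds <- cube_phantom_dataset()
  cfg <- tiny_recon_config(epochs = 3)
  r1 <- train_reconstructor(ds, cfg)
  r2 <- train_reconstructor(ds, cfg)
  expect_identical(r1$history, r2$history)
  expect_lt(tail(r1$history$mae, 1), r1$history$mae[1])
  cfg0 <- tiny_recon_config(epochs = 3)
  cfg0$adv_weight <- 0
  r0 <- train_reconstructor(ds, cfg0)
  expect_lt(tail(r0$history$mae, 1), r0$history$mae[1])
})
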