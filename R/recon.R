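#' Reconstruction stage configuration
#'
#' Defaults follow the tuned hyperparameters of the 3-D reconstruction stage:
#' TLSTM with 247 units, 4 layers and dropout 0.3; a six-block
#' deconvolutional generator (normalization + rectifier in each block);
#' adversarial weight 0.56; adaptive-moment optimizer with betas (0.6, 0.65);
#' generator learning rate 0.001 and discriminator learning rate 0.0015.
#' Desk-scale runs pass smaller `tlstm_units`/`tlstm_layers` and a 16-voxel
#' volume.
#'
#' @param encoder_channels Channels of the small frozen convolutional slice
#'   encoder (its pooled features are also the transductive proximity space).
#' @param tlstm_units Hidden units per TLSTM layer.
#' @param tlstm_layers Stacked TLSTM layers.
#' @param dropout Dropout rate between stacked layers (training only).
#' @param gen_channels Channels of the volume generator blocks.
#' @param adv_weight Adversarial weight in the generator loss.
#' @param gen_lr,disc_lr Learning rates.
#' @param beta1,beta2 Adaptive-moment parameters.
#' @param volume_size Output volume side (must be divisible by 4; the seed
#'   tensor is `volume_size/4` per side).
#' @param min_sequence Minimum accepted slice-sequence length.
#' @param threshold Occupancy binarization threshold.
#' @param epochs Training epochs.
#' @param seed Integer seed.
#' @return An object of class `recon_config`.
#' @export
recon_config <- function(encoder_channels = 6L, tlstm_units = 247L,
                         tlstm_layers = 4L, dropout = 0.3,
                         gen_channels = 6L, adv_weight = 0.56,
                         gen_lr = 0.001, disc_lr = 0.0015,
                         beta1 = 0.6, beta2 = 0.65, volume_size = 16L,
                         min_sequence = 2L, threshold = 0.5, epochs = 5L,
                         seed = 1L) {
  check_number(adv_weight, "adv_weight", lower = 0)
  check_number(tlstm_layers, "tlstm_layers", lower = 1)
  if (volume_size %% 4 != 0) stopf("`volume_size` must be divisible by 4")
  structure(list(encoder_channels = as.integer(encoder_channels),
                 tlstm_units = as.integer(tlstm_units),
                 tlstm_layers = as.integer(tlstm_layers), dropout = dropout,
                 gen_channels = as.integer(gen_channels),
                 adv_weight = adv_weight, gen_lr = gen_lr, disc_lr = disc_lr,
                 beta1 = beta1, beta2 = beta2,
                 volume_size = as.integer(volume_size),
                 min_sequence = as.integer(min_sequence),
                 threshold = threshold, epochs = as.integer(epochs),
                 seed = as.integer(seed)), class = "recon_config")
}

recon_encoder_init <- function(C) {
  list(W = init_mat(9L, C), b = numeric(C))
}

# Per-slice token matrix: conv + relu + 2x average pooling, flattened to
# (H/2 * W/2) x C.
encoder_tokens <- function(enc, slice) {
  x <- array(slice, c(nrow(slice), ncol(slice), 1L))
  a <- conv2d_f(x, enc$W, enc$b)
  r <- relu_f(a$out)
  p <- avgpool2_f(r$out)
  matrix(p$out, prod(dim(p$out)[1:2]), dim(p$out)[3])
}

#' Extract a per-slice feature sequence
#'
#' One feature row per ordered slice: the mean-pooled encoder activations.
#' Deterministic for fixed encoder weights; permuting the slices permutes the
#' rows identically.
#'
#' @param slices List of `H x W` matrices or an `H x W x T` array, ordered
#'   by z.
#' @param encoder Encoder weights (e.g. `model$enc` of a `recon_model`).
#' @return `T x D` feature matrix.
#' @export
extract_features <- function(slices, encoder) {
  slices <- as_slice_list(slices)
  if (length(slices) == 0) stopf("empty slice sequence")
  do.call(rbind, lapply(slices, function(s) colMeans(encoder_tokens(encoder, s))))
}

as_slice_list <- function(slices) {
  if (is.array(slices) && length(dim(slices)) == 3)
    slices <- lapply(seq_len(dim(slices)[3]), function(z) slices[, , z])
  slices
}

#' Build an untrained 3-D reconstruction model
#'
#' Frozen convolutional slice encoder, spatial attention, stacked peephole
#' TLSTM, a dense head mapping the final and mean hidden states to a seed
#' tensor, a six-block deconvolutional volume generator (upsample + 3-D
#' convolution + instance normalization + ReLU, sigmoid output) and a 3-D
#' dilated-convolution discriminator.
#'
#' @param config A [recon_config()].
#' @return An object of class `recon_model`.
#' @export
build_reconstructor <- function(config) {
  stopifnot(inherits(config, "recon_config"))
  with_seed(config$seed, {
    C <- config$encoder_channels
    U <- config$tlstm_units
    Cg <- config$gen_channels
    side <- config$volume_size %/% 4L
    enc <- recon_encoder_init(C)
    attn <- attn_params(C)
    lstm <- lapply(seq_len(config$tlstm_layers), function(l)
      lstm_params(if (l == 1) C else U, U))
    head <- list(W = init_mat(2L * U, side^3 * Cg, scale = 0.05),
                 b = numeric(side^3 * Cg))
    gen <- list()
    for (i in 1:5) {
      cin <- Cg
      gen[[paste0("g", i, "_W")]] <- init_mat(27L * cin, Cg)
      gen[[paste0("g", i, "_b")]] <- numeric(Cg)
      gen[[paste0("g", i, "_gamma")]] <- rep(1, Cg)
      gen[[paste0("g", i, "_beta")]] <- numeric(Cg)
    }
    gen$g6_W <- init_mat(27L * Cg, 1L)
    gen$g6_b <- 0
    disc <- list(d1_W = init_mat(27L, 8L), d1_b = numeric(8L),
                 d2_W = init_mat(27L * 8L, 8L), d2_b = numeric(8L),
                 dd_W = init_mat(8L, 1L), dd_b = 0)
    structure(list(enc = enc, attn = attn, lstm = lstm, head = head,
                   gen = gen, disc = disc, config = config),
              class = "recon_model")
  })
}

# Dropout masks between stacked LSTM layers (training only); one mask per
# layer boundary, shared across time, inverted scaling.
recon_dropout_masks <- function(config, seed) {
  if (config$dropout <= 0 || config$tlstm_layers < 2)
    return(NULL)
  with_seed(seed, lapply(seq_len(config$tlstm_layers - 1L), function(l)
    (runif(config$tlstm_units) > config$dropout) / (1 - config$dropout)))
}

# Full forward pass; when `train` is TRUE dropout masks are applied and all
# caches kept for backprop.
recon_forward <- function(model, slices, train = FALSE, drop_masks = NULL) {
  cfg <- model$config
  slices <- as_slice_list(slices)
  if (length(slices) < cfg$min_sequence)
    stopf("sequence shorter than the configured minimum (%d)", cfg$min_sequence)
  tokens <- lapply(slices, function(s) encoder_tokens(model$enc, s))
  att <- lapply(tokens, function(X) spatial_attention(X, model$attn))
  xs <- lapply(att, `[[`, "summary")
  layer_in <- list(xs)
  lstm_fwds <- vector("list", length(model$lstm))
  for (l in seq_along(model$lstm)) {
    fw <- lstm_seq_forward(layer_in[[l]], model$lstm[[l]])
    lstm_fwds[[l]] <- fw
    hs <- fw$hs
    if (train && !is.null(drop_masks) && l < length(model$lstm))
      hs <- sweep(hs, 2, drop_masks[[l]], "*")
    layer_in[[l + 1]] <- lapply(seq_len(nrow(hs)), function(t) hs[t, ])
  }
  hs_top <- lstm_fwds[[length(model$lstm)]]$hs
  Tn <- nrow(hs_top)
  z <- c(hs_top[Tn, ], colMeans(hs_top))
  hd <- dense_f(z, model$head$W, model$head$b)
  side <- cfg$volume_size %/% 4L
  x <- array(hd$out, c(side, side, side, cfg$gen_channels))
  caches <- list(tokens = tokens, att = att, lstm_fwds = lstm_fwds,
                 layer_in = layer_in, z = z, head = hd$cache, Tn = Tn,
                 drop_masks = drop_masks, gen = list())
  up_at <- c(2L, 4L)                      # blocks that upsample 2x
  for (i in 1:5) {
    blk <- list()
    if (i %in% up_at) {
      up <- upsample3d_f(x); x <- up$out; blk$up <- up$cache
    }
    cv <- conv3d_f(x, model$gen[[paste0("g", i, "_W")]],
                   model$gen[[paste0("g", i, "_b")]])
    nn <- instnorm_f(cv$out, model$gen[[paste0("g", i, "_gamma")]],
                     model$gen[[paste0("g", i, "_beta")]])
    rl <- relu_f(nn$out)
    blk$conv <- cv$cache; blk$inorm <- nn$cache; blk$relu <- rl$cache
    caches$gen[[i]] <- blk
    x <- rl$out
  }
  cv <- conv3d_f(x, model$gen$g6_W, model$gen$g6_b)
  sg <- sigmoid_f(cv$out)
  caches$gen[[6]] <- list(conv = cv$cache, sig = sg$cache)
  list(pred = sg$out[, , , 1], caches = caches)
}

# Backward pass from d(pred) to gradients of attention, LSTM stack, head and
# generator parameters (encoder frozen).
recon_backward <- function(model, fwd, dpred) {
  cfg <- model$config
  cc <- fwd$caches
  g <- list(attn = list(W = model$attn$W * 0, b = 0),
            lstm = lapply(model$lstm, zero_like),
            head = list(W = model$head$W * 0, b = model$head$b * 0),
            gen = zero_like(model$gen))
  dv <- sigmoid_b(array(dpred, c(dim(dpred), 1L)), cc$gen[[6]]$sig)
  b6 <- conv3d_b(dv, cc$gen[[6]]$conv)
  g$gen$g6_W <- b6$dW; g$gen$g6_b <- b6$db
  dx <- b6$dx
  up_at <- c(2L, 4L)
  for (i in 5:1) {
    blk <- cc$gen[[i]]
    drl <- relu_b(dx, blk$relu)
    bn <- instnorm_b(drl, blk$inorm)
    g$gen[[paste0("g", i, "_gamma")]] <- bn$dgamma
    g$gen[[paste0("g", i, "_beta")]] <- bn$dbeta
    bc <- conv3d_b(bn$dx, blk$conv)
    g$gen[[paste0("g", i, "_W")]] <- bc$dW
    g$gen[[paste0("g", i, "_b")]] <- bc$db
    dx <- bc$dx
    if (i %in% up_at) dx <- upsample3d_b(dx, blk$up)
  }
  bh <- dense_b(as.numeric(dx), cc$head)
  g$head$W <- bh$dW; g$head$b <- bh$db
  dz <- bh$dx
  U <- cfg$tlstm_units
  Tn <- cc$Tn
  dh_top <- matrix(rep(dz[(U + 1):(2 * U)] / Tn, each = Tn), Tn, U)
  dh_top[Tn, ] <- dh_top[Tn, ] + dz[1:U]
  dh <- dh_top
  for (l in rev(seq_along(model$lstm))) {
    bw <- lstm_seq_backward(model$lstm[[l]], cc$lstm_fwds[[l]]$caches, dh)
    g$lstm[[l]] <- bw$grads
    if (l > 1) {
      dh <- do.call(rbind, bw$dxs)
      if (!is.null(cc$drop_masks))
        dh <- sweep(dh, 2, cc$drop_masks[[l - 1]], "*")
    } else {
      dxs <- bw$dxs
    }
  }
  for (t in seq_len(Tn)) {
    ab <- spatial_attention_b(cc$tokens[[t]], model$attn, cc$att[[t]], dxs[[t]])
    g$attn$W <- g$attn$W + ab$dW
    g$attn$b <- g$attn$b + ab$db
  }
  g
}

#' Reconstruction generator loss
#'
#' Mean absolute error between the predicted occupancy and the ground-truth
#' volume, plus the adversarial term `partial * (-log d_score)` scaled by the
#' adversarial weight `partial`.
#'
#' @param pred Predicted occupancy grid in `[0, 1]`.
#' @param gt Binary ground-truth volume, same shape.
#' @param d_score Discriminator score in (0, 1].
#' @param partial Adversarial weight.
#' @return Scalar loss.
#' @export
recon_gen_loss <- function(pred, gt, d_score, partial = 0.56) {
  if (!identical(dim(pred), dim(gt))) stopf("shape mismatch")
  if (d_score <= 0) stopf("`d_score` must be > 0")
  mean(abs(pred - gt)) + partial * (-log(d_score))
}

recon_disc_forward <- function(disc, vol) {
  x <- array(vol, c(dim(vol), 1L))
  a1 <- conv3d_f(x, disc$d1_W, disc$d1_b, dil = 1L)
  r1 <- lrelu_f(a1$out)
  a2 <- conv3d_f(r1$out, disc$d2_W, disc$d2_b, dil = 2L)
  r2 <- lrelu_f(a2$out)
  pooled <- apply(r2$out, 4, mean)
  o <- dense_f(pooled, disc$dd_W, disc$dd_b)
  s <- min(max(sigmoid(o$out), 1e-6), 1 - 1e-6)
  list(score = s,
       caches = list(a1 = a1$cache, r1 = r1$cache, a2 = a2$cache,
                     r2 = r2$cache, o = o$cache, s = s,
                     npix = prod(dim(r2$out)[1:3])))
}

recon_disc_backward <- function(disc, fwd, dscore) {
  cc <- fwd$caches
  dlogit <- dscore * cc$s * (1 - cc$s)
  bo <- dense_b(dlogit, cc$o)
  g <- list(dd_W = bo$dW, dd_b = bo$db)
  dmap <- array(rep(bo$dx / cc$npix, each = cc$npix),
                c(cc$a2$dims[1:3], length(bo$dx)))
  d2 <- lrelu_b(dmap, cc$r2)
  b2 <- conv3d_b(d2, cc$a2); g$d2_W <- b2$dW; g$d2_b <- b2$db
  d1 <- lrelu_b(b2$dx, cc$r1)
  b1 <- conv3d_b(d1, cc$a1); g$d1_W <- b1$dW; g$d1_b <- b1$db
  list(grads = g[names(disc)], dx = b1$dx[, , , 1])
}

#' Discriminator plausibility score for a 3-D volume
#'
#' @param model A `recon_model`.
#' @param volume 3-D occupancy grid.
#' @return Scalar score in (0, 1).
#' @export
recon_disc_score <- function(model, volume) {
  if (length(dim(volume)) != 3) stopf("`volume` must be a 3-D array")
  recon_disc_forward(model$disc, volume)$score
}

# Phantom cases are converted to tumor-centered crop sequences (the stage-3
# input in the pipeline is the detected tumor region, not the whole lung
# field): slices and ground truth are cropped around the union of the tumor
# boxes and resampled to the configured cubic volume.
recon_collect <- function(dataset, which_split = "train",
                          side = NULL) {
  if (inherits(dataset, "phantom_dataset")) {
    idx <- which(dataset$split == which_split)
    out <- list()
    for (ci in idx) {
      case <- dataset$cases[[ci]]
      boxes <- unlist(case$tumor_boxes, recursive = FALSE)
      if (length(boxes) == 0) next
      if (is.null(side)) side <- dim(case$tumor_volume)[3]
      slices <- lapply(seq_len(dim(case$slices)[3]),
                       function(z) zscore(case$slices[, , z]))
      zb <- which(vapply(case$tumor_boxes, length, integer(1)) > 0)
      cr <- crop_tumor_sequence(slices, boxes, side, case$tumor_volume,
                                z_range = range(zb))
      out[[length(out) + 1L]] <- list(slices = cr$slices, volume = cr$gt)
    }
    out
  } else dataset
}

recon_check_aligned <- function(samples, cfg) {
  for (s in samples) {
    if (length(s$slices) == 0 || is.null(s$volume))
      stopf("misaligned data: every sample needs slices and a volume")
    if (!all(dim(s$volume) == cfg$volume_size))
      stopf("misaligned data: volume must be %d^3", cfg$volume_size)
  }
}

#' Train the 3-D reconstruction model
#'
#' Alternates discriminator updates (real versus generated volumes, log loss)
#' with generator + TLSTM + attention updates minimizing
#' [recon_gen_loss()] under the adaptive-moment optimizer. The per-epoch
#' history records the MAE, the adversarial term, a 1-D earth-mover's
#' diagnostic between real and generated occupancy histograms, and
#' validation HD/ED.
#'
#' @param dataset A [generate_dataset()] result (slice sequences are the
#'   z-scored case slices, targets the tumor volumes), or a list of
#'   `list(slices, volume)` pairs (then `val_data` may supply validation
#'   pairs).
#' @param config A [recon_config()].
#' @param seed Training seed.
#' @param val_data Optional validation pairs for plain-list datasets.
#' @return List with `model` (class `recon_model`) and `history` tibble.
#' @export
train_reconstructor <- function(dataset, config, seed = config$seed,
                                val_data = NULL) {
  stopifnot(inherits(config, "recon_config"))
  samples <- recon_collect(dataset, "train")
  vals <- if (inherits(dataset, "phantom_dataset"))
    recon_collect(dataset, "val") else val_data
  if (length(samples) == 0) stopf("empty training set")
  recon_check_aligned(samples, config)
  model <- build_reconstructor(config)
  opt <- list(attn = adam_state(model$attn),
              lstm = lapply(model$lstm, adam_state),
              head = adam_state(model$head), gen = adam_state(model$gen))
  dopt <- adam_state(model$disc)
  seeds <- derive_seeds(seed, config$epochs * length(samples) + 1L)
  si <- 0L
  hist <- list()
  for (ep in seq_len(config$epochs)) {
    maes <- c(); advs <- c(); emds <- c()
    for (sm in samples) {
      si <- si + 1L
      masks <- recon_dropout_masks(config, seeds[si])
      fwd <- recon_forward(model, sm$slices, train = TRUE, drop_masks = masks)
      pred <- fwd$pred
      if (any(!is.finite(pred))) stopf("reconstruction diverged")
      n <- length(pred)
      dfw <- recon_disc_forward(model$disc, pred)
      mae <- mean(abs(pred - sm$volume))
      advs <- c(advs, -log(dfw$score))
      maes <- c(maes, mae)
      emds <- c(emds, emd1d(occupancy_hist(pred), occupancy_hist(sm$volume)))
      dpred <- sign(pred - sm$volume) / n
      if (config$adv_weight > 0) {
        db <- recon_disc_backward(model$disc, dfw,
                                  -config$adv_weight / dfw$score)
        dpred <- dpred + db$dx
      }
      g <- recon_backward(model, fwd, dpred)
      g <- list(attn = clamp_grads(g$attn), lstm = lapply(g$lstm, clamp_grads),
                head = clamp_grads(g$head), gen = clamp_grads(g$gen))
      au <- adam_step(model$attn, g$attn, opt$attn, config$gen_lr,
                      config$beta1, config$beta2)
      model$attn <- au$params; opt$attn <- au$state
      for (l in seq_along(model$lstm)) {
        lu <- adam_step(model$lstm[[l]], g$lstm[[l]], opt$lstm[[l]],
                        config$gen_lr, config$beta1, config$beta2)
        attrs <- attributes(model$lstm[[l]])
        model$lstm[[l]] <- lu$params
        attributes(model$lstm[[l]]) <- attrs
        opt$lstm[[l]] <- lu$state
      }
      hu <- adam_step(model$head, g$head, opt$head, config$gen_lr,
                      config$beta1, config$beta2)
      model$head <- hu$params; opt$head <- hu$state
      gu <- adam_step(model$gen, g$gen, opt$gen, config$gen_lr,
                      config$beta1, config$beta2)
      model$gen <- gu$params; opt$gen <- gu$state
      # discriminator: real vs (detached) generated volume
      rf <- recon_disc_forward(model$disc, sm$volume)
      ff <- recon_disc_forward(model$disc, pred)
      dgr <- add_grads(recon_disc_backward(model$disc, rf, -1 / rf$score)$grads,
                       recon_disc_backward(model$disc, ff,
                                           1 / (1 - ff$score))$grads)
      du <- adam_step(model$disc, clamp_grads(dgr), dopt, config$disc_lr,
                      config$beta1, config$beta2)
      model$disc <- du$params; dopt <- du$state
    }
    ev <- recon_eval(model, vals)
    hist[[ep]] <- tibble::tibble(epoch = ep, mae = mean(maes),
                                 adv = mean(advs), emd = mean(emds),
                                 val_hd = ev$hd, val_ed = ev$ed)
  }
  model$seed <- seed
  list(model = model, history = do.call(rbind, hist))
}

occupancy_hist <- function(vol, bins = 10L) {
  h <- tabulate(pmin(floor(as.numeric(vol) * bins) + 1L, bins), bins)
  h + 1e-9
}

recon_eval <- function(model, vals) {
  if (is.null(vals) || length(vals) == 0)
    return(list(hd = NA_real_, ed = NA_real_))
  hds <- c(); eds <- c()
  for (v in vals) {
    pred <- recon_forward(model, v$slices)$pred
    m <- evaluate_reconstruction((pred >= model$config$threshold) * 1L,
                                 v$volume)
    hds <- c(hds, m$HD); eds <- c(eds, m$ED)
  }
  list(hd = mean(hds), ed = mean(eds))
}

#' Reconstruct a 3-D tumor volume from a slice sequence
#'
#' Encoder features, spatial attention and the TLSTM hidden sequence feed the
#' deconvolutional generator; the occupancy grid is binarized at `threshold`.
#' When `tconfig` has `steps > 0` and training pairs are supplied, the model
#' is transductively adapted to the test sequence first.
#'
#' @param model A trained `recon_model`.
#' @param slices Ordered slice sequence (list of matrices or `H x W x T`
#'   array).
#' @param threshold Binarization threshold.
#' @param tconfig Optional [transductive_config()].
#' @param train_data Optional training pairs for the adaptation.
#' @param seed Seed for the adaptation steps.
#' @return List with `prob` (occupancy grid in `[0,1]`) and `mask` (binary).
#' @export
reconstruct <- function(model, slices, threshold = model$config$threshold,
                        tconfig = NULL, train_data = NULL, seed = 1L) {
  stopifnot(inherits(model, "recon_model"))
  if (!is.null(tconfig) && tconfig$steps > 0) {
    if (is.null(train_data)) stopf("transductive adaptation needs train_data")
    model <- transductive_adapt(model, train_data, slices, tconfig, seed)
  }
  pred <- recon_forward(model, slices)$pred
  list(prob = pred, mask = (pred >= threshold) * 1L)
}

#' Transductive adaptation of a reconstruction model
#'
#' Implements the transductive LSTM convention: the model parameters become a
#' function of the unseen test sequence through proximity weights. Training
#' samples are weighted by a Gaussian kernel on pooled encoder features
#' (bandwidth `sigma_k`) centered at the test sequence, and the trainable
#' parameters (attention, TLSTM, head, generator) take `steps` full-batch
#' gradient steps on the weighted MAE reconstruction loss. `steps = 0`
#' returns the model unchanged; `sigma_k = Inf` reduces to uniformly-weighted
#' fine-tuning.
#'
#' @param model A trained `recon_model`.
#' @param train_data List of `list(slices, volume)` pairs (or a
#'   `phantom_dataset`, whose train split is used).
#' @param test_sequence The unseen slice sequence.
#' @param config A [transductive_config()].
#' @param seed Seed for dropout during the adaptation steps.
#' @return The adapted `recon_model`.
#' @export
transductive_adapt <- function(model, train_data, test_sequence, config,
                               seed = 1L) {
  stopifnot(inherits(model, "recon_model"),
            inherits(config, "transductive_config"))
  samples <- recon_collect(train_data, "train")
  if (length(samples) == 0) stopf("empty train subset")
  if (config$steps == 0) return(model)
  feats <- do.call(rbind, lapply(samples, function(s)
    colMeans(extract_features(s$slices, model$enc))))
  test_feat <- colMeans(extract_features(test_sequence, model$enc))
  w <- transductive_weights(feats, test_feat, config$sigma_k)
  seeds <- derive_seeds(seed, config$steps)
  for (k in seq_len(config$steps)) {
    g <- NULL
    for (i in seq_along(samples)) {
      masks <- recon_dropout_masks(model$config, seeds[k])
      fwd <- recon_forward(model, samples[[i]]$slices, train = TRUE,
                           drop_masks = masks)
      dpred <- w[i] * sign(fwd$pred - samples[[i]]$volume) /
        length(fwd$pred)
      gi <- recon_backward(model, fwd, dpred)
      g <- if (is.null(g)) gi else
        list(attn = add_grads(g$attn, gi$attn),
             lstm = Map(add_grads, g$lstm, gi$lstm),
             head = add_grads(g$head, gi$head),
             gen = add_grads(g$gen, gi$gen))
    }
    lr <- config$learn_rate
    step1 <- function(p, gr) tree_map2(function(a, b) a - lr * b, p, gr)
    model$attn <- step1(model$attn, g$attn)
    for (l in seq_along(model$lstm)) {
      attrs <- attributes(model$lstm[[l]])
      model$lstm[[l]] <- step1(model$lstm[[l]], g$lstm[[l]])
      attributes(model$lstm[[l]]) <- attrs
    }
    model$head <- step1(model$head, g$head)
    model$gen <- step1(model$gen, g$gen)
  }
  model
}

#' Evaluate a reconstruction against ground truth
#'
#' Hausdorff distance between the surface point sets and the mean symmetric
#' surface distance ("ED"). An empty prediction or ground truth yields `Inf`
#' sentinels with a warning rather than an error.
#'
#' @param pred Binarized predicted volume.
#' @param gt Binary ground-truth volume.
#' @return List with `HD` and `ED`.
#' @export
evaluate_reconstruction <- function(pred, gt) {
  if (sum(pred) == 0 || sum(gt) == 0) {
    warnf("empty prediction or ground truth; HD/ED reported as Inf")
    return(list(HD = Inf, ED = Inf))
  }
  sp <- surface_points(pred)
  sg <- surface_points(gt)
  list(HD = hd(sp, sg), ED = volume_ed(pred, gt))
}
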