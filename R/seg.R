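#' Segmentation stage configuration
#'
#' Defaults follow the tuned hyperparameters for the lung-segmentation stage:
#' generator learning rate 0.002, critic learning rate 0.001, batch size 68,
#' SGD momentum 0.85 and weight decay 0.001. `adv_weight` mixes the
#' adversarial term with the PPO policy loss; `pixels_per_image` bounds the
#' per-image transition batch so training stays CPU-friendly.
#'
#' @param depth Encoder/decoder depth (number of 2x downsamplings).
#' @param channels Base channel count; doubles per encoder level.
#' @param gen_lr,disc_lr Learning rates for generator and critic.
#' @param batch_size Nominal batch size (kept for provenance; the desk-scale
#'   loop updates per image).
#' @param momentum,weight_decay SGD hyperparameters for both networks.
#' @param adv_weight Weight of the adversarial loss in the generator update.
#' @param epochs Training epochs.
#' @param pixels_per_image Pixels sampled per image for the policy loss.
#' @param replay_every Generator updates between replayed buffer batches.
#' @param critic_clip Weight-clipping bound for the Wasserstein-style critic
#'   (0 disables clipping).
#' @param explore Behavior-policy smoothing: actions are drawn from the
#'   epsilon-smoothed snapshot policy `(1 - 2e) p + e`, which keeps
#'   exploration alive when the policy saturates (off-policy data source).
#' @param entropy_weight Coefficient of the policy-entropy bonus added to the
#'   surrogate; keeps the per-pixel policy away from premature saturation
#'   (the all-background fixed point), as in the standard PPO objective.
#' @param threshold Default mask binarization threshold in (0, 1).
#' @param seed Integer seed.
#' @return An object of class `seg_config`.
#' @export
seg_config <- function(depth = 2L, channels = 8L, gen_lr = 0.002,
                       disc_lr = 0.001, batch_size = 68L, momentum = 0.85,
                       weight_decay = 0.001, adv_weight = 1.0, epochs = 3L,
                       pixels_per_image = 512L, replay_every = 2L,
                       critic_clip = 0.05, explore = 0.05,
                       entropy_weight = 0.1, threshold = 0.5, seed = 1L) {
  check_number(depth, "depth", lower = 1)
  check_number(channels, "channels", lower = 1)
  check_number(gen_lr, "gen_lr", lower = 0, strict_lower = TRUE)
  check_number(disc_lr, "disc_lr", lower = 0, strict_lower = TRUE)
  check_number(adv_weight, "adv_weight", lower = 0)
  check_number(threshold, "threshold", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  structure(list(depth = as.integer(depth), channels = as.integer(channels),
                 gen_lr = gen_lr, disc_lr = disc_lr,
                 batch_size = as.integer(batch_size), momentum = momentum,
                 weight_decay = weight_decay, adv_weight = adv_weight,
                 epochs = as.integer(epochs),
                 pixels_per_image = as.integer(pixels_per_image),
                 replay_every = as.integer(replay_every),
                 critic_clip = critic_clip, explore = explore,
                 entropy_weight = entropy_weight, threshold = threshold,
                 seed = as.integer(seed)), class = "seg_config")
}

seg_channel_plan <- function(config) {
  C <- config$channels
  enc <- C * 2^(seq_len(config$depth) - 1L)
  list(enc = enc, dec_out = c(C, enc[-length(enc)]))
}

#' Build an untrained U-Net style segmentation generator
#'
#' An encoder-decoder with skip connections mapping an `H x W` image to a
#' per-pixel lung probability in `[0, 1]`, plus a linear value head used as
#' the one-step baseline `V(s)` for the policy objective. Parameter count
#' scales with `channels` and `depth`.
#'
#' @param config A [seg_config()].
#' @return An object of class `seg_model` (untrained).
#' @export
build_seg_generator <- function(config) {
  stopifnot(inherits(config, "seg_config"))
  plan <- seg_channel_plan(config)
  with_seed(config$seed, {
    p <- list()
    cin <- 1L
    for (i in seq_len(config$depth)) {
      p[[paste0("enc", i, "_W")]] <- init_mat(9L * cin, plan$enc[i])
      p[[paste0("enc", i, "_b")]] <- numeric(plan$enc[i])
      cin <- plan$enc[i]
    }
    p$bott_W <- init_mat(9L * cin, cin)
    p$bott_b <- numeric(cin)
    cur <- cin
    for (i in rev(seq_len(config$depth))) {
      cat_in <- cur + plan$enc[i]
      p[[paste0("dec", i, "_W")]] <- init_mat(9L * cat_in, plan$dec_out[i])
      p[[paste0("dec", i, "_b")]] <- numeric(plan$dec_out[i])
      cur <- plan$dec_out[i]
    }
    p$out_W <- init_mat(cur, 1L)
    p$out_b <- 0
    p$val_W <- init_mat(cur, 1L)
    p$val_b <- 0
    structure(list(params = p, critic = NULL, config = config),
              class = "seg_model")
  })
}

#' Number of trainable parameters of a model
#' @param model A model object with a `params` (and optionally `critic`) list.
#' @return Integer parameter count.
#' @export
n_params <- function(model) {
  cnt <- function(pl) if (is.null(pl)) 0L else
    sum(vapply(pl, length, integer(1)))
  cnt(model$params) + cnt(model$critic)
}

seg_check_size <- function(config, H, W) {
  f <- 2^config$depth
  if (H %% f != 0 || W %% f != 0)
    stopf("image size %dx%d not divisible by 2^depth = %d; pad the image or lower `depth`",
          H, W, f)
}

# Full forward pass; returns probability map, value map and backward caches.
seg_forward <- function(params, image, config) {
  H <- nrow(image); W <- ncol(image)
  seg_check_size(config, H, W)
  x <- array(image, c(H, W, 1L))
  caches <- list()
  skips <- list()
  for (i in seq_len(config$depth)) {
    cv <- conv2d_f(x, params[[paste0("enc", i, "_W")]],
                   params[[paste0("enc", i, "_b")]])
    rl <- relu_f(cv$out)
    skips[[i]] <- rl$out
    pl <- avgpool2_f(rl$out)
    caches[[paste0("enc", i)]] <- list(conv = cv$cache, relu = rl$cache,
                                       pool = pl$cache)
    x <- pl$out
  }
  cv <- conv2d_f(x, params$bott_W, params$bott_b)
  rl <- relu_f(cv$out)
  caches$bott <- list(conv = cv$cache, relu = rl$cache)
  x <- rl$out
  for (i in rev(seq_len(config$depth))) {
    up <- upsample2_f(x)
    skip <- skips[[i]]
    cat_in <- array(c(up$out, skip), c(dim(up$out)[1], dim(up$out)[2],
                                       dim(up$out)[3] + dim(skip)[3]))
    cv <- conv2d_f(cat_in, params[[paste0("dec", i, "_W")]],
                   params[[paste0("dec", i, "_b")]])
    rl <- relu_f(cv$out)
    caches[[paste0("dec", i)]] <- list(up = up$cache, conv = cv$cache,
                                       relu = rl$cache,
                                       n_up = dim(up$out)[3])
    x <- rl$out
  }
  feat <- x
  lg <- conv2d_f(feat, params$out_W, params$out_b, k = 1L)
  sg <- sigmoid_f(lg$out)
  vl <- conv2d_f(feat, params$val_W, params$val_b, k = 1L)
  list(prob = sg$out[, , 1], value = vl$out[, , 1],
       caches = c(caches, list(out = lg$cache, sig = sg$cache,
                               val = vl$cache)))
}

# Backward pass given gradients on the probability and value maps.
seg_backward <- function(params, fwd, dprob, dvalue, config) {
  caches <- fwd$caches
  grads <- zero_like(params)
  dlog <- sigmoid_b(array(dprob, c(dim(dprob), 1L)), caches$sig)
  bo <- conv2d_b(dlog, caches$out)
  grads$out_W <- bo$dW; grads$out_b <- bo$db
  dfeat <- bo$dx
  bv <- conv2d_b(array(dvalue, c(dim(dvalue), 1L)), caches$val)
  grads$val_W <- bv$dW; grads$val_b <- bv$db
  dfeat <- dfeat + bv$dx
  dskips <- vector("list", config$depth)
  dx <- dfeat
  for (i in seq_len(config$depth)) {
    cc <- caches[[paste0("dec", i)]]
    drl <- relu_b(dx, cc$relu)
    bc <- conv2d_b(drl, cc$conv)
    grads[[paste0("dec", i, "_W")]] <- bc$dW
    grads[[paste0("dec", i, "_b")]] <- bc$db
    n_up <- cc$n_up
    d_up <- bc$dx[, , seq_len(n_up), drop = FALSE]
    dskips[[i]] <- bc$dx[, , -seq_len(n_up), drop = FALSE]
    dx <- upsample2_b(d_up, cc$up)
  }
  drl <- relu_b(dx, caches$bott$relu)
  bc <- conv2d_b(drl, caches$bott$conv)
  grads$bott_W <- bc$dW; grads$bott_b <- bc$db
  dx <- bc$dx
  for (i in rev(seq_len(config$depth))) {
    cc <- caches[[paste0("enc", i)]]
    dpre <- avgpool2_b(dx, cc$pool) + dskips[[i]]
    drl <- relu_b(dpre, cc$relu)
    bc <- conv2d_b(drl, cc$conv)
    grads[[paste0("enc", i, "_W")]] <- bc$dW
    grads[[paste0("enc", i, "_b")]] <- bc$db
    dx <- bc$dx
  }
  grads
}

#' Pixel-wise fusion of a mask and an image
#'
#' Elementwise product of a (probability or binary) mask with the intensity
#' image, merging spatial mask structure with intensity data before the
#' critic sees it.
#'
#' @param mask,image Arrays of identical shape.
#' @return Elementwise product.
#' @export
fuse <- function(mask, image) {
  if (!identical(dim2(mask), dim2(image))) stopf("shape mismatch")
  mask * image
}

# Dilated-convolution critic. Input is an H x W x 2 array: the fused
# mask-times-image plane and the nodule-emphasis plane.
seg_critic_init <- function(channels = 8L) {
  list(c1_W = init_mat(9L * 2L, channels), c1_b = numeric(channels),
       c2_W = init_mat(9L * channels, channels), c2_b = numeric(channels),
       c3_W = init_mat(9L * channels, channels), c3_b = numeric(channels),
       out_W = init_mat(channels, 1L), out_b = 0)
}

seg_critic_forward <- function(cp, input) {
  a1 <- conv2d_f(input, cp$c1_W, cp$c1_b, dil = 1L)
  r1 <- lrelu_f(a1$out)
  a2 <- conv2d_f(r1$out, cp$c2_W, cp$c2_b, dil = 2L)
  r2 <- lrelu_f(a2$out)
  a3 <- conv2d_f(r2$out, cp$c3_W, cp$c3_b, dil = 4L)
  r3 <- lrelu_f(a3$out)
  o <- conv2d_f(r3$out, cp$out_W, cp$out_b, k = 1L)
  list(score = mean(o$out),
       caches = list(a1 = a1$cache, r1 = r1$cache, a2 = a2$cache,
                     r2 = r2$cache, a3 = a3$cache, r3 = r3$cache,
                     o = o$cache, n = length(o$out)))
}

seg_critic_backward <- function(cp, fwd, dscore) {
  cc <- fwd$caches
  dmap <- array(dscore / cc$n, c(cc$o$dims[1], cc$o$dims[2], 1L))
  bo <- conv2d_b(dmap, cc$o)
  g <- list(out_W = bo$dW, out_b = bo$db)
  d3 <- lrelu_b(bo$dx, cc$r3)
  b3 <- conv2d_b(d3, cc$a3); g$c3_W <- b3$dW; g$c3_b <- b3$db
  d2 <- lrelu_b(b3$dx, cc$r2)
  b2 <- conv2d_b(d2, cc$a2); g$c2_W <- b2$dW; g$c2_b <- b2$db
  d1 <- lrelu_b(b2$dx, cc$r1)
  b1 <- conv2d_b(d1, cc$a1); g$c1_W <- b1$dW; g$c1_b <- b1$db
  list(grads = g[names(cp)], dx = b1$dx)
}

#' Critic loss for the segmentation stage
#'
#' Score difference `mean(scores_fake) - mean(scores_real)`; the critic
#' descends this (drives real scores up, fake scores down). Fake scores come
#' from the critic applied to `fuse(G(x), I)` and real scores from
#' `fuse(real_mask, I)`.
#'
#' @param scores_fake,scores_real Non-empty numeric score vectors.
#' @return The loss value.
#' @export
seg_critic_loss <- function(scores_fake, scores_real) {
  if (length(scores_fake) == 0 || length(scores_real) == 0)
    stopf("empty score list")
  mean(scores_fake) - mean(scores_real)
}

#' Per-pixel policy loss (negated off-policy PPO surrogate)
#'
#' Assembles a per-pixel transition batch with asymmetric rewards and
#' one-step advantages `A = r - V`, and returns the negated off-policy
#' clipped surrogate, suitable for gradient descent.
#'
#' @param prob_map Probability map (or vector of probabilities at sampled
#'   pixels).
#' @param sampled_actions Sampled 0/1 actions at those pixels.
#' @param labels True 0/1 labels.
#' @param values Value-head estimates `V(s)`.
#' @param spec A [reward_spec()].
#' @param ppo A [ppo_config()].
#' @param prob_old Probabilities of the sampled actions under the previous
#'   policy.
#' @param prob_behavior Probabilities of the sampled actions under the
#'   behavior policy; required (stored in the replay buffer during training).
#' @return Scalar loss (negated surrogate).
#' @export
pixel_policy_loss <- function(prob_map, sampled_actions, labels, values,
                              spec, ppo, prob_old, prob_behavior) {
  if (missing(prob_behavior) || is.null(prob_behavior))
    stopf("missing behavior probabilities for the sampled pixels")
  p <- as.numeric(prob_map)
  a <- as.numeric(sampled_actions)
  pi_cur <- pmax(ifelse(a == 1, p, 1 - p), 1e-8)
  r <- reward(a, as.numeric(labels), spec)
  adv <- advantage_onestep(r, as.numeric(values))
  batch <- transition_batch(a, as.numeric(labels), r, adv,
                            pi_cur, pmax(prob_old, 1e-8),
                            pmax(prob_behavior, 1e-8))
  -surrogate_offpolicy(batch, ppo$epsilon)
}

# Gradient of the negated off-policy surrogate w.r.t. the pixel probability
# for one sampled action per pixel (used by the exported loss and the
# replayed buffer batches).
ppo_prob_grad <- function(p, a, adv, prob_old, prob_behavior, eps) {
  pi_cur <- pmax(ifelse(a == 1, p, 1 - p), 1e-8)
  mu <- pmax(prob_behavior, 1e-8)
  rho <- pi_cur / mu
  corr <- pmax(prob_old, 1e-8) / mu
  lo <- corr * (1 - eps); hi <- corr * (1 + eps)
  unclip <- rho * adv
  clipped <- clip(rho, lo, hi) * adv
  active <- (unclip <= clipped) | (rho > lo & rho < hi)
  dpi <- (adv / mu) * active
  dp <- dpi * ifelse(a == 1, 1, -1)
  -dp / length(p)              # negated mean
}

# Closed-form two-action expectation of the off-policy clipped surrogate and
# its probability gradient. With only two actions the expectation over
# a ~ mu is evaluated exactly instead of by a one-sample Monte Carlo draw,
# which removes the sampling variance that otherwise starves rare
# minority-pixel updates. Returns the surrogate value and d(-surrogate)/dp.
ppo_expectation <- function(p, y, v, p_old1, mu1, spec, eps) {
  n <- length(p)
  val <- numeric(n)
  grad <- numeric(n)
  for (a in c(1, 0)) {
    pi_a <- pmax(if (a == 1) p else 1 - p, 1e-8)
    mu_a <- pmax(if (a == 1) mu1 else 1 - mu1, 1e-8)
    old_a <- pmax(if (a == 1) p_old1 else 1 - p_old1, 1e-8)
    adv <- reward(rep(a, n), y, spec) - v
    rho <- pi_a / mu_a
    corr <- old_a / mu_a
    lo <- corr * (1 - eps); hi <- corr * (1 + eps)
    unclip <- rho * adv
    clipped <- clip(rho, lo, hi) * adv
    val <- val + mu_a * pmin(unclip, clipped)
    active <- (unclip <= clipped) | (rho > lo & rho < hi)
    # mu_a weight cancels the 1/mu_a of the ratio derivative
    grad <- grad + adv * active * (if (a == 1) 1 else -1)
  }
  list(surrogate = mean(val), dp = -grad / n)
}

# Uniform random pixel subset: the sampled batch keeps the natural class
# imbalance, so the asymmetric reward (not the sampling) is what counteracts
# the majority class.
sample_pixels <- function(labels, n, seed) {
  with_seed(seed, sample_vec(seq_along(labels), n))
}

critic_input <- function(mask, image, tumor_mask = NULL) {
  ch2 <- if (is.null(tumor_mask)) image * 0 else fuse(tumor_mask, image)
  array(c(fuse(mask, image), ch2), c(nrow(image), ncol(image), 2L))
}

action_prob <- function(prob_map, idx, actions) {
  p <- prob_map[idx]
  pmax(ifelse(actions == 1, p, 1 - p), 1e-8)
}

#' Train the segmentation generator
#'
#' Alternates Wasserstein-style critic updates with generator updates whose
#' loss is the negated off-policy PPO surrogate plus `adv_weight` times the
#' adversarial term (negative critic score on fused fakes), together with a
#' squared-error value-head loss. A FIFO replay buffer stores per-image
#' transition batches under the behavior-policy snapshot in force when they
#' were written; snapshots refresh every `snapshot_every` generator updates
#' and stored batches are replayed every `replay_every` updates. With
#' `objective = "ce"` the generator instead minimizes plain per-pixel
#' cross-entropy on the same sampled pixels (no reward asymmetry, no critic):
#' the imbalance-naive twin.
#'
#' @param dataset A [generate_dataset()] result with train/val splits.
#' @param config A [seg_config()].
#' @param spec A [reward_spec()].
#' @param ppo A [ppo_config()].
#' @param seed Training seed (default from `config`).
#' @param objective `"ppo"` (full method) or `"ce"` (cross-entropy twin).
#' @return List with `model` (class `seg_model`) and `history` (tibble with
#'   per-epoch generator loss, critic loss, PPO surrogate, minority-class
#'   recall and validation IoU).
#' @export
train_segmenter <- function(dataset, config, spec = reward_spec(),
                            ppo = ppo_config(), seed = config$seed,
                            objective = c("ppo", "ce")) {
  stopifnot(inherits(dataset, "phantom_dataset"),
            inherits(config, "seg_config"))
  objective <- match.arg(objective)
  tr <- which(dataset$split == "train")
  va <- which(dataset$split == "val")
  if (length(tr) == 0 || length(va) == 0) stopf("empty train or val split")
  slices <- list(); lungs <- list(); tumors <- list()
  for (ci in tr) {
    case <- dataset$cases[[ci]]
    for (z in seq_len(dim(case$slices)[3])) {
      slices[[length(slices) + 1L]] <- zscore(case$slices[, , z])
      lungs[[length(lungs) + 1L]] <- case$lung_mask[, , z]
      tumors[[length(tumors) + 1L]] <- case$tumor_mask[, , z]
    }
  }
  model <- build_seg_generator(config)
  seeds <- derive_seeds(seed, config$epochs * length(slices) * 3L + 10L)
  critic <- with_seed(seeds[length(seeds)], seg_critic_init(config$channels))
  gen_opt <- sgd_state(model$params)
  cr_opt <- sgd_state(critic)
  old_params <- model$params
  snap_params <- model$params
  buffer <- replay_buffer(ppo$buffer_capacity)
  sidx <- 0L
  nxt_seed <- function() {
    sidx <<- sidx + 1L
    seeds[sidx]
  }
  hist <- list()
  updates <- 0L
  for (ep in seq_len(config$epochs)) {
    ep_gen <- c(); ep_cr <- c(); ep_sur <- c()
    for (im in seq_along(slices)) {
      img <- slices[[im]]; y <- lungs[[im]]
      fwd <- seg_forward(model$params, img, config)
      p <- fwd$prob
      if (any(!is.finite(p)) || any(p < 0 | p > 1))
        stopf("probability map left [0,1]; training diverged")
      if (objective == "ce") {
        idx <- sample_pixels(y, config$pixels_per_image, nxt_seed())
        dprob <- p * 0
        dprob[idx] <- (p[idx] - y[idx]) /
          (pmax(p[idx] * (1 - p[idx]), 1e-6) * length(idx))
        # d(BCE)/dp = (p - y) / (p (1 - p)); combined with sigmoid backward
        # in seg_backward this yields the usual (p - y) logit gradient.
        grads <- seg_backward(model$params, fwd, dprob, p * 0, config)
        grads <- clamp_grads(grads)
        up <- sgd_step(model$params, grads, gen_opt, config$gen_lr,
                       config$momentum, config$weight_decay)
        model$params <- up$params; gen_opt <- up$state
        ep_gen <- c(ep_gen, mean(-(y[idx] * log(pmax(p[idx], 1e-8)) +
                                     (1 - y[idx]) * log(pmax(1 - p[idx], 1e-8)))))
        next
      }
      v <- fwd$value
      idx <- sample_pixels(y, config$pixels_per_image, nxt_seed())
      old_fwd <- seg_forward(old_params, img, config)
      snap_fwd <- seg_forward(snap_params, img, config)
      # behavior policy: epsilon-smoothed snapshot (transitions are gathered
      # under mu, not under the current policy -- off-policy data)
      e <- config$explore
      mu_map <- (1 - 2 * e) * snap_fwd$prob + e
      exp_out <- ppo_expectation(p[idx], y[idx], v[idx],
                                 old_fwd$prob[idx], mu_map[idx], spec,
                                 ppo$epsilon)
      sur <- -exp_out$surrogate
      dprob <- p * 0
      dprob[idx] <- exp_out$dp
      if (config$entropy_weight > 0) {
        pc <- pmin(pmax(p[idx], 1e-6), 1 - 1e-6)
        # entropy bonus: descend -c*H(pi), i.e. push saturated pixels back
        dprob[idx] <- dprob[idx] +
          config$entropy_weight * log(pc / (1 - pc)) / length(idx)
      }
      # value head regresses to the expected reward under mu
      r_exp <- mu_map[idx] * reward(rep(1, length(idx)), y[idx], spec) +
        (1 - mu_map[idx]) * reward(rep(0, length(idx)), y[idx], spec)
      dval <- p * 0
      dval[idx] <- (v[idx] - r_exp) / length(idx)
      # adversarial term: maximize critic score on the fused fake
      cin <- critic_input(p, img, tumors[[im]])
      cfwd <- seg_critic_forward(critic, cin)
      cback <- seg_critic_backward(critic, cfwd, -1)   # d(-score)/dinput
      dprob <- dprob + config$adv_weight * cback$dx[, , 1] * img
      old_params <- model$params
      grads <- seg_backward(model$params, fwd, dprob, dval, config)
      grads <- clamp_grads(grads)
      up <- sgd_step(model$params, grads, gen_opt, config$gen_lr,
                     config$momentum, config$weight_decay)
      model$params <- up$params; gen_opt <- up$state
      updates <- updates + 1L
      buffer_push(buffer, list(im = im, idx = idx, mu1 = mu_map[idx],
                               y = y[idx]))
      # off-policy reuse of stored transitions under their original mu
      if (updates %% config$replay_every == 0L && buffer_size(buffer) > 0) {
        rec <- buffer_sample(buffer, 1L, nxt_seed())[[1]]
        rimg <- slices[[rec$im]]
        rfwd <- seg_forward(model$params, rimg, config)
        rofwd <- seg_forward(old_params, rimg, config)
        rexp <- ppo_expectation(rfwd$prob[rec$idx], rec$y,
                                rfwd$value[rec$idx], rofwd$prob[rec$idx],
                                rec$mu1, spec, ppo$epsilon)
        rdprob <- rfwd$prob * 0
        rdprob[rec$idx] <- rexp$dp
        rgrads <- clamp_grads(seg_backward(model$params, rfwd, rdprob,
                                           rfwd$prob * 0, config))
        old_params <- model$params
        rup <- sgd_step(model$params, rgrads, gen_opt, config$gen_lr,
                        config$momentum, config$weight_decay)
        model$params <- rup$params; gen_opt <- rup$state
      }
      if (updates %% ppo$snapshot_every == 0L) snap_params <- model$params
      # critic update: descend mean(score_fake) - mean(score_real)
      f_in <- critic_input(p, img, tumors[[im]])
      r_in <- critic_input(y, img, tumors[[im]])
      ffwd <- seg_critic_forward(critic, f_in)
      rfwd2 <- seg_critic_forward(critic, r_in)
      fb <- seg_critic_backward(critic, ffwd, 1)
      rb <- seg_critic_backward(critic, rfwd2, -1)
      cgrads <- clamp_grads(add_grads(fb$grads, rb$grads))
      cup <- sgd_step(critic, cgrads, cr_opt, config$disc_lr,
                      config$momentum, config$weight_decay)
      critic <- cup$params; cr_opt <- cup$state
      if (config$critic_clip > 0)
        critic <- tree_map(function(w)
          pmax(pmin(w, config$critic_clip), -config$critic_clip), critic)
      ep_cr <- c(ep_cr, seg_critic_loss(ffwd$score, rfwd2$score))
      ep_sur <- c(ep_sur, -sur)
      ep_gen <- c(ep_gen, sur + config$adv_weight * (-cfwd$score))
    }
    ev <- seg_eval(model$params, dataset, va, config)
    hist[[ep]] <- tibble::tibble(
      epoch = ep, gen_loss = mean(ep_gen),
      critic_loss = if (length(ep_cr)) mean(ep_cr) else NA_real_,
      ppo_surrogate = if (length(ep_sur)) mean(ep_sur) else NA_real_,
      minority_recall = ev$recall, val_iou = ev$iou)
  }
  model$critic <- critic
  model$reward_spec <- spec
  model$ppo <- ppo
  model$objective <- objective
  model$seed <- seed
  list(model = model, history = do.call(rbind, hist))
}

seg_eval <- function(params, dataset, case_idx, config) {
  tp <- 0; fn <- 0; inter <- 0; uni <- 0
  for (ci in case_idx) {
    case <- dataset$cases[[ci]]
    for (z in seq_len(dim(case$slices)[3])) {
      p <- seg_forward(params, zscore(case$slices[, , z]), config)$prob
      m <- p >= config$threshold
      y <- case$lung_mask[, , z] == 1
      tp <- tp + sum(m & y); fn <- fn + sum(!m & y)
      inter <- inter + sum(m & y); uni <- uni + sum(m | y)
    }
  }
  list(recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       iou = if (uni > 0) inter / uni else NA_real_)
}

#' Segment an image with a trained (or untrained) model
#'
#' @param model A `seg_model`.
#' @param image `H x W` intensity matrix (z-scored internally if `normalize`).
#' @param threshold Binarization threshold in (0, 1).
#' @param normalize Whether to z-score the image first (default TRUE).
#' @return List with `mask` (binary matrix) and `prob` (probability map).
#' @export
segment <- function(model, image, threshold = model$config$threshold,
                    normalize = TRUE) {
  stopifnot(inherits(model, "seg_model"))
  if (threshold <= 0 || threshold >= 1) stopf("threshold must be in (0, 1)")
  if (normalize) image <- zscore(image)
  p <- seg_forward(model$params, image, model$config)$prob
  list(mask = (p >= threshold) * 1L, prob = p)
}
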