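#' Detection stage configuration
#'
#' Defaults follow the tuned hyperparameters of the tumor-detection stage:
#' RPN anchor scale 102 and ratio 1.1 (a single scale/ratio pair; lists are
#' accepted), RoI positive ratio 0.35, bounding-box refinement std 0.012,
#' generator learning rate 0.01 and discriminator learning rate 0.001. For
#' desk-scale phantoms pass an anchor scale comparable to the tumor diameter.
#'
#' @param anchor_scales Anchor side lengths (pixels).
#' @param anchor_ratios Anchor aspect ratios (h/w).
#' @param stride Anchor grid stride in pixels (backbone downsampling is 4).
#' @param roi_positive_ratio Maximum fraction of positives in a sampled RoI
#'   batch.
#' @param bbox_std Normalizer for box-regression deltas.
#' @param mask_threshold Mask-crop binarization threshold.
#' @param gen_lr,disc_lr Learning rates.
#' @param momentum SGD momentum.
#' @param batch_size Nominal batch size (provenance; desk runs update
#'   per slice).
#' @param channels Backbone base channels.
#' @param epochs Training epochs.
#' @param rois_per_image RoIs sampled per slice for the classification loss.
#' @param score_threshold Objectness threshold for emitting detections.
#' @param nms_iou IoU threshold for non-maximum suppression.
#' @param top_k Maximum detections kept per slice.
#' @param mask_size Side of the square mask crop.
#' @param seed Integer seed.
#' @return An object of class `det_config`.
#' @export
det_config <- function(anchor_scales = 102, anchor_ratios = 1.1, stride = 8L,
                       roi_positive_ratio = 0.35, bbox_std = 0.012,
                       mask_threshold = 0.5, gen_lr = 0.01, disc_lr = 0.001,
                       momentum = 0.85, batch_size = 82L, channels = 8L,
                       epochs = 3L, rois_per_image = 32L,
                       score_threshold = 0.5, nms_iou = 0.3, top_k = 3L,
                       mask_size = 8L, seed = 1L) {
  if (any(anchor_scales <= 0)) stopf("anchor scales must be > 0")
  if (any(anchor_ratios <= 0)) stopf("anchor ratios must be > 0")
  structure(list(anchor_scales = anchor_scales,
                 anchor_ratios = anchor_ratios, stride = as.integer(stride),
                 roi_positive_ratio = roi_positive_ratio,
                 bbox_std = bbox_std, mask_threshold = mask_threshold,
                 gen_lr = gen_lr, disc_lr = disc_lr, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 channels = as.integer(channels), epochs = as.integer(epochs),
                 rois_per_image = as.integer(rois_per_image),
                 score_threshold = score_threshold, nms_iou = nms_iou,
                 top_k = as.integer(top_k), mask_size = as.integer(mask_size),
                 seed = as.integer(seed)), class = "det_config")
}

#' Anchor grid for an image
#'
#' One anchor per (grid center, scale, ratio) combination, centers placed at
#' `stride/2 + k * stride`, boxes clipped to the image bounds. Boxes use the
#' half-open 0-based convention.
#'
#' @param H,W Image size in pixels.
#' @param config A [det_config()].
#' @return Data frame with columns `x0, y0, x1, y1, cy, cx, w, h, row, col, a`.
#' @export
anchor_grid <- function(H, W, config) {
  s <- config$stride
  if (H < s || W < s)
    stopf("no anchor fits an image of %d x %d at stride %d", H, W, s)
  cys <- seq(s / 2, H - s / 2 + 1e-9, by = s)
  cxs <- seq(s / 2, W - s / 2 + 1e-9, by = s)
  combos <- expand.grid(a_ratio = config$anchor_ratios,
                        a_scale = config$anchor_scales)
  out <- list()
  for (ai in seq_len(nrow(combos))) {
    sc <- combos$a_scale[ai]; ra <- combos$a_ratio[ai]
    w <- sc / sqrt(ra); h <- sc * sqrt(ra)
    g <- expand.grid(row = seq_along(cys), col = seq_along(cxs))
    cy <- cys[g$row]; cx <- cxs[g$col]
    out[[ai]] <- data.frame(
      x0 = pmax(0, cx - w / 2), y0 = pmax(0, cy - h / 2),
      x1 = pmin(W, cx + w / 2), y1 = pmin(H, cy + h / 2),
      cy = cy, cx = cx, w = w, h = h, row = g$row, col = g$col, a = ai)
  }
  do.call(rbind, out)
}

#' IoU between two boxes
#' @param b1,b2 Lists or vectors with `x0, y0, x1, y1` (half-open).
#' @return IoU in `[0, 1]`.
#' @export
box_iou <- function(b1, b2) {
  b1 <- as.list(b1); b2 <- as.list(b2)
  ix <- max(0, min(b1$x1, b2$x1) - max(b1$x0, b2$x0))
  iy <- max(0, min(b1$y1, b2$y1) - max(b1$y0, b2$y0))
  inter <- ix * iy
  a1 <- (b1$x1 - b1$x0) * (b1$y1 - b1$y0)
  a2 <- (b2$x1 - b2$x0) * (b2$y1 - b2$y0)
  if (a1 + a2 - inter <= 0) return(0)
  inter / (a1 + a2 - inter)
}

#' Greedy non-maximum suppression
#'
#' Boxes are visited in order of decreasing score; a box is suppressed when
#' its IoU with an already-kept box exceeds `iou_threshold` (strictly), so a
#' threshold of 1 keeps everything and 0 keeps one box per overlapping
#' cluster.
#'
#' @param boxes List of boxes (each with `x0, y0, x1, y1`).
#' @param scores Numeric scores, same length.
#' @param iou_threshold Suppression threshold in `[0, 1]`.
#' @return Integer indices of the kept boxes, in decreasing score order.
#' @export
nms_boxes <- function(boxes, scores, iou_threshold) {
  ord <- order(scores, decreasing = TRUE)
  keep <- integer()
  for (i in ord) {
    ok <- TRUE
    for (j in keep)
      if (box_iou(boxes[[i]], boxes[[j]]) > iou_threshold) { ok <- FALSE; break }
    if (ok) keep <- c(keep, i)
  }
  keep
}

# Feature-grid indices (backbone stride `fs`) of each anchor center.
anchor_feature_index <- function(anchors, fs, feat_dims) {
  cbind(pmin(pmax(ceiling(anchors$cy / fs), 1L), feat_dims[1]),
        pmin(pmax(ceiling(anchors$cx / fs), 1L), feat_dims[2]))
}

# Nearest resampling of a full-image mask restricted to a box, to out x out.
resample_mask_crop <- function(mask, box, out = 8L) {
  ys <- pmin(pmax(floor(box$y0 + (seq_len(out) - 0.5) / out *
                          (box$y1 - box$y0)) + 1L, 1L), nrow(mask))
  xs <- pmin(pmax(floor(box$x0 + (seq_len(out) - 0.5) / out *
                          (box$x1 - box$x0)) + 1L, 1L), ncol(mask))
  mask[ys, xs, drop = FALSE]
}

smooth_l1 <- function(x) ifelse(abs(x) < 1, 0.5 * x^2, abs(x) - 0.5)
smooth_l1_grad <- function(x) ifelse(abs(x) < 1, x, sign(x))

#' Classification and box-regression losses
#'
#' `L_cls` is the mean binary cross-entropy over the sampled RoIs, with
#' positives capped at `roi_positive_ratio` of the sample; `L_box` is the
#' mean over positive RoIs of the summed smooth-L1 of the box-delta errors
#' normalized by `bbox_std`.
#'
#' @param pred_cls Predicted tumor-class probabilities per RoI.
#' @param pred_deltas Matrix `n x 4` of predicted box deltas.
#' @param target_labels 0/1 labels per RoI.
#' @param target_deltas Matrix `n x 4` of target deltas (rows for negatives
#'   are ignored).
#' @param roi_positive_ratio Positive cap.
#' @param bbox_std Delta normalizer.
#' @return List with `L_cls` and `L_box` (0 when there is no positive RoI).
#' @export
cls_box_losses <- function(pred_cls, pred_deltas, target_labels,
                           target_deltas, roi_positive_ratio = 0.35,
                           bbox_std = 1) {
  n <- length(pred_cls)
  if (n == 0) stopf("no RoIs")
  pred_deltas <- rbind(pred_deltas)
  target_deltas <- rbind(target_deltas)
  pos <- which(target_labels == 1)
  cap <- max(1L, ceiling(roi_positive_ratio * n))
  keep <- seq_len(n)
  if (length(pos) > cap) {
    drop_pos <- pos[-seq_len(cap)]
    keep <- setdiff(keep, drop_pos)
  }
  p <- pmin(pmax(pred_cls[keep], 1e-8), 1 - 1e-8)
  y <- target_labels[keep]
  l_cls <- mean(-(y * log(p) + (1 - y) * log(1 - p)))
  pos_kept <- intersect(keep, pos)
  l_box <- if (length(pos_kept) == 0) 0 else
    mean(vapply(pos_kept, function(i)
      sum(smooth_l1((pred_deltas[i, ] - target_deltas[i, ]) / bbox_std)),
      numeric(1)))
  list(L_cls = l_cls, L_box = l_box)
}

#' Adversarial generator loss for detection
#'
#' `(1/N) sum -log D_b(G_b(RoI_i))`: drives predicted regions toward scores
#' the discriminator accepts as real.
#'
#' @param d_scores Discriminator outputs in (0, 1].
#' @return Non-negative loss; 0 iff all scores are 1.
#' @export
adv_gen_loss <- function(d_scores) {
  if (length(d_scores) == 0) stopf("empty score list")
  if (any(d_scores <= 0)) stopf("discriminator scores must be > 0")
  mean(-log(d_scores))
}

#' Discriminator loss for detection
#'
#' `(1/N) sum -[log d_real_i + log(1 - d_fake_i)]`.
#'
#' @param d_real,d_fake Scores in (0, 1), same length.
#' @return Non-negative loss.
#' @export
det_disc_loss <- function(d_real, d_fake) {
  if (length(d_real) == 0 || length(d_fake) == 0) stopf("empty score list")
  if (any(c(d_real, d_fake) <= 0) || any(c(d_real, d_fake) >= 1))
    stopf("discriminator scores must lie in (0, 1)")
  mean(-(log(d_real) + log(1 - d_fake)))
}

#' Total generator loss for detection
#'
#' Unit-weight sum `L_cls + L_box + L_adv`.
#'
#' @param L_cls,L_box,L_adv Finite loss components.
#' @return Their sum.
#' @export
total_gen_loss <- function(L_cls, L_box, L_adv) {
  if (!all(is.finite(c(L_cls, L_box, L_adv)))) stopf("loss components must be finite")
  L_cls + L_box + L_adv
}

# ---- networks --------------------------------------------------------------

det_backbone_init <- function(C) {
  list(b1_W = init_mat(9L, C), b1_b = numeric(C),
       b2_W = init_mat(9L * C, 2L * C), b2_b = numeric(2L * C),
       obj_W = init_mat(2L * C, 1L), obj_b = 0,
       box_W = init_mat(2L * C, 4L, scale = 0.01), box_b = numeric(4L),
       mask_W = init_mat(49L * 2L * C, 64L, scale = 0.05),
       mask_b = numeric(64L))
}

det_backbone_forward <- function(p, image, mask_size) {
  x <- array(image, c(nrow(image), ncol(image), 1L))
  a1 <- conv2d_f(x, p$b1_W, p$b1_b); r1 <- lrelu_f(a1$out)
  p1 <- avgpool2_f(r1$out)
  a2 <- conv2d_f(p1$out, p$b2_W, p$b2_b); r2 <- lrelu_f(a2$out)
  p2 <- avgpool2_f(r2$out)
  feat <- p2$out                           # stride 4
  obj <- conv2d_f(feat, p$obj_W, p$obj_b, k = 1L)
  box <- conv2d_f(feat, p$box_W, p$box_b, k = 1L)
  list(feat = feat, obj_logit = obj$out[, , 1], box_deltas = box$out,
       caches = list(a1 = a1$cache, r1 = r1$cache, p1 = p1$cache,
                     a2 = a2$cache, r2 = r2$cache, p2 = p2$cache,
                     obj = obj$cache, box = box$cache))
}

det_backbone_backward <- function(p, fwd, dobj, dbox, dfeat) {
  cc <- fwd$caches
  g <- list()
  bo <- conv2d_b(array(dobj, c(dim(dobj), 1L)), cc$obj)
  g$obj_W <- bo$dW; g$obj_b <- bo$db
  bb <- conv2d_b(dbox, cc$box)
  g$box_W <- bb$dW; g$box_b <- bb$db
  d <- bo$dx + bb$dx + dfeat
  d <- avgpool2_b(d, cc$p2)
  d <- lrelu_b(d, cc$r2)
  b2 <- conv2d_b(d, cc$a2); g$b2_W <- b2$dW; g$b2_b <- b2$db
  d <- avgpool2_b(b2$dx, cc$p1)
  d <- lrelu_b(d, cc$r1)
  b1 <- conv2d_b(d, cc$a1); g$b1_W <- b1$dW; g$b1_b <- b1$db
  g
}

# Nearest-neighbor crop-and-resize of a feature map to out x out, with the
# index map kept for scatter-add backprop. Box is in image pixels.
crop_resize <- function(feat, box, stride, out = 7L) {
  d <- dim(feat)
  fx0 <- box$x0 / stride; fx1 <- box$x1 / stride
  fy0 <- box$y0 / stride; fy1 <- box$y1 / stride
  ys <- pmin(pmax(ceiling(fy0 + (seq_len(out) - 0.5) / out * (fy1 - fy0)), 1L),
             d[1])
  xs <- pmin(pmax(ceiling(fx0 + (seq_len(out) - 0.5) / out * (fx1 - fx0)), 1L),
             d[2])
  list(crop = feat[ys, xs, , drop = FALSE], ys = ys, xs = xs, dims = d)
}

crop_resize_b <- function(dcrop, cr) {
  dfeat <- array(0, cr$dims)
  for (i in seq_along(cr$ys))
    for (j in seq_along(cr$xs))
      dfeat[cr$ys[i], cr$xs[j], ] <- dfeat[cr$ys[i], cr$xs[j], ] + dcrop[i, j, ]
  dfeat
}

det_disc_init <- function(C) {
  list(d1_W = init_mat(9L * 2L * C, C), d1_b = numeric(C),
       d2_W = init_mat(C, 16L), d2_b = numeric(16L),
       d3_W = init_mat(16L, 1L), d3_b = 0)
}

det_disc_forward <- function(dp, crop) {
  a1 <- conv2d_f(crop, dp$d1_W, dp$d1_b, dil = 2L)
  r1 <- lrelu_f(a1$out)
  pooled <- apply(r1$out, 3, mean)
  h <- dense_f(pooled, dp$d2_W, dp$d2_b)
  hr <- lrelu_f(h$out)
  o <- dense_f(hr$out, dp$d3_W, dp$d3_b)
  s <- sigmoid(o$out)
  list(score = min(max(s, 1e-6), 1 - 1e-6),
       caches = list(a1 = a1$cache, r1 = r1$cache, h = h$cache, hr = hr$cache,
                     o = o$cache, npix = dim(r1$out)[1] * dim(r1$out)[2],
                     s = s))
}

det_disc_backward <- function(dp, fwd, dscore) {
  cc <- fwd$caches
  dlogit <- dscore * cc$s * (1 - cc$s)
  b3 <- dense_b(dlogit, cc$o)
  g <- list(d3_W = b3$dW, d3_b = b3$db)
  dhr <- lrelu_b(b3$dx, cc$hr)
  b2 <- dense_b(dhr, cc$h)
  g$d2_W <- b2$dW; g$d2_b <- b2$db
  dpool <- b2$dx
  dmap <- array(rep(dpool / cc$npix, each = cc$npix),
                c(cc$a1$dims[1], cc$a1$dims[2], length(dpool)))
  dr1 <- lrelu_b(dmap, cc$r1)
  b1 <- conv2d_b(dr1, cc$a1)
  g$d1_W <- b1$dW; g$d1_b <- b1$db
  list(grads = g[names(dp)], dx = b1$dx)
}

box_to_deltas <- function(gt, anchor) {
  wa <- anchor$x1 - anchor$x0; ha <- anchor$y1 - anchor$y0
  wg <- gt$x1 - gt$x0; hg <- gt$y1 - gt$y0
  c(((gt$x0 + gt$x1) / 2 - (anchor$x0 + anchor$x1) / 2) / wa,
    ((gt$y0 + gt$y1) / 2 - (anchor$y0 + anchor$y1) / 2) / ha,
    log(wg / wa), log(hg / ha))
}

deltas_to_box <- function(deltas, anchor, H, W, std = 1) {
  deltas <- deltas * std
  wa <- anchor$x1 - anchor$x0; ha <- anchor$y1 - anchor$y0
  cx <- (anchor$x0 + anchor$x1) / 2 + deltas[1] * wa
  cy <- (anchor$y0 + anchor$y1) / 2 + deltas[2] * ha
  w <- wa * exp(min(max(deltas[3], -2), 2))
  h <- ha * exp(min(max(deltas[4], -2), 2))
  list(x0 = max(0, cx - w / 2), y0 = max(0, cy - h / 2),
       x1 = min(W, cx + w / 2), y1 = min(H, cy + h / 2))
}

#' Propose scored regions of interest
#'
#' Grid-placed anchors at the configured scales and ratios, scored by the
#' model's objectness head, then filtered by non-maximum suppression; the
#' `top_k` survivors are returned in decreasing score order.
#'
#' @param model A `det_model`.
#' @param image `H x W` intensity matrix (already lung-masked).
#' @return Tibble with box coordinates and objectness scores.
#' @export
propose_rois <- function(model, image) {
  cfg <- model$config
  fwd <- det_backbone_forward(model$params, image, cfg$mask_size)
  fs <- nrow(image) / dim(fwd$feat)[1]
  anchors <- anchor_grid(nrow(image), ncol(image), cfg)
  afi <- anchor_feature_index(anchors, fs, dim(fwd$feat)[1:2])
  scores <- sigmoid(fwd$obj_logit[afi])
  boxes <- lapply(seq_len(nrow(anchors)), function(i) as.list(anchors[i, 1:4]))
  keep <- nms_boxes(boxes, scores, cfg$nms_iou)
  keep <- head(keep, cfg$top_k)
  tibble::tibble(x0 = anchors$x0[keep], y0 = anchors$y0[keep],
                 x1 = anchors$x1[keep], y1 = anchors$y1[keep],
                 score = scores[keep])
}

#' Train the lite Mask-R-CNN style detector
#'
#' The generator (backbone + objectness/box/mask heads) minimizes
#' `L_cls + L_box + L_adv` (Eqs. of the detection stage); the RoI-level
#' discriminator minimizes the real/fake log loss on fixed-size feature
#' crops of ground-truth versus predicted boxes from the shared backbone.
#' Training images are the lung-masked z-scored slices.
#'
#' @param dataset A [generate_dataset()] result; cases must carry tumor boxes.
#' @param config A [det_config()].
#' @param seed Training seed.
#' @param adversarial Set `FALSE` to ablate the adversarial term.
#' @param lung_masks Optional list (per case) of `H x W x Z` lung masks to use
#'   instead of the ground-truth masks (error-propagation harness).
#' @return List with `model` (class `det_model`) and `history` tibble.
#' @export
train_detector <- function(dataset, config, seed = config$seed,
                           adversarial = TRUE, lung_masks = NULL) {
  stopifnot(inherits(dataset, "phantom_dataset"), inherits(config, "det_config"))
  tr <- which(dataset$split == "train")
  if (length(tr) == 0) stopf("empty train split")
  samples <- det_collect_slices(dataset, tr, lung_masks)
  if (!any(vapply(samples, function(s) length(s$boxes) > 0, logical(1))))
    stopf("dataset provides no tumor boxes")
  params <- with_seed(seed, det_backbone_init(config$channels))
  disc <- with_seed(derive_seeds(seed, 1L), det_disc_init(config$channels))
  opt <- sgd_state(params)
  dopt <- sgd_state(disc)
  seeds <- derive_seeds(seed, config$epochs * length(samples) + 2L)
  si <- 0L
  hist <- list()
  for (ep in seq_len(config$epochs)) {
    ec <- c(); eb <- c(); ea <- c()
    cfg_ep <- config
    # inverse-time decay keeps the box head from oscillating late in training
    cfg_ep$gen_lr <- config$gen_lr / (1 + 0.3 * (ep - 1))
    cfg_ep$disc_lr <- config$disc_lr / (1 + 0.3 * (ep - 1))
    for (sm in samples) {
      si <- si + 1L
      upd <- det_update(params, disc, sm, cfg_ep, seeds[si], adversarial,
                        opt, dopt)
      params <- upd$params; disc <- upd$disc; opt <- upd$opt; dopt <- upd$dopt
      ec <- c(ec, upd$L_cls); eb <- c(eb, upd$L_box); ea <- c(ea, upd$L_adv)
    }
    hist[[ep]] <- tibble::tibble(epoch = ep, L_cls = mean(ec),
                                 L_box = mean(eb), L_adv = mean(ea),
                                 total = mean(ec) + mean(eb) + mean(ea))
  }
  model <- structure(list(params = params, disc = disc, config = config,
                          seed = seed), class = "det_model")
  list(model = model, history = do.call(rbind, hist))
}

det_collect_slices <- function(dataset, case_idx, lung_masks = NULL) {
  out <- list()
  for (k in seq_along(case_idx)) {
    ci <- case_idx[k]
    case <- dataset$cases[[ci]]
    lm <- if (is.null(lung_masks)) case$lung_mask else lung_masks[[k]]
    for (z in seq_len(dim(case$slices)[3])) {
      img <- fuse(lm[, , z], zscore(case$slices[, , z]))
      out[[length(out) + 1L]] <- list(
        image = img, boxes = case$tumor_boxes[[z]],
        tumor = case$tumor_mask[, , z], case = ci, z = z)
    }
  }
  out
}

det_match_anchors <- function(anchors, boxes) {
  n <- nrow(anchors)
  lab <- rep(0L, n)
  tgt <- matrix(0, n, 4)
  best_gt_iou <- numeric(length(boxes))
  best_gt_anchor <- integer(length(boxes))
  ious <- matrix(0, n, max(1L, length(boxes)))
  if (length(boxes) > 0) {
    for (j in seq_along(boxes)) {
      for (i in seq_len(n))
        ious[i, j] <- box_iou(as.list(anchors[i, 1:4]), boxes[[j]])
      best_gt_anchor[j] <- which.max(ious[, j])
      best_gt_iou[j] <- max(ious[, j])
    }
    amax <- apply(ious, 1, max)
    aarg <- apply(ious, 1, which.max)
    lab[amax >= 0.5] <- 1L
    lab[best_gt_anchor] <- 1L
    for (i in which(lab == 1L)) {
      j <- aarg[i]
      tgt[i, ] <- box_to_deltas(boxes[[j]], as.list(anchors[i, 1:4]))
    }
    # anchors near (but not on) a tumor are ignored, not negatives: their
    # features overlap the positives' receptive fields
    center_in <- rep(FALSE, n)
    for (j in seq_along(boxes)) {
      b <- boxes[[j]]
      center_in <- center_in | (anchors$cx >= b$x0 - 2 & anchors$cx <= b$x1 + 2 &
                                  anchors$cy >= b$y0 - 2 & anchors$cy <= b$y1 + 2)
    }
    neg <- amax < 0.1 & !center_in
  } else {
    neg <- rep(TRUE, n)
  }
  list(labels = lab, targets = tgt, negative = neg & lab == 0L)
}

det_update <- function(params, disc, sm, cfg, seed, adversarial, opt, dopt) {
  img <- sm$image
  H <- nrow(img); W <- ncol(img)
  fwd <- det_backbone_forward(params, img, cfg$mask_size)
  fs <- H / dim(fwd$feat)[1]                     # backbone stride
  anchors <- anchor_grid(H, W, cfg)
  mt <- det_match_anchors(anchors, sm$boxes)
  pos <- which(mt$labels == 1L)
  negs <- which(mt$negative)
  n_pos <- min(length(pos), max(1L, floor(cfg$roi_positive_ratio *
                                            cfg$rois_per_image)))
  n_neg <- min(length(negs), cfg$rois_per_image - n_pos)
  sel <- with_seed(seed, c(sample_vec(pos, n_pos), sample_vec(negs, n_neg)))
  afi <- anchor_feature_index(anchors, fs, dim(fwd$feat)[1:2])
  grid_idx <- function(i) afi[i, ]
  probs <- numeric(length(sel))
  dobj <- fwd$obj_logit * 0
  dbox <- fwd$box_deltas * 0
  for (s in seq_along(sel)) {
    gi <- grid_idx(sel[s])
    probs[s] <- sigmoid(fwd$obj_logit[gi[1], gi[2]])
  }
  y <- mt$labels[sel]
  # class-balanced BCE: positives and negatives contribute equal total weight
  wts <- ifelse(y == 1, 0.5 / max(sum(y == 1), 1L), 0.5 / max(sum(y == 0), 1L))
  if (all(y == y[1])) wts <- rep(1 / length(y), length(y))
  for (s in seq_along(sel)) {
    gi <- grid_idx(sel[s])
    dobj[gi[1], gi[2]] <- dobj[gi[1], gi[2]] + (probs[s] - y[s]) * wts[s]
  }
  L_cls <- sum(wts * -(y * log(pmax(probs, 1e-8)) +
                         (1 - y) * log(pmax(1 - probs, 1e-8))))
  L_box <- 0
  pos_sel <- sel[y == 1]
  if (length(pos_sel) > 0) {
    for (i in pos_sel) {
      gi <- grid_idx(i)
      pred <- fwd$box_deltas[gi[1], gi[2], ]     # head emits normalized deltas
      err <- pred - mt$targets[i, ] / cfg$bbox_std
      L_box <- L_box + sum(smooth_l1(err))
      g <- smooth_l1_grad(err) / length(pos_sel)
      dbox[gi[1], gi[2], ] <- dbox[gi[1], gi[2], ] + g
    }
    L_box <- L_box / length(pos_sel)
  }
  dfeat <- fwd$feat * 0
  # mask head: BCE against the resampled ground-truth tumor crop
  if (length(sm$boxes) > 0) {
    gt_box <- sm$boxes[[1]]
    if (gt_box$x1 > gt_box$x0 && gt_box$y1 > gt_box$y0) {
      cr <- crop_resize(fwd$feat, gt_box, fs)
      xf <- as.numeric(cr$crop)
      df <- dense_f(xf, params$mask_W, params$mask_b)
      mp <- sigmoid(df$out)
      tgt <- as.numeric(resample_mask_crop(sm$tumor, gt_box, 8L))
      dlog <- (mp - tgt) / length(mp)
      bm <- dense_b(dlog, df$cache)
      dfeat <- dfeat + crop_resize_b(array(bm$dx, dim(cr$crop)), cr)
      mask_gW <- bm$dW; mask_gb <- bm$db
    } else {
      mask_gW <- params$mask_W * 0; mask_gb <- params$mask_b * 0
    }
  } else {
    mask_gW <- params$mask_W * 0; mask_gb <- params$mask_b * 0
  }
  L_adv <- 0
  if (adversarial && length(sm$boxes) > 0) {
    # generator path: discriminator score on the top predicted box's features
    ascores <- fwd$obj_logit[afi]
    best <- which.max(ascores)
    bi <- afi[best, 1]; bj <- afi[best, 2]
    pred_box <- deltas_to_box(fwd$box_deltas[bi, bj, ],
                              as.list(anchors[best, 1:4]), H, W,
                              cfg$bbox_std)
    if (pred_box$x1 > pred_box$x0 + 1 && pred_box$y1 > pred_box$y0 + 1) {
      cr <- crop_resize(fwd$feat, pred_box, fs)
      dfw <- det_disc_forward(disc, cr$crop)
      L_adv <- adv_gen_loss(dfw$score)
      db <- det_disc_backward(disc, dfw, -1 / max(dfw$score, 0.05))
      dfeat <- dfeat + pmax(pmin(crop_resize_b(db$dx, cr), 0.5), -0.5)
      # discriminator update: real (gt box) vs fake (predicted box) crops
      gt_box <- sm$boxes[[with_seed(seed, sample.int(length(sm$boxes), 1))]]
      crr <- crop_resize(fwd$feat, gt_box, fs)
      dreal <- det_disc_forward(disc, crr$crop)
      dfake <- det_disc_forward(disc, cr$crop)
      gb_real <- det_disc_backward(disc, dreal,
                                   -1 / max(dreal$score, 0.05))$grads
      gb_fake <- det_disc_backward(disc, dfake,
                                   1 / max(1 - dfake$score, 0.05))$grads
      dg <- clamp_grads(add_grads(gb_real, gb_fake))
      du <- sgd_step(disc, dg, dopt, cfg$disc_lr, cfg$momentum)
      disc <- du$params; dopt <- du$state
    }
  }
  grads <- det_backbone_backward(params, fwd, dobj, dbox, dfeat)
  grads$mask_W <- mask_gW; grads$mask_b <- mask_gb
  grads <- clamp_grads(grads)
  grads <- grads[names(params)]
  gu <- sgd_step(params, grads, opt, cfg$gen_lr, cfg$momentum)
  list(params = gu$params, disc = disc, opt = gu$state, dopt = dopt,
       L_cls = L_cls, L_box = L_box, L_adv = L_adv)
}

#' Detect tumors in one slice
#'
#' Scores all anchors with the objectness head, applies the predicted box
#' refinements, suppresses duplicates with NMS and returns up to `top_k`
#' detections with probability `>= score_threshold`, sorted by decreasing
#' probability. Each detection carries a mask crop thresholded at
#' `mask_threshold`.
#'
#' @param model A `det_model`.
#' @param image Lung-masked intensity matrix.
#' @return List of detections: each a list with `box`, `score`, `mask`.
#' @export
detect <- function(model, image) {
  cfg <- model$config
  fwd <- det_backbone_forward(model$params, image, cfg$mask_size)
  fs <- nrow(image) / dim(fwd$feat)[1]
  anchors <- anchor_grid(nrow(image), ncol(image), cfg)
  afi <- anchor_feature_index(anchors, fs, dim(fwd$feat)[1:2])
  scores <- sigmoid(fwd$obj_logit[afi])
  cand <- which(scores >= cfg$score_threshold)
  if (length(cand) == 0) return(list())
  boxes <- lapply(cand, function(i)
    deltas_to_box(fwd$box_deltas[afi[i, 1], afi[i, 2], ],
                  as.list(anchors[i, 1:4]), nrow(image), ncol(image),
                  cfg$bbox_std))
  keep <- nms_boxes(boxes, scores[cand], cfg$nms_iou)
  keep <- head(keep, cfg$top_k)
  out <- lapply(keep, function(k) {
    box <- boxes[[k]]
    cr <- crop_resize(fwd$feat, box, fs)
    logits <- dense_f(as.numeric(cr$crop),
                      model$params$mask_W, model$params$mask_b)$out
    mask_p <- matrix(sigmoid(logits), 8L, 8L)
    list(box = box, score = scores[cand[k]],
         mask = (mask_p >= cfg$mask_threshold) * 1L, mask_prob = mask_p)
  })
  out[order(vapply(out, function(d) d$score, numeric(1)), decreasing = TRUE)]
}

#' Match detections to ground truth
#'
#' Greedy one-to-one matching in decreasing probability order: a prediction
#' matches an unmatched ground-truth box when their IoU is at least
#' `iou_threshold`.
#'
#' @param preds List of detections (with `box` and `score`) or boxes.
#' @param gts List of ground-truth boxes.
#' @param iou_threshold Matching threshold in (0, 1].
#' @return List with `TP`, `FP`, `FN`.
#' @export
match_detections <- function(preds, gts, iou_threshold = 0.5) {
  if (iou_threshold <= 0 || iou_threshold > 1)
    stopf("iou_threshold must be in (0, 1]")
  get_box <- function(p) if (!is.null(p$box)) p$box else p
  get_score <- function(p) if (!is.null(p$score)) p$score else 1
  if (length(preds) > 1) {
    ord <- order(vapply(preds, get_score, numeric(1)), decreasing = TRUE)
    preds <- preds[ord]
  }
  used <- rep(FALSE, length(gts))
  tp <- 0L
  for (p in preds) {
    if (length(gts) > 0) {
      ious <- vapply(seq_along(gts), function(j)
        if (used[j]) -1 else box_iou(get_box(p), gts[[j]]), numeric(1))
      j <- which.max(ious)
      if (length(j) == 1 && ious[j] >= iou_threshold) {
        used[j] <- TRUE
        tp <- tp + 1L
      }
    }
  }
  list(TP = tp, FP = length(preds) - tp, FN = length(gts) - tp)
}
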