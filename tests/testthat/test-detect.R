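test_that("anchor grid enumerates centers and clips to bounds", {
  cfg <- det_config(anchor_scales = 16, anchor_ratios = 1, stride = 16L)
  g <- anchor_grid(64, 64, cfg)
  expect_equal(nrow(g), 16)                    # 4 x 4 grid, one box each
  expect_true(all(g$x0 >= 0 & g$y0 >= 0 & g$x1 <= 64 & g$y1 <= 64))
  expect_setequal(unique(g$cx), c(8, 24, 40, 56))
  expect_error(anchor_grid(4, 4, det_config(stride = 16L)), "no anchor")
  expect_error(det_config(anchor_scales = -1), "scales")
})

test_that("nms keeps all at threshold 1 and one per cluster at 0", {
  b1 <- list(x0 = 0, y0 = 0, x1 = 10, y1 = 10)
  b2 <- list(x0 = 2, y0 = 2, x1 = 12, y1 = 12)   # overlaps b1
  b3 <- list(x0 = 30, y0 = 30, x1 = 40, y1 = 40) # disjoint
  boxes <- list(b1, b2, b3)
  scores <- c(0.9, 0.8, 0.7)
  expect_length(nms_boxes(boxes, scores, 1), 3)
  keep0 <- nms_boxes(boxes, scores, 0)
  expect_setequal(keep0, c(1, 3))                # one per overlap cluster
  expect_equal(keep0[1], 1)                      # kept in score order
})

test_that("classification and box losses match hand arithmetic", {
  # perfect class probabilities -> zero cross-entropy
  out <- cls_box_losses(c(1 - 1e-9, 1e-9), matrix(0, 2, 4), c(1, 0),
                        matrix(0, 2, 4))
  expect_equal(out$L_cls, 0, tolerance = 1e-6)
  # matching deltas -> zero box loss
  expect_equal(out$L_box, 0)
  # single positive, 0.5 error per coordinate, std 1 -> 4 * 0.125
  out2 <- cls_box_losses(0.8, matrix(0.5, 1, 4), 1, matrix(0, 1, 4),
                         roi_positive_ratio = 1, bbox_std = 1)
  expect_equal(out2$L_box, 0.5)
  expect_equal(out2$L_cls, -log(0.8))
  expect_error(cls_box_losses(numeric(0), NULL, numeric(0), NULL), "RoIs")
})

test_that("adversarial losses follow their formulas", {
  expect_equal(adv_gen_loss(c(1, 1, 1)), 0)
  expect_equal(adv_gen_loss(rep(exp(-1), 5)), 1)
  expect_equal(adv_gen_loss(c(0.5, 0.25)), (log(2) + log(4)) / 2)
  expect_gte(adv_gen_loss(runif(10, 0.01, 1)), 0)
  expect_error(adv_gen_loss(c(0.5, 0)), "> 0")
  expect_equal(det_disc_loss(0.5, 0.5), -(log(0.5) + log(0.5)))
  eps <- 1e-6
  expect_lt(det_disc_loss(1 - eps, eps), 1e-5)
  # permutation invariance and monotonicity
  dr <- runif(6, 0.2, 0.8); df <- runif(6, 0.2, 0.8)
  pr <- sample(6)
  expect_equal(det_disc_loss(dr, df), det_disc_loss(dr[pr], df[pr]))
  expect_lt(det_disc_loss(dr + 0.1, df), det_disc_loss(dr, df))
  expect_lt(det_disc_loss(dr, df - 0.1), det_disc_loss(dr, df))
  expect_equal(total_gen_loss(0, 0, 0), 0)
  expect_equal(total_gen_loss(1, 2, 3), 6)
  expect_equal(total_gen_loss(2, 2, 3), total_gen_loss(1, 2, 3) + 1)
  expect_error(total_gen_loss(Inf, 0, 0), "finite")
})

test_that("detection matching is greedy one-to-one", {
  b <- function(x0, y0, x1, y1) list(x0 = x0, y0 = y0, x1 = x1, y1 = y1)
  gts <- list(b(0, 0, 10, 10), b(20, 20, 30, 30))
  preds <- list(list(box = b(0, 0, 10, 10), score = 0.9),
                list(box = b(20, 20, 30, 30), score = 0.8))
  m <- match_detections(preds, gts, 0.5)
  expect_equal(m, list(TP = 2L, FP = 0L, FN = 0L))
  expect_equal(match_detections(list(), gts, 0.5)$FN, 2L)
  # two predictions on one ground truth: one TP, one FP
  preds2 <- list(list(box = b(0, 0, 10, 10), score = 0.9),
                 list(box = b(1, 1, 11, 11), score = 0.8))
  m2 <- match_detections(preds2, list(gts[[1]]), 0.5)
  expect_equal(m2, list(TP = 1L, FP = 1L, FN = 0L))
  expect_error(match_detections(preds, gts, 0), "iou_threshold")
})

test_that("smoke training is deterministic and reduces the total loss", {
  ds <- generate_dataset(8, phantom_config(
    image_size = 32, n_slices = 4, lung_fraction_target = 0.2,
    tumor_radius_range = c(2.5, 3.5), noise_sd = 0.05, tumor_contrast = 1.5,
    seed = 77))
  cfg <- det_config(anchor_scales = 8, anchor_ratios = 1, stride = 4L,
                    epochs = 4, channels = 4, seed = 2)
  r1 <- train_detector(ds, cfg)
  r2 <- train_detector(ds, cfg)
  expect_identical(r1$history, r2$history)
  expect_lt(tail(r1$history$L_cls, 1), r1$history$L_cls[1])
  # ablation without the adversarial term still reduces L_cls + L_box
  r0 <- train_detector(ds, cfg, adversarial = FALSE)
  expect_true(all(r0$history$L_adv == 0))
  expect_lt(tail(r0$history$L_cls + r0$history$L_box, 1),
            (r0$history$L_cls + r0$history$L_box)[1])
  # detections come out sorted by descending probability
  case <- ds$cases[[which(ds$split == "train")[1]]]
  z <- which(vapply(case$tumor_boxes, length, integer(1)) > 0)[1]
  dd <- detect(r1$model,
               fuse(case$lung_mask[, , z], zscore(case$slices[, , z])))
  if (length(dd) > 1) {
    sc <- vapply(dd, function(d) d$score, numeric(1))
    expect_true(all(diff(sc) <= 0))
  }
  expect_error(train_detector(generate_dataset(
    4, tiny_phantom_config(tumors_per_case = 0L)), cfg), "boxes")
})

test_that("propose_rois returns scored, NMS-filtered anchor boxes", {
  cfg <- det_config(anchor_scales = 8, anchor_ratios = 1, stride = 8L,
                    channels = 4, top_k = 3L, seed = 5)
  model <- structure(list(params = with_seed(5, lungrecon:::det_backbone_init(4L)),
                          config = cfg), class = "det_model")
  img <- matrix(rnorm(32 * 32), 32, 32)
  rois <- propose_rois(model, img)
  expect_lte(nrow(rois), 3)
  expect_true(all(rois$x0 >= 0 & rois$x1 <= 32))
  expect_true(all(diff(rois$score) <= 0))
})
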