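#' Z-score normalization
#'
#' Centers and scales to zero mean and unit variance (population convention,
#' dividing by the root mean squared deviation). A constant input cannot be
#' scaled and maps to all zeros with a warning.
#'
#' @param x Numeric array or matrix.
#' @return Array of the same shape, mean 0 and sd 1 (or all zeros).
#' @export
zscore <- function(x) {
  if (length(x) == 0) stopf("empty input")
  mu <- mean(x)
  s <- sqrt(mean((x - mu)^2))
  if (s == 0) {
    warnf("constant input; z-score undefined, returning zeros")
    return(x * 0)
  }
  (x - mu) / s
}

#' Seed-deterministic augmentation of a slice and its masks
#'
#' Applies one random composition of a rotation in `[-max_rotation,
#' +max_rotation]` degrees, horizontal/vertical flips and a coarse-grid
#' elastic deformation. The identical geometric transform is applied to the
#' image and every mask; masks are resampled nearest-neighbor so they remain
#' binary. Augmentation is meant for training splits only.
#'
#' @param image `H x W` matrix.
#' @param masks List of `H x W` binary matrices (possibly empty).
#' @param seed Integer seed for the transform draw.
#' @param max_rotation Rotation bound in degrees.
#' @param elastic_sd Standard deviation (pixels) of the coarse elastic
#'   displacement field; 0 disables it.
#' @param elastic_grid Control points per side of the elastic grid.
#' @return List with `image` and `masks` (same shapes as the inputs).
#' @export
augment <- function(image, masks = list(), seed = 1L, max_rotation = 15,
                    elastic_sd = 1, elastic_grid = 4L) {
  H <- nrow(image); W <- ncol(image)
  for (m in masks)
    if (!identical(dim(m), dim(image))) stopf("mask/image shape mismatch")
  with_seed(seed, {
    ang <- runif(1, -max_rotation, max_rotation) * pi / 180
    fh <- runif(1) < 0.5
    fv <- runif(1) < 0.5
    if (elastic_sd > 0) {
      gy <- matrix(rnorm(elastic_grid^2, 0, elastic_sd), elastic_grid)
      gx <- matrix(rnorm(elastic_grid^2, 0, elastic_sd), elastic_grid)
    } else gy <- gx <- matrix(0, 1, 1)
    cy <- (H + 1) / 2; cx <- (W + 1) / 2
    grid <- expand.grid(i = seq_len(H), j = seq_len(W))
    # inverse map: output pixel -> source pixel
    di <- grid$i - cy; dj <- grid$j - cx
    si <- cos(ang) * di + sin(ang) * dj + cy
    sj <- -sin(ang) * di + cos(ang) * dj + cx
    if (fh) sj <- W + 1 - sj
    if (fv) si <- H + 1 - si
    if (elastic_sd > 0) {
      up <- function(g, n1, n2) {
        gi <- pmin(pmax(ceiling(seq_len(n1) / n1 * nrow(g)), 1), nrow(g))
        gj <- pmin(pmax(ceiling(seq_len(n2) / n2 * ncol(g)), 1), ncol(g))
        g[gi, gj, drop = FALSE]
      }
      si <- si + as.numeric(up(gy, H, W)[cbind(grid$i, grid$j)])
      sj <- sj + as.numeric(up(gx, H, W)[cbind(grid$i, grid$j)])
    }
    ri <- round(si); rj <- round(sj)
    ok <- ri >= 1 & ri <= H & rj >= 1 & rj <= W
    resample <- function(m) {
      out <- matrix(0, H, W)
      out[cbind(grid$i, grid$j)[ok, , drop = FALSE]] <-
        m[cbind(ri, rj)[ok, , drop = FALSE]]
      out
    }
    list(image = resample(image), masks = lapply(masks, resample))
  })
}

resize_nearest <- function(m, out_h, out_w) {
  gi <- pmin(pmax(ceiling(seq_len(out_h) / out_h * nrow(m)), 1), nrow(m))
  gj <- pmin(pmax(ceiling(seq_len(out_w) / out_w * ncol(m)), 1), ncol(m))
  m[gi, gj, drop = FALSE]
}

# Crop the tumor-bearing slice range (and the ground-truth volume, when
# present) to a square region around the union of detection boxes, then
# resample to side^3. `z_range` is the inclusive slice range to keep
# (default: all slices).
crop_tumor_sequence <- function(slices, boxes, side, gt_volume = NULL,
                                z_range = NULL) {
  H <- nrow(slices[[1]]); W <- ncol(slices[[1]])
  if (is.null(z_range)) z_range <- c(1L, length(slices))
  zs <- z_range[1]:z_range[2]
  slices <- slices[zs]
  x0 <- min(vapply(boxes, function(b) b$x0, numeric(1)))
  y0 <- min(vapply(boxes, function(b) b$y0, numeric(1)))
  x1 <- max(vapply(boxes, function(b) b$x1, numeric(1)))
  y1 <- max(vapply(boxes, function(b) b$y1, numeric(1)))
  cxm <- (x0 + x1) / 2; cym <- (y0 + y1) / 2
  half <- max(x1 - x0, y1 - y0) / 2 + 2
  ys <- pmin(pmax(round(cym - half + 1):round(cym + half), 1), H)
  xs <- pmin(pmax(round(cxm - half + 1):round(cxm + half), 1), W)
  seq_out <- lapply(slices, function(s)
    resize_nearest(s[ys, xs, drop = FALSE], side, side))
  gt_out <- NULL
  if (!is.null(gt_volume)) {
    zi <- zs[pmin(pmax(ceiling(seq_len(side) / side * length(zs)), 1),
                  length(zs))]
    gt_out <- array(0L, c(side, side, side))
    for (k in seq_len(side))
      gt_out[, , k] <- resize_nearest(gt_volume[ys, xs, zi[k]], side, side)
  }
  list(slices = seq_out, gt = gt_out, ys = ys, xs = xs)
}

#' Run the full three-stage pipeline on one case
#'
#' Preprocess (z-score), segment the lungs, restrict the image to the
#' predicted lung fields, detect tumors per slice, crop the detected tumor
#' sequence and reconstruct the 3-D volume, then evaluate against ground
#' truth when present. A case with no detected tumor skips reconstruction
#' with an explicit status rather than failing.
#'
#' @param case A `phantom_case` (or list with `slices` and optional masks).
#' @param models List with elements `seg`, `det`, `recon` (trained models).
#' @param tconfig Optional [transductive_config()] plus `train_data` attached
#'   as `attr(tconfig, "train_data")` for per-case adaptation.
#' @return List with `status`, `lung_mask`, `detections`, `recon`, `metrics`.
#' @export
run_pipeline <- function(case, models, tconfig = NULL) {
  for (nm in c("seg", "det", "recon"))
    if (is.null(models[[nm]]))
      stopf("missing trained model for stage '%s'", nm)
  nz <- dim(case$slices)[3]
  lung_pred <- array(0L, dim(case$slices))
  dets <- vector("list", nz)
  for (z in seq_len(nz)) {
    img <- zscore(case$slices[, , z])
    sg <- segment(models$seg, img, normalize = FALSE)
    lung_pred[, , z] <- sg$mask
    dets[[z]] <- detect(models$det, fuse(sg$mask, img))
  }
  boxes <- list()
  det_slices <- integer()
  for (z in seq_len(nz)) if (length(dets[[z]]) > 0) {
    boxes[[length(boxes) + 1L]] <- dets[[z]][[1]]$box
    det_slices <- c(det_slices, z)
  }
  metrics <- list()
  if (!is.null(case$lung_mask))
    metrics$seg_iou <- iou(lung_pred, case$lung_mask)
  if (length(boxes) == 0) {
    return(list(status = "no_tumor_detected", lung_mask = lung_pred,
                detections = dets, recon = NULL,
                metrics = tibble::as_tibble(metrics)))
  }
  side <- models$recon$config$volume_size
  slices <- lapply(seq_len(nz), function(z) zscore(case$slices[, , z]))
  cr <- crop_tumor_sequence(slices, boxes, side, case$tumor_volume,
                            z_range = range(det_slices))
  train_data <- if (!is.null(tconfig)) attr(tconfig, "train_data") else NULL
  rec <- reconstruct(models$recon, cr$slices, tconfig = tconfig,
                     train_data = train_data)
  if (!is.null(cr$gt)) {
    ev <- evaluate_reconstruction(rec$mask, cr$gt)
    metrics$recon_hd <- ev$HD
    metrics$recon_ed <- ev$ED
  }
  if (!is.null(case$tumor_boxes)) {
    mm <- Reduce(function(acc, z) {
      r <- match_detections(dets[[z]], case$tumor_boxes[[z]])
      list(TP = acc$TP + r$TP, FP = acc$FP + r$FP, FN = acc$FN + r$FN)
    }, seq_len(nz), list(TP = 0L, FP = 0L, FN = 0L))
    metrics$det_tp <- mm$TP; metrics$det_fp <- mm$FP; metrics$det_fn <- mm$FN
  }
  list(status = "ok", lung_mask = lung_pred, detections = dets, recon = rec,
       metrics = tibble::as_tibble(metrics))
}

box_outline_points <- function(b) {
  xs <- seq(b$x0, b$x1, by = 1)
  ys <- seq(b$y0, b$y1, by = 1)
  rbind(cbind(b$y0, xs), cbind(b$y1, xs), cbind(ys, b$x0), cbind(ys, b$x1))
}

# Detection-stage metrics for one case under a given lung-mask source.
detection_case_metrics <- function(case, det_model, lung_mask) {
  nz <- dim(case$slices)[3]
  ious <- c(); hds <- c()
  for (z in seq_len(nz)) {
    gt <- case$tumor_boxes[[z]]
    if (length(gt) == 0) next
    img <- zscore(case$slices[, , z])
    dd <- detect(det_model, fuse(lung_mask[, , z], img))
    if (length(dd) == 0) {
      ious <- c(ious, 0)
      next
    }
    ious <- c(ious, box_iou(dd[[1]]$box, gt[[1]]))
    hds <- c(hds, hd(box_outline_points(dd[[1]]$box),
                     box_outline_points(gt[[1]])))
  }
  list(iou = ious, hd = hds)
}

#' Error-propagation analysis across pipeline stages
#'
#' Evaluates stage 2 (detection) twice — once fed ground-truth lung masks,
#' once fed the segmenter's predicted masks — and stage 3 (reconstruction)
#' twice — once on crops from ground-truth tumor boxes, once on crops from
#' predicted detections. Each metric row reports the mean and sd under both
#' input sources and the absolute difference of the means ("Difference"
#' convention: `|ground_truth - predicted|`).
#'
#' @param dataset A [generate_dataset()] result with ground truth.
#' @param models List with trained `seg`, `det`, `recon` models.
#' @param split Which split to evaluate (default `"test"`).
#' @param use_gt_predictions Harness validation switch: when `TRUE` the
#'   "predicted" arm is fed the ground-truth inputs too, so every difference
#'   must be exactly zero.
#' @return A tibble of class `error_propagation_report` with columns `stage`,
#'   `metric`, `gt_mean`, `gt_sd`, `pred_mean`, `pred_sd`, `difference`.
#' @export
error_propagation <- function(dataset, models, split = "test",
                              use_gt_predictions = FALSE) {
  stopifnot(inherits(dataset, "phantom_dataset"))
  idx <- which(dataset$split == split)
  if (length(idx) == 0) stopf("no cases in split '%s'", split)
  for (ci in idx)
    if (is.null(dataset$cases[[ci]]$lung_mask))
      stopf("missing ground truth")
  det_iou_gt <- c(); det_iou_pr <- c(); det_hd_gt <- c(); det_hd_pr <- c()
  rec_hd_gt <- c(); rec_hd_pr <- c(); rec_ed_gt <- c(); rec_ed_pr <- c()
  side <- models$recon$config$volume_size
  for (ci in idx) {
    case <- dataset$cases[[ci]]
    nz <- dim(case$slices)[3]
    lung_pred <- array(0L, dim(case$slices))
    for (z in seq_len(nz))
      lung_pred[, , z] <- segment(models$seg, case$slices[, , z])$mask
    if (use_gt_predictions) lung_pred <- case$lung_mask
    mg <- detection_case_metrics(case, models$det, case$lung_mask)
    mp <- detection_case_metrics(case, models$det, lung_pred)
    det_iou_gt <- c(det_iou_gt, mg$iou); det_iou_pr <- c(det_iou_pr, mp$iou)
    det_hd_gt <- c(det_hd_gt, mg$hd); det_hd_pr <- c(det_hd_pr, mp$hd)
    # stage 3: ground-truth boxes vs predicted detections as crop source
    slices <- lapply(seq_len(nz), function(z) zscore(case$slices[, , z]))
    gt_boxes <- unlist(case$tumor_boxes, recursive = FALSE)
    pred_boxes <- list()
    pred_z <- integer()
    for (z in seq_len(nz)) {
      img <- zscore(case$slices[, , z])
      dd <- detect(models$det, fuse(lung_pred[, , z], img))
      if (length(dd) > 0) {
        pred_boxes[[length(pred_boxes) + 1L]] <- dd[[1]]$box
        pred_z <- c(pred_z, z)
      }
    }
    gt_z <- which(vapply(case$tumor_boxes, length, integer(1)) > 0)
    if (length(gt_boxes) > 0) {
      crg <- crop_tumor_sequence(slices, gt_boxes, side, case$tumor_volume,
                                 z_range = range(gt_z))
      evg <- suppressWarnings(evaluate_reconstruction(
        reconstruct(models$recon, crg$slices)$mask, crg$gt))
      rec_hd_gt <- c(rec_hd_gt, evg$HD); rec_ed_gt <- c(rec_ed_gt, evg$ED)
      use_gt <- use_gt_predictions || length(pred_boxes) == 0
      bsrc <- if (use_gt) gt_boxes else pred_boxes
      zsrc <- if (use_gt) range(gt_z) else range(pred_z)
      crp <- crop_tumor_sequence(slices, bsrc, side, case$tumor_volume,
                                 z_range = zsrc)
      evp <- suppressWarnings(evaluate_reconstruction(
        reconstruct(models$recon, crp$slices)$mask, crp$gt))
      rec_hd_pr <- c(rec_hd_pr, evp$HD); rec_ed_pr <- c(rec_ed_pr, evp$ED)
    }
  }
  msd <- function(x) if (length(x) == 0) c(NA_real_, NA_real_) else
    c(mean(x[is.finite(x)]), if (length(x) > 1) sd(x[is.finite(x)]) else 0)
  row <- function(stage, metric, gt, pr) {
    a <- msd(gt); b <- msd(pr)
    tibble::tibble(stage = stage, metric = metric, gt_mean = a[1],
                   gt_sd = a[2], pred_mean = b[1], pred_sd = b[2],
                   difference = abs(a[1] - b[1]))
  }
  rep <- rbind(row("detection", "IoU", det_iou_gt, det_iou_pr),
               row("detection", "HD", det_hd_gt, det_hd_pr),
               row("reconstruction", "HD", rec_hd_gt, rec_hd_pr),
               row("reconstruction", "ED", rec_ed_gt, rec_ed_pr))
  attr(rep, "difference_convention") <-
    "difference = |gt_mean - pred_mean| (absolute)"
  class(rep) <- c("error_propagation_report", class(rep))
  rep
}

# ---- serialization ---------------------------------------------------------

#' Write and read phantom cases and datasets
#'
#' A case directory holds the arrays (RDS) and a JSON sidecar with boxes and
#' metadata; a dataset directory holds per-case subdirectories plus a
#' `manifest.json` listing every case, its split and the generator config.
#'
#' @param case A `phantom_case`.
#' @param dir Target directory (created if needed).
#' @return `write_case` returns `dir` invisibly; `read_case` the case.
#' @export
write_case <- function(case, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(case$slices, file.path(dir, "slices.rds"))
  saveRDS(case$lung_mask, file.path(dir, "lung_mask.rds"))
  saveRDS(case$tumor_mask, file.path(dir, "tumor_mask.rds"))
  sidecar <- list(boxes = case$tumor_boxes,
                  seed = case$meta$seed,
                  config = unclass(case$meta$config))
  jsonlite::write_json(sidecar, file.path(dir, "case.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_case
#' @export
read_case <- function(dir) {
  jf <- file.path(dir, "case.json")
  if (!file.exists(jf)) stopf("corrupt case directory: missing 'case.json'")
  side <- jsonlite::read_json(jf, simplifyVector = FALSE)
  for (key in c("boxes", "config", "seed"))
    if (is.null(side[[key]]))
      stopf("corrupt case file: missing key '%s'", key)
  tumor <- readRDS(file.path(dir, "tumor_mask.rds"))
  boxes <- lapply(side$boxes, function(sl)
    lapply(sl, function(b) lapply(b, as.numeric)))
  cfg <- side$config
  config <- phantom_config(cfg$image_size, cfg$n_slices,
                           cfg$lung_fraction_target,
                           unlist(cfg$tumor_radius_range), cfg$tumor_shape,
                           cfg$tumor_contrast, cfg$noise_sd,
                           cfg$tumors_per_case, cfg$seed)
  structure(list(slices = readRDS(file.path(dir, "slices.rds")),
                 lung_mask = readRDS(file.path(dir, "lung_mask.rds")),
                 tumor_mask = tumor, tumor_boxes = boxes,
                 tumor_volume = tumor,
                 meta = list(seed = side$seed, config = config)),
            class = "phantom_case")
}

#' @rdname write_case
#' @param dataset A `phantom_dataset`.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- sprintf("case_%03d", seq_along(dataset$cases))
  for (i in seq_along(dataset$cases))
    write_case(dataset$cases[[i]], file.path(dir, ids[i]))
  manifest <- list(cases = ids, split = dataset$split,
                   config = unclass(dataset$config),
                   package_version = as.character(utils::packageVersion("lungrecon")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_case
#' @export
read_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stopf("corrupt dataset: missing 'manifest.json'")
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  cases <- lapply(manifest$cases, function(id) read_case(file.path(dir, id)))
  cfg <- manifest$config
  config <- phantom_config(cfg$image_size, cfg$n_slices,
                           cfg$lung_fraction_target,
                           unlist(cfg$tumor_radius_range), cfg$tumor_shape,
                           cfg$tumor_contrast, cfg$noise_sd,
                           cfg$tumors_per_case, cfg$seed)
  structure(list(cases = cases, split = manifest$split, config = config),
            class = "phantom_dataset")
}

#' Export a volume as NIfTI
#'
#' @param vol 3-D array.
#' @param path Output `.nii`/`.nii.gz` path.
#' @param spacing Per-axis voxel size, preserved in the header.
#' @return `path` invisibly.
#' @export
export_nifti <- function(vol, path, spacing = c(1, 1, 1)) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stopf("NIfTI export requires the RNifti package")
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

# Watertight voxel-face surface mesh of a binary volume: two triangles per
# boundary face, outward-oriented.
mesh_from_volume <- function(vol) {
  if (sum(vol) == 0) stopf("empty volume has no surface")
  d <- dim(vol)
  verts <- list(); tris <- list()
  vid <- new.env(parent = emptyenv())
  get_v <- function(y, x, z) {
    key <- paste(y, x, z, sep = ",")
    id <- vid[[key]]
    if (is.null(id)) {
      verts[[length(verts) + 1L]] <<- c(y, x, z)
      id <- length(verts)
      vid[[key]] <- id
    }
    id
  }
  at <- function(y, x, z) {
    if (y < 1 || y > d[1] || x < 1 || x > d[2] || z < 1 || z > d[3]) 0
    else vol[y, x, z]
  }
  fg <- which(vol != 0, arr.ind = TRUE)
  for (r in seq_len(nrow(fg))) {
    y <- fg[r, 1]; x <- fg[r, 2]; z <- fg[r, 3]
    faces <- list(
      list(dir = c(-1, 0, 0), corners = list(c(y - 1, x - 1, z - 1), c(y - 1, x, z - 1), c(y - 1, x, z), c(y - 1, x - 1, z))),
      list(dir = c(1, 0, 0), corners = list(c(y, x - 1, z - 1), c(y, x - 1, z), c(y, x, z), c(y, x, z - 1))),
      list(dir = c(0, -1, 0), corners = list(c(y - 1, x - 1, z - 1), c(y - 1, x - 1, z), c(y, x - 1, z), c(y, x - 1, z - 1))),
      list(dir = c(0, 1, 0), corners = list(c(y - 1, x, z - 1), c(y, x, z - 1), c(y, x, z), c(y - 1, x, z))),
      list(dir = c(0, 0, -1), corners = list(c(y - 1, x - 1, z - 1), c(y, x - 1, z - 1), c(y, x, z - 1), c(y - 1, x, z - 1))),
      list(dir = c(0, 0, 1), corners = list(c(y - 1, x - 1, z), c(y - 1, x, z), c(y, x, z), c(y, x - 1, z))))
    for (f in faces) {
      if (at(y + f$dir[1], x + f$dir[2], z + f$dir[3]) == 0) {
        ids <- vapply(f$corners, function(cn) get_v(cn[1], cn[2], cn[3]),
                      integer(1))
        tris[[length(tris) + 1L]] <- ids[c(1, 2, 3)]
        tris[[length(tris) + 1L]] <- ids[c(1, 3, 4)]
      }
    }
  }
  list(vertices = do.call(rbind, verts), triangles = do.call(rbind, tris))
}

#' Export a binary volume as an STL or OBJ surface mesh
#'
#' Writes the watertight voxel-face surface of the foreground as ASCII STL or
#' Wavefront OBJ.
#'
#' @param vol Binary 3-D array with non-empty foreground.
#' @param path Output path.
#' @param format `"stl"` or `"obj"` (default from the file extension).
#' @return `path` invisibly.
#' @export
export_mesh <- function(vol, path, format = tools::file_ext(path)) {
  mesh <- mesh_from_volume(vol)
  format <- tolower(format)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "stl") {
    writeLines("solid lungrecon", con)
    for (r in seq_len(nrow(mesh$triangles))) {
      v <- mesh$vertices[mesh$triangles[r, ], , drop = FALSE]
      nrm <- pracma_cross(v[2, ] - v[1, ], v[3, ] - v[1, ])
      nn <- sqrt(sum(nrm^2)); if (nn > 0) nrm <- nrm / nn
      writeLines(c(sprintf("facet normal %g %g %g", nrm[1], nrm[2], nrm[3]),
                   "  outer loop",
                   sprintf("    vertex %g %g %g", v[, 1], v[, 2], v[, 3]),
                   "  endloop", "endfacet"), con)
    }
    writeLines("endsolid lungrecon", con)
  } else if (format == "obj") {
    writeLines(sprintf("v %g %g %g", mesh$vertices[, 1], mesh$vertices[, 2],
                       mesh$vertices[, 3]), con)
    writeLines(sprintf("f %d %d %d", mesh$triangles[, 1],
                       mesh$triangles[, 2], mesh$triangles[, 3]), con)
  } else stopf("unknown mesh format '%s'", format)
  invisible(path)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Save and load trained models
#'
#' Models serialize with their config snapshot and seed.
#'
#' @param model A `seg_model`, `det_model` or `recon_model`.
#' @param path Output path (`.rds`).
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)

#' Write a machine-readable run manifest
#'
#' Records the configuration hash, global seed and package version for a
#' pipeline run.
#'
#' @param dir Output directory.
#' @param config Any configuration list.
#' @param seed Global seed.
#' @return The manifest path, invisibly.
#' @export
write_run_manifest <- function(dir, config, seed) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  manifest <- list(
    config_hash = sum(utf8ToInt(as.character(cfg_json))),
    seed = seed,
    package_version = as.character(utils::packageVersion("lungrecon")),
    timestamp = format(Sys.time(), tz = "UTC"))
  path <- file.path(dir, "run_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
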