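#' Configuration for the synthetic thorax phantom generator
#'
#' The phantom emulates the statistical structure of annotated thoracic CT at
#' desk scale: per-case ordered 2-D slices, two mirrored elliptical lung fields
#' with per-slice radius modulation, minority-class tumor voxels rasterized as
#' spheres, ellipsoids or lobulated blobs, and a voxel-aligned 3-D tumor ground
#' truth obtained by stacking the per-slice tumor masks.
#'
#' Intensities are arbitrary units: background 0, lung parenchyma -1, tumor
#' -1 + `tumor_contrast`, plus additive Gaussian noise. Grids are stored as
#' `H x W x n_slices` arrays; coordinates are 0-based; boxes are half-open
#' `[x0, x1) x [y0, y1)`.
#'
#' @param image_size Pixels per side (>= 16).
#' @param n_slices Slices per case (>= 4).
#' @param lung_fraction_target Fraction of image pixels inside lungs (0, 0.5].
#' @param tumor_radius_range Numeric length-2, min/max tumor radius in voxels;
#'   min >= 1 and max <= `image_size / 4`.
#' @param tumor_shape One of `"sphere"`, `"ellipsoid"`, `"lobulated"`.
#' @param tumor_contrast Intensity delta between tumor and lung parenchyma.
#' @param noise_sd Additive Gaussian noise scale.
#' @param tumors_per_case Integer >= 0.
#' @param seed Integer seed; identical config + seed yields identical cases.
#' @return An object of class `phantom_config`.
#' @export
#' @examples
#' cfg <- phantom_config(image_size = 32, n_slices = 8, tumors_per_case = 1)
#' case <- generate_case(cfg)
#' imbalance_report(case$lung_mask)
phantom_config <- function(image_size = 64L, n_slices = 16L,
                           lung_fraction_target = 0.12,
                           tumor_radius_range = c(3, 6),
                           tumor_shape = c("sphere", "ellipsoid", "lobulated"),
                           tumor_contrast = 0.8, noise_sd = 0.05,
                           tumors_per_case = 1L, seed = 1L) {
  tumor_shape <- match.arg(tumor_shape)
  check_number(image_size, "image_size", lower = 16)
  check_number(n_slices, "n_slices", lower = 4)
  check_number(lung_fraction_target, "lung_fraction_target",
               lower = 0, upper = 0.5, strict_lower = TRUE)
  if (length(tumor_radius_range) != 2L || tumor_radius_range[1] < 1 ||
      tumor_radius_range[2] < tumor_radius_range[1] ||
      tumor_radius_range[2] > image_size / 4)
    stopf("`tumor_radius_range` must be (min, max) with min >= 1 and max <= image_size/4")
  check_number(tumor_contrast, "tumor_contrast")
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(tumors_per_case, "tumors_per_case", lower = 0)
  check_number(seed, "seed")
  structure(list(
    image_size = as.integer(image_size), n_slices = as.integer(n_slices),
    lung_fraction_target = lung_fraction_target,
    tumor_radius_range = as.numeric(tumor_radius_range),
    tumor_shape = tumor_shape, tumor_contrast = tumor_contrast,
    noise_sd = noise_sd, tumors_per_case = as.integer(tumors_per_case),
    seed = as.integer(seed)), class = "phantom_config")
}

# Lung-field geometry shared by generation and feasibility checks. The two
# ellipse semi-axes solve 2*pi*a*b = lung_fraction_target * S^2 with a fixed
# aspect ratio, so the pixel-counted fraction tracks the target.
lung_geometry <- function(config) {
  S <- config$image_size
  aspect <- 1.9
  a <- sqrt(config$lung_fraction_target * S^2 / (2 * pi * aspect))
  b <- aspect * a
  list(a = a, b = b, cx = c(0.28, 0.72) * S, cy = 0.5 * S)
}

# Per-slice radius modulation, normalized so the mean slice area matches the
# in-plane ellipse area (mean of m^2 equals 1).
slice_modulation <- function(n_slices) {
  zc <- (n_slices + 1) / 2
  span <- 0.62 * n_slices
  m <- sqrt(pmax(0.25, 1 - ((seq_len(n_slices) - zc) / span)^2))
  m / sqrt(mean(m^2))
}

rasterize_lungs <- function(config) {
  S <- config$image_size
  g <- lung_geometry(config)
  m <- slice_modulation(config$n_slices)
  yy <- matrix(seq_len(S) - 0.5, S, S)          # pixel centers, y down rows
  xx <- t(yy)
  mask <- array(0L, c(S, S, config$n_slices))
  for (z in seq_len(config$n_slices)) {
    az <- g$a * m[z]; bz <- g$b * m[z]
    sl <- ((xx - g$cx[1])^2 / az^2 + (yy - g$cy)^2 / bz^2 <= 1) |
          ((xx - g$cx[2])^2 / az^2 + (yy - g$cy)^2 / bz^2 <= 1)
    mask[, , z] <- as.integer(sl)
  }
  mask
}

# Rasterize one tumor as an implicit surface on the voxel grid.
# Returns an H x W x Z binary array.
rasterize_tumor <- function(config, center, radius) {
  S <- config$image_size; nz <- config$n_slices
  vol <- array(0L, c(S, S, nz))
  r_ext <- radius * 1.4
  ys <- max(1, floor(center[1] - r_ext)):min(S, ceiling(center[1] + r_ext))
  xs <- max(1, floor(center[2] - r_ext)):min(S, ceiling(center[2] + r_ext))
  zs <- max(1, floor(center[3] - r_ext)):min(nz, ceiling(center[3] + r_ext))
  grid <- expand.grid(y = ys, x = xs, z = zs)
  dy <- grid$y - 0.5 - center[1]
  dx <- grid$x - 0.5 - center[2]
  dz <- grid$z - 0.5 - center[3]
  if (config$tumor_shape == "sphere") {
    inside <- dy^2 + dx^2 + dz^2 <= radius^2
  } else if (config$tumor_shape == "ellipsoid") {
    s <- runif(3, 0.7, 1.3)
    s <- s / prod(s)^(1 / 3)
    inside <- (dy / s[1])^2 + (dx / s[2])^2 + (dz / s[3])^2 <= radius^2
  } else {
    # sphere with a low-order angular-harmonic perturbation of the radius
    co <- runif(3, -0.18, 0.18)
    rr <- sqrt(dy^2 + dx^2 + dz^2)
    theta <- acos(ifelse(rr > 0, dz / pmax(rr, 1e-9), 1))
    phi <- atan2(dy, dx)
    rdir <- radius * (1 + co[1] * sin(2 * theta) * cos(phi) +
                        co[2] * sin(theta) * cos(2 * phi) +
                        co[3] * cos(2 * theta))
    inside <- rr <= rdir
  }
  idx <- cbind(grid$y, grid$x, grid$z)[inside, , drop = FALSE]
  vol[idx] <- 1L
  vol
}

# Tight half-open 0-based boxes around connected tumor components of a slice.
slice_boxes <- function(mask2d) {
  if (!any(mask2d == 1)) return(list())
  lab <- label_components(mask2d)
  lapply(seq_len(max(lab)), function(l) {
    w <- which(lab == l, arr.ind = TRUE)
    list(x0 = min(w[, 2]) - 1L, y0 = min(w[, 1]) - 1L,
         x1 = max(w[, 2]), y1 = max(w[, 1]))
  })
}

# 4-connected 2-D component labeling (EBImage when available, else a small
# BFS fallback so the core generator has no hard Bioconductor dependency).
label_components <- function(mask2d) {
  if (requireNamespace("EBImage", quietly = TRUE)) {
    lab <- EBImage::bwlabel(mask2d)
    return(matrix(as.integer(lab), nrow(mask2d), ncol(mask2d)))
  }
  H <- nrow(mask2d); W <- ncol(mask2d)
  lab <- matrix(0L, H, W)
  cur <- 0L
  for (start in which(mask2d == 1 & lab == 0L)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[length(queue)]; queue <- queue[-length(queue)]
      i <- (p - 1L) %% H + 1L; j <- (p - 1L) %/% H + 1L
      for (nb in list(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))) {
        if (nb[1] >= 1L && nb[1] <= H && nb[2] >= 1L && nb[2] <= W) {
          q <- nb[1] + (nb[2] - 1L) * H
          if (mask2d[q] == 1 && lab[q] == 0L) { lab[q] <- cur; queue <- c(queue, q) }
        }
      }
    }
  }
  lab
}

#' Generate one synthetic phantom case
#'
#' @param config A [phantom_config()].
#' @return An object of class `phantom_case` with elements `slices`,
#'   `lung_mask`, `tumor_mask` (all `H x W x n_slices` arrays), `tumor_boxes`
#'   (per-slice list of boxes), `tumor_volume` (identical to the stacked
#'   tumor masks) and `meta`.
#' @export
generate_case <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  g <- lung_geometry(config)
  rmin <- config$tumor_radius_range[1]
  if (config$tumors_per_case > 0 && rmin > 0.8 * min(g$a, g$b))
    stopf("infeasible geometry: tumor radius %.1f exceeds lung extent (semi-axes %.1f x %.1f)",
          rmin, g$a, g$b)
  with_seed(config$seed, {
    lung <- rasterize_lungs(config)
    tumor <- array(0L, dim(lung))
    m <- slice_modulation(config$n_slices)
    if (config$tumors_per_case > 0) {
      for (t in seq_len(config$tumors_per_case)) {
        side <- sample(1:2, 1)
        zc <- runif(1, 0.35, 0.65) * config$n_slices
        mz <- m[max(1L, min(config$n_slices, round(zc)))]
        cy <- g$cy + runif(1, -0.45, 0.45) * g$b * mz
        cx <- g$cx[side] + runif(1, -0.45, 0.45) * g$a * mz
        r <- runif(1, config$tumor_radius_range[1], config$tumor_radius_range[2])
        tumor <- pmax(tumor, rasterize_tumor(config, c(cy, cx, zc), r))
      }
      tumor <- tumor * lung                      # containment: tumor within lungs
    }
    intensity <- -1 * lung + config$tumor_contrast * tumor
    if (config$noise_sd > 0)
      intensity <- intensity + array(rnorm(length(intensity), 0, config$noise_sd),
                                     dim(intensity))
    boxes <- lapply(seq_len(config$n_slices),
                    function(z) slice_boxes(tumor[, , z]))
    structure(list(
      slices = intensity, lung_mask = lung, tumor_mask = tumor,
      tumor_boxes = boxes, tumor_volume = tumor,
      meta = list(seed = config$seed, config = config)),
      class = "phantom_case")
  })
}

#' Generate a labelled phantom dataset with a 70/15/15 split
#'
#' Cases receive deterministic per-case seeds derived from `config$seed`, and
#' are assigned to train/validation/test splits in 70/15/15 proportion:
#' validation and test each get `floor(0.15 * n_cases)` cases and the training
#' split takes the remainder. Splitting is by case (patient analog), not by
#' slice, to avoid leakage.
#'
#' @param n_cases Number of cases (>= 3).
#' @param config A [phantom_config()]; its seed drives case seeds and the split.
#' @return An object of class `phantom_dataset`: list with `cases` (list of
#'   [generate_case()] results) and `split` (character vector,
#'   `"train"`/`"val"`/`"test"`).
#' @export
generate_dataset <- function(n_cases, config) {
  stopifnot(inherits(config, "phantom_config"))
  if (n_cases < 3) stopf("`n_cases` must be >= 3 to populate all splits")
  n_cases <- as.integer(n_cases)
  seeds <- derive_seeds(config$seed, n_cases + 1L)
  cases <- lapply(seq_len(n_cases), function(i) {
    ci <- config
    ci$seed <- seeds[i]
    generate_case(ci)
  })
  n_val <- max(1L, floor(0.15 * n_cases))
  n_test <- max(1L, floor(0.15 * n_cases))
  n_train <- n_cases - n_val - n_test
  perm <- with_seed(seeds[n_cases + 1L], sample.int(n_cases))
  split <- character(n_cases)
  split[perm[seq_len(n_train)]] <- "train"
  split[perm[n_train + seq_len(n_val)]] <- "val"
  split[perm[n_train + n_val + seq_len(n_test)]] <- "test"
  structure(list(cases = cases, split = split, config = config),
            class = "phantom_dataset")
}

#' Minority-class fraction of a binary mask
#'
#' @param mask Binary array (any shape).
#' @return Fraction of pixels equal to 1, in `[0, 1]`.
#' @export
imbalance_report <- function(mask) {
  if (length(mask) == 0) stopf("empty grid")
  if (!all(mask %in% c(0, 1))) stopf("mask must be binary")
  sum(mask == 1) / length(mask)
}
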