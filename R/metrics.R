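#' Intersection over union of two binary masks
#'
#' `|A ∩ B| / |A ∪ B|` over the non-zero pixels of each mask. If both masks
#' are empty the union is empty; by convention the function returns 1 (perfect
#' agreement of empties) with a warning, and 0 if exactly one mask is empty.
#'
#' @param a,b Binary arrays of identical shape.
#' @return A number in `[0, 1]`.
#' @export
iou <- function(a, b) {
  if (!identical(dim2(a), dim2(b))) stopf("mask shapes differ")
  ia <- a != 0; ib <- b != 0
  u <- sum(ia | ib)
  if (u == 0) {
    warnf("both masks empty; IoU = 1 by convention")
    return(1)
  }
  sum(ia & ib) / u
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Euclidean distance between two points
#'
#' @param p,q Numeric vectors of equal length.
#' @return Non-negative straight-line distance.
#' @export
euclidean <- function(p, q) {
  if (length(p) != length(q)) stopf("dimension mismatch")
  sqrt(sum((q - p)^2))
}

as_point_matrix <- function(x, name) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (nrow(x) == 0) stopf("`%s` must be a non-empty point set", name)
  x
}

# All pairwise squared distances between rows of a and rows of b.
cross_dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}

#' Directed Hausdorff distance
#'
#' `h(A, B) = max over a in A of min over b in B of ||a - b||`.
#'
#' @param a,b Point sets: matrices with one point per row (equal column
#'   counts), or single points as vectors.
#' @return Non-negative distance.
#' @export
directed_hd <- function(a, b) {
  a <- as_point_matrix(a, "a"); b <- as_point_matrix(b, "b")
  if (ncol(a) != ncol(b)) stopf("dimension mismatch")
  sqrt(max(apply(cross_dist2(a, b), 1, min)))
}

#' Hausdorff distance
#'
#' Symmetric worst-case nearest-neighbor distance:
#' `max(h(A, B), h(B, A))`.
#'
#' @inheritParams directed_hd
#' @return Non-negative distance; 0 iff the point sets are equal.
#' @export
hd <- function(a, b) max(directed_hd(a, b), directed_hd(b, a))

#' Surface voxels of a 3-D binary volume
#'
#' Foreground voxels with at least one six-connected background neighbor; the
#' grid boundary counts as background.
#'
#' @param vol 3-D binary array.
#' @param spacing Per-axis voxel size (length 1 or 3); coordinates are
#'   multiplied by it.
#' @return Matrix of 0-based voxel coordinates, one row per surface voxel,
#'   columns in array-index order.
#' @export
surface_points <- function(vol, spacing = 1) {
  if (length(dim(vol)) != 3) stopf("`vol` must be a 3-D array")
  if (!any(vol != 0)) stopf("empty foreground")
  d <- dim(vol)
  f <- vol != 0
  padded <- array(FALSE, d + 2)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- f
  core <- function(di, dj, dk)
    padded[2:(d[1] + 1) + di, 2:(d[2] + 1) + dj, 2:(d[3] + 1) + dk]
  has_bg <- !core(-1, 0, 0) | !core(1, 0, 0) | !core(0, -1, 0) |
            !core(0, 1, 0) | !core(0, 0, -1) | !core(0, 0, 1)
  pts <- which(f & has_bg, arr.ind = TRUE) - 1
  spacing <- rep(spacing, length.out = 3)
  sweep(pts, 2, spacing, "*")
}

#' Mean symmetric surface distance between two 3-D volumes
#'
#' The average of the mean nearest-neighbor distance from the predicted
#' surface to the ground-truth surface and the reverse. Used as the volume
#' "corresponding-point" alignment error; symmetric by construction.
#'
#' @param pred,gt 3-D binary arrays of the same shape, both with non-empty
#'   surfaces.
#' @param spacing Per-axis voxel size.
#' @return Non-negative distance; 0 when `pred == gt`.
#' @export
volume_ed <- function(pred, gt, spacing = 1) {
  if (!identical(dim(pred), dim(gt))) stopf("shape mismatch")
  sp <- surface_points(pred, spacing)
  sg <- surface_points(gt, spacing)
  d2 <- cross_dist2(sp, sg)
  (mean(sqrt(apply(d2, 1, min))) + mean(sqrt(apply(d2, 2, min)))) / 2
}

#' One-dimensional earth mover's distance between histograms
#'
#' Both histograms are normalized to unit mass; the result is the Wasserstein-1
#' transport cost `sum |CDF1 - CDF2| * binwidth`.
#'
#' @param h1,h2 Non-negative histograms with equal bin counts.
#' @param binwidth Width of each bin.
#' @return Non-negative cost; 0 iff the normalized histograms are equal.
#' @export
emd1d <- function(h1, h2, binwidth = 1) {
  if (length(h1) != length(h2)) stopf("histograms must have equal bin counts")
  if (any(h1 < 0) || any(h2 < 0)) stopf("histogram masses must be non-negative")
  s1 <- sum(h1); s2 <- sum(h2)
  if (s1 == 0 || s2 == 0) stopf("zero total mass")
  sum(abs(cumsum(h1 / s1) - cumsum(h2 / s2))) * binwidth
}
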