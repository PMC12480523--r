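test_that("iou matches hand counts and conventions", {
  a <- matrix(0, 4, 4); a[1:2, 1:2] <- 1
  b <- matrix(0, 4, 4); b[1:2, 2:3] <- 1
  expect_equal(iou(a, b), 2 / 6)           # 2x1 strip overlap of two 2x2 blocks
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, b), iou(b, a))
  d <- matrix(0, 4, 4); d[3:4, 3:4] <- 1
  expect_equal(iou(a, d), 0)
  expect_warning(v <- iou(matrix(0, 2, 2), matrix(0, 2, 2)), "empty")
  expect_equal(v, 1)
  expect_equal(iou(matrix(0, 2, 2), matrix(c(1, 0, 0, 0), 2, 2)), 0)
  expect_error(iou(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("euclidean distance is exact", {
  expect_equal(euclidean(c(1, 2), c(1, 2)), 0)
  expect_equal(euclidean(c(0, 0, 0), c(3, 4, 0)), 5)
  set.seed(1)
  for (k in 1:20) {
    p <- rnorm(3); q <- rnorm(3)
    ref <- sqrt((q[1] - p[1])^2 + (q[2] - p[2])^2 + (q[3] - p[3])^2)
    expect_lt(abs(euclidean(p, q) - ref), 1e-12)
  }
  expect_error(euclidean(c(1, 2), c(1, 2, 3)), "dimension")
})

test_that("hausdorff distances agree with the brute-force oracle", {
  expect_equal(hd(matrix(c(0, 0), 1), matrix(c(3, 4), 1)), 5)
  set.seed(7)
  for (k in 1:25) {
    a <- matrix(runif(2 * sample(2:50, 1), -5, 5), ncol = 2)
    b <- matrix(runif(2 * sample(2:50, 1), -5, 5), ncol = 2)
    expect_equal(directed_hd(a, b), bf_directed_hd(a, b))
    expect_equal(hd(a, b), max(bf_directed_hd(a, b), bf_directed_hd(b, a)))
  }
  a <- matrix(rnorm(20), ncol = 2)
  expect_equal(hd(a, a), 0)
  expect_error(directed_hd(a[0, , drop = FALSE], a), "non-empty")
})

test_that("hd satisfies the metric axioms on random point sets", {
  set.seed(11)
  for (k in 1:20) {
    a <- matrix(runif(10), ncol = 2)
    b <- matrix(runif(10), ncol = 2)
    cc <- matrix(runif(10), ncol = 2)
    expect_equal(hd(a, b), hd(b, a))
    expect_gte(hd(a, b), 0)
    expect_lte(hd(a, cc), hd(a, b) + hd(b, cc) + 1e-12)
  }
})

test_that("surface_points finds six-connected boundary voxels", {
  v <- array(0L, c(5, 5, 5)); v[3, 3, 3] <- 1L
  expect_equal(nrow(surface_points(v)), 1)
  expect_equal(as.numeric(surface_points(v)), c(2, 2, 2))   # 0-based
  cube <- array(0L, c(5, 5, 5)); cube[2:4, 2:4, 2:4] <- 1L
  expect_equal(nrow(surface_points(cube)), 26)              # all but center
  # grid boundary counts as background
  full <- array(1L, c(3, 3, 3))
  expect_equal(nrow(surface_points(full)), 26)
  expect_error(surface_points(array(0L, c(3, 3, 3))), "empty")
  # spacing scales coordinates
  sp <- surface_points(v, spacing = c(2, 1, 1))
  expect_equal(as.numeric(sp), c(4, 2, 2))
})

test_that("volume_ed matches the double-loop oracle and is symmetric", {
  s1 <- rand_sphere_volume(3.2, 12, c(6, 6, 6))
  s2 <- rand_sphere_volume(3.2, 12, c(7, 6, 6))
  expect_equal(volume_ed(s1, s1), 0)
  expect_equal(volume_ed(s1, s2), bf_volume_ed(s1, s2))
  expect_equal(volume_ed(s1, s2), volume_ed(s2, s1))
})

test_that("emd1d matches the sorted-atom transport oracle", {
  expect_equal(emd1d(c(1, 2, 3), c(1, 2, 3)), 0)
  h1 <- c(1, 0, 0, 0, 0); h2 <- c(0, 0, 0, 0, 1)
  expect_equal(emd1d(h1, h2), 4)         # one unit moved four bins
  set.seed(3)
  for (k in 1:30) {
    nb <- sample(2:10, 1)
    a <- as.numeric(rmultinom(1, 40, runif(nb)))
    b <- as.numeric(rmultinom(1, 40, runif(nb)))
    expect_lt(abs(emd1d(a, b) - bf_emd1d_atoms(a, b)), 1e-9)
  }
  expect_error(emd1d(c(0, 0), c(0, 0)), "zero total mass")
  expect_error(emd1d(c(1, 2), c(1, 2, 3)), "equal bin")
  expect_error(emd1d(c(-1, 2), c(1, 2)), "non-negative")
})
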