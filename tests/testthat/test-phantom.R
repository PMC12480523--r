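test_that("config invariants are enforced", {
  expect_error(phantom_config(image_size = 8), "image_size")
  expect_error(phantom_config(n_slices = 2), "n_slices")
  expect_error(phantom_config(lung_fraction_target = 0.7), "lung_fraction")
  expect_error(phantom_config(tumor_radius_range = c(0.5, 3)),
               "tumor_radius_range")
  expect_error(phantom_config(image_size = 32, tumor_radius_range = c(2, 20)),
               "tumor_radius_range")
})

test_that("generated cases satisfy the structural invariants", {
  cfg <- tiny_phantom_config(seed = 3L, tumors_per_case = 2L)
  case <- generate_case(cfg)
  expect_identical(dim(case$slices), dim(case$lung_mask))
  expect_identical(dim(case$tumor_mask), dim(case$lung_mask))
  # containment: every tumor pixel is a lung pixel
  expect_true(all(case$tumor_mask <= case$lung_mask))
  # stacking tumor mask slices reproduces the 3-D ground truth exactly
  expect_identical(case$tumor_mask, case$tumor_volume)
  # boxes tightly bound connected components, half-open convention
  for (z in seq_len(cfg$n_slices)) {
    for (b in case$tumor_boxes[[z]]) {
      sl <- case$tumor_mask[, , z]
      crop <- sl[(b$y0 + 1):b$y1, (b$x0 + 1):b$x1, drop = FALSE]
      expect_true(any(crop == 1))
      expect_true(any(crop[1, ] == 1) && any(crop[nrow(crop), ] == 1))
      expect_true(any(crop[, 1] == 1) && any(crop[, ncol(crop)] == 1))
    }
  }
})

test_that("no-tumor configuration yields empty annotations", {
  case <- generate_case(tiny_phantom_config(tumors_per_case = 0L))
  expect_true(all(case$tumor_mask == 0))
  expect_true(all(vapply(case$tumor_boxes, length, integer(1)) == 0))
})

test_that("identical seed and config give bit-identical cases", {
  cfg <- tiny_phantom_config(seed = 7L)
  expect_identical(generate_case(cfg), generate_case(cfg))
})

test_that("infeasible tumor geometry raises a configuration error", {
  cfg <- phantom_config(image_size = 64, lung_fraction_target = 0.02,
                        tumor_radius_range = c(6, 8))
  expect_error(generate_case(cfg), "infeasible geometry")
})

test_that("lung fraction is controllable to within 0.05", {
  cfg <- phantom_config(image_size = 64, n_slices = 6,
                        lung_fraction_target = 0.15, seed = 42)
  case <- generate_case(cfg)
  expect_lt(abs(imbalance_report(case$lung_mask) - 0.15), 0.05)
  # mean over many cases tracks the target
  fr <- vapply(1:50, function(s) {
    c2 <- phantom_config(image_size = 32, n_slices = 4,
                         lung_fraction_target = 0.12,
                         tumor_radius_range = c(2, 3), seed = s)
    imbalance_report(generate_case(c2)$lung_mask)
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.12), 0.05)
})

test_that("dataset splits follow the 70/15/15 rounding rule", {
  ds <- generate_dataset(20, tiny_phantom_config())
  expect_equal(sum(ds$split == "train"), 14)
  expect_equal(sum(ds$split == "val"), 3)
  expect_equal(sum(ds$split == "test"), 3)
  ds3 <- generate_dataset(3, tiny_phantom_config())
  expect_equal(sort(ds3$split), c("test", "train", "val"))
  expect_error(generate_dataset(2, tiny_phantom_config()), "n_cases")
  # same seed, same assignment
  ds2 <- generate_dataset(20, tiny_phantom_config())
  expect_identical(ds$split, ds2$split)
})

test_that("imbalance_report counts minority pixels", {
  expect_equal(imbalance_report(matrix(0, 8, 8)), 0)
  expect_equal(imbalance_report(matrix(1, 4, 4)), 1)
  m <- matrix(0, 8, 8); m[1:16] <- 1
  expect_equal(imbalance_report(m), 0.25)
  expect_error(imbalance_report(numeric(0)), "empty")
  expect_error(imbalance_report(matrix(0.5, 2, 2)), "binary")
})
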