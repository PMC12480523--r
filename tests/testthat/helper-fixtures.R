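# Shared small fixtures, built once per test run.

tiny_phantom_config <- function(seed = 11L, ...) {
  phantom_config(image_size = 32L, n_slices = 4L,
                 lung_fraction_target = 0.12,
                 tumor_radius_range = c(2, 3), noise_sd = 0.05,
                 tumor_contrast = 1.2, seed = seed, ...)
}

tiny_dataset <- local({
  ds <- NULL
  function() {
    if (is.null(ds)) ds <<- generate_dataset(8, tiny_phantom_config())
    ds
  }
})

cube_phantom_dataset <- local({
  ds <- NULL
  function(n = 10, seed = 21L) {
    if (is.null(ds))
      ds <<- generate_dataset(n, phantom_config(
        image_size = 16L, n_slices = 16L, lung_fraction_target = 0.4,
        tumor_radius_range = c(2, 2.5), noise_sd = 0.05,
        tumor_contrast = 1.2, tumor_shape = "sphere", seed = seed))
    ds
  }
})

tiny_recon_config <- function(seed = 5L, epochs = 2L) {
  recon_config(encoder_channels = 4L, tlstm_units = 8L, tlstm_layers = 1L,
               dropout = 0, gen_channels = 4L, epochs = epochs,
               volume_size = 16L, seed = seed)
}

# Numerical gradient of a scalar-valued function at selected indices.
num_grad <- function(fun, arr, idx = seq_along(arr), eps = 1e-6) {
  g <- numeric(length(idx))
  for (k in seq_along(idx)) {
    a1 <- arr; a1[idx[k]] <- a1[idx[k]] + eps
    a2 <- arr; a2[idx[k]] <- a2[idx[k]] - eps
    g[k] <- (fun(a1) - fun(a2)) / (2 * eps)
  }
  g
}

# Brute-force directed Hausdorff by explicit double loop.
bf_directed_hd <- function(a, b) {
  worst <- 0
  for (i in seq_len(nrow(a))) {
    best <- Inf
    for (j in seq_len(nrow(b)))
      best <- min(best, sqrt(sum((a[i, ] - b[j, ])^2)))
    worst <- max(worst, best)
  }
  worst
}

# Brute-force mean symmetric surface distance by explicit loops.
bf_volume_ed <- function(pred, gt) {
  sp <- surface_points(pred)
  sg <- surface_points(gt)
  m1 <- mean(vapply(seq_len(nrow(sp)), function(i)
    min(vapply(seq_len(nrow(sg)), function(j)
      sqrt(sum((sp[i, ] - sg[j, ])^2)), numeric(1))), numeric(1)))
  m2 <- mean(vapply(seq_len(nrow(sg)), function(j)
    min(vapply(seq_len(nrow(sp)), function(i)
      sqrt(sum((sp[i, ] - sg[j, ])^2)), numeric(1))), numeric(1)))
  (m1 + m2) / 2
}

# Optimal 1-D transport for integer-mass histograms by sorted atom matching
# (independent of the CDF identity used by the implementation).
bf_emd1d_atoms <- function(h1, h2, binwidth = 1) {
  scale <- sum(h1) / sum(h2)
  a <- rep(seq_along(h1), h1)
  b <- rep(seq_along(h2), round(h2 * scale))
  stopifnot(length(a) == length(b))
  sum(abs(sort(a) - sort(b))) * binwidth / length(a)
}

# Independent scalar peephole-LSTM step written in plain arithmetic.
oracle_lstm_step <- function(x, h, c, p) {
  H <- length(h)
  i <- f <- g <- o <- numeric(H)
  for (k in seq_len(H)) {
    ai <- sum(x * p$Wxi[, k]) + sum(h * p$Whi[, k]) + p$wci[k] * c[k] + p$bi[k]
    af <- sum(x * p$Wxf[, k]) + sum(h * p$Whf[, k]) + p$wcf[k] * c[k] + p$bf[k]
    ag <- sum(x * p$Wxc[, k]) + sum(h * p$Whc[, k]) + p$bc[k]
    i[k] <- 1 / (1 + exp(-ai))
    f[k] <- 1 / (1 + exp(-af))
    g[k] <- tanh(ag)
  }
  cn <- f * c + i * g
  for (k in seq_len(H)) {
    ao <- sum(x * p$Wxo[, k]) + sum(h * p$Who[, k]) + p$wco[k] * cn[k] + p$bo[k]
    o[k] <- 1 / (1 + exp(-ao))
  }
  list(h = o * tanh(cn), c = cn)
}

rand_sphere_volume <- function(r, dimlen = 12, center = rep(dimlen / 2, 3)) {
  v <- array(0L, rep(dimlen, 3))
  for (z in 1:dimlen) for (y in 1:dimlen) for (x in 1:dimlen)
    if ((y - center[1])^2 + (x - center[2])^2 + (z - center[3])^2 <= r^2)
      v[y, x, z] <- 1L
  v
}
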