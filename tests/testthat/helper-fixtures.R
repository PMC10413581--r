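# Shared fixtures: tiny network configs and independent oracles.

tiny_net <- function(...) {
  seg_model_config(levels = 3, base_channels = 2, attention_kernel = 3, ...)
}

tiny_train <- function(steps = 5, seed = 1, ...) {
  seg_train_config(patch_size = 8, steps = steps, seed = seed,
                   model = tiny_net(), ...)
}

rand_volume <- function(dim = c(8, 8, 8), seed = 1, spacing = c(2, 2, 2)) {
  withr::with_seed(seed, image_volume(array(rnorm(prod(dim)), dim),
                                      spacing = spacing))
}

rand_mask <- function(dim = c(8, 8, 8), seed = 1, p = 0.2,
                      spacing = c(2, 2, 2)) {
  withr::with_seed(seed, label_mask(array(rbinom(prod(dim), 1, p), dim),
                                    spacing = spacing))
}

# Brute-force 3D convolution: triple loop over output voxels and kernel
# offsets, independent of the package's C++ path.
brute_conv3d <- function(arr, kern, stride = 1, pad = (dim(kern)[1] - 1) / 2) {
  d <- dim(arr); k <- dim(kern)[1]
  dp <- array(0, d + 2 * pad)
  dp[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <- arr
  od <- (d + 2 * pad - k) %/% stride + 1
  out <- array(0, od)
  for (i in seq_len(od[1])) for (j in seq_len(od[2])) for (l in seq_len(od[3])) {
    i0 <- (i - 1) * stride; j0 <- (j - 1) * stride; l0 <- (l - 1) * stride
    out[i, j, l] <- sum(dp[i0 + seq_len(k), j0 + seq_len(k), l0 + seq_len(k)] * kern)
  }
  out
}

# Independent trilinear resize (cell-centre aligned), scalar loop version.
brute_trilinear <- function(arr, osd) {
  sd <- dim(arr)
  out <- array(0, osd)
  for (a3 in seq_len(osd[3])) for (a2 in seq_len(osd[2])) for (a1 in seq_len(osd[1])) {
    u <- (c(a1, a2, a3) - 0.5) / (osd / sd) - 0.5
    i0 <- floor(u); fr <- u - i0
    acc <- 0
    for (b1 in 0:1) for (b2 in 0:1) for (b3 in 0:1) {
      idx <- pmin(pmax(i0 + c(b1, b2, b3), 0), sd - 1) + 1
      wgt <- prod(ifelse(c(b1, b2, b3) == 1, fr, 1 - fr))
      acc <- acc + wgt * arr[idx[1], idx[2], idx[3]]
    }
    out[a1, a2, a3] <- acc
  }
  out
}

# Set every trainable parameter to zero except batch-norm scale (1).
zero_params <- function(P) {
  for (nm in names(P)) {
    v <- P[[nm]]$value
    P[[nm]]$value <- if (grepl("\\.g$", nm)) v * 0 + 1 else v * 0
  }
  P
}
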