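test_that("decoder output shapes and attention ranges hold", {
  cfg <- seg_model_config(levels = 4, base_channels = 8)
  P <- withr::with_seed(6, wmhseg:::init_wmh_params(cfg))
  arr <- withr::with_seed(7, array(rnorm(32^3), c(32, 32, 32)))
  fw <- wmhseg:::wmh_forward(P, cfg, arr)
  expect_equal(fw$final$sdim, c(32L, 32L, 32L))
  expect_equal(ncol(fw$final$value), 1L)
  # three supervision heads (levels 3, 2, 1), all lifted to the label grid
  expect_length(fw$heads, 3L)
  for (h in fw$heads) expect_equal(h$sdim, c(32L, 32L, 32L))
  # attention maps strictly inside (0, 1) at every level
  for (a in fw$atts) {
    expect_gt(min(a$I_s), 0)
    expect_lt(max(a$I_s), 1)
  }
})

test_that("attention states satisfy their defining algebra", {
  cfg <- tiny_net()
  P <- withr::with_seed(8, wmhseg:::init_wmh_params(cfg))
  arr <- withr::with_seed(9, array(rnorm(8^3), c(8, 8, 8)))
  fw <- wmhseg:::wmh_forward(P, cfg, arr)
  for (a in fw$atts) {
    # Z = Relu(I + proj(I_c)) voxelwise, hence nonnegative
    expect_equal(a$Z, pmax(a$I + a$I_c, 0), tolerance = 1e-12)
    expect_true(all(a$Z >= 0))
    expect_equal(dim(a$I), dim(a$I_c))
  }
})

test_that("element-wise attention multiplication follows the limits and a loop oracle", {
  feat <- withr::with_seed(10, matrix(rnorm(27 * 4), 27, 4))
  tape <- wmhseg:::new_tape()
  fx <- wmhseg:::td_input(feat, c(3L, 3L, 3L))
  ones <- wmhseg:::td_input(matrix(1, 27, 1), c(3L, 3L, 3L))
  zero <- wmhseg:::td_input(matrix(0, 27, 1), c(3L, 3L, 3L))
  expect_equal(wmhseg:::op_mul_map(tape, fx, ones)$value, feat)
  expect_true(all(wmhseg:::op_mul_map(tape, fx, zero)$value == 0))
  map <- withr::with_seed(11, matrix(runif(27), 27, 1))
  got <- wmhseg:::op_mul_map(tape, fx, wmhseg:::td_input(map, c(3L, 3L, 3L)))$value
  want <- feat * 0
  for (v in 1:27) for (c in 1:4) want[v, c] <- feat[v, c] * map[v, 1]
  expect_equal(got, want, tolerance = 1e-15)
})

test_that("spatial attention map is sigmoid(conv(mean ; max)) by direct formula", {
  # 2x2x2 single-channel features, 1^3 attention kernel set by hand
  feat <- withr::with_seed(12, matrix(rnorm(8), 8, 1))
  tape <- wmhseg:::new_tape()
  x <- wmhseg:::td_input(feat, c(2L, 2L, 2L))
  mm <- wmhseg:::op_chan_meanmax(tape, x)
  # single channel: mean and max both equal the channel itself
  expect_equal(mm$value[, 1], feat[, 1])
  expect_equal(mm$value[, 2], feat[, 1])
  w <- wmhseg:::td_param(matrix(c(0.7, -0.2), 2, 1))
  b <- wmhseg:::td_param(0.1)
  al <- wmhseg:::op_conv3d(tape, mm, w, b, k = 1, stride = 1, pad = 0)
  Is <- wmhseg:::op_sigmoid(tape, al)
  expect_equal(as.vector(Is$value),
               1 / (1 + exp(-(0.7 * feat[, 1] - 0.2 * feat[, 1] + 0.1))))
  # zero-initialized attention conv gives I_s = 0.5 everywhere
  w0 <- wmhseg:::td_param(matrix(0, 2, 1)); b0 <- wmhseg:::td_param(0)
  Is0 <- wmhseg:::op_sigmoid(
    tape, wmhseg:::op_conv3d(tape, mm, w0, b0, k = 1, stride = 1, pad = 0))
  expect_true(all(Is0$value == 0.5))
})

test_that("supervision heads with zero weights emit zero logits", {
  cfg <- tiny_net()
  P <- withr::with_seed(13, wmhseg:::init_wmh_params(cfg))
  for (l in 1:2) {
    P[[sprintf("head%d.w", l)]]$value[] <- 0
    P[[sprintf("head%d.b", l)]]$value[] <- 0
  }
  arr <- withr::with_seed(14, array(rnorm(8^3), c(8, 8, 8)))
  fw <- wmhseg:::wmh_forward(P, cfg, arr)
  for (h in fw$heads) {
    expect_true(all(h$value == 0))
    expect_true(all(1 / (1 + exp(-h$value)) == 0.5))
  }
})

test_that("attention ablation freezes I_s at exactly 1 and reduces to a plain skip decoder", {
  cfg_on <- tiny_net()
  cfg_off <- tiny_net(attention = FALSE)
  P <- withr::with_seed(15, wmhseg:::init_wmh_params(cfg_on))
  arr <- withr::with_seed(16, array(rnorm(8^3), c(8, 8, 8)))
  fw_off <- wmhseg:::wmh_forward(P, cfg_off, arr)
  for (a in fw_off$atts) {
    expect_true(all(a$I_s == 1))
    # with the gate wide open the fused volume is Relu(u + proj(skip))
    expect_equal(a$Z, pmax(a$I + a$I_c, 0), tolerance = 1e-12)
  }
  # and the ablated forward differs from the attention forward
  fw_on <- wmhseg:::wmh_forward(P, cfg_on, arr)
  expect_false(isTRUE(all.equal(fw_on$final$value, fw_off$final$value)))
})
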