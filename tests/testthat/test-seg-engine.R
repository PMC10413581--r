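test_that("composite loss has its closed forms", {
  # 2^3 target with 4 foreground voxels, logits all zero:
  # soft-Dice loss = 1 - (2*0.5*4 + eps)/(0.5*8 + 4 + eps) ~ 0.5, BCE = ln 2
  tgt <- array(c(1, 1, 1, 1, 0, 0, 0, 0), c(2, 2, 2))
  z0 <- array(0, c(2, 2, 2))
  expect_equal(composite_loss(z0, list(), tgt, w_dice = 1, w_ce = 0), 0.5,
               tolerance = 1e-5)
  expect_equal(composite_loss(z0, list(), tgt, w_dice = 0, w_ce = 1), log(2),
               tolerance = 1e-12)
  # perfect prediction in the saturated-logit limit
  zp <- ifelse(tgt == 1, 20, -20)
  expect_lt(composite_loss(zp, list(), tgt), 1e-6)
  # lambda = 0 reduces to the final head alone
  expect_equal(
    composite_loss(z0, list(zp, zp), tgt, lambda = c(0, 0)),
    composite_loss(z0, list(), tgt))
  # auxiliary heads contribute with their weights
  expect_equal(
    composite_loss(zp, list(z0), tgt, lambda = 0.5),
    0.5 * composite_loss(z0, list(), tgt),
    tolerance = 1e-5)
  expect_error(composite_loss(array(0, c(2, 2, 4)), list(), tgt),
               class = "wmh_shape_error")
})

test_that("training is deterministic under the seed and lr 0 freezes parameters", {
  pair <- list(image = rand_volume(c(8, 8, 8), seed = 20),
               mask = rand_mask(c(8, 8, 8), seed = 21, p = 0.3))
  m1 <- train_segmenter(list(pair), tiny_train(steps = 10, seed = 5))
  m2 <- train_segmenter(list(pair), tiny_train(steps = 10, seed = 5))
  expect_identical(m1$trace, m2$trace)
  p1 <- sliding_window_predict(m1, pair$image)
  p2 <- sliding_window_predict(m2, pair$image)
  expect_identical(p1$data, p2$data)

  m0 <- train_segmenter(list(pair), tiny_train(steps = 5, seed = 5, lr = 0))
  init <- withr::with_seed(5, wmhseg:::init_wmh_params(tiny_net()))
  for (nm in names(init))
    expect_identical(m0$params[[nm]]$value, init[[nm]]$value)
  expect_equal(diff(range(m0$trace)), 0)
})

test_that("deep supervision sends gradient into every head", {
  pair <- list(image = rand_volume(c(8, 8, 8), seed = 22),
               mask = rand_mask(c(8, 8, 8), seed = 23, p = 0.3))
  m <- train_segmenter(list(pair), tiny_train(steps = 1))
  init <- withr::with_seed(1, wmhseg:::init_wmh_params(tiny_net()))
  for (l in 1:2) {
    nm <- sprintf("head%d.w", l)
    expect_false(isTRUE(all.equal(m$params[[nm]]$value, init[[nm]]$value)))
  }
})

test_that("model checkpoints reload to bit-identical inference", {
  pair <- list(image = rand_volume(c(8, 8, 8), seed = 24),
               mask = rand_mask(c(8, 8, 8), seed = 25, p = 0.3))
  m <- train_segmenter(list(pair), tiny_train(steps = 3))
  path <- withr::local_tempfile(fileext = ".rds")
  write_model(m, path)
  m2 <- read_model(path)
  expect_identical(sliding_window_predict(m, pair$image)$data,
                   sliding_window_predict(m2, pair$image)$data)
  expect_identical(m2$trace, m$trace)
  gl <- glance(m)
  expect_equal(gl$steps, 3)
  expect_equal(nrow(tidy(m)), 3)
})

test_that("sliding-window fusion matches an explicit accumulation oracle", {
  cfg <- tiny_train(steps = 1, seed = 30)
  pair <- list(image = rand_volume(c(8, 8, 8), seed = 31),
               mask = rand_mask(c(8, 8, 8), seed = 32, p = 0.3))
  model <- train_segmenter(list(pair), cfg)
  vol <- rand_volume(c(12, 12, 12), seed = 33)
  got <- sliding_window_predict(model, vol)
  # oracle: enumerate covering windows and average with the same Gaussian
  arr <- zscore_normalize(vol)$data
  p <- 8L
  offs <- c(0L, 4L)
  w3 <- wmhseg:::gaussian_window(p)
  acc <- array(0, dim(arr)); den <- array(0, dim(arr))
  for (ow in offs) for (oh in offs) for (od in offs) {
    id <- od + 1:p; ih <- oh + 1:p; iw <- ow + 1:p
    pr <- wmhseg:::predict_patch(model, arr[id, ih, iw])
    acc[id, ih, iw] <- acc[id, ih, iw] + pr * w3
    den[id, ih, iw] <- den[id, ih, iw] + w3
  }
  expect_equal(got$data, acc / den, tolerance = 1e-12)
  expect_true(all(got$data >= 0 & got$data <= 1))
  # a window exactly the volume size is a plain forward pass
  direct <- wmhseg:::predict_patch(model, zscore_normalize(pair$image)$data)
  expect_equal(sliding_window_predict(model, pair$image)$data,
               array(direct, c(8, 8, 8)), tolerance = 1e-12)
  expect_error(sliding_window_predict(model, rand_volume(c(4, 4, 4))),
               class = "wmh_shape_error")
})

test_that("binarization follows the >= tie rule and counting oracle", {
  prob <- image_volume(array(0.5, c(3, 3, 3)))
  expect_true(all(binarize(prob, 0.5)$data == 1))
  expect_true(all(binarize(prob, 0)$data == 1))
  expect_error(binarize(prob, 1.5), class = "wmh_config_error")
  expect_error(binarize(prob, -0.1), class = "wmh_config_error")
  pr <- withr::with_seed(34, image_volume(array(runif(6^3), c(6, 6, 6))))
  msk <- binarize(pr, 0.5)
  expect_equal(sum(msk$data), sum(pr$data >= 0.5))
  expect_error(binarize(image_volume(array(1.2, c(2, 2, 2)))),
               class = "wmh_validation_error")
})
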