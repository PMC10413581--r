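#' Training configuration for the segmentation network
#'
#' @param patch_size cubic training patch edge in voxels; must be divisible
#'   by `2^(levels-1)` of the network config.
#' @param batch_size patches whose gradients are averaged per optimizer step.
#' @param steps number of optimizer steps.
#' @param lr Adam learning rate (default 2e-3; chosen so the capacity check below converges at desk scale).
#' @param optimizer only `"adam"` is provided.
#' @param w_dice,w_ce weights of the soft-Dice and cross-entropy terms on the
#'   final head; auxiliary heads use unit internal weights scaled by the
#'   deep-supervision weights of the network config.
#' @param seed RNG seed covering initialization and patch sampling.
#' @param model a [seg_model_config()].
#' @return list of class `wmh_train_config`.
#' @export
seg_train_config <- function(patch_size = 32, batch_size = 1, steps = 500,
                             lr = 2e-3, optimizer = "adam",
                             w_dice = 1, w_ce = 1, seed = 7,
                             model = seg_model_config()) {
  if (w_dice < 0 || w_ce < 0 || w_dice + w_ce <= 0)
    stop_wmh("loss weights must be >= 0 with w_dice + w_ce > 0",
             class = "wmh_config_error")
  if (!identical(optimizer, "adam"))
    stop_wmh("unknown optimizer: ", optimizer, class = "wmh_config_error")
  div <- 2L^(model$levels - 1L)
  if (patch_size %% div != 0)
    stop_wmh("patch_size must be divisible by ", div,
             class = "wmh_config_error")
  structure(list(patch_size = as.integer(patch_size),
                 batch_size = as.integer(batch_size),
                 steps = as.integer(steps), lr = lr, optimizer = optimizer,
                 w_dice = w_dice, w_ce = w_ce, seed = as.integer(seed),
                 model = model),
            class = "wmh_train_config")
}

#' Soft-Dice score
#'
#' `(2*sum(p*t) + eps) / (sum(p) + sum(t) + eps)` between a probability (or
#' binary) map and a binary target; 1 is perfect overlap.
#'
#' @param p predicted probabilities (`wmh_volume` or array).
#' @param t binary target (`wmh_mask` or array).
#' @param eps smoothing constant.
#' @return scalar in \[0, 1\].
#' @export
soft_dice <- function(p, t, eps = 1e-5) {
  pv <- if (inherits(p, "wmh_volume")) p$data else p
  tv <- if (inherits(t, "wmh_volume")) t$data else t
  (2 * sum(pv * tv) + eps) / (sum(pv) + sum(tv) + eps)
}

#' Attention-weighted deeply-supervised segmentation loss
#'
#' `w_dice * softDice + w_ce * BCE` on the final logits plus
#' `sum(lambda_d * (softDice + BCE))` over the auxiliary decoder heads, all
#' against the same full-resolution binary target.
#'
#' @param final_logits 3D array (or vector) of logits at the label grid.
#' @param head_logits list of full-resolution auxiliary logit arrays (may be
#'   empty).
#' @param target binary mask (`wmh_mask` or array) matching the logits grid.
#' @param w_dice,w_ce weights of the final-head loss terms.
#' @param lambda nonnegative weight per auxiliary head.
#' @param eps soft-Dice smoothing.
#' @return scalar loss.
#' @export
composite_loss <- function(final_logits, head_logits = list(), target,
                           w_dice = 1, w_ce = 1,
                           lambda = 0.5^seq_along(head_logits), eps = 1e-5) {
  tv <- as.vector(if (inherits(target, "wmh_volume")) target$data else target)
  one <- function(z, wd, wc) {
    zv <- as.vector(if (inherits(z, "wmh_volume")) z$data else z)
    if (length(zv) != length(tv))
      stop_wmh("logit/target shape mismatch", class = "wmh_shape_error")
    p <- 1 / (1 + exp(-zv))
    dice <- 1 - (2 * sum(p * tv) + eps) / (sum(p) + sum(tv) + eps)
    bce <- mean(pmax(zv, 0) - zv * tv + log1p(exp(-abs(zv))))
    wd * dice + wc * bce
  }
  total <- one(final_logits, w_dice, w_ce)
  for (i in seq_along(head_logits))
    total <- total + lambda[i] * one(head_logits[[i]], 1, 1)
  total
}

adam_step <- function(params, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (p in params) {
    if (is.null(p$grad)) next
    g <- p$grad
    if (is.null(p$m)) { p$m <- g * 0; p$v <- g * 0 }
    p$m <- beta1 * p$m + (1 - beta1) * g
    p$v <- beta2 * p$v + (1 - beta2) * g^2
    mhat <- p$m / (1 - beta1^t)
    vhat <- p$v / (1 - beta2^t)
    p$value <- p$value - lr * mhat / (sqrt(vhat) + eps)
  }
  invisible()
}

sample_patch <- function(img_arr, mask_arr, p) {
  d <- dim(img_arr)
  if (any(d < p))
    stop_wmh("volume (", paste(d, collapse = "x"),
             ") smaller than patch size ", p, class = "wmh_shape_error")
  o <- vapply(d, function(n) if (n == p) 0L else sample.int(n - p + 1L, 1L) - 1L,
              integer(1))
  id <- o[1] + seq_len(p); ih <- o[2] + seq_len(p); iw <- o[3] + seq_len(p)
  list(x = img_arr[id, ih, iw], t = mask_arr[id, ih, iw])
}

step_loss_and_grads <- function(P, cfg, xarr, tarr, tc) {
  fw <- wmh_forward(P, cfg, xarr)
  tape <- fw$tape
  tv <- as.vector(tarr)
  nodes <- list(op_dice_bce(tape, fw$final, tv, tc$w_dice, tc$w_ce))
  wts <- 1
  lam <- cfg$deep_supervision_weights
  hl <- fw$heads
  for (i in seq_along(hl)) {
    nodes[[length(nodes) + 1L]] <- op_dice_bce(tape, hl[[i]], tv, 1, 1)
    # heads are ordered deepest-first; lam is ordered from the output up
    lev <- as.integer(sub("level", "", names(hl)[i]))
    wts <- c(wts, lam[lev])
  }
  total <- op_weighted_sum(tape, nodes, wts)
  td_backward(tape, total)
  total$value
}

#' Train the segmentation network
#'
#' Deterministic CPU training: seeded He initialization, seeded patch
#' sampling, Adam updates. Images are z-score normalized per volume before
#' patch extraction.
#'
#' @param pairs list of `list(image = wmh_volume, mask = wmh_mask)` pairs.
#' @param config a [seg_train_config()].
#' @return a `wmh_model`: parameters, config, and the per-step loss trace.
#' @export
train_segmenter <- function(pairs, config = seg_train_config()) {
  if (length(pairs) == 0)
    stop_wmh("need at least one (image, mask) pair", class = "wmh_config_error")
  for (pr in pairs) {
    if (!inherits(pr$image, "wmh_volume") || !inherits(pr$mask, "wmh_mask"))
      stop_wmh("each pair needs $image (wmh_volume) and $mask (wmh_mask)",
               class = "wmh_config_error")
    if (!all(dim(pr$image$data) == dim(pr$mask$data)))
      stop_wmh("image/mask shape mismatch", class = "wmh_shape_error")
  }
  cfg <- config$model
  set.seed(config$seed)
  P <- init_wmh_params(cfg)
  imgs <- lapply(pairs, function(pr) zscore_normalize(pr$image)$data)
  msks <- lapply(pairs, function(pr) pr$mask$data)
  trace <- numeric(config$steps)
  for (s in seq_len(config$steps)) {
    td_zero_grads(P)
    bl <- 0
    for (b in seq_len(config$batch_size)) {
      i <- sample.int(length(pairs), 1L)
      pt <- sample_patch(imgs[[i]], msks[[i]], config$patch_size)
      bl <- bl + step_loss_and_grads(P, cfg, array(pt$x, rep(config$patch_size, 3)),
                                     pt$t, config)
    }
    if (config$batch_size > 1)
      for (p in P) if (!is.null(p$grad)) p$grad <- p$grad / config$batch_size
    adam_step(P, config$lr, s)
    trace[s] <- bl / config$batch_size
  }
  structure(list(params = P, config = config, trace = trace),
            class = "wmh_model")
}

#' @export
print.wmh_model <- function(x, ...) {
  np <- sum(vapply(x$params, function(p) length(p$value), numeric(1)))
  cat(sprintf("<wmh_model> %d levels, %s parameters, %d steps, final loss %.4f\n",
              x$config$model$levels, format(np, big.mark = ","),
              length(x$trace), utils::tail(x$trace, 1)))
  invisible(x)
}

#' Predict a WMH probability map for one patch-sized array
#'
#' @param model a trained `wmh_model`.
#' @param arr normalized 3D array with dims divisible by `2^(levels-1)`.
#' @return 3D array of probabilities in (0, 1).
#' @keywords internal
predict_patch <- function(model, arr) {
  fw <- wmh_forward(model$params, model$config$model, arr)
  array(1 / (1 + exp(-fw$final$value)), dim(arr))
}

gaussian_window <- function(p, sigma = p / 8) {
  g <- exp(-((seq_len(p) - (p + 1) / 2)^2) / (2 * sigma^2))
  outer(outer(g, g), g)
}

#' Sliding-window inference
#'
#' Tiles the volume with patches at stride `patch_size / 2`, runs the network
#' on each, and fuses per-voxel probabilities with Gaussian importance
#' weights (`sigma = patch_size / 8`) so window seams do not imprint on the
#' output.
#'
#' @param model a trained `wmh_model`.
#' @param vol a raw (unnormalized) `wmh_volume`; z-scoring is applied here.
#' @return a `wmh_volume` of probabilities on the same grid as `vol`.
#' @export
sliding_window_predict <- function(model, vol) {
  stopifnot(inherits(model, "wmh_model"), inherits(vol, "wmh_volume"))
  p <- model$config$patch_size
  d <- dim(vol$data)
  if (any(d < p))
    stop_wmh("volume (", paste(d, collapse = "x"),
             ") smaller than the training patch size ", p,
             class = "wmh_shape_error")
  arr <- zscore_normalize(vol)$data
  s <- max(p %/% 2L, 1L)
  axis_offsets <- function(n) {
    offs <- seq.int(0L, n - p, by = s)
    if (utils::tail(offs, 1) != n - p) offs <- c(offs, n - p)
    offs
  }
  offs <- lapply(d, axis_offsets)
  w3 <- gaussian_window(p)
  acc <- array(0, d); den <- array(0, d)
  for (ow in offs[[3]]) for (oh in offs[[2]]) for (od in offs[[1]]) {
    id <- od + seq_len(p); ih <- oh + seq_len(p); iw <- ow + seq_len(p)
    pr <- predict_patch(model, arr[id, ih, iw])
    acc[id, ih, iw] <- acc[id, ih, iw] + pr * w3
    den[id, ih, iw] <- den[id, ih, iw] + w3
  }
  image_volume(acc / den, spacing = vol$spacing, origin = vol$origin)
}

#' Threshold a probability map into a binary WMH mask
#'
#' Voxels with probability `>= threshold` become foreground (ties map to
#' foreground by convention).
#'
#' @param prob probability `wmh_volume` with values in \[0, 1\].
#' @param threshold scalar in \[0, 1\].
#' @return a `wmh_mask`.
#' @export
binarize <- function(prob, threshold = 0.5) {
  stopifnot(inherits(prob, "wmh_volume"))
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < 0 || threshold > 1)
    stop_wmh("threshold must be a single value in [0, 1]",
             class = "wmh_config_error")
  if (min(prob$data) < 0 || max(prob$data) > 1)
    stop_wmh("probability volume has values outside [0, 1]",
             class = "wmh_validation_error")
  label_mask((prob$data >= threshold) * 1, spacing = prob$spacing,
             origin = prob$origin)
}

#' Save / load a trained model
#'
#' The checkpoint stores the training config, every parameter value and the
#' loss trace; reloading reproduces inference bit-for-bit.
#'
#' @param model a `wmh_model`.
#' @param path checkpoint file path.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "wmh_model"))
  saveRDS(list(config = model$config,
               values = lapply(model$params, function(p) p$value),
               trace = model$trace), path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  ck <- readRDS(path)
  P <- lapply(ck$values, td_param)
  structure(list(params = P, config = ck$config, trace = ck$trace),
            class = "wmh_model")
}

#' @importFrom generics tidy
#' @export
tidy.wmh_model <- function(x, ...) {
  tibble::tibble(step = seq_along(x$trace), loss = x$trace)
}

#' @importFrom generics glance
#' @export
glance.wmh_model <- function(x, ...) {
  tibble::tibble(
    steps = length(x$trace),
    final_loss = utils::tail(x$trace, 1),
    n_parameters = sum(vapply(x$params, function(p) length(p$value), numeric(1))),
    patch_size = x$config$patch_size,
    seed = x$config$seed)
}
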