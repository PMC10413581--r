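# Minimal reverse-mode autodiff used by the segmentation network.
#
# Feature volumes travel as N x C matrices (N = D*H*W voxels, depth-fastest
# column-major order) with the spatial extent carried in `sdim`. Nodes are
# environments created in topological order on a tape; backward() walks the
# tape in reverse. Trainable parameters are tape-independent environments so
# one set of parameters can be reused across training steps.

new_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$ops <- list()
  tp$n <- 0L
  tp
}

# Trainable parameter: value + accumulated gradient + Adam state.
td_param <- function(value) {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- NULL
  p$is_param <- TRUE
  p
}

# Non-trainable input node.
td_input <- function(value, sdim) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$sdim <- sdim
  nd$grad <- NULL
  nd$is_param <- FALSE
  nd
}

# Register an op node. `bwd(node, g)` must return a list of gradients
# aligned with `parents` (NULL entries allowed for inputs that need none).
td_node <- function(tape, value, sdim, parents, bwd, cache = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$sdim <- sdim
  nd$grad <- NULL
  nd$parents <- parents
  nd$bwd <- bwd
  nd$cache <- cache
  nd$is_param <- FALSE
  tape$n <- tape$n + 1L
  tape$ops[[tape$n]] <- nd
  nd
}

td_accum <- function(target, g) {
  if (is.null(g)) return(invisible())
  if (is.null(target$grad)) target$grad <- g
  else target$grad <- target$grad + g
  invisible()
}

# Backpropagate from a scalar loss node through every op on the tape.
td_backward <- function(tape, loss) {
  loss$grad <- 1
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$ops[[i]]
    if (is.null(nd$grad)) next
    gs <- nd$bwd(nd, nd$grad)
    for (j in seq_along(nd$parents)) td_accum(nd$parents[[j]], gs[[j]])
  }
  invisible()
}

td_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible()
}

conv_out_extent <- function(n, k, stride, pad)
  as.integer((n + 2L * pad - k) %/% stride + 1L)

# 3D convolution, kernel k^3, arbitrary stride, symmetric zero padding.
# Weight param: (k^3 * Cin) x Cout matrix; bias param: length Cout (or NULL).
op_conv3d <- function(tape, x, w, b, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  sd <- x$sdim
  bias <- if (is.null(b)) numeric(ncol(w$value)) else b$value
  out <- cpp_conv3d_fw(x$value, sd[1], sd[2], sd[3], w$value, bias,
                       k, stride, pad)
  osd <- vapply(sd, conv_out_extent, integer(1), k = k,
                stride = stride, pad = pad)
  td_node(tape, out, osd, list(x, w, b), function(nd, g) {
    r <- cpp_conv3d_bw(x$value, sd[1], sd[2], sd[3], w$value, g,
                       k, stride, pad)
    list(r$gx, r$gw, if (is.null(b)) NULL else as.numeric(r$gb))
  })
}

# Cached output-index permutations for the 2x transposed convolution.
.tconv_idx_cache <- new.env(parent = emptyenv())

tconv2_indices <- function(sd) {
  key <- paste(sd, collapse = "x")
  got <- .tconv_idx_cache[[key]]
  if (!is.null(got)) return(got)
  D <- sd[1]; H <- sd[2]; W <- sd[3]
  d <- rep.int(seq_len(D) - 1L, H * W)
  h <- rep.int(rep(seq_len(H) - 1L, each = D), W)
  w <- rep(seq_len(W) - 1L, each = D * H)
  idx <- vector("list", 8L)
  for (kw in 0:1) for (kh in 0:1) for (kd in 0:1) {
    kix <- kd + 2L * kh + 4L * kw
    idx[[kix + 1L]] <- (2L * d + kd) + 2L * D * (2L * h + kh) +
      4L * D * H * (2L * w + kw) + 1L
  }
  .tconv_idx_cache[[key]] <- idx
  idx
}

# Transposed convolution, kernel 2, stride 2 (exact x2 upsampling, no
# overlap). Weight param: Cin x (8 * Cout), column index kidx + 8*cout.
op_tconv2 <- function(tape, x, w, b) {
  sd <- x$sdim
  cin <- ncol(x$value)
  cout <- ncol(w$value) %/% 8L
  idx <- tconv2_indices(sd)
  y <- x$value %*% w$value
  out <- matrix(0, 8L * nrow(x$value), cout)
  for (kix in 1:8)
    out[idx[[kix]], ] <- y[, kix + 8L * (seq_len(cout) - 1L), drop = FALSE]
  out <- sweep(out, 2, b$value, "+")
  osd <- 2L * sd
  td_node(tape, out, osd, list(x, w, b), function(nd, g) {
    gy <- matrix(0, nrow(x$value), 8L * cout)
    for (kix in 1:8)
      gy[, kix + 8L * (seq_len(cout) - 1L)] <- g[idx[[kix]], , drop = FALSE]
    list(gy %*% t(w$value), crossprod(x$value, gy), colSums(g))
  })
}

# Batch normalization over the voxel dimension (one statistic per channel;
# with single-patch batches this is the batch statistic of that patch, used
# identically at train and inference time so runs are self-consistent).
op_batchnorm <- function(tape, x, gamma, beta, eps = 1e-5) {
  xv <- x$value
  n <- nrow(xv)
  mu <- colMeans(xv)
  xc <- sweep(xv, 2, mu)
  v <- colMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, inv, "*")
  out <- sweep(sweep(xhat, 2, gamma$value, "*"), 2, beta$value, "+")
  td_node(tape, out, x$sdim, list(x, gamma, beta), function(nd, g) {
    ggamma <- colSums(g * xhat)
    gbeta <- colSums(g)
    t1 <- sweep(g * n, 2, gbeta)
    t2 <- sweep(xhat, 2, ggamma, "*")
    gx <- sweep(t1 - t2, 2, gamma$value * inv / n, "*")
    list(gx, ggamma, gbeta)
  })
}

op_elu <- function(tape, x) {
  xv <- x$value
  neg <- xv <= 0
  out <- xv
  out[neg] <- exp(xv[neg]) - 1
  td_node(tape, out, x$sdim, list(x), function(nd, g) {
    d <- array(1, dim(xv))
    d[neg] <- out[neg] + 1
    list(g * d)
  })
}

op_relu <- function(tape, x) {
  out <- pmax(x$value, 0)
  td_node(tape, out, x$sdim, list(x), function(nd, g) {
    list(g * (x$value > 0))
  })
}

# Clamped into the open interval so the attention-range invariant survives
# double-precision saturation of extreme logits; the gradient there is
# numerically zero either way.
op_sigmoid <- function(tape, x) {
  out <- pmin(pmax(1 / (1 + exp(-x$value)), 1e-12), 1 - 1e-12)
  td_node(tape, out, x$sdim, list(x), function(nd, g) {
    list(g * out * (1 - out))
  })
}

op_add <- function(tape, a, b) {
  td_node(tape, a$value + b$value, a$sdim, list(a, b),
          function(nd, g) list(g, g))
}

# alpha * x with a learnable scalar alpha (the cross-level coefficients).
op_scale <- function(tape, alpha, x) {
  td_node(tape, as.numeric(alpha$value) * x$value, x$sdim, list(alpha, x),
          function(nd, g) list(sum(g * x$value), as.numeric(alpha$value) * g))
}

# Broadcast a single-channel spatial map over all channels of `feat`.
op_mul_map <- function(tape, feat, map) {
  mv <- as.vector(map$value)
  td_node(tape, feat$value * mv, feat$sdim, list(feat, map), function(nd, g) {
    list(g * mv, matrix(rowSums(g * feat$value), ncol = 1))
  })
}

# Channel-wise mean and max pooled into a 2-channel map (spatial attention
# input). Max gradient is split evenly across tied argmax channels.
op_chan_meanmax <- function(tape, x) {
  xv <- x$value
  C <- ncol(xv)
  mx <- do.call(pmax, lapply(seq_len(C), function(j) xv[, j]))
  out <- cbind(rowMeans(xv), mx)
  td_node(tape, out, x$sdim, list(x), function(nd, g) {
    mask <- xv == mx
    gx <- matrix(g[, 1] / C, nrow(xv), C) + mask * (g[, 2] / rowSums(mask))
    list(gx)
  })
}

# Dense 1D trilinear-resampling matrix mapping n_in samples to n_out,
# cell-centre aligned (output coord o maps to input (o + .5)/f - .5).
tri_axis_matrix <- function(n_in, n_out) {
  f <- n_out / n_in
  U <- matrix(0, n_out, n_in)
  for (o in seq_len(n_out)) {
    u <- (o - 0.5) / f - 0.5
    i0 <- floor(u)
    fr <- u - i0
    ia <- min(max(i0, 0), n_in - 1)
    ib <- min(max(i0 + 1, 0), n_in - 1)
    U[o, ia + 1] <- U[o, ia + 1] + (1 - fr)
    U[o, ib + 1] <- U[o, ib + 1] + fr
  }
  U
}

apply_axis <- function(arr, U, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(seq_along(d), axis))
  a <- aperm(arr, perm)
  m <- U %*% matrix(a, nrow = d[axis])
  d2 <- d; d2[axis] <- nrow(U)
  out <- array(m, c(nrow(U), d2[-axis]))
  aperm(out, order(perm))
}

# Trilinear resize of a single-channel map to `osd` (used to lift deep
# supervision logits to the full label grid).
op_trilinear <- function(tape, x, osd) {
  sd <- x$sdim
  Us <- lapply(1:3, function(a) tri_axis_matrix(sd[a], osd[a]))
  arr <- array(x$value, sd)
  for (a in 1:3) arr <- apply_axis(arr, Us[[a]], a)
  td_node(tape, matrix(as.vector(arr), ncol = 1), osd, list(x),
          function(nd, g) {
            garr <- array(g, osd)
            for (a in 1:3) garr <- apply_axis(garr, t(Us[[a]]), a)
            list(matrix(as.vector(garr), ncol = 1))
          })
}

# Soft-Dice + binary cross-entropy of a single-channel logit map against a
# binary target, both averaged into one scalar node.
op_dice_bce <- function(tape, z, target, w_dice = 1, w_ce = 1, eps = 1e-5) {
  zv <- as.vector(z$value)
  t <- as.vector(target)
  n <- length(zv)
  p <- 1 / (1 + exp(-zv))
  s1 <- sum(p * t); sp <- sum(p); st <- sum(t)
  dice_loss <- 1 - (2 * s1 + eps) / (sp + st + eps)
  bce <- mean(pmax(zv, 0) - zv * t + log1p(exp(-abs(zv))))
  val <- w_dice * dice_loss + w_ce * bce
  td_node(tape, val, NULL, list(z), function(nd, g) {
    denom <- (sp + st + eps)
    ddice_dp <- -(2 * t * denom - (2 * s1 + eps)) / denom^2
    gz <- w_dice * ddice_dp * p * (1 - p) + w_ce * (p - t) / n
    list(matrix(g * gz, ncol = 1))
  })
}

# Weighted sum of scalar nodes (total training loss).
op_weighted_sum <- function(tape, nodes, weights) {
  val <- sum(vapply(seq_along(nodes), function(i)
    weights[i] * nodes[[i]]$value, numeric(1)))
  td_node(tape, val, NULL, nodes, function(nd, g) {
    lapply(weights, function(w) g * w)
  })
}
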