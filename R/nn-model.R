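# Network definition: residual encoder with multi-layer cross-connected
# shortcuts and decoder with spatial-attention-weighted deep supervision.
#
# The encoder stacks L levels of two conv blocks (3^3 conv + batch norm +
# ELU) with a within-level residual add. Level inputs are stride-2
# downsamplings of the previous level plus cross-level shortcuts reaching
# back up to two levels, each a strided 1^3 projection scaled by a learnable
# scalar (alpha for level-1, gamma for level-2). The decoder mirrors the
# encoder with 2x transposed-conv upsampling; at each level a spatial
# attention map in (0,1) (sigmoid over a 7^3 conv of channel-mean/max
# pooling) reweights the upsampled features, a 1^3-projected encoder skip is
# added residually under a ReLU, and a 1^3 head emits auxiliary logits that
# are trilinearly lifted to the full grid for deep supervision.

#' Segmentation network hyperparameters
#'
#' @param levels number of resolution levels; spatial extent halves and
#'   channel count doubles per level.
#' @param base_channels channels at full resolution.
#' @param alpha_init,gamma_init initial values of the learnable cross-level
#'   shortcut coefficients (scalars, one pair per receiving level).
#' @param attention_kernel spatial attention convolution kernel edge (odd).
#' @param deep_supervision_weights loss weight per decoder head, ordered
#'   from the full-resolution head down; defaults to 0.5^d where d is the
#'   head's distance from the output.
#' @param attention logical; `FALSE` freezes the attention map at exactly 1
#'   (ablation: a plain skip-connection decoder).
#' @return a list of class `wmh_net_config`.
#' @export
seg_model_config <- function(levels = 4, base_channels = 8,
                             alpha_init = 1, gamma_init = 1,
                             attention_kernel = 7,
                             deep_supervision_weights = NULL,
                             attention = TRUE) {
  if (attention_kernel %% 2 == 0)
    stop_wmh("attention_kernel must be odd", class = "wmh_config_error")
  if (is.null(deep_supervision_weights))
    deep_supervision_weights <- 0.5^seq_len(levels - 1)
  if (length(deep_supervision_weights) != levels - 1 ||
      any(deep_supervision_weights < 0))
    stop_wmh("need ", levels - 1, " nonnegative deep-supervision weights",
             class = "wmh_config_error")
  structure(list(levels = as.integer(levels),
                 base_channels = as.integer(base_channels),
                 alpha_init = alpha_init, gamma_init = gamma_init,
                 attention_kernel = as.integer(attention_kernel),
                 deep_supervision_weights = deep_supervision_weights,
                 attention = isTRUE(attention)),
            class = "wmh_net_config")
}

he_init <- function(k, cin, cout) {
  matrix(stats::rnorm(k^3 * cin * cout, 0, sqrt(2 / (k^3 * cin))),
         k^3 * cin, cout)
}

# Allocate all trainable parameters (uses the current RNG state).
init_wmh_params <- function(cfg) {
  L <- cfg$levels
  ch <- cfg$base_channels * 2L^(seq_len(L) - 1L)
  P <- list()
  conv <- function(name, k, cin, cout, bias = TRUE) {
    P[[paste0(name, ".w")]] <<- td_param(he_init(k, cin, cout))
    if (bias) P[[paste0(name, ".b")]] <<- td_param(numeric(cout))
  }
  bn <- function(name, c) {
    P[[paste0(name, ".g")]] <<- td_param(rep(1, c))
    P[[paste0(name, ".s")]] <<- td_param(numeric(c))
  }
  # encoder level 1
  conv("enc1.c1", 3, 1, ch[1]); bn("enc1.bn1", ch[1])
  conv("enc1.c2", 3, ch[1], ch[1]); bn("enc1.bn2", ch[1])
  conv("enc1.proj", 1, 1, ch[1], bias = FALSE)
  for (l in 2:L) {
    conv(sprintf("down%d", l), 3, ch[l - 1], ch[l])
    conv(sprintf("enc%d.c1", l), 3, ch[l], ch[l]); bn(sprintf("enc%d.bn1", l), ch[l])
    conv(sprintf("enc%d.c2", l), 3, ch[l], ch[l]); bn(sprintf("enc%d.bn2", l), ch[l])
    conv(sprintf("short%d.a", l), 1, ch[l - 1], ch[l], bias = FALSE)
    P[[sprintf("alpha%d", l)]] <- td_param(cfg$alpha_init)
    if (l >= 3) {
      conv(sprintf("short%d.g", l), 1, ch[l - 2], ch[l], bias = FALSE)
      P[[sprintf("gamma%d", l)]] <- td_param(cfg$gamma_init)
    }
  }
  for (l in (L - 1):1) {
    P[[sprintf("dec%d.up.w", l)]] <- td_param(
      matrix(stats::rnorm(ch[l + 1] * 8 * ch[l], 0, sqrt(2 / ch[l + 1])),
             ch[l + 1], 8 * ch[l]))
    P[[sprintf("dec%d.up.b", l)]] <- td_param(numeric(ch[l]))
    # gate bias starts positive so I_s ~ sigmoid(2) = 0.88: the decoder
    # begins close to a plain skip decoder (same start-as-identity
    # philosophy as the alpha/gamma shortcut coefficients) and learns to
    # close gates where attention should suppress background
    conv(sprintf("att%d", l), cfg$attention_kernel, 2, 1)
    P[[sprintf("att%d.b", l)]] <- td_param(2)
    conv(sprintf("dec%d.skip", l), 1, ch[l], ch[l])
    conv(sprintf("dec%d.c", l), 3, ch[l], ch[l]); bn(sprintf("dec%d.bn", l), ch[l])
    conv(sprintf("head%d", l), 1, ch[l], 1)
  }
  conv("final", 1, ch[1], 1)
  P
}

conv_block <- function(tape, x, P, cname, bname) {
  h <- op_conv3d(tape, x, P[[paste0(cname, ".w")]], P[[paste0(cname, ".b")]],
                 k = 3, stride = 1, pad = 1)
  h <- op_batchnorm(tape, h, P[[paste0(bname, ".g")]], P[[paste0(bname, ".s")]])
  op_elu(tape, h)
}

# Cross-level shortcut feeding level l: alpha_l * P(y_{l-1}) + gamma_l *
# P(y_{l-2}); absent terms are dropped. P is a strided 1^3 projection.
shortcut_node <- function(tape, P, ys, l) {
  pa <- op_conv3d(tape, ys[[l - 1]], P[[sprintf("short%d.a.w", l)]], NULL,
                  k = 1, stride = 2, pad = 0)
  sc <- op_scale(tape, P[[sprintf("alpha%d", l)]], pa)
  if (l >= 3) {
    pg <- op_conv3d(tape, ys[[l - 2]], P[[sprintf("short%d.g.w", l)]], NULL,
                    k = 1, stride = 4, pad = 0)
    sc <- op_add(tape, sc, op_scale(tape, P[[sprintf("gamma%d", l)]], pg))
  }
  sc
}

encoder_forward_nodes <- function(tape, P, cfg, x) {
  L <- cfg$levels
  ys <- vector("list", L)
  h <- conv_block(tape, x, P, "enc1.c1", "enc1.bn1")
  h <- conv_block(tape, h, P, "enc1.c2", "enc1.bn2")
  pr <- op_conv3d(tape, x, P[["enc1.proj.w"]], NULL, k = 1, stride = 1, pad = 0)
  ys[[1]] <- op_add(tape, h, pr)
  for (l in 2:L) {
    dn <- op_conv3d(tape, ys[[l - 1]], P[[sprintf("down%d.w", l)]],
                    P[[sprintf("down%d.b", l)]], k = 3, stride = 2, pad = 1)
    inp <- op_add(tape, dn, shortcut_node(tape, P, ys, l))
    b <- conv_block(tape, inp, P, sprintf("enc%d.c1", l), sprintf("enc%d.bn1", l))
    b <- conv_block(tape, b, P, sprintf("enc%d.c2", l), sprintf("enc%d.bn2", l))
    ys[[l]] <- op_add(tape, b, inp)
  }
  ys
}

decoder_forward_nodes <- function(tape, P, cfg, ys) {
  L <- cfg$levels
  full <- ys[[1]]$sdim
  ak <- cfg$attention_kernel
  heads <- list()
  atts <- list()
  d <- ys[[L]]
  for (l in (L - 1):1) {
    u <- op_tconv2(tape, d, P[[sprintf("dec%d.up.w", l)]],
                   P[[sprintf("dec%d.up.b", l)]])
    if (cfg$attention %||% TRUE) {
      mm <- op_chan_meanmax(tape, u)
      al <- op_conv3d(tape, mm, P[[sprintf("att%d.w", l)]],
                      P[[sprintf("att%d.b", l)]],
                      k = ak, stride = 1, pad = (ak - 1L) %/% 2L)
      Is <- op_sigmoid(tape, al)
    } else {
      Is <- td_input(matrix(1, nrow(u$value), 1), u$sdim)
    }
    I <- op_mul_map(tape, u, Is)
    Ic <- op_conv3d(tape, ys[[l]], P[[sprintf("dec%d.skip.w", l)]],
                    P[[sprintf("dec%d.skip.b", l)]], k = 1, stride = 1, pad = 0)
    Z <- op_relu(tape, op_add(tape, I, Ic))
    d <- conv_block(tape, Z, P, sprintf("dec%d.c", l), sprintf("dec%d.bn", l))
    # deep supervision reads the fused (attended + skip) volume Z_d
    hz <- op_conv3d(tape, Z, P[[sprintf("head%d.w", l)]],
                    P[[sprintf("head%d.b", l)]], k = 1, stride = 1, pad = 0)
    if (!all(hz$sdim == full)) hz <- op_trilinear(tape, hz, full)
    heads[[sprintf("level%d", l)]] <- hz
    atts[[sprintf("level%d", l)]] <- list(
      level = l, I_s = as.vector(Is$value), I = I$value,
      I_c = Ic$value, Z = Z$value, sdim = u$sdim)
  }
  final <- op_conv3d(tape, d, P[["final.w"]], P[["final.b"]],
                     k = 1, stride = 1, pad = 0)
  list(final = final, heads = heads, atts = atts)
}

# Full forward pass on one normalized 3D array. Returns tape nodes so the
# caller can attach a loss and backpropagate, plus attention states.
wmh_forward <- function(P, cfg, arr, tape = new_tape()) {
  sd <- dim(arr)
  div <- 2L^(cfg$levels - 1L)
  if (any(sd %% div != 0))
    stop_wmh("input dims (", paste(sd, collapse = "x"),
             ") must be divisible by ", div, class = "wmh_shape_error")
  x <- td_input(matrix(as.vector(arr), ncol = 1), sd)
  ys <- encoder_forward_nodes(tape, P, cfg, x)
  dec <- decoder_forward_nodes(tape, P, cfg, ys)
  list(tape = tape, input = x, encoder = ys, final = dec$final,
       heads = dec$heads, atts = dec$atts)
}

#' Run the encoder on a volume and return its feature pyramid
#'
#' Mainly an inspection/testing surface; training and prediction use the
#' full network. Level `l` of the returned pyramid has spatial extent
#' `dim(vol) / 2^(l-1)` and `base_channels * 2^(l-1)` channels.
#'
#' @param vol a normalized `wmh_volume` (or 3D array).
#' @param params model parameters as created during [train_segmenter()]
#'   (a `wmh_model$params`), or NULL to initialize fresh ones (seeded by the
#'   caller).
#' @param config a [seg_model_config()].
#' @return list of per-level feature arrays, dim `c(D, H, W, channels)`.
#' @export
encoder_forward <- function(vol, params = NULL, config = seg_model_config()) {
  arr <- if (inherits(vol, "wmh_volume")) vol$data else as.array(vol)
  sd <- dim(arr)
  div <- 2L^(config$levels - 1L)
  if (any(sd %% div != 0))
    stop_wmh("input dims (", paste(sd, collapse = "x"),
             ") must be divisible by ", div, class = "wmh_shape_error")
  P <- params %||% init_wmh_params(config)
  tape <- new_tape()
  x <- td_input(matrix(as.vector(arr), ncol = 1), sd)
  ys <- encoder_forward_nodes(tape, P, config, x)
  lapply(ys, function(nd) array(nd$value, c(nd$sdim, ncol(nd$value))))
}
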