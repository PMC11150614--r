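# Dual-branch segmentation network: a hierarchical convolutional stem
# and branch (pre-activation bottlenecks), a transformer branch over
# stride-16 patch tokens, bidirectional fusion blocks coupling the two,
# and a U-shaped decoder emitting a per-pixel vessel probability map.

#' Model configuration
#'
#' Assembles and validates the hyper-parameters of the dual-branch
#' vessel segmentation network.
#'
#' @param preset `"default"` (transformer depth 12, embedding 384) or
#'   `"tiny"`, a CPU-friendly preset (depth 2, embedding 64) used for
#'   desk-scale training and the test-suite.
#' @param backbone_name identifier of the convolutional backbone family;
#'   purely informational (the backbone is always the package's own
#'   reduced residual hierarchy).
#' @param n_trans_blocks number of transformer blocks `N` (>= 1).
#' @param embed_dim token embedding dimension `J`; must be divisible by
#'   `n_heads`.
#' @param n_heads number of self-attention heads.
#' @param mlp_ratio width multiplier of the transformer MLP hidden layer.
#' @param patch_stride stride of the tokenized grid relative to the
#'   input, fixed at 16: each token summarises one 16 x 16 input patch.
#' @param stem_channels four integers: channel widths of the stride
#'   2/4/8/16 stem stages.
#' @param n_conv_blocks number of bottleneck blocks in the CNN branch.
#' @param decoder_channels three integers: decoder widths at strides
#'   8, 4 and 1.
#' @param enable_cnn_branch,enable_trans_branch,enable_fusion ablation
#'   switches; at least one branch must stay enabled, and fusion is
#'   only meaningful when both branches are on.
#' @param out_classes number of output maps, fixed at 1 (vessel
#'   probability).
#' @return an object of class `vn_model_config`.
#' @export
model_config <- function(preset = c("default", "tiny"),
                         backbone_name = "resnet-bottleneck",
                         n_trans_blocks = NULL, embed_dim = NULL,
                         n_heads = NULL, mlp_ratio = 4,
                         patch_stride = 16L,
                         stem_channels = NULL, n_conv_blocks = NULL,
                         decoder_channels = NULL,
                         enable_cnn_branch = TRUE,
                         enable_trans_branch = TRUE,
                         enable_fusion = TRUE,
                         out_classes = 1L) {
  preset <- match.arg(preset)
  def <- if (preset == "tiny") {
    list(n_trans_blocks = 2L, embed_dim = 64L, n_heads = 2L,
         stem_channels = c(8L, 16L, 24L, 32L), n_conv_blocks = 2L,
         decoder_channels = c(32L, 16L, 8L))
  } else {
    list(n_trans_blocks = 12L, embed_dim = 384L, n_heads = 6L,
         stem_channels = c(32L, 64L, 128L, 256L), n_conv_blocks = 4L,
         decoder_channels = c(128L, 64L, 32L))
  }
  cfg <- list(
    preset = preset,
    backbone_name = backbone_name,
    n_trans_blocks = as.integer(n_trans_blocks %||% def$n_trans_blocks),
    embed_dim = as.integer(embed_dim %||% def$embed_dim),
    n_heads = as.integer(n_heads %||% def$n_heads),
    mlp_ratio = mlp_ratio,
    patch_stride = as.integer(patch_stride),
    stem_channels = as.integer(stem_channels %||% def$stem_channels),
    n_conv_blocks = as.integer(n_conv_blocks %||% def$n_conv_blocks),
    decoder_channels = as.integer(decoder_channels %||% def$decoder_channels),
    enable_cnn_branch = isTRUE(enable_cnn_branch),
    enable_trans_branch = isTRUE(enable_trans_branch),
    enable_fusion = isTRUE(enable_fusion),
    out_classes = as.integer(out_classes))
  class(cfg) <- "vn_model_config"
  validate_model_config(cfg)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_error <- function(msg) stop(errorCondition(msg, class = c("vn_config_error", "error")))
input_error <- function(msg) stop(errorCondition(msg, class = c("vn_input_error", "error")))

validate_model_config <- function(cfg) {
  if (!cfg$enable_cnn_branch && !cfg$enable_trans_branch)
    config_error("at least one of the CNN and transformer branches must be enabled")
  if (cfg$n_trans_blocks < 1L) config_error("n_trans_blocks must be >= 1")
  if (cfg$embed_dim %% cfg$n_heads != 0L)
    config_error("embed_dim must be divisible by n_heads")
  if (cfg$patch_stride != 16L) config_error("patch_stride is fixed at 16")
  if (length(cfg$stem_channels) != 4L) config_error("stem_channels must have length 4")
  if (length(cfg$decoder_channels) != 3L) config_error("decoder_channels must have length 3")
  if (cfg$out_classes != 1L) config_error("out_classes is fixed at 1")
  invisible(cfg)
}

# simple parameter holder (e.g. the learned class token)
nn_param <- function(dims, sd = 0.02) {
  L <- new.env(parent = emptyenv())
  L$type <- "param"
  L$p <- list(v = array(trunc_normal(prod(dims), sd = sd), dim = dims))
  L$g <- zero_like(L$p)
  class(L) <- c("nn_param", "nn_layer")
  L
}

# ---- composite blocks ------------------------------------------------------

#' Pre-activation bottleneck block
#'
#' Residual unit of 1x1 down-projection, 3x3 spatial convolution and
#' 1x1 up-projection, each preceded by batch norm + ReLU.  With
#' matching channels and stride 1 the shortcut is the identity, so
#' zeroing the final projection makes the whole block the identity map.
#' A stage transition (`stride = 2` and/or `cout != cin`) routes the
#' shortcut through a strided 1x1 convolution + batch norm.
#'
#' @param cin,cout input/output channel counts
#' @param stride 1 (same resolution) or 2 (stage transition)
#' @param mid bottleneck width; default `max(cout %/% 4, 4)`
#' @return a block object usable with [bottleneck_apply()]
#' @export
new_conv_bottleneck <- function(cin, cout, stride = 1L, mid = NULL) {
  mid <- mid %||% max(cout %/% 4L, 4L)
  blk <- new.env(parent = emptyenv())
  blk$cin <- cin; blk$cout <- cout; blk$stride <- as.integer(stride); blk$mid <- mid
  blk$bn1 <- nn_batchnorm(cin)
  blk$conv1 <- nn_conv2d(cin, mid, k = 1L)
  blk$bn2 <- nn_batchnorm(mid)
  blk$conv2 <- nn_conv2d(mid, mid, k = 3L, stride = blk$stride)
  blk$bn3 <- nn_batchnorm(mid)
  blk$conv3 <- nn_conv2d(mid, cout, k = 1L)
  blk$projects <- (cin != cout || blk$stride != 1L)
  if (blk$projects) {
    blk$conv_s <- nn_conv2d(cin, cout, k = 1L, stride = blk$stride)
    blk$bn_s <- nn_batchnorm(cout)
  }
  class(blk) <- "vn_bottleneck"
  blk
}

bottleneck_fwd <- function(blk, X, H, W, B, training) {
  z1 <- batchnorm_fwd(blk$bn1, X, training)
  r1 <- relu_fwd(z1)
  y1 <- conv2d_fwd(blk$conv1, r1, H, W, B)
  z2 <- batchnorm_fwd(blk$bn2, y1$out, training)
  r2 <- relu_fwd(z2)
  y2 <- conv2d_fwd(blk$conv2, r2, H, W, B)
  z3 <- batchnorm_fwd(blk$bn3, y2$out, training)
  r3 <- relu_fwd(z3)
  y3 <- conv2d_fwd(blk$conv3, r3, y2$H, y2$W, B)
  if (blk$projects) {
    s <- conv2d_fwd(blk$conv_s, X, H, W, B)
    short <- batchnorm_fwd(blk$bn_s, s$out, training)
  } else short <- X
  blk$cache <- list(z1 = z1, z2 = z2, z3 = z3)
  list(out = short + y3$out, H = y3$H, W = y3$W)
}

bottleneck_bwd <- function(blk, dY) {
  cc <- blk$cache
  dr3 <- conv2d_bwd(blk$conv3, dY)
  dz3 <- relu_bwd(dr3, cc$z3)
  dy2 <- batchnorm_bwd(blk$bn3, dz3)
  dr2 <- conv2d_bwd(blk$conv2, dy2)
  dz2 <- relu_bwd(dr2, cc$z2)
  dy1 <- batchnorm_bwd(blk$bn2, dz2)
  dr1 <- conv2d_bwd(blk$conv1, dy1)
  dz1 <- relu_bwd(dr1, cc$z1)
  dX <- batchnorm_bwd(blk$bn1, dz1)
  if (blk$projects) {
    ds <- batchnorm_bwd(blk$bn_s, dY)
    dX <- dX + conv2d_bwd(blk$conv_s, ds)
  } else dX <- dX + dY
  dX
}

#' Transformer block (pre-norm)
#'
#' Multi-head self-attention plus a two-layer MLP (up-projection, GELU,
#' down-projection), each preceded by layer norm and wrapped in a
#' residual connection.
#'
#' @param embed_dim token dimension J
#' @param n_heads attention heads
#' @param mlp_ratio hidden width multiplier of the MLP
#' @return a block object usable with [transformer_block_apply()]
#' @export
new_transformer_block <- function(embed_dim, n_heads, mlp_ratio = 4) {
  blk <- new.env(parent = emptyenv())
  hidden <- as.integer(round(embed_dim * mlp_ratio))
  blk$J <- embed_dim
  blk$ln1 <- nn_layernorm(embed_dim)
  blk$mha <- nn_mha(embed_dim, n_heads)
  blk$ln2 <- nn_layernorm(embed_dim)
  blk$fc1 <- nn_linear(embed_dim, hidden)
  blk$fc2 <- nn_linear(hidden, embed_dim)
  class(blk) <- "vn_trans_block"
  blk
}

trans_block_fwd <- function(blk, Tm, L1, B) {
  n1 <- layernorm_fwd(blk$ln1, Tm)
  a <- mha_fwd(blk$mha, n1, L1, B)
  t1 <- Tm + a
  n2 <- layernorm_fwd(blk$ln2, t1)
  h1 <- linear_fwd(blk$fc1, n2)
  hg <- gelu_fwd(h1)
  m <- linear_fwd(blk$fc2, hg)
  blk$cache <- list(h1 = h1)
  t1 + m
}

trans_block_bwd <- function(blk, dY) {
  dhg <- linear_bwd(blk$fc2, dY)
  dh1 <- gelu_bwd(dhg, blk$cache$h1)
  dn2 <- linear_bwd(blk$fc1, dh1)
  dt1 <- dY + layernorm_bwd(blk$ln2, dn2)
  da <- mha_bwd(blk$mha, dt1)
  dt1 + layernorm_bwd(blk$ln1, da)
}

# token matrix layout: per image, row 1 is the class token followed by
# L spatial tokens in pixel (column-major) order.
tok_insert_cls <- function(Xf, B, Lsp, cls_row) {
  J <- ncol(Xf)
  Tm <- matrix(0, B * (Lsp + 1L), J)
  for (b in seq_len(B)) {
    Tm[(b - 1L) * (Lsp + 1L) + 1L, ] <- cls_row
    Tm[(b - 1L) * (Lsp + 1L) + 1L + seq_len(Lsp), ] <-
      Xf[(b - 1L) * Lsp + seq_len(Lsp), , drop = FALSE]
  }
  Tm
}

tok_spatial_idx <- function(B, Lsp) {
  as.vector(vapply(seq_len(B),
                   function(b) (b - 1L) * (Lsp + 1L) + 1L + seq_len(Lsp),
                   integer(Lsp)))
}

tok_cls_idx <- function(B, Lsp) (seq_len(B) - 1L) * (Lsp + 1L) + 1L

# ---- model assembly --------------------------------------------------------

#' Build the dual-branch segmentation model
#'
#' Constructs all layers deterministically from `config` and `seed`:
#' two builds with the same arguments yield identical parameter
#' tensors.  Disabled branches contribute no parameters at all.
#'
#' @param config a [model_config()] object
#' @param seed integer seed for weight initialisation
#' @return an object of class `vn_model`
#' @export
build_model <- function(config, seed = 0L) {
  validate_model_config(config)
  m <- new.env(parent = emptyenv())
  m$config <- config
  m$seed <- as.integer(seed)
  sc <- config$stem_channels
  J <- config$embed_dim
  with_seed(seed, {
    m$stem <- list(
      list(conv = nn_conv2d(3L, sc[1], k = 3L, stride = 2L), bn = nn_batchnorm(sc[1])),
      list(conv = nn_conv2d(sc[1], sc[2], k = 3L, stride = 2L), bn = nn_batchnorm(sc[2])),
      list(conv = nn_conv2d(sc[2], sc[3], k = 3L, stride = 2L), bn = nn_batchnorm(sc[3])),
      list(conv = nn_conv2d(sc[3], sc[4], k = 3L, stride = 2L), bn = nn_batchnorm(sc[4])))
    if (config$enable_cnn_branch) {
      m$cnn_blocks <- lapply(seq_len(config$n_conv_blocks), function(i)
        new_conv_bottleneck(sc[4], sc[4], stride = 1L, mid = max(sc[4] %/% 2L, 4L)))
      # pre-activation stacks end with a final norm + ReLU
      m$cnn_final_bn <- nn_batchnorm(sc[4])
    }
    if (config$enable_trans_branch) {
      m$patch_embed <- nn_conv2d(sc[4], J, k = 3L, stride = 1L, init = "trunc")
      m$cls_token <- nn_param(c(1L, J))
      m$trans_blocks <- lapply(seq_len(config$n_trans_blocks), function(i)
        new_transformer_block(J, config$n_heads, config$mlp_ratio))
      m$trans_final_ln <- nn_layernorm(J)
    }
    if (config$enable_fusion && config$enable_cnn_branch && config$enable_trans_branch) {
      # fusion after each paired block, excluding the first pair
      pair_ids <- seq_len(min(config$n_conv_blocks, config$n_trans_blocks))
      pair_ids <- pair_ids[pair_ids >= 2L]
      m$fusion_ids <- pair_ids
      # zero-initialised projections: fusion starts as an identity
      # perturbation and grows during training (residual-adapter init)
      m$fusion <- lapply(pair_ids, function(i) list(
        c2t_proj = nn_linear(sc[4], J, zero_init = TRUE),
        c2t_ln = nn_layernorm(J),
        t2c_proj = nn_linear(J, sc[4], zero_init = TRUE),
        t2c_bn = nn_batchnorm(sc[4])))
      names(m$fusion) <- as.character(pair_ids)
    } else m$fusion_ids <- integer(0)
    head_cin <- (if (config$enable_cnn_branch) sc[4] else 0L) +
                (if (config$enable_trans_branch) J else 0L)
    dc <- config$decoder_channels
    m$head <- list(conv = nn_conv2d(head_cin, sc[4], k = 3L), bn = nn_batchnorm(sc[4]))
    m$dec8 <- list(conv = nn_conv2d(sc[4] + sc[3], dc[1], k = 3L), bn = nn_batchnorm(dc[1]))
    m$dec4 <- list(conv = nn_conv2d(dc[1] + sc[2], dc[2], k = 3L), bn = nn_batchnorm(dc[2]))
    m$dec1 <- list(conv = nn_conv2d(dc[2], dc[3], k = 3L), bn = nn_batchnorm(dc[3]))
    m$out_conv <- nn_conv2d(dc[3], 1L, k = 1L)
  })
  class(m) <- "vn_model"
  m
}

#' @export
print.vn_model <- function(x, ...) {
  cat(sprintf("<vn_model> preset=%s params=%d cnn=%s trans=%s fusion=%s\n",
              x$config$preset, model_nparams(x),
              x$config$enable_cnn_branch, x$config$enable_trans_branch,
              length(x$fusion_ids) > 0))
  invisible(x)
}

model_layers <- function(m) {
  collect_layers(list(
    m$stem,
    if (!is.null(m$cnn_blocks)) lapply(m$cnn_blocks, function(b) {
      ls <- list(b$bn1, b$conv1, b$bn2, b$conv2, b$bn3, b$conv3)
      if (b$projects) ls <- c(ls, list(b$conv_s, b$bn_s))
      ls
    }),
    m$cnn_final_bn,
    if (!is.null(m$patch_embed)) list(m$patch_embed, m$cls_token),
    if (!is.null(m$trans_blocks)) lapply(m$trans_blocks, function(b)
      list(b$ln1, b$mha, b$ln2, b$fc1, b$fc2)),
    m$trans_final_ln,
    m$fusion,
    m$head, m$dec8, m$dec4, m$dec1, m$out_conv))
}

#' Number of trainable parameters
#' @param m a `vn_model`
#' @return integer parameter count
#' @export
model_nparams <- function(m) sum(vapply(model_layers(m), layer_nparams, 1L))

# parameters of one standalone transformer block, counted analytically
# elsewhere in tests; here by traversal
block_nparams <- function(blk) {
  sum(vapply(collect_layers(list(blk$ln1, blk$mha, blk$ln2, blk$fc1, blk$fc2)),
             layer_nparams, 1L))
}

#' Count attention parameters of a model (zero when the transformer
#' branch is disabled)
#' @param m a `vn_model`
#' @return integer
#' @export
model_attention_nparams <- function(m) {
  if (is.null(m$trans_blocks)) return(0L)
  sum(vapply(m$trans_blocks, function(b) layer_nparams(b$mha), 1L))
}

# ---- forward / backward ----------------------------------------------------

# reflect-pad (bottom/right) index map: padded pixel -> original pixel
pad_reflect_idx <- function(H0, W0, Hp, Wp) {
  if (Hp - H0 >= H0 || Wp - W0 >= W0)
    input_error("input too small to reflect-pad to the backbone stride")
  h <- seq_len(Hp); w <- seq_len(Wp)
  hs <- ifelse(h <= H0, h, 2L * H0 - h)
  ws <- ifelse(w <= W0, w, 2L * W0 - w)
  as.vector(outer(hs, ws, function(a, b) a + H0 * (b - 1L)))
}

#' Forward pass of the segmentation model
#'
#' Standardises each image per channel, reflect-pads to a multiple of
#' 32, runs the dual-branch encoder and the U-shaped decoder, and
#' returns per-pixel vessel probabilities cropped back to the input
#' size.  Values are squashed through a logistic, so the map lies in
#' \[0, 1\].
#'
#' @param m a `vn_model`
#' @param images a list of H x W x 3 arrays with values in \[0, 1\]
#'   (all the same size), or a single such array
#' @param training logical; batch-norm uses batch statistics and caches
#'   are kept for [model_backward()] when `TRUE`
#' @return list with `probs` (list of H x W matrices), `logits`
#'   (padded logit matrix, column vector) and the geometry needed to
#'   route gradients back
#' @export
model_forward <- function(m, images, training = FALSE) {
  if (is.array(images) && length(dim(images)) == 3L) images <- list(images)
  B <- length(images)
  d <- dim(images[[1]])
  if (length(d) != 3L || d[3] != 3L) input_error("inputs must be H x W x 3 RGB arrays")
  H0 <- d[1]; W0 <- d[2]
  for (im in images) if (!all(dim(im) == d)) input_error("all images in a batch must share dimensions")
  Hp <- 32L * as.integer(ceiling(H0 / 32)); Wp <- 32L * as.integer(ceiling(W0 / 32))
  pidx <- pad_reflect_idx(H0, W0, Hp, Wp)
  X <- matrix(0, Hp * Wp * B, 3L)
  for (b in seq_len(B)) {
    img <- matrix(images[[b]], H0 * W0, 3L)
    mu <- colMeans(img)
    sdv <- sqrt(colMeans((img - bcast_row(mu, nrow(img)))^2)) + 1e-6
    img <- (img - bcast_row(mu, nrow(img))) / bcast_row(sdv, nrow(img))
    X[(b - 1L) * Hp * Wp + seq_len(Hp * Wp), ] <- img[pidx, , drop = FALSE]
  }
  tape <- new.env(parent = emptyenv())
  tape$B <- B; tape$H0 <- H0; tape$W0 <- W0; tape$Hp <- Hp; tape$Wp <- Wp
  tape$pidx <- pidx
  cfg <- m$config

  # stem: four stride-2 conv/bn/relu stages -> features at strides 2..16
  cur <- X; Hc <- Hp; Wc <- Wp
  tape$stem <- vector("list", 4L)
  feats <- vector("list", 4L)
  dims <- vector("list", 4L)
  for (s in 1:4) {
    y <- conv2d_fwd(m$stem[[s]]$conv, cur, Hc, Wc, B)
    z <- batchnorm_fwd(m$stem[[s]]$bn, y$out, training)
    cur <- relu_fwd(z)
    Hc <- y$H; Wc <- y$W
    tape$stem[[s]] <- list(z = z)
    feats[[s]] <- cur
    dims[[s]] <- c(Hc, Wc)
  }
  f4 <- feats[[2]]; f8 <- feats[[3]]; f16 <- feats[[4]]
  H16 <- dims[[4]][1]; W16 <- dims[[4]][2]
  H8 <- dims[[3]][1]; W8 <- dims[[3]][2]
  H4 <- dims[[2]][1]; W4 <- dims[[2]][2]
  Lsp <- H16 * W16

  x <- if (cfg$enable_cnn_branch) f16 else NULL
  Tm <- NULL
  if (cfg$enable_trans_branch) {
    pe <- conv2d_fwd(m$patch_embed, f16, H16, W16, B)
    Tm <- tok_insert_cls(pe$out, B, Lsp, m$cls_token$p$v[1, ])
  }
  tape$Lsp <- Lsp; tape$H16 <- H16; tape$W16 <- W16
  L1 <- Lsp + 1L
  sp_idx <- if (cfg$enable_trans_branch) tok_spatial_idx(B, Lsp) else NULL
  tape$sp_idx <- sp_idx

  n_steps <- max(if (cfg$enable_cnn_branch) cfg$n_conv_blocks else 0L,
                 if (cfg$enable_trans_branch) cfg$n_trans_blocks else 0L)
  tape$fused_at <- intersect(m$fusion_ids, seq_len(n_steps))
  for (i in seq_len(n_steps)) {
    if (cfg$enable_cnn_branch && i <= cfg$n_conv_blocks)
      x <- bottleneck_fwd(m$cnn_blocks[[i]], x, H16, W16, B, training)$out
    if (cfg$enable_trans_branch && i <= cfg$n_trans_blocks)
      Tm <- trans_block_fwd(m$trans_blocks[[i]], Tm, L1, B)
    if (i %in% tape$fused_at) {
      fz <- m$fusion[[as.character(i)]]
      # concurrent exchange: both directions read the pre-fusion x and Tm
      a <- linear_fwd(fz$c2t_proj, x)            # token grid == stride-16 grid
      Tmid <- Tm
      Tmid[sp_idx, ] <- Tmid[sp_idx, ] + a
      Tnew <- layernorm_fwd(fz$c2t_ln, Tmid)
      bmat <- linear_fwd(fz$t2c_proj, Tm[sp_idx, , drop = FALSE])
      xnew <- batchnorm_fwd(fz$t2c_bn, x + bmat, training)
      Tm <- Tnew; x <- xnew
    }
  }

  if (!is.null(x)) {
    zf <- batchnorm_fwd(m$cnn_final_bn, x, training)
    x <- relu_fwd(zf)
    tape$zf <- zf
  }
  if (!is.null(Tm)) Tm <- layernorm_fwd(m$trans_final_ln, Tm)
  head_in <- if (!is.null(x) && !is.null(Tm)) cbind(x, Tm[sp_idx, , drop = FALSE])
             else if (!is.null(x)) x
             else Tm[sp_idx, , drop = FALSE]
  hy <- conv2d_fwd(m$head$conv, head_in, H16, W16, B)
  hz <- batchnorm_fwd(m$head$bn, hy$out, training)
  h16 <- relu_fwd(hz)
  tape$hz <- hz

  u8 <- resample_fwd(h16, H16, W16, B, H8, W8)
  tape$u8_ops <- attr(u8, "ops")
  c8 <- cbind(u8, f8)
  y8 <- conv2d_fwd(m$dec8$conv, c8, H8, W8, B)
  z8 <- batchnorm_fwd(m$dec8$bn, y8$out, training)
  d8 <- relu_fwd(z8); tape$z8 <- z8

  u4 <- resample_fwd(d8, H8, W8, B, H4, W4)
  tape$u4_ops <- attr(u4, "ops")
  c4 <- cbind(u4, f4)
  y4 <- conv2d_fwd(m$dec4$conv, c4, H4, W4, B)
  z4 <- batchnorm_fwd(m$dec4$bn, y4$out, training)
  d4 <- relu_fwd(z4); tape$z4 <- z4

  u1 <- resample_fwd(d4, H4, W4, B, Hp, Wp)
  tape$u1_ops <- attr(u1, "ops")
  y1 <- conv2d_fwd(m$dec1$conv, u1, Hp, Wp, B)
  z1 <- batchnorm_fwd(m$dec1$bn, y1$out, training)
  d1 <- relu_fwd(z1); tape$z1 <- z1

  logits <- conv2d_fwd(m$out_conv, d1, Hp, Wp, B)$out
  probs_pad <- sigmoid(logits)

  crop_idx <- as.vector(outer(seq_len(H0), seq_len(W0), function(a, b) a + Hp * (b - 1L)))
  tape$crop_idx <- crop_idx
  probs <- lapply(seq_len(B), function(b)
    matrix(probs_pad[(b - 1L) * Hp * Wp + crop_idx], H0, W0))
  m$tape <- tape
  list(probs = probs, logits = logits, H0 = H0, W0 = W0, Hp = Hp, Wp = Wp,
       B = B, crop_idx = crop_idx)
}

# Back-propagate d(loss)/d(logits) (padded column matrix) through the
# whole network, accumulating parameter gradients in the layers.
model_backward <- function(m, dlogits) {
  tape <- m$tape; cfg <- m$config
  B <- tape$B
  dd1 <- conv2d_bwd(m$out_conv, dlogits)
  dz1 <- relu_bwd(dd1, tape$z1)
  dy1 <- batchnorm_bwd(m$dec1$bn, dz1)
  du1 <- conv2d_bwd(m$dec1$conv, dy1)
  dd4 <- resample_bwd(du1, tape$u1_ops)

  dz4 <- relu_bwd(dd4, tape$z4)
  dy4 <- batchnorm_bwd(m$dec4$bn, dz4)
  dc4 <- conv2d_bwd(m$dec4$conv, dy4)
  dc1w <- m$config$stem_channels[2]
  du4 <- dc4[, seq_len(ncol(dc4) - dc1w), drop = FALSE]
  df4 <- dc4[, ncol(dc4) - dc1w + seq_len(dc1w), drop = FALSE]
  dd8 <- resample_bwd(du4, tape$u4_ops)

  dz8 <- relu_bwd(dd8, tape$z8)
  dy8 <- batchnorm_bwd(m$dec8$bn, dz8)
  dc8 <- conv2d_bwd(m$dec8$conv, dy8)
  dc2w <- m$config$stem_channels[3]
  du8 <- dc8[, seq_len(ncol(dc8) - dc2w), drop = FALSE]
  df8 <- dc8[, ncol(dc8) - dc2w + seq_len(dc2w), drop = FALSE]
  dh16 <- resample_bwd(du8, tape$u8_ops)

  dhz <- relu_bwd(dh16, tape$hz)
  dhy <- batchnorm_bwd(m$head$bn, dhz)
  dhead_in <- conv2d_bwd(m$head$conv, dhy)

  sc4 <- m$config$stem_channels[4]
  sp_idx <- tape$sp_idx
  Lsp <- tape$Lsp; L1 <- Lsp + 1L
  dx <- NULL; dT <- NULL
  if (cfg$enable_cnn_branch && cfg$enable_trans_branch) {
    dx <- dhead_in[, seq_len(sc4), drop = FALSE]
    dT <- matrix(0, B * L1, cfg$embed_dim)
    dT[sp_idx, ] <- dhead_in[, sc4 + seq_len(cfg$embed_dim), drop = FALSE]
  } else if (cfg$enable_cnn_branch) {
    dx <- dhead_in
  } else {
    dT <- matrix(0, B * L1, cfg$embed_dim)
    dT[sp_idx, ] <- dhead_in
  }
  if (!is.null(dx)) {
    dzf <- relu_bwd(dx, tape$zf)
    dx <- batchnorm_bwd(m$cnn_final_bn, dzf)
  }
  if (!is.null(dT)) dT <- layernorm_bwd(m$trans_final_ln, dT)

  n_steps <- max(if (cfg$enable_cnn_branch) cfg$n_conv_blocks else 0L,
                 if (cfg$enable_trans_branch) cfg$n_trans_blocks else 0L)
  for (i in rev(seq_len(n_steps))) {
    if (i %in% tape$fused_at) {
      fz <- m$fusion[[as.character(i)]]
      dx_mid <- batchnorm_bwd(fz$t2c_bn, dx)
      dT_from_t2c <- linear_bwd(fz$t2c_proj, dx_mid)
      dT_mid <- layernorm_bwd(fz$c2t_ln, dT)
      da <- dT_mid[sp_idx, , drop = FALSE]
      dx_from_c2t <- linear_bwd(fz$c2t_proj, da)
      dx <- dx_mid + dx_from_c2t
      dT <- dT_mid
      dT[sp_idx, ] <- dT[sp_idx, ] + dT_from_t2c
    }
    if (cfg$enable_trans_branch && i <= cfg$n_trans_blocks)
      dT <- trans_block_bwd(m$trans_blocks[[i]], dT)
    if (cfg$enable_cnn_branch && i <= cfg$n_conv_blocks)
      dx <- bottleneck_bwd(m$cnn_blocks[[i]], dx)
  }

  df16 <- if (!is.null(dx)) dx else matrix(0, B * Lsp, sc4)
  if (cfg$enable_trans_branch) {
    cls_idx <- tok_cls_idx(B, Lsp)
    m$cls_token$g$v <- m$cls_token$g$v + matrix(colSums(dT[cls_idx, , drop = FALSE]), 1L)
    dpe <- dT[sp_idx, , drop = FALSE]
    df16 <- df16 + conv2d_bwd(m$patch_embed, dpe)
  }

  # stem backward; decoder skips add into the stage-2 (stride 4) and
  # stage-3 (stride 8) outputs
  dcur <- df16
  for (s in rev(1:4)) {
    dz <- relu_bwd(dcur, tape$stem[[s]]$z)
    dy <- batchnorm_bwd(m$stem[[s]]$bn, dz)
    dcur <- conv2d_bwd(m$stem[[s]]$conv, dy)
    if (s == 4L) dcur <- dcur + df8
    if (s == 3L) dcur <- dcur + df4
  }
  invisible(dcur)
}
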