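# Standalone block-level operations on explicit FeatureMap /
# TokenSequence containers.  The same layer machinery is used inside
# the assembled model; these wrappers exist so that each architectural
# contract (residual identity, attention normalisation, fusion
# alignment arithmetic) can be exercised in isolation.

#' Feature map container
#'
#' @param values H x W x C numeric array of activations
#' @param stride integer downsampling factor relative to the network
#'   input; one of 4, 8, 16, 32
#' @return object of class `vn_feature_map`
#' @export
feature_map <- function(values, stride) {
  d <- dim(values)
  if (length(d) != 3L || any(d < 1L)) input_error("feature map must be H x W x C")
  if (!stride %in% c(4L, 8L, 16L, 32L)) input_error("stride must be one of 4, 8, 16, 32")
  if (!all(is.finite(values))) input_error("feature map values must be finite")
  structure(list(values = values, stride = as.integer(stride)),
            class = "vn_feature_map")
}

#' Token sequence container
#'
#' Rows are tokens; the first row is the class token, followed by
#' `grid_h * grid_w` spatial tokens in column-major pixel order.
#'
#' @param values (L+1) x J numeric matrix
#' @param grid_h,grid_w token grid dimensions with `grid_h * grid_w = L`
#' @return object of class `vn_token_sequence`
#' @export
token_sequence <- function(values, grid_h, grid_w) {
  if (!is.matrix(values)) input_error("token sequence must be a matrix")
  if (nrow(values) != grid_h * grid_w + 1L)
    input_error("token count must equal grid_h * grid_w + 1 (class token)")
  if (!all(is.finite(values))) input_error("token values must be finite")
  structure(list(values = values, grid_h = as.integer(grid_h),
                 grid_w = as.integer(grid_w)),
            class = "vn_token_sequence")
}

fm_to_mat <- function(fm) {
  d <- dim(fm$values)
  matrix(fm$values, d[1] * d[2], d[3])
}

mat_to_fm <- function(X, H, W, stride) {
  feature_map(array(X, dim = c(H, W, ncol(X))), stride)
}

#' Apply a bottleneck block to a feature map
#'
#' @param blk a block from [new_conv_bottleneck()]
#' @param fm a [feature_map()] with `C == blk$cin`
#' @param training logical, batch-norm mode
#' @return a `vn_feature_map`; spatial dims halve at a stage transition
#' @export
bottleneck_apply <- function(blk, fm, training = FALSE) {
  d <- dim(fm$values)
  if (d[3] != blk$cin) config_error("channel mismatch between input and block")
  y <- bottleneck_fwd(blk, fm_to_mat(fm), d[1], d[2], 1L, training)
  out_stride <- fm$stride * blk$stride
  if (!out_stride %in% c(4L, 8L, 16L, 32L)) out_stride <- fm$stride
  mat_to_fm(y$out, y$H, y$W, out_stride)
}

#' Apply a transformer block to a token sequence
#'
#' Shape is preserved; per-head attention rows are non-negative and sum
#' to one (softmax).  Attention weights of the last call are retrievable
#' with [attention_weights()].
#'
#' @param blk a block from [new_transformer_block()]
#' @param ts a [token_sequence()]
#' @return a `vn_token_sequence` of identical shape
#' @export
transformer_block_apply <- function(blk, ts) {
  out <- trans_block_fwd(blk, ts$values, nrow(ts$values), 1L)
  token_sequence(out, ts$grid_h, ts$grid_w)
}

#' Attention weights of the last forward pass
#' @param blk a transformer block already applied to a sequence
#' @return list (one per head) of (L+1) x (L+1) row-stochastic matrices
#' @export
attention_weights <- function(blk) blk$mha$cache$per_image[[1]]$P

#' Patch embedding over a stride-16 feature map
#'
#' A 3 x 3 stride-1 convolution projects the stride-16 backbone feature
#' map to the token dimension, so each token's receptive field covers a
#' 16 x 16 input patch; a learned class token is prepended and no
#' positional embedding is added.
#'
#' @param cin input channels
#' @param embed_dim token dimension J
#' @return a patch-embedding object
#' @export
new_patch_embed <- function(cin, embed_dim) {
  pe <- new.env(parent = emptyenv())
  pe$conv <- nn_conv2d(cin, embed_dim, k = 3L, init = "trunc")
  pe$cls <- nn_param(c(1L, embed_dim))
  class(pe) <- "vn_patch_embed"
  pe
}

#' @rdname new_patch_embed
#' @param pe a patch-embedding object
#' @param fm a stride-16 [feature_map()]
#' @export
patch_embed_apply <- function(pe, fm) {
  if (fm$stride != 16L)
    input_error("patch embedding expects the stride-16 feature map")
  d <- dim(fm$values)
  y <- conv2d_fwd(pe$conv, fm_to_mat(fm), d[1], d[2], 1L)
  token_sequence(rbind(pe$cls$p$v[1, ], y$out), d[1], d[2])
}

#' Bidirectional CNN/transformer fusion pair
#'
#' Holds the 1 x 1 projections and the normalisation layers of one
#' fusion block: feature maps are average-pooled onto the token grid,
#' projected to the token dimension and added to the spatial tokens
#' (then layer-normalised); tokens are bilinearly up-sampled onto the
#' feature grid, projected to the channel count and added to the map
#' (then batch-normalised).
#'
#' @param channels CNN feature channels C
#' @param embed_dim token dimension J
#' @return a fusion-pair object
#' @export
new_fusion_pair <- function(channels, embed_dim) {
  fp <- new.env(parent = emptyenv())
  fp$c2t_proj <- nn_linear(channels, embed_dim)
  fp$c2t_ln <- nn_layernorm(embed_dim)
  fp$t2c_proj <- nn_linear(embed_dim, channels)
  fp$t2c_bn <- nn_batchnorm(channels)
  class(fp) <- "vn_fusion_pair"
  fp
}

#' Fuse a CNN feature map into a token sequence
#' @param fp a [new_fusion_pair()] object
#' @param fm a [feature_map()] whose spatial dims are an integer
#'   multiple of the token grid
#' @param ts a [token_sequence()]
#' @param training logical (unused; layer norm has no mode)
#' @return a `vn_token_sequence` with the shape of `ts`
#' @export
fuse_cnn_to_trans <- function(fp, fm, ts, training = FALSE) {
  d <- dim(fm$values)
  if (d[1] %% ts$grid_h != 0L || d[2] %% ts$grid_w != 0L)
    input_error("feature dims must be an integer multiple of the token grid")
  X <- fm_to_mat(fm)
  if (d[1] != ts$grid_h || d[2] != ts$grid_w)
    X <- resample_fwd(X, d[1], d[2], 1L, ts$grid_h, ts$grid_w, mode = "avgpool")
  a <- linear_fwd(fp$c2t_proj, X)
  Tmid <- ts$values
  Tmid[-1L, ] <- Tmid[-1L, ] + a
  token_sequence(layernorm_fwd(fp$c2t_ln, Tmid), ts$grid_h, ts$grid_w)
}

#' Fuse a token sequence into a CNN feature map
#'
#' The class token is dropped before the spatial broadcast.
#' @inheritParams fuse_cnn_to_trans
#' @return a `vn_feature_map` with the shape of `fm`
#' @export
fuse_trans_to_cnn <- function(fp, ts, fm, training = FALSE) {
  d <- dim(fm$values)
  tsp <- ts$values[-1L, , drop = FALSE]
  if (d[1] != ts$grid_h || d[2] != ts$grid_w)
    tsp <- resample_fwd(tsp, ts$grid_h, ts$grid_w, 1L, d[1], d[2], mode = "bilinear")
  bmat <- linear_fwd(fp$t2c_proj, tsp)
  out <- batchnorm_fwd(fp$t2c_bn, fm_to_mat(fm) + bmat, training)
  mat_to_fm(out, d[1], d[2], fm$stride)
}
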