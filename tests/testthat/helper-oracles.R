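# Independent brute-force oracles used to pin down expected values.
# These never call into the implementation paths they check.

# per-pixel binary cross-entropy, selection by explicit sort
oracle_topk <- function(s, g, k_percent) {
  s <- pmin(pmax(as.numeric(s), 1e-7), 1 - 1e-7)
  g <- as.numeric(g)
  ce <- -(g * log(s) + (1 - g) * log(1 - s))
  n_sel <- max(1L, as.integer(ceiling(k_percent / 100 * length(ce))))
  mean(sort(ce, decreasing = TRUE)[seq_len(n_sel)])
}

# explicit per-pixel loop over the confusion table
oracle_confusion <- function(pred, gt, fov = NULL) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
    if (!is.null(fov) && fov[i, j] == 0) next
    p <- pred[i, j] > 0; g <- gt[i, j] > 0
    if (p && g) tp <- tp + 1L
    else if (p && !g) fp <- fp + 1L
    else if (!p && !g) tn <- tn + 1L
    else fn <- fn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

# O(n^2) pairwise AUROC with half-credit ties
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels > 0]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# brute-force single-image multi-head attention from explicit weights
oracle_attention <- function(Tb, Wqkv, bqkv, Wo, bo, n_heads) {
  J <- ncol(Tb); dh <- J / n_heads; L1 <- nrow(Tb)
  QKV <- Tb %*% Wqkv + matrix(bqkv, L1, 3 * J, byrow = TRUE)
  O <- matrix(0, L1, J)
  P_list <- list()
  for (h in seq_len(n_heads)) {
    sl <- (h - 1) * dh + seq_len(dh)
    Q <- QKV[, sl, drop = FALSE]
    K <- QKV[, J + sl, drop = FALSE]
    V <- QKV[, 2 * J + sl, drop = FALSE]
    S <- Q %*% t(K) / sqrt(dh)
    P <- t(apply(S, 1, function(r) { e <- exp(r - max(r)); e / sum(e) }))
    O[, sl] <- P %*% V
    P_list[[h]] <- P
  }
  list(out = O %*% Wo + matrix(bo, L1, J, byrow = TRUE), P = P_list)
}

# small deterministic fixtures ----------------------------------------------

tiny_cfg <- function(...) {
  args <- list(preset = "tiny", n_trans_blocks = 2, embed_dim = 16, n_heads = 2,
               stem_channels = c(4, 6, 8, 12), n_conv_blocks = 2,
               decoder_channels = c(8, 6, 4), mlp_ratio = 2)
  ov <- list(...)
  args[names(ov)] <- ov
  do.call(model_config, args)
}

rand_image <- function(H, W, seed = 1) {
  vesselnet:::with_seed(seed, array(runif(H * W * 3), dim = c(H, W, 3)))
}

# zero every parameter of a layer
zero_layer <- function(L) {
  for (nm in names(L$p)) L$p[[nm]][] <- 0
  invisible(L)
}
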