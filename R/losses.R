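# Training losses: TopK cross-entropy over the hardest k% of pixels,
# soft Dice, and their unweighted sum.  "Hardest" means largest
# per-pixel binary cross-entropy; the k = 100 degenerate recovers plain
# mean cross-entropy and doubles as the cross-entropy ablation arm.

#' Loss configuration
#'
#' @param k_percent the k of the TopK loss, in (0, 100]; the loss
#'   averages cross-entropy over the `ceiling(k% * N)` pixels with the
#'   largest per-pixel loss (floored at one pixel)
#' @param use_topk,use_dice,use_ce ablation switches; `use_ce` replaces
#'   the TopK term by full-image mean cross-entropy (k = 100); at
#'   least one term must stay enabled
#' @param epsilon Dice denominator stabiliser (> 0)
#' @param per_image compute the TopK selection per image instead of
#'   over the flattened batch (default: per batch)
#' @return object of class `vn_loss_config`
#' @export
loss_config <- function(k_percent = 10, use_topk = TRUE, use_dice = TRUE,
                        use_ce = FALSE, epsilon = 1e-6, per_image = FALSE) {
  if (use_ce) use_topk <- FALSE
  if (!use_topk && !use_dice && !use_ce)
    config_error("at least one loss term must be enabled")
  if (!(k_percent > 0 && k_percent <= 100))
    config_error("k_percent must lie in (0, 100]")
  if (epsilon <= 0) config_error("epsilon must be positive")
  structure(list(k_percent = k_percent, use_topk = use_topk,
                 use_dice = use_dice, use_ce = use_ce,
                 epsilon = epsilon, per_image = per_image),
            class = "vn_loss_config")
}

.loss_clamp <- 1e-7

as_loss_vec <- function(x) {
  if (is.list(x)) unlist(lapply(x, as.numeric), use.names = FALSE)
  else as.numeric(x)
}

bce_per_pixel <- function(s, g) {
  s <- pmin(pmax(s, .loss_clamp), 1 - .loss_clamp)
  -(g * log(s) + (1 - g) * log1p(-s))
}

#' TopK loss
#'
#' Mean per-pixel binary cross-entropy over the k% of pixels with the
#' largest per-pixel loss (ties broken by pixel index).  At
#' `k_percent = 100` this is plain mean cross-entropy; for smaller k it
#' can only increase, never decrease.
#'
#' @param probs predicted probabilities in \[0, 1\] (vector, matrix, or
#'   list of maps)
#' @param target binary ground truth, same shape
#' @param k_percent percentage of pixels kept
#' @return non-negative scalar
#' @export
topk_loss <- function(probs, target, k_percent = 10) {
  s <- as_loss_vec(probs); g <- as_loss_vec(target)
  if (length(s) != length(g)) input_error("probability and target shapes differ")
  ce <- bce_per_pixel(s, g)
  n_sel <- max(1L, as.integer(ceiling(k_percent / 100 * length(ce))))
  # stable order => ties resolved by pixel index
  sel <- order(ce, decreasing = TRUE)[seq_len(n_sel)]
  mean(ce[sel])
}

#' Dice loss (soft)
#'
#' `1 - (2|Vs ∩ Vg| + eps) / (|Vs| + |Vg| + eps)` with the soft
#' intersection `sum(s * g)`.  Returns 0 for a perfect binary match and
#' approaches 1 for disjoint masks as `eps -> 0`; two empty masks give
#' 0 by the epsilon convention.
#'
#' @inheritParams topk_loss
#' @param epsilon stabiliser added to numerator and denominator
#' @return scalar in \[0, 1\]
#' @export
dice_loss <- function(probs, target, epsilon = 1e-6) {
  s <- as_loss_vec(probs); g <- as_loss_vec(target)
  if (length(s) != length(g)) input_error("probability and target shapes differ")
  1 - (2 * sum(s * g) + epsilon) / (sum(s) + sum(g) + epsilon)
}

#' Combined segmentation loss
#'
#' Unweighted sum of the enabled terms: TopK (or its k = 100
#' cross-entropy replacement) plus Dice.
#'
#' @inheritParams topk_loss
#' @param config a [loss_config()]
#' @return named list with `total` and the individual terms
#' @export
combined_loss <- function(probs, target, config = loss_config()) {
  lt <- 0; ld <- 0
  if (config$use_topk) lt <- topk_loss(probs, target, config$k_percent)
  if (config$use_ce) lt <- topk_loss(probs, target, 100)
  if (config$use_dice) ld <- dice_loss(probs, target, config$epsilon)
  list(total = lt + ld, topk = lt, dice = ld)
}

# gradient of the combined loss w.r.t. the *logits* (sigmoid folded in),
# used by the training loop.  The TopK pixel selection is treated as
# constant, the standard subgradient.
combined_loss_grad_logits <- function(s, g, config) {
  n <- length(s)
  dz <- numeric(n)
  if (config$use_topk || config$use_ce) {
    kp <- if (config$use_ce) 100 else config$k_percent
    ce <- bce_per_pixel(s, g)
    n_sel <- max(1L, as.integer(ceiling(kp / 100 * n)))
    sel <- order(ce, decreasing = TRUE)[seq_len(n_sel)]
    dz[sel] <- dz[sel] + (s[sel] - g[sel]) / n_sel
  }
  if (config$use_dice) {
    e <- config$epsilon
    den <- sum(s) + sum(g) + e
    num <- 2 * sum(s * g) + e
    ds <- -(2 * g * den - num) / den^2
    dz <- dz + ds * s * (1 - s)
  }
  dz
}
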