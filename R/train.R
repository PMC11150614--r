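# Training, inference and evaluation orchestration: AdamW with cosine
# learning-rate decay, random 118 x 118 patches (64 in the tiny
# preset) with on-the-fly rotation, best-checkpoint selection on
# validation Dice, overlap-averaged tiled whole-image inference, and
# publication-style evaluation tables.

#' Training configuration
#'
#' @param preset `"default"` (the published recipe: 118 px patches,
#'   batch 16, learning rate 1e-4) or `"tiny"` (64 px patches, batch 6,
#'   CPU-scale model) for desk-scale runs
#' @param model a [model_config()]
#' @param loss a [loss_config()]
#' @param lr0 initial learning rate (default 1e-4)
#' @param lr_min cosine-decay floor (default 1e-6)
#' @param beta1 AdamW first-moment coefficient ("momentum", 0.9)
#' @param beta2 AdamW second-moment coefficient
#' @param weight_decay decoupled weight decay
#' @param batch_size patches per iteration
#' @param patch_size square patch side (>= 32)
#' @param iterations optimisation steps
#' @param val_frac fraction of training records held out for validation
#' @param val_every validate (and possibly snapshot) every this many
#'   iterations
#' @param augment apply random rotation in \[-20, 20\] degrees
#' @param seed master seed: weight init, split and sampling stream
#' @return object of class `vn_train_config`
#' @export
train_config <- function(preset = c("default", "tiny"), model = NULL, loss = loss_config(),
                         lr0 = 1e-4, lr_min = 1e-6, beta1 = 0.9, beta2 = 0.999,
                         weight_decay = 1e-4, batch_size = NULL, patch_size = NULL,
                         iterations = NULL, val_frac = 0.1, val_every = 50L,
                         augment = TRUE, seed = 0L) {
  preset <- match.arg(preset)
  # the tiny preset compresses the published recipe (lr 1e-4, 20k
  # iterations) into a CPU-scale budget: a higher initial rate is needed
  # for the cosine schedule to do useful work in ~400 steps
  def <- if (preset == "tiny")
    list(batch_size = 6L, patch_size = 64L, iterations = 400L, lr0 = 3e-3)
  else list(batch_size = 16L, patch_size = 118L, iterations = 20000L, lr0 = 1e-4)
  if (missing(lr0)) lr0 <- def$lr0
  cfg <- list(preset = preset,
              model = model %||% model_config(preset),
              loss = loss,
              lr0 = lr0, lr_min = lr_min, beta1 = beta1, beta2 = beta2,
              weight_decay = weight_decay,
              batch_size = as.integer(batch_size %||% def$batch_size),
              patch_size = as.integer(patch_size %||% def$patch_size),
              iterations = as.integer(iterations %||% def$iterations),
              val_frac = val_frac, val_every = as.integer(val_every),
              augment = isTRUE(augment), seed = as.integer(seed))
  if (cfg$batch_size < 1L) config_error("batch_size must be >= 1")
  if (cfg$patch_size < 32L) config_error("patch_size must be >= 32")
  if (cfg$lr0 < 0) config_error("lr0 must be non-negative")
  class(cfg) <- "vn_train_config"
  cfg
}

# ---- AdamW -----------------------------------------------------------------

adamw_init <- function(layers) {
  lapply(layers, function(L) lapply(L$p, function(p) list(m = p * 0, v = p * 0)))
}

adamw_step <- function(layers, state, lr, beta1, beta2, wd, t, eps = 1e-8) {
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  for (i in seq_along(layers)) {
    L <- layers[[i]]
    for (nm in names(L$p)) {
      g <- L$g[[nm]]
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      state[[i]][[nm]] <- st
      upd <- (st$m / bc1) / (sqrt(st$v / bc2) + eps)
      L$p[[nm]] <- L$p[[nm]] - lr * (upd + wd * L$p[[nm]])
    }
  }
  state
}

cosine_lr <- function(it, iterations, lr0, lr_min) {
  if (iterations <= 1L) return(lr0)
  lr_min + 0.5 * (lr0 - lr_min) * (1 + cos(pi * (it - 1) / (iterations - 1)))
}

# ---- parameter snapshots ---------------------------------------------------

get_model_params <- function(m) {
  lapply(model_layers(m), function(L) {
    out <- list(p = L$p)
    if (inherits(L, "nn_batchnorm")) { out$rmean <- L$rmean; out$rvar <- L$rvar }
    out
  })
}

set_model_params <- function(m, snap) {
  layers <- model_layers(m)
  stopifnot(length(layers) == length(snap))
  for (i in seq_along(layers)) {
    layers[[i]]$p <- snap[[i]]$p
    if (inherits(layers[[i]], "nn_batchnorm")) {
      layers[[i]]$rmean <- snap[[i]]$rmean
      layers[[i]]$rvar <- snap[[i]]$rvar
    }
  }
  invisible(m)
}

#' Save / load a model checkpoint
#'
#' Weights and running statistics go into a single serialised file;
#' the model configuration is additionally written as a JSON sidecar
#' (`<path>.json`) for inspection without loading the binary.
#'
#' @param m a `vn_model`
#' @param path checkpoint file path
#' @return `path` (save) or the restored `vn_model` (load)
#' @export
save_checkpoint <- function(m, path) {
  obj <- list(config = unclass(m$config), seed = m$seed,
              params = get_model_params(m))
  saveRDS(obj, path)
  jsonlite::write_json(unclass(m$config), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  cfg <- obj$config; class(cfg) <- "vn_model_config"
  m <- build_model(cfg, seed = obj$seed)
  set_model_params(m, obj$params)
  m
}

# ---- training --------------------------------------------------------------

#' Train the segmentation model
#'
#' Per iteration: sample `batch_size` random square patches from the
#' training records (rotation-augmented on the fly), run the network,
#' compute the combined TopK + Dice loss, back-propagate and take one
#' AdamW step under cosine learning-rate decay.  Every `val_every`
#' iterations the model is scored on the held-out validation records
#' (soft Dice) and the best snapshot is kept and restored at the end.
#'
#' @param records list of image records (the training pool)
#' @param cfg a [train_config()]
#' @param verbose print a line every 25 iterations
#' @return list with `model` (best-validation weights), `log`
#'   (data.frame: iteration, lr, total/topk/dice loss, val_dice),
#'   `best_val`, and `cfg`
#' @export
train_model <- function(records, cfg = train_config("tiny"), verbose = FALSE) {
  if (length(records) < 1L) input_error("training needs at least one record")
  sp <- split_train_val(records, cfg$val_frac, cfg$seed)
  if (length(sp$val) == 0L) input_error("validation set is empty")
  model <- build_model(cfg$model, seed = cfg$seed)
  layers <- model_layers(model)
  state <- adamw_init(layers)
  log_rows <- vector("list", cfg$iterations)
  best_val <- -Inf; best_snap <- NULL
  ps <- cfg$patch_size
  with_seed(cfg$seed + 1L, {
    for (it in seq_len(cfg$iterations)) {
      imgs <- vector("list", cfg$batch_size)
      msks <- vector("list", cfg$batch_size)
      for (b in seq_len(cfg$batch_size)) {
        rec <- sp$train[[sample.int(length(sp$train), 1L)]]
        pt <- sample_patch(rec, ps)
        if (cfg$augment) {
          aug <- augment_rotation(pt$image, pt$mask)
          imgs[[b]] <- aug$image; msks[[b]] <- aug$mask
        } else {
          imgs[[b]] <- pt$image; msks[[b]] <- pt$mask
        }
      }
      fw <- model_forward(model, imgs, training = TRUE)
      s <- unlist(lapply(fw$probs, as.numeric), use.names = FALSE)
      g <- unlist(lapply(msks, as.numeric), use.names = FALSE)
      ls <- combined_loss(s, g, cfg$loss)
      dz <- combined_loss_grad_logits(s, g, cfg$loss)
      # scatter the cropped-pixel gradient into the padded logit grid
      npad <- fw$Hp * fw$Wp
      dlog <- matrix(0, npad * fw$B, 1L)
      norig <- fw$H0 * fw$W0
      for (b in seq_len(fw$B))
        dlog[(b - 1L) * npad + fw$crop_idx, 1L] <- dz[(b - 1L) * norig + seq_len(norig)]
      zero_grads(layers)
      model_backward(model, dlog)
      lr <- cosine_lr(it, cfg$iterations, cfg$lr0, cfg$lr_min)
      state <- adamw_step(layers, state, lr, cfg$beta1, cfg$beta2, cfg$weight_decay, it)
      vd <- NA_real_
      if (it %% cfg$val_every == 0L || it == cfg$iterations) {
        vd <- validate_dice(model, sp$val, ps)
        if (vd >= best_val) { best_val <- vd; best_snap <- get_model_params(model) }
      }
      log_rows[[it]] <- data.frame(iteration = it, lr = lr, loss = ls$total,
                                   topk = ls$topk, dice = ls$dice, val_dice = vd)
      if (verbose && (it %% 25L == 0L || it == 1L))
        cat(sprintf("it %4d lr %.2e loss %.4f (topk %.4f dice %.4f) val %.3f\n",
                    it, lr, ls$total, ls$topk, ls$dice, vd))
    }
  })
  if (!is.null(best_snap)) set_model_params(model, best_snap)
  list(model = model, log = do.call(rbind, log_rows), best_val = best_val, cfg = cfg)
}

# mean hard-Dice (F1 at threshold 0.5) over validation records, tiled
# inference; aligns snapshot selection with the reported test metric
validate_dice <- function(model, val_records, window) {
  scores <- vapply(val_records, function(rec) {
    p <- predict_probs(model, rec$image, window = window)
    cts <- confusion_counts(threshold_map(p), rec$mask, rec$fov)
    if (2 * cts$tp + cts$fp + cts$fn == 0) return(0)
    2 * cts$tp / (2 * cts$tp + cts$fp + cts$fn)
  }, 1)
  mean(scores)
}

#' Whole-image vessel probability map
#'
#' Images larger than the inference window are tiled with overlapping
#' windows (stride = window / 2, last window aligned to the border)
#' and per-window probabilities are averaged where windows overlap.
#'
#' @param model a trained `vn_model`
#' @param image H x W x 3 array in \[0, 1\]
#' @param window square window side (default: 2 x the tiny patch, 128);
#'   images not larger than the window are run in one padded pass
#' @param max_batch windows run per forward pass
#' @return H x W probability matrix
#' @export
predict_probs <- function(model, image, window = 128L, max_batch = 8L) {
  H <- dim(image)[1]; W <- dim(image)[2]
  if (H <= window && W <= window) {
    return(model_forward(model, list(image), training = FALSE)$probs[[1]])
  }
  win <- as.integer(min(window, H, W))
  stride <- max(1L, win %/% 2L)
  starts <- function(total) {
    s <- seq.int(1L, max(1L, total - win + 1L), by = stride)
    if (s[length(s)] != total - win + 1L) s <- c(s, total - win + 1L)
    s
  }
  sy <- starts(H); sx <- starts(W)
  tiles <- expand.grid(y = sy, x = sx)
  acc <- matrix(0, H, W); cnt <- matrix(0, H, W)
  i <- 1L
  while (i <= nrow(tiles)) {
    jj <- i:min(i + max_batch - 1L, nrow(tiles))
    imgs <- lapply(jj, function(j)
      image[tiles$y[j] + seq_len(win) - 1L, tiles$x[j] + seq_len(win) - 1L, , drop = FALSE])
    out <- model_forward(model, imgs, training = FALSE)$probs
    for (k in seq_along(jj)) {
      j <- jj[k]
      ys <- tiles$y[j] + seq_len(win) - 1L; xs <- tiles$x[j] + seq_len(win) - 1L
      acc[ys, xs] <- acc[ys, xs] + out[[k]]
      cnt[ys, xs] <- cnt[ys, xs] + 1
    }
    i <- jj[length(jj)] + 1L
  }
  acc / cnt
}

#' Evaluate predictions on test records
#'
#' Computes per-image threshold metrics (at 0.5) and AUROC inside the
#' FOV, then aggregates to a mean with percentile-bootstrap intervals,
#' the shape segmentation papers print as `mean (low, high)`.
#'
#' @param records list of image records to evaluate
#' @param predict_fun function(record) -> probability matrix; use
#'   [predict_probs()] wrapped over a trained model, or an oracle
#' @param n_boot,alpha,seed bootstrap parameters (see [bootstrap_ci()])
#' @param threshold vessel threshold (default 0.5)
#' @return list with `per_image` (data.frame), `summary`
#'   (bootstrap data.frame) and `table` (formatted character row)
#' @export
evaluate_records <- function(records, predict_fun, n_boot = 1000L,
                             alpha = 0.05, seed = 0L, threshold = 0.5) {
  rows <- lapply(records, function(rec) {
    p <- predict_fun(rec)
    pred <- threshold_map(p, threshold)
    cts <- confusion_counts(pred, rec$mask, rec$fov)
    mt <- compute_metrics(cts)
    keep <- if (!is.null(rec$fov)) as.logical(rec$fov) else TRUE
    au <- auroc(as.numeric(p)[keep], as.numeric(rec$mask)[keep])
    data.frame(id = rec$id, acc = mt$acc, se = mt$se, sp = mt$sp,
               f1 = mt$f1, auroc = au)
  })
  per_image <- do.call(rbind, rows)
  if (nrow(per_image) >= 2L) {
    ci <- bootstrap_ci(per_image[-1], n_boot, alpha, seed)
    tab <- format_metrics_row(ci)
  } else {
    ci <- data.frame(metric = names(per_image)[-1],
                     mean = as.numeric(per_image[1, -1]),
                     low = NA_real_, high = NA_real_)
    tab <- stats::setNames(sprintf("%.1f", 100 * ci$mean), ci$metric)
  }
  list(per_image = per_image, summary = ci, table = tab)
}

#' Evaluate a trained model on test records
#'
#' Convenience wrapper binding [predict_probs()] into
#' [evaluate_records()].
#'
#' @inheritParams evaluate_records
#' @param model a trained `vn_model`
#' @param window inference window side
#' @return see [evaluate_records()]
#' @export
evaluate_model <- function(model, records, window = 128L, n_boot = 1000L,
                           alpha = 0.05, seed = 0L) {
  evaluate_records(records, function(rec) predict_probs(model, rec$image, window),
                   n_boot = n_boot, alpha = alpha, seed = seed)
}
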