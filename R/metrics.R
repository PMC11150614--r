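# Evaluation metrics inside the camera field of view: accuracy,
# sensitivity, specificity, F1 at threshold 0.5, and AUROC as the
# Mann-Whitney rank statistic; percentile-bootstrap intervals across
# test images.

#' Pixel confusion counts
#'
#' Counts true/false positives/negatives between a binary prediction
#' and ground truth, restricted to the field of view when a FOV mask is
#' supplied.
#'
#' @param pred,gt binary matrices of identical shape (vessel = 1)
#' @param fov optional binary matrix; pixels with 0 are excluded
#' @return object of class `vn_confusion`: list(tp, fp, tn, fn)
#' @export
confusion_counts <- function(pred, gt, fov = NULL) {
  if (!all(dim(pred) == dim(gt))) input_error("prediction/ground-truth shape mismatch")
  p <- as.logical(pred); g <- as.logical(gt)
  if (!is.null(fov)) {
    if (!all(dim(fov) == dim(gt))) input_error("FOV shape mismatch")
    keep <- as.logical(fov)
    p <- p[keep]; g <- g[keep]
  }
  structure(list(tp = sum(p & g), fp = sum(p & !g),
                 tn = sum(!p & !g), fn = sum(!p & g)),
            class = "vn_confusion")
}

#' Threshold metrics from confusion counts
#'
#' Acc = (TP+TN)/(TP+TN+FP+FN), SE = TP/(TP+FN), SP = TN/(TN+FP),
#' F1 = 2TP/(2TP+FP+FN).  An undefined ratio (zero denominator) is
#' reported as `NaN` with a warning, never silently as 0.
#'
#' @param cts a [confusion_counts()] object
#' @return named list with acc, se, sp, f1
#' @export
compute_metrics <- function(cts) {
  tp <- cts$tp; fp <- cts$fp; tn <- cts$tn; fn <- cts$fn
  n <- tp + fp + tn + fn
  if (n == 0) input_error("no pixels evaluated")
  safe_div <- function(num, den, what) {
    if (den == 0) { warning(sprintf("%s undefined: zero denominator", what)); return(NaN) }
    num / den
  }
  list(acc = (tp + tn) / n,
       se = safe_div(tp, tp + fn, "sensitivity"),
       sp = safe_div(tn, tn + fp, "specificity"),
       f1 = safe_div(2 * tp, 2 * tp + fp + fn, "F1"))
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney rank statistic (ties counted one half),
#' which equals the exact trapezoidal area for finite samples and is
#' invariant under strictly monotone transforms of the scores.
#'
#' @param probs numeric scores
#' @param labels binary labels (both classes must be present)
#' @return scalar in \[0, 1\]
#' @export
auroc <- function(probs, labels) {
  g <- as.logical(labels)
  npos <- sum(g); nneg <- sum(!g)
  if (npos == 0 || nneg == 0)
    input_error("AUROC undefined: both classes must be present")
  r <- rank(as.numeric(probs), ties.method = "average")
  (sum(r[g]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Percentile bootstrap intervals over test images
#'
#' Resamples images with replacement and takes percentile bounds of the
#' resampled mean of each per-image metric.
#'
#' @param per_image data.frame, one row per test image, numeric metric
#'   columns
#' @param n_boot bootstrap replicates (a warning is raised below 100)
#' @param alpha two-sided level (default 0.05 for a 95% interval)
#' @param seed integer seed; intervals are reproducible
#' @return data.frame with columns metric, mean, low, high
#' @export
bootstrap_ci <- function(per_image, n_boot = 1000L, alpha = 0.05, seed = 0L) {
  if (nrow(per_image) < 2L) input_error("bootstrap needs at least two images")
  if (n_boot < 100L) warning("fewer than 100 bootstrap replicates")
  cols <- names(per_image)[vapply(per_image, is.numeric, TRUE)]
  M <- as.matrix(per_image[cols])
  n <- nrow(M)
  means <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n_boot, n)
    t(apply(idx, 1, function(ii) colMeans(M[ii, , drop = FALSE], na.rm = TRUE)))
  })
  qs <- apply(means, 2, stats::quantile,
              probs = c(alpha / 2, 1 - alpha / 2), na.rm = TRUE, names = FALSE)
  data.frame(metric = cols, mean = colMeans(M, na.rm = TRUE),
             low = qs[1, ], high = qs[2, ], row.names = NULL)
}

#' Format an evaluation table the way segmentation papers print it
#'
#' One row per metric: `mean (low, high)` in percent.
#'
#' @param ci a [bootstrap_ci()] result
#' @param digits decimals (default 1)
#' @return character vector of formatted cells, named by metric
#' @export
format_metrics_row <- function(ci, digits = 1) {
  out <- sprintf(paste0("%.", digits, "f (%.", digits, "f, %.", digits, "f)"),
                 100 * ci$mean, 100 * ci$low, 100 * ci$high)
  stats::setNames(out, ci$metric)
}
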