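# Evaluation battery: confusion matrix, Dice, per-class IoU / mIoU, mean
# recall, the two accuracy variants, HD95, expected calibration error and
# entropy maps.

#' Pixel confusion matrix
#'
#' @param pred,truth Integer arrays of equal shape with class labels in
#'   `0..n_classes-1`.
#' @param n_classes Number of classes (default 2).
#' @return `n_classes` x `n_classes` integer matrix, rows = true class,
#'   columns = predicted class; accumulable across images by addition.
#' @export
confusion <- function(pred, truth, n_classes = 2L) {
  if (!identical(dim(pred), dim(truth)) && length(pred) != length(truth)) {
    stop("pred and truth shapes disagree")
  }
  p <- as.integer(pred)
  t <- as.integer(truth)
  if (any(p < 0L | p >= n_classes) || any(t < 0L | t >= n_classes)) {
    stop("labels out of range 0..", n_classes - 1L)
  }
  cm <- matrix(tabulate(t * n_classes + p + 1L, nbins = n_classes^2),
               n_classes, n_classes, byrow = TRUE)
  dimnames(cm) <- list(true = 0:(n_classes - 1), pred = 0:(n_classes - 1))
  cm
}

#' Dice coefficient of two binary masks
#'
#' `2 |X ∩ Y| / (|X| + |Y|)`; 1 by convention when both masks are empty.
#'
#' @param pred_mask,truth_mask Binary arrays of equal shape.
#' @return Scalar in \[0, 1\].
#' @export
dice <- function(pred_mask, truth_mask) {
  x <- pred_mask > 0
  y <- truth_mask > 0
  s <- sum(x) + sum(y)
  if (s == 0) return(1)
  2 * sum(x & y) / s
}

#' Per-class IoU and mean IoU from a confusion matrix
#'
#' IoU_i = TP_i / (TP_i + FP_i + FN_i).  A class absent from both truth and
#' prediction scores 1 by convention and is flagged via the
#' `"absent_classes"` attribute.
#'
#' @param cm Confusion matrix from [confusion()].
#' @return List with `per_class_iou` and `miou`.
#' @export
miou <- function(cm) {
  n <- nrow(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  denom <- tp + fp + fn
  iou <- ifelse(denom == 0, 1, tp / pmax(denom, 1))
  res <- list(per_class_iou = as.numeric(iou), miou = mean(iou))
  attr(res, "absent_classes") <- which(denom == 0) - 1L
  res
}

#' Mean recall and the two accuracy variants from a confusion matrix
#'
#' `mrecall` macro-averages TP_i / (TP_i + FN_i) over classes present in
#' the truth (absent classes are excluded and flagged).  `accuracy_eq8` is
#' sum(TP) / sum(TP + FP + FN): each misclassified pixel enters the
#' denominator once as an FP and once as an FN, so this differs from the
#' standard `pixel_accuracy` = trace / total, which is reported alongside.
#'
#' @param cm Confusion matrix from [confusion()].
#' @return List with `mrecall`, `accuracy_eq8`, `pixel_accuracy`.
#' @export
mrecall_and_accuracy <- function(cm) {
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  present <- rowSums(cm) > 0
  rec <- tp[present] / (tp[present] + fn[present])
  res <- list(mrecall = mean(rec),
              accuracy_eq8 = sum(tp) / sum(tp + fp + fn),
              pixel_accuracy = sum(tp) / sum(cm))
  attr(res, "empty_true_classes") <- which(!present) - 1L
  res
}

# Boundary pixels: foreground with at least one 4-neighbour outside the
# foreground (image border counts as outside).
boundary_pixels <- function(mask) {
  m <- mask > 0
  d <- dim(m)
  pad <- matrix(FALSE, d[1] + 2L, d[2] + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L)] <- m
  inner <- pad[1:d[1], 2:(d[2] + 1L)] & pad[3:(d[1] + 2L), 2:(d[2] + 1L)] &
    pad[2:(d[1] + 1L), 1:d[2]] & pad[2:(d[1] + 1L), 3:(d[2] + 2L)]
  which(m & !inner, arr.ind = TRUE)
}

#' 95th-percentile Hausdorff boundary distance
#'
#' Pools the directed nearest-neighbour Euclidean distances from each
#' boundary to the other and returns their 95th percentile.  Both masks
#' empty gives 0; exactly one empty returns `Inf`.
#'
#' @param pred_mask,truth_mask Binary arrays of equal shape.
#' @param spacing Optional physical size of one pixel (distances are
#'   multiplied by it); distances are in pixel units when `NULL`.
#' @param percentile Percentile of the pooled distances (default 0.95).
#' @return Non-negative scalar (possibly `Inf`).
#' @export
hd95 <- function(pred_mask, truth_mask, spacing = NULL, percentile = 0.95) {
  pe <- sum(pred_mask > 0) == 0
  te <- sum(truth_mask > 0) == 0
  if (pe && te) return(0)
  if (pe || te) return(Inf)
  a <- boundary_pixels(pred_mask)
  b <- boundary_pixels(truth_mask)
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  pooled <- sqrt(c(apply(d2, 1, min), apply(d2, 2, min)))
  v <- as.numeric(stats::quantile(pooled, percentile, names = FALSE))
  if (!is.null(spacing)) v <- v * spacing
  v
}

#' Expected calibration error of a probability map
#'
#' Pixels are binned by maximum-class confidence into `n_bins` equal-width
#' bins over \[0, 1\]; ECE is the bin-weighted mean absolute gap between
#' confidence and accuracy.
#'
#' @param probs Numeric array (..., C) of per-pixel class probabilities.
#' @param truth Integer array of true labels `0..C-1`, same shape as
#'   `probs` without the class dimension.
#' @param n_bins Number of bins (default 15).
#' @return Scalar in \[0, 1\].
#' @export
ece <- function(probs, truth, n_bins = 15L) {
  d <- dim(probs)
  C <- d[length(d)]
  m <- matrix(probs, ncol = C)
  conf <- do.call(pmax, lapply(seq_len(C), function(c) m[, c]))
  pred <- max.col(m, ties.method = "first") - 1L
  correct <- pred == as.integer(truth)
  bins <- pmin(pmax(ceiling(conf * n_bins), 1L), n_bins)
  nb <- tabulate(bins, n_bins)
  acc <- vapply(seq_len(n_bins), function(b) sum(correct[bins == b]), 1)
  cf <- vapply(seq_len(n_bins), function(b) sum(conf[bins == b]), 1)
  occ <- nb > 0
  sum(nb[occ] / length(conf) * abs(acc[occ] / nb[occ] - cf[occ] / nb[occ]))
}

#' Per-pixel Shannon entropy of a probability map
#'
#' @param probs Numeric array (H, W, C) or (H, W, N, C).
#' @return Array of per-pixel entropies `-sum_c p_c log p_c` (natural log),
#'   bounded by log(C).
#' @export
entropy_map <- function(probs) {
  d <- dim(probs)
  C <- d[length(d)]
  m <- matrix(probs, ncol = C)
  t <- m * log(m)
  t[m == 0] <- 0
  e <- -rowSums(t)
  array(e, d[-length(d)])
}

# Assemble the full battery from accumulated pieces.
new_metric_report <- function(cm, dice_values, hd95_values, ece_value,
                              mean_entropy = NA_real_) {
  mi <- miou(cm)
  ra <- mrecall_and_accuracy(cm)
  tp <- cm[2, 2]; fp <- cm[1, 2]; fn <- cm[2, 1]
  f1 <- if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
  structure(list(
    dice = mean(dice_values),
    miou = mi$miou,
    per_class_iou = mi$per_class_iou,
    mrecall = ra$mrecall,
    accuracy_eq8 = ra$accuracy_eq8,
    pixel_accuracy = ra$pixel_accuracy,
    f1 = f1,
    hd95 = mean(hd95_values[is.finite(hd95_values)]),
    hd95_infinite = sum(!is.finite(hd95_values)),
    ece = ece_value,
    mean_entropy = mean_entropy,
    confusion = cm,
    n_images = length(dice_values)),
    class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("segmentation metrics over %d images\n", x$n_images))
  cat(sprintf("  dice     %.4f   miou %.4f   mrecall %.4f\n",
              x$dice, x$miou, x$mrecall))
  cat(sprintf("  accuracy (eq8) %.4f   pixel accuracy %.4f   f1 %.4f\n",
              x$accuracy_eq8, x$pixel_accuracy, x$f1))
  cat(sprintf("  hd95 %.3f px (%d infinite)   ece %.4f\n",
              x$hd95, x$hd95_infinite, x$ece))
  invisible(x)
}
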