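# Training objective: supervised cross-entropy on labeled pixels plus a
# weighted triplet consistency loss over the (original, weak, strong) views
# of unlabeled images, combined as total = supervised + lambda * triplet.

#' Loss weights
#'
#' @param lambda_u Plateau value of the unsupervised weight lambda.
#' @param alpha,beta,gamma Non-negative weights of the original-weak,
#'   original-strong and weak-strong consistency pairs.
#' @param ramp_epochs Epochs over which lambda ramps from ~0 to `lambda_u`
#'   (sigmoid-shaped); 0 disables the ramp.
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(lambda_u = 1, alpha = 1, beta = 1, gamma = 1,
                         ramp_epochs = 40L) {
  w <- list(lambda_u = lambda_u, alpha = alpha, beta = beta, gamma = gamma,
            ramp_epochs = as.integer(ramp_epochs))
  if (any(unlist(w[1:4]) < 0) || w$ramp_epochs < 0) {
    stop("all loss weights must be non-negative")
  }
  structure(w, class = "loss_weights")
}

#' Mean pixel-wise cross-entropy between logits and a binary mask
#'
#' @param logits Numeric array (H, W, N, 2) of class scores, or (H, W, 2)
#'   for a single image.
#' @param mask Integer array (H, W, N) or (H, W) with values in \{0, 1\}.
#' @return Non-negative scalar: mean over pixels of -log p(true class).
#' @export
supervised_loss <- function(logits, mask) {
  d <- dim(logits)
  if (length(d) == 3L) {
    dim(logits) <- c(d[1], d[2], 1L, d[3])
    dim(mask) <- c(dim(mask), 1L)
    d <- dim(logits)
  }
  if (!all(dim(mask) == d[1:3])) stop("logits and mask shapes disagree")
  if (!all(mask %in% c(0, 1))) stop("mask values must lie in {0, 1}")
  op_softmax_ce(tconst(logits), mask)$v
}

#' Triplet consistency loss over three probability maps
#'
#' Mean over the batch of the weighted pairwise squared L2 distances
#' between the softmax outputs for the original, weakly augmented and
#' strongly augmented views:
#' alpha * ||p_o - p_w||^2 + beta * ||p_o - p_s||^2 + gamma * ||p_w - p_s||^2.
#'
#' @param p_orig,p_weak,p_strong Numeric arrays (H, W, N, C) of per-pixel
#'   class probabilities for the three views of the same N images.
#' @param weights A [loss_weights()].
#' @param distance `"mean"` (default): per-image squared distances are
#'   averaged over pixels and channels, making the loss magnitude
#'   resolution-independent; `"sum"`: plain summed squared differences.
#' @return Non-negative scalar; 0 iff the three maps coincide (for
#'   positive weights).
#' @export
triplet_consistency_loss <- function(p_orig, p_weak, p_strong,
                                     weights = loss_weights(),
                                     distance = c("mean", "sum")) {
  distance <- match.arg(distance)
  d <- dim(p_orig)
  if (!identical(d, dim(p_weak)) || !identical(d, dim(p_strong))) {
    stop("the three probability maps must have identical shapes")
  }
  if (length(d) == 3L) d <- c(d[1], d[2], 1L, d[3])
  M <- d[3]
  red <- function(a, b) {
    s <- sum((a - b)^2)
    if (distance == "mean") s / length(a) else s / M
  }
  weights$alpha * red(p_orig, p_weak) +
    weights$beta * red(p_orig, p_strong) +
    weights$gamma * red(p_weak, p_strong)
}

#' Combine supervised and unsupervised loss components
#'
#' @param sup Supervised loss value.
#' @param unsup Unsupervised (triplet consistency) loss value.
#' @param lambda_effective Current unsupervised weight.
#' @return `sup + lambda_effective * unsup`.
#' @export
total_loss <- function(sup, unsup, lambda_effective) {
  stopifnot(is.finite(sup), is.finite(unsup), is.finite(lambda_effective))
  sup + lambda_effective * unsup
}

#' Unsupervised weight schedule
#'
#' Sigmoid-shaped ramp `lambda_u * exp(-5 (1 - t)^2)` with
#' `t = epoch / ramp_epochs`, clamped to the plateau `lambda_u` from
#' `ramp_epochs` onwards; monotone non-decreasing in `epoch`.
#'
#' @param epoch 0-based epoch index.
#' @param weights A [loss_weights()].
#' @return The effective lambda for this epoch.
#' @export
lambda_schedule <- function(epoch, weights) {
  stopifnot(epoch >= 0)
  r <- weights$ramp_epochs
  if (r == 0L || epoch >= r) return(weights$lambda_u)
  t <- epoch / r
  weights$lambda_u * exp(-5 * (1 - t)^2)
}
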