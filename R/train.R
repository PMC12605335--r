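# Semi-supervised training loop.
#
# Each optimisation step draws a mixed batch: labeled images drive the
# supervised cross-entropy, and for each unlabeled image the (original,
# weak, strong) triple is pushed through the shared network in three
# forward passes to form the triplet consistency loss.  The two terms
# combine as total = supervised + lambda * triplet with a ramped lambda,
# optimised by SGD with momentum under a cosine learning-rate decay.

#' Training configuration
#'
#' Defaults follow the published training recipe: SGD with momentum 0.9,
#' initial learning rate 0.01 decaying to 0.001 (cosine), batch size 8.
#'
#' @param initial_lr,min_lr Cosine learning-rate schedule endpoints.
#' @param batch_size Total images per step (labeled + unlabeled).
#' @param epochs Training epochs.
#' @param momentum SGD momentum.
#' @param labeled_fraction_per_batch Fraction of each batch drawn from the
#'   labeled pool when unlabeled data are present.
#' @param seed Master seed; all stochastic components derive their streams
#'   from it.
#' @param eval_every Evaluate test mIoU (for model selection) every this
#'   many epochs; the best-mIoU state is retained.
#' @param constant_lambda `TRUE` skips the lambda ramp.
#' @param triplet_on_labeled Also apply the consistency loss to labeled
#'   images (off by default).
#' @param verbose Print one line per epoch.
#' @return An object of class `train_config`.
#' @export
train_config <- function(initial_lr = 0.01, min_lr = 0.001,
                         batch_size = 8L, epochs = 200L, momentum = 0.9,
                         labeled_fraction_per_batch = 0.5, seed = 0L,
                         eval_every = 5L, constant_lambda = FALSE,
                         triplet_on_labeled = FALSE, verbose = FALSE) {
  stopifnot(min_lr <= initial_lr, batch_size >= 1, epochs >= 1,
            momentum >= 0, momentum < 1,
            labeled_fraction_per_batch > 0, labeled_fraction_per_batch < 1)
  structure(list(initial_lr = initial_lr, min_lr = min_lr,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), momentum = momentum,
                 labeled_fraction_per_batch = labeled_fraction_per_batch,
                 seed = as.integer(seed), eval_every = as.integer(eval_every),
                 constant_lambda = isTRUE(constant_lambda),
                 triplet_on_labeled = isTRUE(triplet_on_labeled),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

cosine_lr <- function(epoch0, cfg) {
  if (cfg$epochs <= 1L) return(cfg$initial_lr)
  t <- epoch0 / (cfg$epochs - 1L)
  cfg$min_lr + 0.5 * (cfg$initial_lr - cfg$min_lr) * (1 + cos(pi * t))
}

samples_to_batch <- function(samples) {
  d <- dim(samples[[1]]$image)
  x <- array(0, c(d[1], d[2], length(samples), 3L))
  for (i in seq_along(samples)) x[, , i, ] <- samples[[i]]$image / 255
  x
}

masks_to_batch <- function(samples) {
  d <- dim(samples[[1]]$mask)
  m <- array(0L, c(d[1], d[2], length(samples)))
  for (i in seq_along(samples)) m[, , i] <- samples[[i]]$mask
  m
}

#' Fit the semi-supervised segmentation network
#'
#' @param split A [split_dataset()] result; training uses the masks of the
#'   labeled subset only, consistency regularisation uses the remaining
#'   training images without their masks.
#' @param encoder An [encoder_config()].
#' @param decoder A [decoder_config()].
#' @param loss A [loss_weights()].
#' @param train A [train_config()].
#' @return An object of class `lessnet_fit` with the trained model, the
#'   per-epoch loss history, and the selected best state.
#' @export
lessnet <- function(split,
                    encoder = encoder_config("tiny-test"),
                    decoder = decoder_config_tiny(),
                    loss = loss_weights(),
                    train = train_config()) {
  stopifnot(inherits(split, "dataset_split"))
  lab_ids <- split$labeled_ids
  labeled <- Filter(function(s) s$id %in% lab_ids, split$train)
  unlabeled <- Filter(function(s) !(s$id %in% lab_ids), split$train)
  if (length(labeled) == 0L) stop("training requires at least 1 labeled sample")
  if (any(vapply(labeled, function(s) is.null(s$mask), TRUE))) {
    stop("labeled samples must carry masks")
  }
  if (length(unlabeled) > 0L && train$batch_size < 2L) {
    stop("batch_size must be >= 2 when unlabeled data are present")
  }
  d <- dim(labeled[[1]]$image)
  if (d[1] %% 32L != 0L || d[2] %% 32L != 0L) {
    stop("image size must be divisible by 32")
  }

  model <- lessnet_model(encoder, decoder,
                         seed = derive_seed(train$seed, 1L))
  vel <- lapply(model$P, function(p) array(0, dim(p$v) %||% length(p$v)))
  n_lab_b <- if (length(unlabeled) == 0L) train$batch_size else
    max(1L, min(train$batch_size - 1L,
                round(train$batch_size * train$labeled_fraction_per_batch)))
  n_unl_b <- train$batch_size - n_lab_b
  if (length(unlabeled) == 0L) n_unl_b <- 0L
  # one epoch = one pass over the labeled pool (mixed batches resample the
  # unlabeled pool freely)
  steps <- max(1L, ceiling(length(labeled) / n_lab_b))

  wpol <- augmentation_policy("weak")
  spol <- augmentation_policy("strong")
  history <- data.frame(epoch = integer(), lr = double(), lambda = double(),
                        supervised = double(), unsupervised = double(),
                        total = double(), test_miou = double())
  best <- list(miou = -Inf, state = NULL, epoch = NA_integer_)
  draw <- function(pool, k) pool[sample.int(length(pool), k,
                                            replace = k > length(pool))]

  for (epoch in seq_len(train$epochs)) {
    lam <- if (train$constant_lambda) loss$lambda_u else
      lambda_schedule(epoch - 1L, loss)
    lr <- cosine_lr(epoch - 1L, train)
    ep_seed <- derive_seed(train$seed, 1000L + epoch)
    sup_sum <- 0; unsup_sum <- 0; tot_sum <- 0
    for (step in seq_len(steps)) {
      st_seed <- derive_seed(ep_seed, step)
      model$training <- TRUE
      ad_record(TRUE)
      ad_reset_tape()
      parts <- local_seed(st_seed, {
        lb <- draw(labeled, n_lab_b)
        ub <- if (n_unl_b > 0L) draw(unlabeled, n_unl_b) else list()
        vseeds <- sample.int(2^30, 2L)
        list(lb = lb, ub = ub, vseeds = vseeds)
      })
      xl <- samples_to_batch(parts$lb)
      yl <- masks_to_batch(parts$lb)
      use_tri <- (n_unl_b > 0L || train$triplet_on_labeled) && lam > 0
      if (use_tri) {
        uo <- c(parts$ub, if (train$triplet_on_labeled) parts$lb)
        nu <- length(uo)
        xo <- samples_to_batch(uo)
        dh <- dim(xo)[1]; dw <- dim(xo)[2]
        xw <- array(0, dim(xo)); xs <- array(0, dim(xo))
        wmaps <- vector("list", nu); smaps <- vector("list", nu)
        for (i in seq_len(nu)) {
          img <- uo[[i]]$image / 255
          ow <- local_seed(derive_seed(parts$vseeds[1], i),
                           sample_policy_ops(wpol))
          os <- local_seed(derive_seed(parts$vseeds[2], i),
                           sample_policy_ops(spol))
          xw[, , i, ] <- apply_ops(img, NULL, ow)$image
          xs[, , i, ] <- apply_ops(img, NULL, os)$image
          wmaps[[i]] <- alignment_map(dh, dw, ow)
          smaps[[i]] <- alignment_map(dh, dw, os)
        }
        # one combined forward pass: labeled batch plus the three view
        # batches of the unlabeled images
        nl <- dim(xl)[3]
        lg_all <- model_forward(model, op_concat_n(lapply(
          list(xl, xo, xw, xs), tconst)))
        l_sup <- op_softmax_ce(op_slice_n(lg_all, seq_len(nl)), yl)
        p_o <- op_softmax_c(op_slice_n(lg_all, nl + seq_len(nu)))
        # view predictions are inverse-warped to the original frame before
        # the pairwise MSE; out-of-frame pixels carry zero weight
        p_w <- op_warp_batch(op_softmax_c(
          op_slice_n(lg_all, nl + nu + seq_len(nu))), wmaps)
        p_s <- op_warp_batch(op_softmax_c(
          op_slice_n(lg_all, nl + 2L * nu + seq_len(nu))), smaps)
        vmask <- function(maps1, maps2) {
          v <- array(0, c(dh, dw, nu, 2L))
          for (i in seq_len(nu)) {
            vi <- maps1[[i]]$valid
            if (!is.null(maps2)) vi <- vi & maps2[[i]]$valid
            v[, , i, 1] <- vi; v[, , i, 2] <- vi
          }
          v
        }
        wmse <- function(a, b, vm) {
          op_scale(op_sum_all(op_mul(op_square(op_sub(a, b)), tconst(vm))),
                   1 / max(sum(vm), 1))
        }
        l_tri <- op_add(
          op_add(op_scale(wmse(p_o, p_w, vmask(wmaps, NULL)), loss$alpha),
                 op_scale(wmse(p_o, p_s, vmask(smaps, NULL)), loss$beta)),
          op_scale(wmse(p_w, p_s, vmask(wmaps, smaps)), loss$gamma))
      } else {
        l_sup <- op_softmax_ce(model_forward(model, xl), yl)
        l_tri <- tconst(0)
      }
      l_tot <- op_add(l_sup, op_scale(l_tri, lam))
      if (!is.finite(l_tot$v)) {
        stop(sprintf("non-finite loss at epoch %d step %d (sup=%g unsup=%g)",
                     epoch, step, l_sup$v, l_tri$v))
      }
      ad_backward(l_tot)
      for (nm in names(model$P)) {
        p <- model$P[[nm]]
        if (is.null(p$grad)) next
        vel[[nm]] <- train$momentum * vel[[nm]] + p$grad
        p$v <- p$v - lr * vel[[nm]]
        p$grad <- NULL
      }
      ad_reset_tape()
      sup_sum <- sup_sum + l_sup$v
      unsup_sum <- unsup_sum + l_tri$v
      tot_sum <- tot_sum + l_tot$v
    }
    row <- data.frame(epoch = epoch, lr = lr, lambda = lam,
                      supervised = sup_sum / steps,
                      unsupervised = unsup_sum / steps,
                      total = tot_sum / steps, test_miou = NA_real_)
    if (length(split$test) > 0L &&
        (epoch %% train$eval_every == 0L || epoch == train$epochs)) {
      mrep <- evaluate_model(model, split$test)
      row$test_miou <- mrep$miou
      if (mrep$miou > best$miou) {
        best <- list(miou = mrep$miou, state = model_state(model),
                     epoch = epoch)
      }
    }
    history <- rbind(history, row)
    if (train$verbose) {
      message(sprintf(
        "epoch %3d  lr %.4f  lambda %.3f  sup %.4f  unsup %.5f  total %.4f%s",
        epoch, lr, lam, row$supervised, row$unsupervised, row$total,
        if (is.na(row$test_miou)) "" else sprintf("  miou %.4f",
                                                  row$test_miou)))
    }
  }
  if (is.null(best$state)) {
    best <- list(miou = NA_real_, state = model_state(model),
                 epoch = train$epochs)
  }
  structure(list(model = model, history = history, best = best,
                 final_state = model_state(model),
                 encoder_config = model$encoder_config,
                 decoder_config = model$decoder_config,
                 loss_weights = loss, train_config = train,
                 n_labeled = length(labeled),
                 n_unlabeled = length(unlabeled),
                 n_test = length(split$test)),
            class = "lessnet_fit")
}

# Evaluate a live model (current parameters) on samples with masks.
evaluate_model <- function(model, samples, n_bins = 15L,
                           use_state = NULL, chunk = 8L) {
  if (length(samples) == 0L) stop("cannot evaluate on an empty sample list")
  if (any(vapply(samples, function(s) is.null(s$mask), TRUE))) {
    stop("evaluation requires masks on all samples")
  }
  if (!is.null(use_state)) model_load_state(model, use_state)
  model$training <- FALSE
  ad_record(FALSE)
  cm <- matrix(0, 2, 2)
  dices <- c(); hds <- c()
  nb <- numeric(n_bins); accb <- numeric(n_bins); confb <- numeric(n_bins)
  ent_sum <- 0; ent_n <- 0
  idx <- split(seq_along(samples),
               ceiling(seq_along(samples) / chunk))
  for (ii in idx) {
    x <- samples_to_batch(samples[ii])
    probs <- op_softmax_c(model_forward(model, x))$v
    for (k in seq_along(ii)) {
      s <- samples[[ii[k]]]
      p <- probs[, , k, , drop = FALSE]
      dim(p) <- c(dim(probs)[1:2], 2L)
      pred <- (p[, , 2] > p[, , 1]) * 1L
      cm <- cm + confusion(pred, s$mask)
      if (sum(s$mask) > 0) {
        dices <- c(dices, dice(pred, s$mask))
        hds <- c(hds, hd95(pred, s$mask))
      }
      conf <- as.vector(pmax(p[, , 1], p[, , 2]))
      corr <- as.vector(pred == s$mask)
      bins <- pmin(pmax(ceiling(conf * n_bins), 1L), n_bins)
      nb <- nb + tabulate(bins, n_bins)
      accb <- accb + tabulate(bins[corr], n_bins)
      confb <- confb + vapply(seq_len(n_bins),
                              function(b) sum(conf[bins == b]), 1)
      e <- entropy_map(p)
      ent_sum <- ent_sum + sum(e); ent_n <- ent_n + length(e)
    }
  }
  occ <- nb > 0
  ece_val <- sum(nb[occ] / sum(nb) * abs(accb[occ] / nb[occ] -
                                           confb[occ] / nb[occ]))
  new_metric_report(cm, dices, hds, ece_val, ent_sum / ent_n)
}

#' Evaluate a fitted model or checkpoint on labeled samples
#'
#' Runs inference (argmax over the two classes, ties to background),
#' accumulates a global confusion matrix for mIoU / mean recall / accuracy,
#' averages Dice and HD95 per image over images with non-empty truth, and
#' computes ECE and the mean prediction entropy.
#'
#' @param object A `lessnet_fit` or a checkpoint loaded with
#'   [load_checkpoint()].
#' @param samples List of `image_sample` objects with masks.
#' @param use Which parameter state of a fit to use: `"best"` (default) or
#'   `"final"`.
#' @return A `metric_report`.
#' @export
evaluate <- function(object, samples, use = c("best", "final")) {
  use <- match.arg(use)
  stopifnot(inherits(object, "lessnet_fit"))
  st <- if (use == "best") object$best$state else object$final_state
  evaluate_model(object$model, samples, use_state = st)
}

# ---- checkpointing ---------------------------------------------------------

#' Save a fitted model to a checkpoint file
#'
#' A single archive holding the parameter state (best and final), the
#' configuration snapshot and the training history; restoring yields
#' bit-identical evaluation outputs.
#'
#' @param fit A `lessnet_fit`.
#' @param path Target file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "lessnet_fit"))
  saveRDS(list(best = fit$best, final_state = fit$final_state,
               encoder_config = fit$encoder_config,
               decoder_config = fit$decoder_config,
               loss_weights = fit$loss_weights,
               train_config = fit$train_config,
               history = fit$history,
               n_labeled = fit$n_labeled, n_unlabeled = fit$n_unlabeled,
               n_test = fit$n_test),
          path)
  invisible(path)
}

#' Load a checkpoint saved by [save_checkpoint()]
#'
#' @param path Checkpoint file.
#' @return A `lessnet_fit` with a freshly rebuilt model carrying the saved
#'   parameters.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- lessnet_model(ck$encoder_config, ck$decoder_config, seed = 0L)
  model_load_state(model, ck$final_state)
  structure(c(list(model = model), ck), class = "lessnet_fit")
}

# ---- S3 methods ------------------------------------------------------------

#' @export
print.lessnet_fit <- function(x, ...) {
  cat("semi-supervised segmentation fit\n")
  cat(sprintf("  encoder: %s; %.3f M parameters\n",
              x$encoder_config$variant, n_parameters(x$model) / 1e6))
  cat(sprintf("  data: %d labeled + %d unlabeled train, %d test\n",
              x$n_labeled, x$n_unlabeled, x$n_test))
  h <- x$history
  cat(sprintf("  %d epochs; final total loss %.4f (sup %.4f, unsup %.5f)\n",
              nrow(h), h$total[nrow(h)], h$supervised[nrow(h)],
              h$unsupervised[nrow(h)]))
  if (is.finite(x$best$miou)) {
    cat(sprintf("  best test mIoU %.4f at epoch %d\n", x$best$miou,
                x$best$epoch))
  }
  invisible(x)
}

#' @export
summary.lessnet_fit <- function(object, ...) {
  print(object)
  print(profile_model(object$model, c(64L, 64L)))
  invisible(object)
}

#' @export
coef.lessnet_fit <- function(object, ...) {
  lapply(object$best$state$params, identity)
}

#' Predict segmentation masks or probability maps
#'
#' @param object A `lessnet_fit`.
#' @param samples An `image_sample`, a list of them, or an (H, W, 3) / (H,
#'   W, N, 3) array in \[0, 1\].
#' @param type `"mask"` (hard 0/1 labels, ties to background) or `"prob"`
#'   (per-pixel class probabilities).
#' @param use Parameter state: `"best"` or `"final"`.
#' @param ... Unused.
#' @return A list (one element per image) of (H, W) masks or
#'   (H, W, 2) probability arrays.
#' @export
predict.lessnet_fit <- function(object, samples, type = c("mask", "prob"),
                                use = c("best", "final"), ...) {
  type <- match.arg(type)
  use <- match.arg(use)
  if (inherits(samples, "image_sample")) samples <- list(samples)
  if (is.list(samples)) {
    x <- samples_to_batch(samples)
  } else {
    x <- samples
    if (length(dim(x)) == 3L) dim(x) <- c(dim(x)[1:2], 1L, 3L)
  }
  st <- if (use == "best") object$best$state else object$final_state
  model_load_state(object$model, st)
  probs <- model_probs(object$model, x)
  lapply(seq_len(dim(probs)[3]), function(k) {
    p <- probs[, , k, , drop = FALSE]
    dim(p) <- c(dim(probs)[1:2], 2L)
    if (type == "prob") p else (p[, , 2] > p[, , 1]) * 1L
  })
}

#' Plot the training history of a fit
#'
#' Draws the supervised, weighted unsupervised and total loss per epoch,
#' plus the test mIoU where recorded.
#'
#' @param x A `lessnet_fit`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.lessnet_fit <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch,
                    cbind(h$total, h$supervised, h$lambda * h$unsupervised),
                    type = "l", lty = 1, col = c("black", "steelblue",
                                                 "firebrick"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", legend = c("total", "supervised",
                                          "lambda x unsupervised"),
                   col = c("black", "steelblue", "firebrick"), lty = 1,
                   bty = "n")
  if (any(is.finite(h$test_miou))) {
    graphics::par(new = TRUE)
    graphics::plot(h$epoch, h$test_miou, type = "p", pch = 20,
                   col = "darkgreen", axes = FALSE, xlab = "", ylab = "")
    graphics::axis(4)
  }
  invisible(x)
}
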