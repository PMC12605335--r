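# Full segmentation network: encoder + fusion decoder + 2-class head.

#' Assemble the segmentation network
#'
#' Builds the hybrid CNN-Transformer encoder and the multi-scale
#' channel-attention fusion decoder with freshly initialised weights.
#'
#' @param encoder An [encoder_config()].
#' @param decoder A [decoder_config()]; the default pairs the reference
#'   small encoder with the reference decoder widths and matches the
#'   published parameter / GFLOP budget, while `decoder_config_tiny()`
#'   accompanies the `tiny-test` encoder.
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `lessnet_model`.
#' @export
lessnet_model <- function(encoder = encoder_config("small"),
                          decoder = decoder_config(),
                          seed = 0L) {
  M <- model_env()
  local_seed(seed, {
    enc <- build_encoder(M, encoder)
    dec <- build_decoder(M, decoder, enc$channels)
  })
  M$enc <- enc
  M$dec <- dec
  M$encoder_config <- encoder
  M$decoder_config <- decoder
  class(M) <- "lessnet_model"
  M
}

# Forward pass to logits.  batch: (H, W, N, 3) array in [0, 1] or a tnsr.
model_forward <- function(model, batch) {
  x <- if (is_tnsr(batch)) batch else tconst(batch)
  d <- dim(x$v)
  if (d[1] %% 32L != 0L || d[2] %% 32L != 0L) {
    stop("input spatial size ", d[1], "x", d[2], " is not divisible by 32")
  }
  model$dec$fwd(model$enc$fwd(x))
}

# Inference: softmax probabilities (H, W, N, 2), no gradient recording.
model_probs <- function(model, batch) {
  model$training <- FALSE
  ad_record(FALSE)
  op_softmax_c(model_forward(model, batch))$v
}

# Hard prediction per pixel: class 1 only where p(anomaly) strictly exceeds
# p(background); ties resolve to class 0.
probs_to_pred <- function(probs) {
  (probs[, , , 2, drop = FALSE] > probs[, , , 1, drop = FALSE]) * 1L
}

n_parameters <- function(model) {
  sum(vapply(model$P, function(p) length(p$v), 1))
}

#' Profile a model: trainable parameters and forward-pass GFLOPs
#'
#' Parameters are counted exactly from the parameter store.  GFLOPs are
#' accumulated analytically over the network graph at the given input size,
#' counting one multiply-accumulate of convolutions, linear layers and
#' attention matrix products as one operation (the convention of common
#' convolutional-network profilers); normalisation, activations and
#' interpolation are not counted.
#'
#' @param model A `lessnet_model`.
#' @param input_size Integer vector (H, W), both divisible by 32.
#' @return An object of class `model_profile` with fields
#'   `parameters_millions`, `gflops` and `input_size`.
#' @export
profile_model <- function(model, input_size = c(512L, 512L)) {
  stopifnot(inherits(model, "lessnet_model"))
  h <- as.integer(input_size[1])
  w <- as.integer(input_size[2])
  if (h %% 32L != 0L || w %% 32L != 0L) {
    stop("input size must be divisible by 32")
  }
  macs <- model$enc$prof(h, w)$macs + model$dec$prof(h, w)$macs
  structure(list(parameters_millions = n_parameters(model) / 1e6,
                 gflops = macs / 1e9,
                 input_size = c(h, w),
                 convention = "1 MAC = 1 FLOP; conv/linear/attention only"),
            class = "model_profile")
}

#' @export
print.model_profile <- function(x, ...) {
  cat(sprintf("model profile @ %dx%d\n", x$input_size[1], x$input_size[2]))
  cat(sprintf("  parameters: %.3f M\n", x$parameters_millions))
  cat(sprintf("  gflops:     %.3f  (%s)\n", x$gflops, x$convention))
  invisible(x)
}

# ---- parameter state (checkpointing) ---------------------------------------

model_state <- function(model) {
  list(params = lapply(model$P, function(p) p$v),
       bn = lapply(model$bn, function(st) {
         list(mean = st$running_mean, var = st$running_var)
       }))
}

model_load_state <- function(model, state) {
  stopifnot(identical(sort(names(model$P)), sort(names(state$params))))
  for (nm in names(state$params)) model$P[[nm]]$v <- state$params[[nm]]
  for (nm in names(state$bn)) {
    model$bn[[nm]]$running_mean <- state$bn[[nm]]$mean
    model$bn[[nm]]$running_var <- state$bn[[nm]]$var
  }
  invisible(model)
}
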