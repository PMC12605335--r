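# YAML run configuration: one nested document drives every module, and one
# master seed fans out to all stochastic components via derived streams.

#' Default run configuration
#'
#' Nested sections `data`, `augmentation`, `model` (`encoder`, `decoder`),
#' `loss`, `train`, `eval`, plus the master `seed`.  Training defaults
#' mirror the published recipe (lr 0.01 -> 0.001, batch 8, 200 epochs,
#' momentum 0.9, 512x512); the `data` section defaults to the tiny
#' synthetic study so that a default run finishes on a CPU.
#'
#' @return A nested list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    seed = 0L,
    data = list(
      n_images = 250L,
      image_size = 64L,
      lesion_kinds = c("point", "extensive", "trapezoidal", "vessel"),
      lesion_area_fraction_range = c(0.01, 0.2),
      reflection_probability = 0.3,
      blur_probability = 0.2,
      test_fraction = 0.2,
      label_ratio = 0.2),
    augmentation = list(
      offline_factor = 5L,
      weak = list(hflip_probability = 0.5, brightness_delta = 0.1,
                  contrast_factor_range = c(0.9, 1.1)),
      strong = list(hflip_probability = 0.5, brightness_delta = 0.1,
                    contrast_factor_range = c(0.9, 1.1),
                    rotation_limit_deg = 20, saturation_delta = 0.2,
                    hue_delta = 0.05)),
    model = list(
      encoder = list(variant = "tiny-test", width_multiplier = 1,
                     patch_size = 2L),
      decoder = list(preset = "tiny"),
      use_channel_attention = TRUE,
      use_global_fusion = TRUE),
    loss = list(lambda_u = 1, alpha = 1, beta = 1, gamma = 1,
                ramp_epochs = 5L, constant_lambda = FALSE),
    train = list(initial_lr = 0.01, min_lr = 0.001, batch_size = 8L,
                 epochs = 25L, momentum = 0.9,
                 labeled_fraction_per_batch = 0.5, eval_every = 5L),
    eval = list(n_bins = 15L)),
    class = "run_config")
}

check_keys <- function(value, template, path = "") {
  if (!is.list(template) || !is.list(value)) return(invisible(NULL))
  unknown <- setdiff(names(value), names(template))
  if (length(unknown) > 0L) {
    stop("unknown configuration key", if (length(unknown) > 1) "s" else "",
         ": ", paste0(path, unknown, collapse = ", "), call. = FALSE)
  }
  for (nm in names(value)) {
    check_keys(value[[nm]], template[[nm]], paste0(path, nm, "."))
  }
  invisible(NULL)
}

#' Load and validate a YAML run configuration
#'
#' Unknown keys anywhere in the document are rejected with a diagnostic
#' naming the offending key; known keys override the defaults.
#'
#' @param path YAML file, or `NULL` for the defaults.
#' @return A `run_config`.
#' @export
load_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  check_keys(user, cfg)
  merged <- utils::modifyList(cfg, user)
  class(merged) <- "run_config"
  merged
}

#' Write a run configuration as YAML
#'
#' @param config A `run_config`.
#' @param path Target file.
#' @return `path`, invisibly.
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Materialise module-level configuration objects from a run_config.
config_objects <- function(cfg) {
  dc <- cfg$data
  syn <- synthetic_config(
    image_size = dc$image_size, lesion_kinds = dc$lesion_kinds,
    lesion_area_fraction_range = dc$lesion_area_fraction_range,
    reflection_probability = dc$reflection_probability,
    blur_probability = dc$blur_probability,
    seed = derive_seed(cfg$seed, 10L))
  ec <- cfg$model$encoder
  enc <- encoder_config(variant = ec$variant,
                        patch_size = ec$patch_size %||% 2L,
                        width_multiplier = ec$width_multiplier %||% 1)
  dec_args <- cfg$model$decoder
  dec <- if (identical(dec_args$preset, "tiny")) {
    decoder_config_tiny(
      use_channel_attention = cfg$model$use_channel_attention,
      use_global_fusion = cfg$model$use_global_fusion)
  } else {
    do.call(decoder_config,
            c(dec_args[setdiff(names(dec_args), "preset")],
              list(use_channel_attention = cfg$model$use_channel_attention,
                   use_global_fusion = cfg$model$use_global_fusion)))
  }
  lw <- loss_weights(lambda_u = cfg$loss$lambda_u, alpha = cfg$loss$alpha,
                     beta = cfg$loss$beta, gamma = cfg$loss$gamma,
                     ramp_epochs = cfg$loss$ramp_epochs)
  tc <- train_config(
    initial_lr = cfg$train$initial_lr, min_lr = cfg$train$min_lr,
    batch_size = cfg$train$batch_size, epochs = cfg$train$epochs,
    momentum = cfg$train$momentum,
    labeled_fraction_per_batch = cfg$train$labeled_fraction_per_batch,
    seed = derive_seed(cfg$seed, 20L), eval_every = cfg$train$eval_every,
    constant_lambda = cfg$loss$constant_lambda)
  list(synthetic = syn, encoder = enc, decoder = dec, loss = lw, train = tc)
}
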