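# Multi-scale channel-attention fusion decoder.
#
# Instead of U-Net skip concatenation, every encoder level is (i) resized to
# a common resolution, concatenated and projected by a 1x1 convolution into
# a global context feature, and (ii) gated by a channel-attention block
# before entering its decoder stage.  Each decoder stage fuses, by
# element-wise addition after aligning 1x1 convolutions, the upsampled
# previous decoder state, the attention-gated encoder level and the resized
# global feature, then refines the sum with 3x3 convolutions.  Upsampling is
# bilinear throughout (half-pixel convention); a light convolutional head
# emits the 2-class score map, and the final x2 interpolation restores the
# full input resolution.

#' Decoder configuration
#'
#' @param widths Four positive integers: decoder state channels at strides
#'   16, 8, 4, 2 (deep to shallow).
#' @param global_channels Channels of the projected global context feature.
#' @param global_stride Stride at which the global feature is assembled.
#' @param reduction Channel-attention reduction ratio.
#' @param refine Number of 3x3 refinement convolutions per decoder stage
#'   (length 4, deep to shallow).
#' @param head_channels Channels of the 3x3 head convolution.
#' @param full_res_refine Number of 3x3 convolutions applied at full input
#'   resolution after the final upsampling (0 = pure interpolation).
#' @param num_classes Output classes (2: background, anomaly).
#' @param use_channel_attention Ablation switch: `FALSE` replaces the
#'   channel-attention gate with the identity.
#' @param use_global_fusion Ablation switch: `FALSE` drops the global
#'   context branch, degrading the decoder to plain additive upsampling.
#' @return An object of class `decoder_config`.
#' @export
decoder_config <- function(widths = c(496L, 384L, 256L, 160L),
                           global_channels = 512L,
                           global_stride = 4L,
                           reduction = 16L,
                           refine = c(1L, 1L, 1L, 2L),
                           head_channels = 112L,
                           full_res_refine = 2L,
                           num_classes = 2L,
                           use_channel_attention = TRUE,
                           use_global_fusion = TRUE) {
  stopifnot(length(widths) == 4L, length(refine) == 4L)
  structure(list(widths = as.integer(widths),
                 global_channels = as.integer(global_channels),
                 global_stride = as.integer(global_stride),
                 reduction = as.integer(reduction),
                 refine = as.integer(refine),
                 head_channels = as.integer(head_channels),
                 full_res_refine = as.integer(full_res_refine),
                 num_classes = as.integer(num_classes),
                 use_channel_attention = isTRUE(use_channel_attention),
                 use_global_fusion = isTRUE(use_global_fusion)),
            class = "decoder_config")
}

#' Tiny decoder configuration matched to the tiny-test encoder
#'
#' @inheritParams decoder_config
#' @param ... Further overrides passed to [decoder_config()].
#' @return A `decoder_config`.
#' @export
decoder_config_tiny <- function(widths = c(48L, 32L, 24L, 16L),
                                global_channels = 32L, reduction = 8L,
                                head_channels = 16L, full_res_refine = 0L,
                                ...) {
  decoder_config(widths = widths, global_channels = global_channels,
                 reduction = reduction, head_channels = head_channels,
                 full_res_refine = full_res_refine, ...)
}

build_decoder <- function(M, cfg, enc_channels) {
  W <- cfg$widths
  G <- cfg$global_channels
  nc <- cfg$num_classes
  use_g <- cfg$use_global_fusion
  # global context projection over the concatenated, commonly-resized pyramid
  gproj <- if (use_g) {
    conv_bn_act(M, "dec.global", sum(enc_channels), G, 1L)
  } else NULL
  init <- conv_bn_act(M, "dec.init", enc_channels[5], W[1], 1L)
  enc_lv <- c(4L, 3L, 2L, 1L)
  prevW <- c(W[1], W[1], W[2], W[3])
  stages <- lapply(1:4, function(k) {
    nm <- paste0("dec.s", k)
    e <- enc_channels[enc_lv[k]]
    st <- list(
      prev = layer_conv(M, paste0(nm, ".prev"), prevW[k], W[k], 1L),
      ca = if (cfg$use_channel_attention) {
        ca_block(M, paste0(nm, ".ca"), e, cfg$reduction)
      } else NULL,
      enc = layer_conv(M, paste0(nm, ".enc"), e, W[k], 1L),
      glob = if (use_g) layer_conv(M, paste0(nm, ".glob"), G, W[k], 1L),
      bn = layer_bn(M, paste0(nm, ".bn"), W[k]),
      refine = lapply(seq_len(cfg$refine[k]), function(r) {
        conv_bn_act(M, paste0(nm, ".ref", r), W[k], W[k], 3L)
      }))
    st
  })
  head <- conv_bn_act(M, "dec.head", W[4], cfg$head_channels, 3L)
  full <- lapply(seq_len(cfg$full_res_refine), function(r) {
    conv_bn_act(M, paste0("dec.full", r), cfg$head_channels,
                cfg$head_channels, 3L)
  })
  cls <- layer_conv(M, "dec.cls", cfg$head_channels, nc, 1L)

  global_fwd <- function(pyr) {
    gs <- cfg$global_stride
    ref <- which(c(2L, 4L, 8L, 16L, 32L) == gs)
    dg <- dim(pyr[[ref]]$v)
    resized <- lapply(pyr, function(f) op_bilinear(f, dg[1], dg[2]))
    gproj$fwd(op_concat_c(resized))
  }

  list(
    global_fwd = global_fwd,
    fwd = function(pyr) {
      glob <- if (use_g) global_fwd(pyr)
      state <- init$fwd(pyr[[5]])
      for (k in 1:4) {
        st <- stages[[k]]
        e <- pyr[[enc_lv[k]]]
        de <- dim(e$v)
        up <- op_bilinear(state, de[1], de[2])
        acc <- st$prev$fwd(up)
        eg <- if (!is.null(st$ca)) st$ca$fwd(e)$y else e
        acc <- op_add(acc, st$enc$fwd(eg))
        if (use_g) {
          gg <- op_bilinear(glob, de[1], de[2])
          acc <- op_add(acc, st$glob$fwd(gg))
        }
        state <- op_silu(st$bn$fwd(acc))
        for (rf in st$refine) state <- rf$fwd(state)
      }
      ds <- dim(state$v)
      y <- head$fwd(state)
      y <- op_bilinear(y, ds[1] * 2L, ds[2] * 2L)
      for (fr in full) y <- fr$fwd(y)
      cls$fwd(y)
    },
    prof = function(h, w) {
      # h, w: input image size; stage resolutions follow the stride plan
      hw <- function(s) c(h %/% s, w %/% s)
      macs <- 0
      if (use_g) {
        g <- hw(cfg$global_stride)
        macs <- macs + gproj$prof(g[1], g[2])$macs
      }
      i5 <- hw(32L)
      macs <- macs + init$prof(i5[1], i5[2])$macs
      strides <- c(16L, 8L, 4L, 2L)
      for (k in 1:4) {
        st <- stages[[k]]
        r <- hw(strides[k])
        macs <- macs + st$prev$prof(r[1], r[2])$macs
        if (!is.null(st$ca)) macs <- macs + st$ca$prof(r[1], r[2])$macs
        macs <- macs + st$enc$prof(r[1], r[2])$macs
        if (use_g) macs <- macs + st$glob$prof(r[1], r[2])$macs
        for (rf in st$refine) macs <- macs + rf$prof(r[1], r[2])$macs
      }
      r <- hw(2L)
      macs <- macs + head$prof(r[1], r[2])$macs
      for (fr in full) macs <- macs + fr$prof(h, w)$macs
      macs <- macs + cls$prof(h, w)$macs
      list(macs = macs)
    })
}

#' Build the global multi-scale context feature from a pyramid
#'
#' All five pyramid levels are bilinearly resized to the resolution of the
#' level at `target_stride`, concatenated along channels, and projected by a
#' freshly initialised 1x1 convolution (with batch normalisation and SiLU)
#' to `global_channels`.
#'
#' @param pyramid A `feature_pyramid` as returned by [encode()].
#' @param target_stride One of the pyramid strides (default 4).
#' @param global_channels Output channels of the projection.
#' @param seed Integer seed for the projection weights.
#' @return Numeric array (H/stride, W/stride, N, global_channels).
#' @export
build_global_feature <- function(pyramid, target_stride = 4L,
                                 global_channels = 64L, seed = 0L) {
  stopifnot(inherits(pyramid, "feature_pyramid"))
  ref <- which(pyramid$strides == target_stride)
  if (length(ref) != 1L) stop("target_stride must be one of the pyramid strides")
  M <- model_env()
  cin <- sum(vapply(pyramid$levels, function(f) dim(f)[4], 1))
  local_seed(seed,
             proj <- conv_bn_act(M, "gproj", cin, global_channels, 1L))
  M$training <- FALSE
  ad_record(FALSE)
  dg <- dim(pyramid$levels[[ref]])
  resized <- lapply(pyramid$levels,
                    function(f) op_bilinear(tconst(f), dg[1], dg[2]))
  proj$fwd(op_concat_c(resized))$v
}

#' Apply channel attention to a feature map
#'
#' Pools the map along each spatial axis, passes the descriptors through a
#' shared reduction convolution and per-axis expansion convolutions with a
#' sigmoid, and gates the input by the resulting row weights `s_h` and
#' column weights `s_w`.
#'
#' @param feature_map Numeric array (H, W, N, C).
#' @param reduction Channel reduction ratio.
#' @param seed Integer seed for the attention weights.
#' @return List with `output` (gated map), `s_h` (H, 1, N, C) and `s_w`
#'   (1, W, N, C); all gate entries lie strictly in (0, 1).
#' @export
channel_attention <- function(feature_map, reduction = 16L, seed = 0L) {
  d <- dim(feature_map)
  stopifnot(length(d) == 4L)
  M <- model_env()
  local_seed(seed, ca <- ca_block(M, "ca", d[4], reduction))
  M$training <- FALSE
  ad_record(FALSE)
  r <- ca$fwd(tconst(feature_map))
  list(output = r$y$v, s_h = r$s_h$v, s_w = r$s_w$v)
}
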