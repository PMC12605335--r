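# Hybrid CNN-Transformer encoder.
#
# The backbone follows the small MobileViT layout: a strided convolutional
# stem and inverted-residual stages provide the stride-2 and stride-4
# levels; the stride-8/16/32 stages each combine an inverted-residual
# downsampling block with a MobileViT block (local convolution, patch
# transformer, convolutional fusion).  Five intermediate feature maps at
# strides 2, 4, 8, 16, 32 form the feature pyramid consumed by the decoder.

#' Encoder configuration
#'
#' @param variant `"small"` (the reference configuration used by the full
#'   model) or `"tiny-test"` (a narrow configuration for fast CPU
#'   experiments at small image sizes).
#' @param stage_channels Five positive integers: output channels of the
#'   stride-2/4/8/16/32 stages.
#' @param stem_channels Channels of the stride-2 convolutional stem.
#' @param transformer_dims Token widths of the three transformer stages.
#' @param transformer_depths Number of transformer layers per transformer
#'   stage.
#' @param transformer_ffn Hidden widths of the transformer feed-forward
#'   blocks (default twice the token width).
#' @param heads Attention heads (must divide every transformer dim).
#' @param patch_size Transformer patch size in pixels (square).
#' @param expand Expansion factor of the inverted-residual blocks.
#' @param width_multiplier Multiplies all channel plans (rounded to
#'   multiples of 4, minimum 4); 1 keeps the plan as given.
#' @return An object of class `encoder_config`.
#' @export
encoder_config <- function(variant = c("small", "tiny-test"),
                           stage_channels = NULL,
                           stem_channels = NULL,
                           transformer_dims = NULL,
                           transformer_depths = NULL,
                           transformer_ffn = NULL,
                           heads = NULL,
                           patch_size = 2L,
                           expand = NULL,
                           width_multiplier = 1) {
  variant <- match.arg(variant)
  base <- if (variant == "small") {
    list(stem = 16L, ch = c(32L, 64L, 96L, 128L, 160L),
         dims = c(144L, 192L, 240L), depths = c(2L, 4L, 3L),
         heads = 4L, expand = 4L)
  } else {
    list(stem = 8L, ch = c(8L, 16L, 24L, 32L, 48L),
         dims = c(24L, 32L, 48L), depths = c(1L, 1L, 1L),
         heads = 2L, expand = 2L)
  }
  rnd4 <- function(x) pmax(4L, as.integer(round(x / 4) * 4))
  cfg <- list(
    variant = variant,
    stem_channels = as.integer(stem_channels %||% base$stem),
    stage_channels = as.integer(stage_channels %||% base$ch),
    transformer_dims = as.integer(transformer_dims %||% base$dims),
    transformer_depths = as.integer(transformer_depths %||% base$depths),
    heads = as.integer(heads %||% base$heads),
    patch_size = as.integer(patch_size),
    expand = as.integer(expand %||% base$expand),
    width_multiplier = width_multiplier)
  if (width_multiplier != 1) {
    cfg$stem_channels <- rnd4(cfg$stem_channels * width_multiplier)
    cfg$stage_channels <- rnd4(cfg$stage_channels * width_multiplier)
    cfg$transformer_dims <- rnd4(cfg$transformer_dims * width_multiplier)
  }
  cfg$transformer_ffn <-
    as.integer(transformer_ffn %||% (2L * cfg$transformer_dims))
  if (length(cfg$stage_channels) != 5L) {
    stop("stage_channels must have exactly 5 entries")
  }
  if (any(cfg$transformer_dims %% cfg$heads != 0L)) {
    stop("transformer dims must be divisible by the number of heads")
  }
  structure(cfg, class = "encoder_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

build_encoder <- function(M, cfg) {
  ch <- cfg$stage_channels
  dims <- cfg$transformer_dims
  dep <- cfg$transformer_depths
  ffn <- cfg$transformer_ffn
  ex <- cfg$expand
  stem <- conv_bn_act(M, "enc.stem", 3L, cfg$stem_channels, 3L, 2L, 1L)
  s1 <- mv2_block(M, "enc.s1", cfg$stem_channels, ch[1], 1L, ex)
  s2a <- mv2_block(M, "enc.s2a", ch[1], ch[2], 2L, ex)
  s2b <- mv2_block(M, "enc.s2b", ch[2], ch[2], 1L, ex)
  s2c <- mv2_block(M, "enc.s2c", ch[2], ch[2], 1L, ex)
  s3a <- mv2_block(M, "enc.s3a", ch[2], ch[3], 2L, ex)
  s3b <- mobilevit_block(M, "enc.s3b", ch[3], dims[1], dep[1],
                         cfg$patch_size, cfg$heads, ffn[1])
  s4a <- mv2_block(M, "enc.s4a", ch[3], ch[4], 2L, ex)
  s4b <- mobilevit_block(M, "enc.s4b", ch[4], dims[2], dep[2],
                         cfg$patch_size, cfg$heads, ffn[2])
  s5a <- mv2_block(M, "enc.s5a", ch[4], ch[5], 2L, ex)
  s5b <- mobilevit_block(M, "enc.s5b", ch[5], dims[3], dep[3],
                         cfg$patch_size, cfg$heads, ffn[3])
  list(
    fwd = function(x) {
      f1 <- s1$fwd(stem$fwd(x))
      f2 <- s2c$fwd(s2b$fwd(s2a$fwd(f1)))
      f3 <- s3b$fwd(s3a$fwd(f2))
      f4 <- s4b$fwd(s4a$fwd(f3))
      f5 <- s5b$fwd(s5a$fwd(f4))
      list(f1, f2, f3, f4, f5)
    },
    prof = function(h, w) {
      macs <- 0
      p <- stem$prof(h, w)
      macs <- macs + p$macs
      for (blk in list(s1)) {
        p2 <- blk$prof(p$h, p$w); macs <- macs + p2$macs; p <- p2
      }
      h1 <- p$h; w1 <- p$w
      for (blk in list(s2a, s2b, s2c)) {
        p2 <- blk$prof(p$h, p$w); macs <- macs + p2$macs; p <- p2
      }
      for (blk in list(s3a, s3b)) {
        p2 <- blk$prof(p$h, p$w); macs <- macs + p2$macs; p <- p2
      }
      for (blk in list(s4a, s4b)) {
        p2 <- blk$prof(p$h, p$w); macs <- macs + p2$macs; p <- p2
      }
      for (blk in list(s5a, s5b)) {
        p2 <- blk$prof(p$h, p$w); macs <- macs + p2$macs; p <- p2
      }
      list(macs = macs)
    },
    channels = ch,
    strides = c(2L, 4L, 8L, 16L, 32L))
}

#' Run the encoder on a batch of images
#'
#' @param batch Numeric array of shape (H, W, N, 3) with values in
#'   \[0, 1\], H and W divisible by 32.
#' @param config An [encoder_config()].
#' @param seed Integer seed for weight initialisation.
#' @return A `feature_pyramid`: list with `levels` (five arrays in the
#'   (H, W, N, C) layout), `strides` and `channels`.
#' @export
encode <- function(batch, config = encoder_config("tiny-test"), seed = 0L) {
  d <- dim(batch)
  if (length(d) != 4L || d[4] != 3L) {
    stop("batch must be an (H, W, N, 3) array")
  }
  if (d[1] %% 32L != 0L || d[2] %% 32L != 0L) {
    stop("spatial size ", d[1], "x", d[2], " is not divisible by 32")
  }
  M <- model_env()
  local_seed(seed, enc <- build_encoder(M, config))
  M$training <- FALSE
  ad_record(FALSE)
  lv <- enc$fwd(tconst(batch))
  structure(list(levels = lapply(lv, function(t) t$v),
                 strides = enc$strides,
                 channels = enc$channels),
            class = "feature_pyramid")
}
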