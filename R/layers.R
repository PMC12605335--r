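# Layer constructors.
#
# A model is an environment `M` with a flat named parameter store `M$P`, a
# list of batch-norm state environments `M$bn`, and a `training` flag.  Each
# constructor returns a list with a `fwd` closure mapping tnsr to tnsr and a
# `prof` closure mapping an input spatial size to list(macs, h, w) for the
# analytic profiler (multiply-accumulates for one image; norms, activations
# and interpolations are not counted, matching common conv-net profilers).

model_env <- function() {
  M <- new.env(parent = emptyenv())
  M$P <- list()
  M$bn <- list()
  M$training <- TRUE
  M
}

reg_param <- function(M, name, v) {
  if (!is.null(M$P[[name]])) stop("duplicate parameter name: ", name)
  p <- tparam(v)
  M$P[[name]] <- p
  p
}

he_init <- function(fan_in, n) {
  stats::rnorm(n, sd = sqrt(2 / fan_in))
}

layer_conv <- function(M, name, cin, cout, k = 1L, stride = 1L,
                       pad = (k - 1L) %/% 2L) {
  w <- reg_param(M, paste0(name, ".w"),
                 matrix(he_init(k * k * cin, k * k * cin * cout),
                        k * k * cin, cout))
  b <- reg_param(M, paste0(name, ".b"), numeric(cout))
  list(
    fwd = function(x) op_conv2d(x, w, b, k, k, stride, pad),
    prof = function(h, wd) {
      ho <- (h + 2 * pad - k) %/% stride + 1L
      wo <- (wd + 2 * pad - k) %/% stride + 1L
      list(macs = as.numeric(ho) * wo * cout * k * k * cin, h = ho, w = wo)
    },
    out_ch = cout)
}

layer_dwconv <- function(M, name, ch, k = 3L, stride = 1L,
                         pad = (k - 1L) %/% 2L) {
  w <- reg_param(M, paste0(name, ".w"),
                 array(he_init(k * k, k * k * ch), c(k, k, ch)))
  b <- reg_param(M, paste0(name, ".b"), numeric(ch))
  list(
    fwd = function(x) op_dwconv(x, w, b, k, k, stride, pad),
    prof = function(h, wd) {
      ho <- (h + 2 * pad - k) %/% stride + 1L
      wo <- (wd + 2 * pad - k) %/% stride + 1L
      list(macs = as.numeric(ho) * wo * ch * k * k, h = ho, w = wo)
    },
    out_ch = ch)
}

layer_bn <- function(M, name, ch, momentum = 0.1, eps = 1e-5) {
  g <- reg_param(M, paste0(name, ".g"), rep(1, ch))
  b <- reg_param(M, paste0(name, ".b"), numeric(ch))
  st <- new.env(parent = emptyenv())
  st$running_mean <- numeric(ch)
  st$running_var <- rep(1, ch)
  st$momentum <- momentum
  st$eps <- eps
  M$bn[[name]] <- st
  list(
    fwd = function(x) op_batchnorm(x, g, b, st, M$training),
    prof = function(h, wd) list(macs = 0, h = h, w = wd),
    out_ch = ch)
}

layer_ln <- function(M, name, d) {
  g <- reg_param(M, paste0(name, ".g"), rep(1, d))
  b <- reg_param(M, paste0(name, ".b"), numeric(d))
  list(fwd = function(x) op_layernorm(x, g, b))
}

layer_linear <- function(M, name, din, dout) {
  w <- reg_param(M, paste0(name, ".w"),
                 matrix(stats::rnorm(din * dout, sd = sqrt(1 / din)),
                        din, dout))
  b <- reg_param(M, paste0(name, ".b"), numeric(dout))
  list(fwd = function(x) op_linear(x, w, b))
}

# conv -> BN -> SiLU
conv_bn_act <- function(M, name, cin, cout, k = 1L, stride = 1L,
                        pad = (k - 1L) %/% 2L) {
  cv <- layer_conv(M, paste0(name, ".conv"), cin, cout, k, stride, pad)
  bn <- layer_bn(M, paste0(name, ".bn"), cout)
  list(
    fwd = function(x) op_silu(bn$fwd(cv$fwd(x))),
    prof = cv$prof,
    out_ch = cout)
}

# MobileNetV2 inverted residual block: 1x1 expand -> 3x3 depthwise -> 1x1
# project, residual when the shape is preserved.
mv2_block <- function(M, name, cin, cout, stride = 1L, expand = 4L) {
  hid <- cin * expand
  ex <- conv_bn_act(M, paste0(name, ".exp"), cin, hid, 1L)
  dw <- layer_dwconv(M, paste0(name, ".dw"), hid, 3L, stride, 1L)
  dbn <- layer_bn(M, paste0(name, ".dwbn"), hid)
  pr <- layer_conv(M, paste0(name, ".proj"), hid, cout, 1L)
  pbn <- layer_bn(M, paste0(name, ".projbn"), cout)
  res <- stride == 1L && cin == cout
  list(
    fwd = function(x) {
      y <- ex$fwd(x)
      y <- op_silu(dbn$fwd(dw$fwd(y)))
      y <- pbn$fwd(pr$fwd(y))
      if (res) y <- op_add(y, x)
      y
    },
    prof = function(h, wd) {
      a <- ex$prof(h, wd)
      b <- dw$prof(a$h, a$w)
      c3 <- pr$prof(b$h, b$w)
      list(macs = a$macs + b$macs + c3$macs, h = c3$h, w = c3$w)
    },
    out_ch = cout)
}

# Pre-norm transformer encoder layer over token matrices.
transformer_layer <- function(M, name, d, ffn, heads) {
  ln1 <- layer_ln(M, paste0(name, ".ln1"), d)
  qkv <- layer_linear(M, paste0(name, ".qkv"), d, 3L * d)
  proj <- layer_linear(M, paste0(name, ".proj"), d, d)
  ln2 <- layer_ln(M, paste0(name, ".ln2"), d)
  fc1 <- layer_linear(M, paste0(name, ".fc1"), d, ffn)
  fc2 <- layer_linear(M, paste0(name, ".fc2"), ffn, d)
  list(
    fwd = function(x, slen) {
      h <- ln1$fwd(x)
      z <- qkv$fwd(h)
      Tn <- nrow(z$v)
      q <- op_reshape(op_gather_cols(z, 1:d), c(Tn, d))
      k <- op_reshape(op_gather_cols(z, (d + 1):(2 * d)), c(Tn, d))
      v <- op_reshape(op_gather_cols(z, (2 * d + 1):(3 * d)), c(Tn, d))
      att <- op_attention(q, k, v, slen, heads)
      x <- op_add(x, proj$fwd(att))
      x <- op_add(x, fc2$fwd(op_silu(fc1$fwd(ln2$fwd(x)))))
      x
    },
    # tokens = h*w per image; macs counts qkv, attention matmuls, proj, ffn
    prof = function(h, wd, slen) {
      tk <- as.numeric(h) * wd
      list(macs = tk * d * 3 * d + 2 * tk * slen * d + tk * d * d +
             2 * tk * d * ffn)
    })
}

# Column slice of a (T x C) matrix as a differentiable op.
op_gather_cols <- function(a, cols) {
  v <- a$v[, cols, drop = FALSE]
  if (!rec_of(a)) return(tconst(v))
  nc <- ncol(a$v)
  tnsr_new(v, rg = TRUE, bk = function(g) {
    gfull <- matrix(0, nrow(a$v), nc)
    gfull[, cols] <- g
    acc_grad(a, gfull)
  })
}

# MobileViT block: local 3x3 conv -> 1x1 to transformer width -> unfold into
# non-overlapping patches -> transformer over the patch sequence (tokens at
# the same intra-patch offset attend across patches) -> fold back -> 1x1
# conv -> concat with the input -> 3x3 fusion conv.
mobilevit_block <- function(M, name, ch, d, depth, patch = 2L, heads = 4L,
                            ffn = 2L * d) {
  loc <- conv_bn_act(M, paste0(name, ".local"), ch, ch, 3L)
  pre <- layer_conv(M, paste0(name, ".pre"), ch, d, 1L)
  tls <- lapply(seq_len(depth), function(i) {
    transformer_layer(M, paste0(name, ".tf", i), d, ffn, heads)
  })
  lnf <- layer_ln(M, paste0(name, ".lnf"), d)
  post <- conv_bn_act(M, paste0(name, ".post"), d, ch, 1L)
  fuse <- conv_bn_act(M, paste0(name, ".fuse"), 2L * ch, ch, 3L)
  idx_cache <- new.env(parent = emptyenv())
  unfold_idx <- function(H, W, N, p) {
    key <- paste(H, W, N, p)
    if (!is.null(idx_cache[[key]])) return(idx_cache[[key]])
    h <- rep(0:(H - 1), times = W * N)
    w <- rep(rep(0:(W - 1), each = H), times = N)
    n <- rep(0:(N - 1), each = H * W)
    Np <- (H %/% p) * (W %/% p)
    P <- p * p
    np <- (h %/% p) + (H %/% p) * (w %/% p)
    pp <- (h %% p) + p * (w %% p)
    t_of_r <- np + Np * (pp + P * n) + 1L
    idx <- integer(length(t_of_r))
    idx[t_of_r] <- seq_along(t_of_r)   # tokens[t, ] = rows[idx[t], ]
    res <- list(idx = idx, inv = t_of_r, Np = Np)
    idx_cache[[key]] <- res
    res
  }
  list(
    fwd = function(x) {
      dx <- dim(x$v)
      H <- dx[1]; W <- dx[2]; N <- dx[3]
      if (H %% patch != 0L || W %% patch != 0L) {
        stop("feature map size ", H, "x", W,
             " not divisible by patch size ", patch)
      }
      y <- loc$fwd(x)
      y <- pre$fwd(y)
      u <- unfold_idx(H, W, N, patch)
      tok <- op_gather_rows(op_reshape(y, c(H * W * N, d)), u$idx)
      for (tl in tls) tok <- tl$fwd(tok, u$Np)
      tok <- lnf$fwd(tok)
      y <- op_reshape(op_gather_rows(tok, u$inv), c(H, W, N, d))
      y <- post$fwd(y)
      y <- op_concat_c(list(x, y))
      fuse$fwd(y)
    },
    prof = function(h, wd) {
      m <- loc$prof(h, wd)$macs + pre$prof(h, wd)$macs
      slen <- (h %/% patch) * (wd %/% patch)
      for (tl in tls) m <- m + tl$prof(h, wd, slen)$macs
      m <- m + post$prof(h, wd)$macs + fuse$prof(h, wd)$macs
      list(macs = m, h = h, w = wd)
    },
    out_ch = ch)
}

# Channel attention over one feature map: descriptors pooled separately
# along the height and width axes pass through a shared reduction conv and
# per-axis expansion convs with sigmoid, giving row gates s_h and column
# gates s_w that multiply the input (coordinate-attention style).
ca_block <- function(M, name, ch, reduction = 16L) {
  red <- max(4L, ch %/% reduction)
  shared <- layer_conv(M, paste0(name, ".red"), ch, red, 1L)
  sbn <- layer_bn(M, paste0(name, ".redbn"), red)
  exp_h <- layer_conv(M, paste0(name, ".exph"), red, ch, 1L)
  exp_w <- layer_conv(M, paste0(name, ".expw"), red, ch, 1L)
  list(
    fwd = function(x) {
      ph <- op_mean_axis(x, 2L)           # (H, 1, N, C) row descriptor
      pw <- op_mean_axis(x, 1L)           # (1, W, N, C) column descriptor
      rh <- op_silu(sbn$fwd(shared$fwd(ph)))
      rw <- op_silu(sbn$fwd(shared$fwd(pw)))
      s_h <- op_sigmoid(exp_h$fwd(rh))
      s_w <- op_sigmoid(exp_w$fwd(rw))
      list(y = op_gate(op_gate(x, s_h), s_w), s_h = s_h, s_w = s_w)
    },
    prof = function(h, wd) {
      per <- (as.numeric(h) + wd) * (ch * red + red * ch)
      list(macs = per, h = h, w = wd)
    },
    out_ch = ch)
}
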