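# Reverse-mode automatic differentiation over dense arrays.
#
# A tensor node ("tnsr") is an environment holding the value, an optional
# gradient accumulator, and a backward closure that pushes the node's
# gradient onto its parents.  Nodes are appended to a global tape in
# creation order during recording, so walking the tape backwards is a valid
# topological order for backpropagation.  Feature maps use the layout
# (H, W, N, C); token matrices are (tokens x features).

.ad <- new.env(parent = emptyenv())
.ad$on <- FALSE
.ad$tape <- vector("list", 0L)
.ad$i <- 0L

#' Enable or disable gradient recording
#'
#' While recording is off, tensor operations compute values only and keep no
#' backward closures or cached intermediates (inference mode).
#'
#' @param on Logical; record operations onto the tape?
#' @return The previous recording state, invisibly.
#' @keywords internal
ad_record <- function(on) {
  prev <- .ad$on
  .ad$on <- isTRUE(on)
  invisible(prev)
}

ad_reset_tape <- function() {
  .ad$tape <- vector("list", 256L)
  .ad$i <- 0L
  invisible(NULL)
}

tnsr_new <- function(v, rg = FALSE, bk = NULL) {
  n <- new.env(parent = emptyenv())
  n$v <- v
  n$grad <- NULL
  n$rg <- rg
  n$bk <- bk
  class(n) <- "tnsr"
  if (!is.null(bk) && rg && .ad$on) {
    i <- .ad$i + 1L
    if (i > length(.ad$tape)) length(.ad$tape) <- 2L * i
    .ad$tape[[i]] <- n
    .ad$i <- i
  }
  n
}

is_tnsr <- function(x) inherits(x, "tnsr")

#' Create a constant (non-trainable) tensor
#' @param v Numeric array.
#' @keywords internal
tconst <- function(v) tnsr_new(v, rg = FALSE)

#' Create a trainable parameter tensor
#' @param v Numeric array initial value.
#' @keywords internal
tparam <- function(v) tnsr_new(v, rg = TRUE)

rec_of <- function(...) {
  if (!.ad$on) return(FALSE)
  for (p in list(...)) if (p$rg) return(TRUE)
  FALSE
}

acc_grad <- function(node, g) {
  if (!node$rg) return(invisible(NULL))
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

#' Run backpropagation from a scalar loss node
#' @param loss A scalar tnsr produced under recording.
#' @keywords internal
ad_backward <- function(loss) {
  stopifnot(is_tnsr(loss), length(loss$v) == 1L)
  loss$grad <- 1
  if (.ad$i < 1L) return(invisible(NULL))
  for (k in seq(.ad$i, 1L)) {
    n <- .ad$tape[[k]]
    if (!is.null(n$grad) && !is.null(n$bk)) n$bk(n$grad)
  }
  invisible(NULL)
}

# ---- elementwise / structural primitives -----------------------------------

op_add <- function(a, b) {
  v <- a$v + b$v
  if (!rec_of(a, b)) return(tconst(v))
  tnsr_new(v, rg = TRUE, bk = function(g) {
    acc_grad(a, g)
    acc_grad(b, g)
  })
}

# Add a length-C bias vector across the channel (last) dimension of an
# (H, W, N, C) array, or across columns of a (T x C) matrix.
op_bias <- function(a, b) {
  d <- dim(a$v)
  C <- d[length(d)]
  per <- prod(d) / C
  v <- a$v + rep(b$v, each = per)
  if (!rec_of(a, b)) return(tconst(v))
  tnsr_new(v, rg = TRUE, bk = function(g) {
    acc_grad(a, g)
    acc_grad(b, colSums(matrix(g, nrow = per, ncol = C)))
  })
}

op_sub <- function(a, b) {
  v <- a$v - b$v
  if (!rec_of(a, b)) return(tconst(v))
  tnsr_new(v, rg = TRUE, bk = function(g) {
    acc_grad(a, g)
    acc_grad(b, -g)
  })
}

op_mul <- function(a, b) {
  v <- a$v * b$v
  if (!rec_of(a, b)) return(tconst(v))
  tnsr_new(v, rg = TRUE, bk = function(g) {
    acc_grad(a, g * b$v)
    acc_grad(b, g * a$v)
  })
}

op_scale <- function(a, s) {
  v <- a$v * s
  if (!rec_of(a)) return(tconst(v))
  tnsr_new(v, rg = TRUE, bk = function(g) acc_grad(a, g * s))
}

op_square <- function(a) {
  v <- a$v * a$v
  if (!rec_of(a)) return(tconst(v))
  tnsr_new(v, rg = TRUE, bk = function(g) acc_grad(a, 2 * g * a$v))
}

op_mean_all <- function(a) {
  n <- length(a$v)
  v <- sum(a$v) / n
  if (!rec_of(a)) return(tconst(v))
  tnsr_new(v, rg = TRUE, bk = function(g) {
    acc_grad(a, array(g / n, dim(a$v)))
  })
}

op_sum_all <- function(a) {
  v <- sum(a$v)
  if (!rec_of(a)) return(tconst(v))
  tnsr_new(v, rg = TRUE, bk = function(g) acc_grad(a, array(g, dim(a$v))))
}

op_reshape <- function(a, dims) {
  v <- a$v
  od <- dim(v)
  dim(v) <- dims
  if (!rec_of(a)) return(tconst(v))
  tnsr_new(v, rg = TRUE, bk = function(g) {
    dim(g) <- od
    acc_grad(a, g)
  })
}

op_aperm <- function(a, perm) {
  v <- aperm(a$v, perm)
  if (!rec_of(a)) return(tconst(v))
  inv <- order(perm)
  tnsr_new(v, rg = TRUE, bk = function(g) acc_grad(a, aperm(g, inv)))
}

# Gather rows of a (T x C) matrix; idx must be a permutation of 1..T.
op_gather_rows <- function(a, idx) {
  v <- a$v[idx, , drop = FALSE]
  if (!rec_of(a)) return(tconst(v))
  inv <- integer(length(idx))
  inv[idx] <- seq_along(idx)
  tnsr_new(v, rg = TRUE, bk = function(g) acc_grad(a, g[inv, , drop = FALSE]))
}

# Concatenate (H, W, N, Ci) arrays along the channel axis (contiguous in the
# chosen layout, so this is a plain value concatenation).
op_concat_c <- function(xs) {
  ds <- lapply(xs, function(x) dim(x$v))
  cc <- vapply(ds, function(d) d[4], 1)
  v <- array(unlist(lapply(xs, function(x) as.vector(x$v)), use.names = FALSE),
             dim = c(ds[[1]][1:3], sum(cc)))
  if (!do.call(rec_of, xs)) return(tconst(v))
  sz <- vapply(ds, prod, 1)
  ends <- cumsum(sz)
  starts <- c(1, ends[-length(ends)] + 1)
  tnsr_new(v, rg = TRUE, bk = function(g) {
    gv <- as.vector(g)
    for (k in seq_along(xs)) {
      gk <- gv[starts[k]:ends[k]]
      dim(gk) <- ds[[k]]
      acc_grad(xs[[k]], gk)
    }
  })
}

# ---- nonlinearities --------------------------------------------------------

op_sigmoid <- function(a) {
  v <- 1 / (1 + exp(-a$v))
  if (!rec_of(a)) return(tconst(v))
  tnsr_new(v, rg = TRUE, bk = function(g) acc_grad(a, g * v * (1 - v)))
}

op_silu <- function(a) {
  v <- cpp_silu(a$v)
  dim(v) <- dim(a$v)
  if (!rec_of(a)) return(tconst(v))
  tnsr_new(v, rg = TRUE, bk = function(g) {
    gx <- cpp_silu_bwd(a$v, g)
    dim(gx) <- dim(a$v)
    acc_grad(a, gx)
  })
}

op_relu <- function(a) {
  v <- pmax(a$v, 0)
  dim(v) <- dim(a$v)
  if (!rec_of(a)) return(tconst(v))
  m <- a$v > 0
  tnsr_new(v, rg = TRUE, bk = function(g) acc_grad(a, g * m))
}

# Softmax over the last (channel) dimension of an (H, W, N, C) array.
op_softmax_c <- function(a) {
  d <- dim(a$v)
  C <- d[length(d)]
  m <- matrix(a$v, ncol = C)
  mx <- m[, 1]
  for (cc in seq_len(C)[-1]) mx <- pmax(mx, m[, cc])
  m <- m - mx
  e <- exp(m)
  p <- e / rowSums(e)
  v <- array(p, d)
  if (!rec_of(a)) return(tconst(v))
  tnsr_new(v, rg = TRUE, bk = function(g) {
    gm <- matrix(g, ncol = C)
    dot <- rowSums(gm * p)
    ga <- p * (gm - dot)
    dim(ga) <- d
    acc_grad(a, ga)
  })
}

# ---- dense algebra ---------------------------------------------------------

op_matmul <- function(a, b) {
  v <- a$v %*% b$v
  if (!rec_of(a, b)) return(tconst(v))
  tnsr_new(v, rg = TRUE, bk = function(g) {
    acc_grad(a, g %*% t(b$v))
    acc_grad(b, crossprod(a$v, g))
  })
}

# Linear layer on a (T x d_in) token matrix.
op_linear <- function(x, w, b) op_bias(op_matmul(x, w), b)

# ---- convolution and resampling (compiled kernels) -------------------------

# Full convolution via im2col + GEMM.  x: (H, W, N, C) tnsr; w: (kh*kw*Cin x
# Cout) tnsr; b: length-Cout tnsr.
op_conv2d <- function(x, w, b, kh, kw, stride = 1L, pad = 0L) {
  d <- dim(x$v)
  H <- d[1]; W <- d[2]; N <- d[3]; C <- d[4]
  Ho <- (H + 2 * pad - kh) %/% stride + 1L
  Wo <- (W + 2 * pad - kw) %/% stride + 1L
  one <- kh == 1L && kw == 1L && stride == 1L && pad == 0L
  cols <- if (one) {
    matrix(x$v, nrow = H * W * N, ncol = C)   # a 1x1 conv is a plain GEMM
  } else {
    cpp_im2col(x$v, H, W, N, C, kh, kw, stride, stride, pad, pad)
  }
  Cout <- ncol(w$v)
  y <- cols %*% w$v
  y <- y + rep(b$v, each = nrow(y))
  dim(y) <- c(Ho, Wo, N, Cout)
  if (!rec_of(x, w, b)) return(tconst(y))
  tnsr_new(y, rg = TRUE, bk = function(g) {
    gm <- matrix(g, ncol = Cout)
    acc_grad(b, colSums(gm))
    acc_grad(w, crossprod(cols, gm))
    if (x$rg) {
      gcols <- gm %*% t(w$v)
      gx <- if (one) gcols else
        cpp_col2im(gcols, H, W, N, C, kh, kw, stride, stride, pad, pad)
      dim(gx) <- d
      acc_grad(x, gx)
    }
  })
}

# Depthwise convolution; w: (kh*kw*C) tnsr (ky fastest), b: length-C tnsr.
op_dwconv <- function(x, w, b, kh, kw, stride = 1L, pad = 0L) {
  d <- dim(x$v)
  H <- d[1]; W <- d[2]; N <- d[3]; C <- d[4]
  Ho <- (H + 2 * pad - kh) %/% stride + 1L
  Wo <- (W + 2 * pad - kw) %/% stride + 1L
  y <- cpp_dwconv(x$v, H, W, N, C, w$v, b$v,
                  kh, kw, stride, stride, pad, pad)
  dim(y) <- c(Ho, Wo, N, C)
  if (!rec_of(x, w, b)) return(tconst(y))
  tnsr_new(y, rg = TRUE, bk = function(g) {
    r <- cpp_dwconv_bwd(x$v, g, H, W, N, C,
                        w$v, kh, kw, stride, stride, pad, pad)
    gx <- r$gx; dim(gx) <- d
    acc_grad(x, gx)
    acc_grad(w, array(r$gw, dim(w$v)))
    acc_grad(b, r$gb)
  })
}

# Bilinear resize of an (H, W, N, C) array to (Ho, Wo); half-pixel centers,
# align_corners = FALSE, applied consistently everywhere in the package.
op_bilinear <- function(x, Ho, Wo) {
  d <- dim(x$v)
  if (d[1] == Ho && d[2] == Wo) return(x)
  v <- cpp_bilinear(x$v, d[1], d[2], d[3], d[4], Ho, Wo)
  dim(v) <- c(Ho, Wo, d[3], d[4])
  if (!rec_of(x)) return(tconst(v))
  tnsr_new(v, rg = TRUE, bk = function(g) {
    gx <- cpp_bilinear_bwd(g, d[1], d[2], d[3], d[4], Ho, Wo)
    dim(gx) <- d
    acc_grad(x, gx)
  })
}

# ---- normalisation ---------------------------------------------------------

# Batch normalisation over (H, W, N) per channel.  `layer` is an environment
# carrying running_mean / running_var / momentum / eps and a training flag.
op_batchnorm <- function(x, gamma, beta, layer, training) {
  d <- dim(x$v)
  C <- d[4]
  per <- prod(d[1:3])
  xv <- x$v
  if (training) {
    st <- cpp_bn_stats(xv, per, C)
    mu <- st$mu
    va <- st$va
    layer$running_mean <- (1 - layer$momentum) * layer$running_mean +
      layer$momentum * mu
    layer$running_var <- (1 - layer$momentum) * layer$running_var +
      layer$momentum * va
  } else {
    mu <- layer$running_mean
    va <- layer$running_var
  }
  istd <- 1 / sqrt(va + layer$eps)
  a <- istd * gamma$v
  y <- cpp_affine_c(xv, per, C, a, beta$v - mu * a)
  dim(y) <- d
  if (!rec_of(x, gamma, beta)) return(tconst(y))
  tnsr_new(y, rg = TRUE, bk = function(g) {
    r <- cpp_bn_bwd(xv, g, per, C, mu, istd, gamma$v, training)
    acc_grad(beta, r$gbeta)
    acc_grad(gamma, r$ggamma)
    if (x$rg) {
      gx <- r$gx
      dim(gx) <- d
      acc_grad(x, gx)
    }
  })
}

# Layer normalisation across the feature (column) dimension of (T x d).
op_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  xm <- x$v
  dd <- ncol(xm)
  mu <- rowMeans(xm)
  xc <- xm - mu
  va <- rowMeans(xc * xc)
  istd <- 1 / sqrt(va + eps)
  xhat <- xc * istd
  y <- sweep(xhat, 2, gamma$v, "*")
  y <- sweep(y, 2, beta$v, "+")
  if (!rec_of(x, gamma, beta)) return(tconst(y))
  tnsr_new(y, rg = TRUE, bk = function(g) {
    acc_grad(beta, colSums(g))
    acc_grad(gamma, colSums(g * xhat))
    if (x$rg) {
      gxhat <- sweep(g, 2, gamma$v, "*")
      sg <- rowMeans(gxhat)
      sgx <- rowMeans(gxhat * xhat)
      gx <- (gxhat - sg - xhat * sgx) * istd
      acc_grad(x, gx)
    }
  })
}

# ---- pooling ---------------------------------------------------------------

# Mean over one spatial axis of (H, W, N, C): axis 1 pools rows away
# (result (1, W, N, C)), axis 2 pools columns away (result (H, 1, N, C)).
op_mean_axis <- function(x, axis) {
  d <- dim(x$v)
  if (axis == 1L) {
    m <- colMeans(matrix(x$v, nrow = d[1]))
    v <- array(m, c(1L, d[2], d[3], d[4]))
  } else {
    a <- aperm(x$v, c(2, 1, 3, 4))
    m <- colMeans(matrix(a, nrow = d[2]))
    v <- array(m, c(d[1], 1L, d[3], d[4]))
  }
  if (!rec_of(x)) return(tconst(v))
  tnsr_new(v, rg = TRUE, bk = function(g) {
    if (axis == 1L) {
      gx <- array(rep(as.vector(g) / d[1], each = d[1]), d)
    } else {
      ga <- array(rep(as.vector(aperm(g, c(2, 1, 3, 4))) / d[2],
                      each = d[2]), c(d[2], d[1], d[3], d[4]))
      gx <- aperm(ga, c(2, 1, 3, 4))
    }
    acc_grad(x, gx)
  })
}

# Broadcast-multiply a feature map by an axis gate: s has size 1 along the
# broadcast axis (1 => gate constant over rows, 2 => over columns).
op_gate <- function(x, s) {
  d <- dim(x$v)
  ds <- dim(s$v)
  sv <- s$v
  if (ds[1] == 1L && d[1] > 1L) {
    sb <- array(rep(as.vector(sv), each = d[1]), d)
  } else if (ds[2] == 1L && d[2] > 1L) {
    sb <- aperm(array(rep(as.vector(aperm(sv, c(2, 1, 3, 4))), each = d[2]),
                      c(d[2], d[1], d[3], d[4])), c(2, 1, 3, 4))
  } else {
    sb <- sv
  }
  v <- x$v * sb
  if (!rec_of(x, s)) return(tconst(v))
  tnsr_new(v, rg = TRUE, bk = function(g) {
    acc_grad(x, g * sb)
    if (s$rg) {
      gs <- g * x$v
      if (ds[1] == 1L && d[1] > 1L) {
        gsum <- array(colSums(matrix(gs, nrow = d[1])),
                      c(1L, d[2], d[3], d[4]))
      } else if (ds[2] == 1L && d[2] > 1L) {
        ga <- aperm(gs, c(2, 1, 3, 4))
        gsum <- aperm(array(colSums(matrix(ga, nrow = d[2])),
                            c(1L, d[1], d[3], d[4])), c(2, 1, 3, 4))
      } else {
        gsum <- gs
      }
      acc_grad(s, gsum)
    }
  })
}

# ---- attention -------------------------------------------------------------

# Multi-head self-attention over contiguous row blocks of length `seq_len`
# in (T x d) token matrices q, k, v (already projected).  Heads split the
# feature dimension evenly.
op_attention <- function(q, k, v, slen, heads) {
  Tn <- nrow(q$v)
  dmod <- ncol(q$v)
  dh <- dmod %/% heads
  nb <- Tn %/% slen
  scale <- 1 / sqrt(dh)
  out <- matrix(0, Tn, dmod)
  rec <- rec_of(q, k, v)
  Acache <- if (rec) vector("list", nb * heads) else NULL
  for (b in seq_len(nb)) {
    rows <- ((b - 1) * slen + 1):(b * slen)
    for (h in seq_len(heads)) {
      cols <- ((h - 1) * dh + 1):(h * dh)
      Q <- q$v[rows, cols, drop = FALSE]
      K <- k$v[rows, cols, drop = FALSE]
      S <- tcrossprod(Q, K) * scale
      S <- S - apply(S, 1, max)
      E <- exp(S)
      A <- E / rowSums(E)
      out[rows, cols] <- A %*% v$v[rows, cols, drop = FALSE]
      if (rec) Acache[[(b - 1) * heads + h]] <- A
    }
  }
  if (!rec) return(tconst(out))
  tnsr_new(out, rg = TRUE, bk = function(g) {
    gq <- matrix(0, Tn, dmod); gk <- gq; gv <- gq
    for (b in seq_len(nb)) {
      rows <- ((b - 1) * slen + 1):(b * slen)
      for (h in seq_len(heads)) {
        cols <- ((h - 1) * dh + 1):(h * dh)
        A <- Acache[[(b - 1) * heads + h]]
        G <- g[rows, cols, drop = FALSE]
        V <- v$v[rows, cols, drop = FALSE]
        gv[rows, cols] <- crossprod(A, G)
        gA <- tcrossprod(G, V)
        dot <- rowSums(gA * A)
        gS <- A * (gA - dot) * scale
        gq[rows, cols] <- gS %*% k$v[rows, cols, drop = FALSE]
        gk[rows, cols] <- crossprod(gS, q$v[rows, cols, drop = FALSE])
      }
    }
    acc_grad(q, gq)
    acc_grad(k, gk)
    acc_grad(v, gv)
  })
}

# ---- losses ----------------------------------------------------------------

# Fused softmax + cross-entropy against integer class targets.
# logits: (H, W, N, C) tnsr; target: (H, W, N) array with values 0..C-1.
op_softmax_ce <- function(logits, target) {
  d <- dim(logits$v)
  C <- d[4]
  per <- prod(d[1:3])
  m <- matrix(logits$v, nrow = per, ncol = C)
  mx <- m[, 1]
  for (cc in seq_len(C)[-1]) mx <- pmax(mx, m[, cc])
  e <- exp(m - mx)
  se <- rowSums(e)
  p <- e / se
  idx <- cbind(seq_len(per), as.integer(target) + 1L)
  nll <- (log(se) + mx) - m[idx]
  v <- mean(nll)
  if (!rec_of(logits)) return(tconst(v))
  tnsr_new(v, rg = TRUE, bk = function(g) {
    gp <- p
    gp[idx] <- gp[idx] - 1
    gp <- gp * (g / per)
    dim(gp) <- d
    acc_grad(logits, gp)
  })
}

# Differentiable per-image warp of an (H, W, N, C) tensor under
# precomputed gather maps (one alignment map per image), used to bring
# view predictions back to the original frame before the consistency
# loss.  Linear in x; the backward pass scatter-adds through the same
# weights.
op_warp_batch <- function(x, maps) {
  d <- dim(x$v)
  H <- d[1]; W <- d[2]; N <- d[3]; C <- d[4]
  P <- H * W
  v <- array(0, d)
  xm <- matrix(x$v, ncol = N * C)   # (H*W) x (N*C), plane-major columns
  vm <- matrix(0, P, N * C)
  colsel <- function(n) n + N * (seq_len(C) - 1L)
  for (n in seq_len(N)) {
    mp <- maps[[n]]
    cs <- colsel(n)
    xn <- xm[, cs, drop = FALSE]
    acc <- mp$w[, 1] * xn[mp$idx[, 1], , drop = FALSE]
    for (k in 2:4) {
      acc <- acc + mp$w[, k] * xn[mp$idx[, k], , drop = FALSE]
    }
    vm[, cs] <- acc
  }
  v <- array(vm, d)
  if (!rec_of(x)) return(tconst(v))
  tnsr_new(v, rg = TRUE, bk = function(g) {
    gm <- matrix(g, ncol = N * C)
    gx <- matrix(0, P, N * C)
    for (n in seq_len(N)) {
      mp <- maps[[n]]
      cs <- colsel(n)
      gn <- gm[, cs, drop = FALSE]
      for (k in 1:4) {
        r <- rowsum(gn * mp$w[, k], mp$idx[, k])
        ri <- as.integer(rownames(r))
        gx[ri, cs] <- gx[ri, cs] + r
      }
    }
    dim(gx) <- d
    acc_grad(x, gx)
  })
}

# Slice images (3rd axis) out of an (H, W, N, C) tensor.
op_slice_n <- function(x, idx) {
  d <- dim(x$v)
  v <- x$v[, , idx, , drop = FALSE]
  if (!rec_of(x)) return(tconst(v))
  tnsr_new(v, rg = TRUE, bk = function(g) {
    gx <- array(0, d)
    gx[, , idx, ] <- g
    acc_grad(x, gx)
  })
}

# Concatenate (H, W, Ni, C) tensors along the image axis.
op_concat_n <- function(xs) {
  ds <- lapply(xs, function(x) dim(x$v))
  ns <- vapply(ds, function(d) d[3], 1L)
  N <- sum(ns)
  d1 <- ds[[1]]
  v <- array(0, c(d1[1], d1[2], N, d1[4]))
  off <- 0L
  for (x in xs) {
    n <- dim(x$v)[3]
    v[, , (off + 1L):(off + n), ] <- x$v
    off <- off + n
  }
  if (!do.call(rec_of, xs)) return(tconst(v))
  offs <- cumsum(c(0L, ns))
  tnsr_new(v, rg = TRUE, bk = function(g) {
    for (k in seq_along(xs)) {
      acc_grad(xs[[k]], g[, , (offs[k] + 1L):(offs[k + 1L]), , drop = FALSE])
    }
  })
}
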