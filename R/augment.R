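# Weak/strong view policies and the offline dataset-expansion operator.
#
# Geometry (flips, rotation, scaling, translation) is applied identically
# to image and mask: bilinear resampling with reflected borders for the
# image, nearest-neighbour with background fill for the mask, so masks stay
# strictly binary.  Photometric operations (brightness, contrast,
# saturation, hue) never touch the mask.

#' Augmentation policy
#'
#' The weak policy applies random horizontal flips and minor brightness /
#' contrast adjustments; the strong policy is a superset adding substantial
#' rotations (up to 20 degrees) and shifts in saturation and hue.
#'
#' @param strength `"weak"` or `"strong"`.
#' @param hflip_probability Probability of a horizontal flip.
#' @param brightness_delta Brightness offset drawn from ± this value.
#' @param contrast_factor_range Contrast factor interval.
#' @param rotation_limit_deg Rotation angle drawn uniformly from ± this
#'   limit (degrees); must be 0 for the weak policy.
#' @param saturation_delta Saturation offset bound; 0 for weak.
#' @param hue_delta Hue offset bound (fraction of the hue circle); 0 for
#'   weak.
#' @return An object of class `augmentation_policy`.
#' @export
augmentation_policy <- function(strength = c("weak", "strong"),
                                hflip_probability = 0.5,
                                brightness_delta = 0.1,
                                contrast_factor_range = c(0.9, 1.1),
                                rotation_limit_deg = NULL,
                                saturation_delta = NULL,
                                hue_delta = NULL) {
  strength <- match.arg(strength)
  if (strength == "weak") {
    rotation_limit_deg <- rotation_limit_deg %||% 0
    saturation_delta <- saturation_delta %||% 0
    hue_delta <- hue_delta %||% 0
    if (rotation_limit_deg != 0 || saturation_delta != 0 || hue_delta != 0) {
      stop("the weak policy must have zero rotation/saturation/hue limits")
    }
  } else {
    rotation_limit_deg <- rotation_limit_deg %||% 20
    saturation_delta <- saturation_delta %||% 0.2
    hue_delta <- hue_delta %||% 0.05
  }
  stopifnot(is_prob(hflip_probability), brightness_delta >= 0,
            length(contrast_factor_range) == 2L,
            contrast_factor_range[1] <= contrast_factor_range[2],
            rotation_limit_deg >= 0, saturation_delta >= 0, hue_delta >= 0)
  structure(list(strength = strength,
                 hflip_probability = hflip_probability,
                 brightness_delta = brightness_delta,
                 contrast_factor_range = as.numeric(contrast_factor_range),
                 rotation_limit_deg = rotation_limit_deg,
                 saturation_delta = saturation_delta,
                 hue_delta = hue_delta),
            class = "augmentation_policy")
}

# Reflect an out-of-range 1-based index back into 1..n.
reflect_idx <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * n - 2L
  j <- (i - 1L) %% p
  j <- ifelse(j < 0L, j + p, j)
  as.integer(ifelse(j >= n, p - j, j) + 1L)
}

# Inverse-mapped affine warp about the image centre.
# A maps output coords to source coords: src = A %*% (dst - c) + c + shift.
affine_warp <- function(plane_list, A, shift = c(0, 0),
                        interp = c("bilinear", "nearest"), fill = 0) {
  interp <- match.arg(interp)
  d <- dim(plane_list[[1]])
  H <- d[1]; W <- d[2]
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  ys <- rep(seq_len(H), times = W) - cy
  xs <- rep(seq_len(W), each = H) - cx
  sy <- A[1, 1] * ys + A[1, 2] * xs + cy + shift[1]
  sx <- A[2, 1] * ys + A[2, 2] * xs + cx + shift[2]
  if (interp == "nearest") {
    ry <- round(sy); rx <- round(sx)
    ok <- ry >= 1 & ry <= H & rx >= 1 & rx <= W
    idx <- (pmin(pmax(rx, 1), W) - 1) * H + pmin(pmax(ry, 1), H)
    lapply(plane_list, function(p) {
      v <- p[idx]
      v[!ok] <- fill
      matrix(v, H, W)
    })
  } else {
    y0 <- floor(sy); x0 <- floor(sx)
    fy <- sy - y0; fx <- sx - x0
    iy0 <- reflect_idx(y0, H); iy1 <- reflect_idx(y0 + 1, H)
    ix0 <- reflect_idx(x0, W); ix1 <- reflect_idx(x0 + 1, W)
    i00 <- (ix0 - 1L) * H + iy0; i10 <- (ix0 - 1L) * H + iy1
    i01 <- (ix1 - 1L) * H + iy0; i11 <- (ix1 - 1L) * H + iy1
    lapply(plane_list, function(p) {
      v <- p[i00] * (1 - fy) * (1 - fx) + p[i10] * fy * (1 - fx) +
        p[i01] * (1 - fy) * fx + p[i11] * fy * fx
      matrix(v, H, W)
    })
  }
}

# Vectorised HSV -> RGB (h, s, v in [0, 1]).
hsv_to_rgb <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6) %% 6
  f <- h6 - floor(h6)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
        ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
        ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
        ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  list(r = r, g = g, b = b)
}

# Core augmentation on a double image in [0, 1] (H, W, 3) and an optional
# integer mask; `ops` is a list of sampled operation parameters.
apply_ops <- function(img, mask, ops) {
  if (isTRUE(ops$hflip)) {
    img <- img[, dim(img)[2]:1, , drop = FALSE]
    if (!is.null(mask)) mask <- mask[, ncol(mask):1, drop = FALSE]
  }
  if (isTRUE(ops$vflip)) {
    img <- img[dim(img)[1]:1, , , drop = FALSE]
    if (!is.null(mask)) mask <- mask[nrow(mask):1, , drop = FALSE]
  }
  ang <- ops$angle %||% 0
  sc <- ops$scale %||% 1
  shift <- ops$shift %||% c(0, 0)
  if (ang != 0 || sc != 1 || any(shift != 0)) {
    th <- ang * pi / 180
    A <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2) / sc
    planes <- affine_warp(list(img[, , 1], img[, , 2], img[, , 3]),
                          A, shift, "bilinear")
    img <- array(c(planes[[1]], planes[[2]], planes[[3]]), dim(img))
    if (!is.null(mask)) {
      mask <- affine_warp(list(mask), A, shift, "nearest", fill = 0)[[1]]
      storage.mode(mask) <- "integer"
    }
  }
  if (!is.null(ops$brightness) && ops$brightness != 0) {
    img <- img + ops$brightness
  }
  if (!is.null(ops$contrast) && ops$contrast != 1) {
    img <- (img - 0.5) * ops$contrast + 0.5
  }
  if ((ops$sat %||% 0) != 0 || (ops$hue %||% 0) != 0) {
    img <- clamp01(img)
    hsv <- grDevices::rgb2hsv(rbind(as.vector(img[, , 1]),
                                    as.vector(img[, , 2]),
                                    as.vector(img[, , 3])),
                              maxColorValue = 1)
    rgb <- hsv_to_rgb(hsv[1, ] + (ops$hue %||% 0),
                      clamp01(hsv[2, ] + (ops$sat %||% 0)), hsv[3, ])
    img <- array(c(rgb$r, rgb$g, rgb$b), dim(img))
  }
  list(image = clamp01(img), mask = mask)
}

sample_policy_ops <- function(policy) {
  ops <- list(
    hflip = stats::runif(1) < policy$hflip_probability,
    brightness = stats::runif(1, -policy$brightness_delta,
                              policy$brightness_delta),
    contrast = stats::runif(1, policy$contrast_factor_range[1],
                            policy$contrast_factor_range[2]))
  if (policy$rotation_limit_deg > 0) {
    ops$angle <- stats::runif(1, -policy$rotation_limit_deg,
                              policy$rotation_limit_deg)
  }
  if (policy$saturation_delta > 0) {
    ops$sat <- stats::runif(1, -policy$saturation_delta,
                            policy$saturation_delta)
  }
  if (policy$hue_delta > 0) {
    ops$hue <- stats::runif(1, -policy$hue_delta, policy$hue_delta)
  }
  ops
}

augment_sample <- function(sample, policy, seed, new_id = sample$id) {
  img <- sample$image / 255
  res <- local_seed(seed, apply_ops(img, sample$mask,
                                    sample_policy_ops(policy)))
  new_image_sample(new_id,
                   array(as.integer(round(res$image * 255)),
                         dim(sample$image)),
                   res$mask)
}

#' Weakly augment a sample (the view generator t)
#'
#' Random horizontal flip plus minor brightness and contrast adjustment;
#' the mask follows the geometry exactly and is untouched by photometric
#' operations.
#'
#' @param sample An `image_sample`.
#' @param seed Integer seed; identical seeds give identical outputs.
#' @param policy A weak [augmentation_policy()].
#' @return The augmented `image_sample` (same spatial size).
#' @export
weak_augment <- function(sample, seed,
                         policy = augmentation_policy("weak")) {
  augment_sample(sample, policy, seed)
}

#' Strongly augment a sample (the view generator T)
#'
#' The weak transforms plus a substantial rotation (uniform within the
#' rotation limit, default 20 degrees) and saturation/hue shifts.  The mask
#' is rotated with nearest-neighbour resampling and stays binary.
#'
#' @inheritParams weak_augment
#' @param policy A strong [augmentation_policy()].
#' @return The augmented `image_sample`.
#' @export
strong_augment <- function(sample, seed,
                           policy = augmentation_policy("strong")) {
  augment_sample(sample, policy, seed)
}

#' Offline dataset expansion
#'
#' Returns the original samples plus `factor - 1` augmented variants per
#' sample (default expansion factor 5, matching 405 -> 2025).  Each variant
#' applies one random composition drawn from horizontal/vertical flips,
#' rotation, random scaling, translation, and brightness/contrast
#' adjustment; masks are transformed consistently.
#'
#' @param samples List of `image_sample` objects, all with masks.
#' @param seed Integer seed.
#' @param factor Total expansion factor (>= 1).
#' @return List of `length(samples) * factor` samples; variants carry ids
#'   `<id>-a<k>`.
#' @export
expand_offline <- function(samples, seed = 0L, factor = 5L) {
  stopifnot(is_count(factor), factor >= 1)
  if (length(samples) == 0L) return(list())
  if (any(vapply(samples, function(s) is.null(s$mask), TRUE))) {
    stop("offline expansion requires a mask on every sample")
  }
  out <- vector("list", length(samples) * factor)
  j <- 0L
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    out[[j <- j + 1L]] <- s
    for (k in seq_len(factor - 1L)) {
      ops <- local_seed(derive_seed(seed, i * 131L + k), {
        o <- list(hflip = stats::runif(1) < 0.5,
                  vflip = stats::runif(1) < 0.5,
                  brightness = stats::runif(1, -0.1, 0.1),
                  contrast = stats::runif(1, 0.9, 1.1))
        if (stats::runif(1) < 0.7) o$angle <- stats::runif(1, -20, 20)
        if (stats::runif(1) < 0.5) o$scale <- stats::runif(1, 0.9, 1.1)
        if (stats::runif(1) < 0.5) {
          o$shift <- stats::runif(2, -0.1, 0.1) * dim(s$image)[1:2]
        }
        o
      })
      res <- apply_ops(s$image / 255, s$mask, ops)
      out[[j <- j + 1L]] <- new_image_sample(
        paste0(s$id, "-a", k),
        array(as.integer(round(res$image * 255)), dim(s$image)),
        res$mask)
    }
  }
  out
}

# ---- prediction alignment for consistency training -------------------------

# Map taking a per-pixel field predicted in a view's geometry back to the
# original frame: for original pixel (i, j), sample the view at the
# forward-transformed location (bilinear; out-of-bounds pixels are marked
# invalid).  Only the geometric part of an op set (hflip, rotation) is
# relevant; photometric ops do not move pixels.
alignment_map <- function(H, W, ops) {
  stopifnot(is.null(ops$vflip) || !isTRUE(ops$vflip),
            is.null(ops$scale), is.null(ops$shift))
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  ys <- rep(seq_len(H), times = W)
  xs <- rep(seq_len(W), each = H)
  if (isTRUE(ops$hflip)) xs <- W + 1L - xs
  ang <- ops$angle %||% 0
  if (ang != 0) {
    th <- ang * pi / 180
    # inverse of the warp matrix used in apply_ops (A = R(th), sc = 1)
    Ai <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    sy <- Ai[1, 1] * (ys - cy) + Ai[1, 2] * (xs - cx) + cy
    sx <- Ai[2, 1] * (ys - cy) + Ai[2, 2] * (xs - cx) + cx
  } else {
    sy <- ys; sx <- xs
  }
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  valid <- y0 >= 1 & (y0 + 1) <= H & x0 >= 1 & (x0 + 1) <= W
  cl <- function(v, n) pmin(pmax(v, 1L), n)
  i00 <- as.integer((cl(x0, W) - 1) * H + cl(y0, H))
  i10 <- as.integer((cl(x0, W) - 1) * H + cl(y0 + 1, H))
  i01 <- as.integer((cl(x0 + 1, W) - 1) * H + cl(y0, H))
  i11 <- as.integer((cl(x0 + 1, W) - 1) * H + cl(y0 + 1, H))
  w00 <- (1 - fy) * (1 - fx) * valid
  w10 <- fy * (1 - fx) * valid
  w01 <- (1 - fy) * fx * valid
  w11 <- fy * fx * valid
  list(idx = cbind(i00, i10, i01, i11), w = cbind(w00, w10, w01, w11),
       valid = valid)
}

# Apply an alignment map to one plane (numeric matrix), e.g. in tests.
apply_alignment <- function(plane, map) {
  v <- map$w[, 1] * plane[map$idx[, 1]] + map$w[, 2] * plane[map$idx[, 2]] +
    map$w[, 3] * plane[map$idx[, 3]] + map$w[, 4] * plane[map$idx[, 4]]
  matrix(v, nrow(plane), ncol(plane))
}
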