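# Seeded generator of endoscopy-like RGB frames with ground-truth bleeding
# masks, plus the train/test split and label-ratio machinery.
#
# The renderer emulates the condition taxonomy of the nasal bleeding
# setting: reddish irregular lesions (point-like, extensive, trapezoidal,
# vessel-shaped) on a textured pink-orange mucosa background, with optional
# near-saturated specular reflections and whole-frame blur as distractors
# (never labeled foreground).

#' Synthetic dataset configuration
#'
#' @param image_size Side length in pixels of the square frames.
#' @param lesion_kinds Subset of `"point"`, `"extensive"`, `"trapezoidal"`,
#'   `"vessel"`; one kind is drawn uniformly per image.
#' @param lesion_area_fraction_range Interval (lo, hi) with
#'   0 < lo <= hi < 1: the lesion area fraction of each mask is drawn
#'   uniformly from it (and guaranteed to stay inside it).
#' @param reflection_probability Probability of adding specular patches.
#' @param blur_probability Probability of blurring the whole frame.
#' @param seed Integer seed; identical configurations generate identical
#'   pixel data.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(image_size = 512L,
                             lesion_kinds = c("point", "extensive",
                                              "trapezoidal", "vessel"),
                             lesion_area_fraction_range = c(0.01, 0.2),
                             reflection_probability = 0.3,
                             blur_probability = 0.2,
                             seed = 0L) {
  r <- lesion_area_fraction_range
  if (length(r) != 2L || !all(is.finite(r)) || r[1] <= 0 || r[2] < r[1] ||
      r[2] >= 1) {
    stop("invalid lesion_area_fraction_range: need 0 < lo <= hi < 1")
  }
  lesion_kinds <- match.arg(lesion_kinds, several.ok = TRUE)
  if (!is_count(image_size) || image_size < 8) {
    stop("image_size must be a positive integer >= 8")
  }
  if (!is_prob(reflection_probability) || !is_prob(blur_probability)) {
    stop("probabilities must lie in [0, 1]")
  }
  structure(list(image_size = as.integer(image_size),
                 lesion_kinds = lesion_kinds,
                 lesion_area_fraction_range = as.numeric(r),
                 reflection_probability = reflection_probability,
                 blur_probability = blur_probability,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# One image sample: 8-bit RGB image, optional binary mask, identifier.
new_image_sample <- function(id, image, mask = NULL) {
  structure(list(id = id, image = image, mask = mask),
            class = "image_sample")
}

#' @export
print.image_sample <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("image_sample '%s' %dx%d%s\n", x$id, d[1], d[2],
              if (is.null(x$mask)) " (no mask)"
              else sprintf(", mask fg %.3f", mean(x$mask))))
  invisible(x)
}

# Fast approximate gaussian blur: three box-blur passes per axis via
# cumulative sums.
box_blur1 <- function(m, r) {
  if (r < 1) return(m)
  n <- nrow(m)
  idx_hi <- pmin(seq_len(n) + r, n)
  idx_lo <- pmax(seq_len(n) - r - 1L, 0L)
  cs <- apply(m, 2, cumsum)
  cs0 <- rbind(0, cs)
  (cs0[idx_hi + 1L, , drop = FALSE] - cs0[idx_lo + 1L, , drop = FALSE]) /
    (idx_hi - idx_lo)
}

blur2d <- function(m, sigma) {
  r <- max(1L, as.integer(round(sigma)))
  for (i in 1:3) {
    m <- box_blur1(m, r)
    m <- t(box_blur1(t(m), r))
  }
  m
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Continuous lesion "field" per kind; higher values = more lesion-like.
lesion_field <- function(kind, S) {
  xs <- matrix(rep(seq_len(S), each = S), S, S) / S   # column coord
  ys <- matrix(rep(seq_len(S), times = S), S, S) / S  # row coord
  bump <- function(cx, cy, sx, sy, th) {
    xr <- (xs - cx) * cos(th) + (ys - cy) * sin(th)
    yr <- -(xs - cx) * sin(th) + (ys - cy) * cos(th)
    exp(-(xr^2 / sx^2 + yr^2 / sy^2))
  }
  f <- matrix(0, S, S)
  if (kind == "point") {
    for (i in seq_len(sample(1:3, 1))) {
      f <- pmax(f, bump(stats::runif(1, 0.25, 0.75),
                        stats::runif(1, 0.25, 0.75),
                        stats::runif(1, 0.03, 0.10),
                        stats::runif(1, 0.03, 0.10),
                        stats::runif(1, 0, pi)))
    }
  } else if (kind == "extensive") {
    for (i in seq_len(sample(3:6, 1))) {
      f <- pmax(f, bump(stats::runif(1, 0.3, 0.7), stats::runif(1, 0.3, 0.7),
                        stats::runif(1, 0.12, 0.30),
                        stats::runif(1, 0.12, 0.30),
                        stats::runif(1, 0, pi)))
    }
  } else if (kind == "trapezoidal") {
    # warped quadrilateral, softened by blurring its rasterisation
    cx <- stats::runif(1, 0.35, 0.65); cy <- stats::runif(1, 0.35, 0.65)
    ang <- sort(stats::runif(4, 0, 2 * pi))
    rad <- stats::runif(4, 0.12, 0.30)
    px <- cx + rad * cos(ang); py <- cy + rad * sin(ang)
    inside <- matrix(FALSE, S, S)
    j <- 4L
    for (i in 1:4) {  # even-odd rule point-in-polygon, vectorised
      cond <- ((py[i] > ys) != (py[j] > ys)) &
        (xs < (px[j] - px[i]) * (ys - py[i]) / (py[j] - py[i]) + px[i])
      inside <- xor(inside, cond)
      j <- i
    }
    f <- blur2d(inside * 1, S / 40)
  } else { # vessel: smooth thick polyline
    nseg <- 6L
    pts <- matrix(0, nseg + 1L, 2L)
    pts[1, ] <- stats::runif(2, 0.25, 0.75)
    th <- stats::runif(1, 0, 2 * pi)
    for (i in seq_len(nseg)) {
      th <- th + stats::runif(1, -0.8, 0.8)
      pts[i + 1L, ] <- pts[i, ] + 0.12 * c(cos(th), sin(th))
    }
    pts <- clamp01(pts)
    dmin <- matrix(Inf, S, S)
    for (i in seq_len(nseg)) {
      a <- pts[i, ]; b <- pts[i + 1L, ]
      ab <- b - a
      len2 <- sum(ab^2) + 1e-12
      t <- clamp01(((xs - a[1]) * ab[1] + (ys - a[2]) * ab[2]) / len2)
      dmin <- pmin(dmin, (xs - a[1] - t * ab[1])^2 + (ys - a[2] - t * ab[2])^2)
    }
    w <- stats::runif(1, 0.015, 0.04)
    f <- exp(-dmin / w^2)
  }
  # tiny jitter breaks ties so thresholding selects an exact pixel count
  f + matrix(stats::runif(S * S), S, S) * 1e-9
}

render_sample <- function(id, cfg) {
  S <- cfg$image_size
  r <- cfg$lesion_area_fraction_range
  # mucosa background: directional pink-orange gradient + smooth texture
  th <- stats::runif(1, 0, 2 * pi)
  g <- outer(seq_len(S) / S, seq_len(S) / S,
             function(y, x) x * cos(th) + y * sin(th))
  g <- (g - min(g)) / (max(g) - min(g) + 1e-12)
  tex <- blur2d(matrix(stats::runif(S * S), S, S), S / 16)
  tex <- (tex - min(tex)) / (max(tex) - min(tex) + 1e-12)
  base_r <- 0.75 + 0.15 * g + 0.08 * tex
  base_g <- 0.42 + 0.12 * g + 0.10 * tex
  base_b <- 0.40 + 0.08 * g + 0.08 * tex
  img <- array(0, c(S, S, 3))
  img[, , 1] <- base_r; img[, , 2] <- base_g; img[, , 3] <- base_b

  # lesion mask with exact pixel-count control
  kind <- if (length(cfg$lesion_kinds) == 1L) cfg$lesion_kinds else
    sample(cfg$lesion_kinds, 1L)
  f <- lesion_field(kind, S)
  frac <- stats::runif(1, r[1], r[2])
  k <- min(max(round(frac * S * S), ceiling(r[1] * S * S)),
           floor(r[2] * S * S))
  thr <- sort(f, decreasing = TRUE)[k]
  mask <- (f >= thr) * 1L
  dim(mask) <- c(S, S)

  # paint the lesion: dark red band with soft edges and pixel noise
  alpha <- clamp01(blur2d(mask * 1, max(1, S / 128)))
  lr <- 0.50 + 0.10 * tex
  lg <- 0.08 + 0.06 * tex
  lb <- 0.08 + 0.05 * tex
  img[, , 1] <- img[, , 1] * (1 - alpha) + lr * alpha
  img[, , 2] <- img[, , 2] * (1 - alpha) + lg * alpha
  img[, , 3] <- img[, , 3] * (1 - alpha) + lb * alpha

  # specular reflections: near-saturated patches, background only
  if (stats::runif(1) < cfg$reflection_probability) {
    for (i in seq_len(sample(1:3, 1))) {
      rf <- lesion_field("point", S)
      rmask <- rf > stats::quantile(rf, 1 - stats::runif(1, 0.002, 0.01))
      rmask <- rmask & mask == 0L
      for (ch in 1:3) {
        pl <- img[, , ch]
        pl[rmask] <- stats::runif(1, 0.95, 1.0)
        img[, , ch] <- pl
      }
    }
  }
  img <- img + array(stats::rnorm(S * S * 3, sd = 0.015), c(S, S, 3))
  if (stats::runif(1) < cfg$blur_probability) {
    for (ch in 1:3) img[, , ch] <- blur2d(img[, , ch], max(1, S / 64))
  }
  img8 <- array(as.integer(round(clamp01(img) * 255)), c(S, S, 3))
  new_image_sample(id, img8, mask)
}

#' Generate a synthetic endoscopy dataset
#'
#' @param n Number of samples (>= 0).
#' @param config A [synthetic_config()].
#' @return List of `image_sample` objects, each with a binary mask;
#'   repeated calls with the same configuration are identical.
#' @export
generate_dataset <- function(n, config = synthetic_config()) {
  stopifnot(is_count(n))
  if (!inherits(config, "synthetic_config")) {
    stop("config must be a synthetic_config object")
  }
  if (n == 0L) return(list())
  local_seed(config$seed, {
    lapply(seq_len(n), function(i) {
      render_sample(sprintf("synth%04d", i), config)
    })
  })
}

#' Split samples into train/test with a labeled subset
#'
#' Shuffles deterministically, holds out `test_fraction` of the samples,
#' and marks `floor(label_ratio * n_train)` training samples (drawn
#' uniformly) as labeled.
#'
#' @param samples List of `image_sample` objects.
#' @param test_fraction Fraction held out for testing (0 < f < 1).
#' @param label_ratio Fraction of the training subset whose masks are
#'   visible to the supervised loss (0 < r <= 1).
#' @param seed Integer seed.
#' @return An object of class `dataset_split` with fields `train`, `test`,
#'   `labeled_ids`, `label_ratio`.
#' @export
split_dataset <- function(samples, test_fraction = 0.2, label_ratio = 0.5,
                          seed = 0L) {
  if (length(samples) == 0L) stop("cannot split an empty sample list")
  if (!(test_fraction > 0 && test_fraction < 1)) {
    stop("test_fraction must lie strictly in (0, 1)")
  }
  if (!(label_ratio > 0 && label_ratio <= 1)) {
    stop("label_ratio must lie in (0, 1]")
  }
  n <- length(samples)
  ids <- vapply(samples, function(s) s$id, "")
  if (anyDuplicated(ids)) stop("sample ids must be unique")
  local_seed(seed, {
    ord <- sample.int(n)
    n_train <- floor(n * (1 - test_fraction) + 1e-9)
    n_train <- min(max(n_train, 1L), n - 1L)
    train <- samples[ord[seq_len(n_train)]]
    test <- samples[ord[(n_train + 1L):n]]
    n_lab <- floor(label_ratio * n_train + 1e-9)
    if (n_lab < 1L) {
      stop("label_ratio ", label_ratio, " yields zero labeled samples ",
           "after rounding; at least 1 is required")
    }
    lab_idx <- sample.int(n_train, n_lab)
    labeled_ids <- vapply(train[lab_idx], function(s) s$id, "")
  })
  structure(list(train = train, test = test, labeled_ids = labeled_ids,
                 label_ratio = label_ratio),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("dataset_split: %d train (%d labeled, ratio %.3g), %d test\n",
              length(x$train), length(x$labeled_ids), x$label_ratio,
              length(x$test)))
  invisible(x)
}

# ---- dataset directory I/O -------------------------------------------------

#' Write samples (and optionally a split manifest) to a dataset directory
#'
#' Layout: `<root>/images/<id>.png`, `<root>/masks/<id>.png` (mask PNGs
#' store 0/255) and, when a split is given, `<root>/manifest.json` listing
#' train/test/labeled ids.
#'
#' @param samples List of `image_sample` objects.
#' @param root Target directory (created if needed).
#' @param split Optional `dataset_split` over these samples.
#' @return `root`, invisibly.
#' @export
write_dataset <- function(samples, root, split = NULL) {
  dir.create(file.path(root, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(root, "masks"), recursive = TRUE,
             showWarnings = FALSE)
  for (s in samples) {
    png::writePNG(s$image / 255,
                  file.path(root, "images", paste0(s$id, ".png")))
    if (!is.null(s$mask)) {
      png::writePNG(s$mask * 1.0,
                    file.path(root, "masks", paste0(s$id, ".png")))
    }
  }
  if (!is.null(split)) {
    man <- list(
      train = vapply(split$train, function(s) s$id, ""),
      test = vapply(split$test, function(s) s$id, ""),
      labeled = split$labeled_ids,
      label_ratio = split$label_ratio)
    jsonlite::write_json(man, file.path(root, "manifest.json"),
                         auto_unbox = FALSE, pretty = TRUE)
  }
  invisible(root)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param root Dataset directory.
#' @return List with `samples` (all samples, masks attached when present)
#'   and `split` (a `dataset_split`, or `NULL` without a manifest).
#' @export
read_dataset <- function(root) {
  files <- sort(list.files(file.path(root, "images"), pattern = "\\.png$"))
  samples <- lapply(files, function(f) {
    id <- sub("\\.png$", "", f)
    img <- png::readPNG(file.path(root, "images", f))
    img8 <- array(as.integer(round(img * 255)), dim(img))
    mp <- file.path(root, "masks", f)
    mask <- NULL
    if (file.exists(mp)) {
      m <- png::readPNG(mp)
      if (length(dim(m)) == 3L) m <- m[, , 1]
      mask <- (m > 0.5) * 1L
      dim(mask) <- dim(m)[1:2]
    }
    new_image_sample(id, img8, mask)
  })
  names(samples) <- vapply(samples, function(s) s$id, "")
  split <- NULL
  mf <- file.path(root, "manifest.json")
  if (file.exists(mf)) {
    man <- jsonlite::read_json(mf, simplifyVector = TRUE)
    split <- structure(list(train = unname(samples[man$train]),
                            test = unname(samples[man$test]),
                            labeled_ids = man$labeled,
                            label_ratio = man$label_ratio),
                       class = "dataset_split")
  }
  list(samples = unname(samples), split = split)
}
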