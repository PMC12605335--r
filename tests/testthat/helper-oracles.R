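# Brute-force reference implementations (naive per-pixel loops) used as
# independent oracles for the metric suite, plus tiny fixture builders.

oracle_confusion <- function(pred, truth, n = 2L) {
  cm <- matrix(0L, n, n)
  for (i in seq_along(pred)) {
    cm[truth[i] + 1L, pred[i] + 1L] <- cm[truth[i] + 1L, pred[i] + 1L] + 1L
  }
  cm
}

oracle_dice <- function(pred, truth) {
  inter <- 0L; a <- 0L; b <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] > 0 && truth[i] > 0) inter <- inter + 1L
    if (pred[i] > 0) a <- a + 1L
    if (truth[i] > 0) b <- b + 1L
  }
  if (a + b == 0L) 1 else 2 * inter / (a + b)
}

oracle_iou <- function(cm) {
  n <- nrow(cm)
  iou <- numeric(n)
  for (i in seq_len(n)) {
    tp <- cm[i, i]
    fp <- sum(cm[, i]) - tp
    fn <- sum(cm[i, ]) - tp
    iou[i] <- if (tp + fp + fn == 0) 1 else tp / (tp + fp + fn)
  }
  iou
}

oracle_boundary <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  out <- NULL
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (mask[i, j] > 0) {
      nb <- c(if (i > 1) mask[i - 1, j] else 0,
              if (i < H) mask[i + 1, j] else 0,
              if (j > 1) mask[i, j - 1] else 0,
              if (j < W) mask[i, j + 1] else 0)
      if (any(nb == 0)) out <- rbind(out, c(i, j))
    }
  }
  out
}

oracle_hd95 <- function(pred, truth, percentile = 0.95) {
  if (sum(pred) == 0 && sum(truth) == 0) return(0)
  if (sum(pred) == 0 || sum(truth) == 0) return(Inf)
  a <- oracle_boundary(pred); b <- oracle_boundary(truth)
  da <- apply(a, 1, function(p) {
    min(apply(b, 1, function(q) sqrt(sum((p - q)^2))))
  })
  db <- apply(b, 1, function(p) {
    min(apply(a, 1, function(q) sqrt(sum((p - q)^2))))
  })
  as.numeric(stats::quantile(c(da, db), percentile, names = FALSE))
}

oracle_ece <- function(probs, truth, n_bins = 15L) {
  C <- dim(probs)[3]
  npx <- prod(dim(probs)[1:2])
  conf <- numeric(npx); correct <- logical(npx)
  pm <- matrix(probs, ncol = C)
  tv <- as.integer(truth)
  for (i in seq_len(npx)) {
    conf[i] <- max(pm[i, ])
    correct[i] <- (which.max(pm[i, ]) - 1L) == tv[i]
  }
  tot <- 0
  for (b in seq_len(n_bins)) {
    lo <- (b - 1) / n_bins; hi <- b / n_bins
    sel <- if (b == 1L) conf <= hi else conf > lo & conf <= hi
    if (any(sel)) {
      tot <- tot + sum(sel) / npx * abs(mean(correct[sel]) - mean(conf[sel]))
    }
  }
  tot
}

oracle_entropy <- function(p) {
  s <- 0
  for (v in p) if (v > 0) s <- s - v * log(v)
  s
}

random_mask <- function(h = 8L, w = 8L) {
  matrix(sample(0:1, h * w, replace = TRUE, prob = c(0.6, 0.4)), h, w)
}

random_probmap <- function(h = 8L, w = 8L) {
  a <- matrix(runif(h * w), h, w)
  array(c(1 - a, a), c(h, w, 2L))
}

# One flat test image with a given mask (values 0..255).
flat_sample <- function(id, mask, value = 128L) {
  img <- array(value, c(dim(mask), 3L))
  lessnet:::new_image_sample(id, img, mask)
}

tiny_sample_set <- function(n, size = 64L, seed = 42L) {
  generate_dataset(n, synthetic_config(image_size = size, seed = seed))
}
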