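# Metric battery against hand-worked examples and brute-force oracles.

test_that("confusion matrix matches enumeration and conserves pixels", {
  pred <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(unname(confusion(pred, pred)), diag(c(2L, 2L)))

  # 10 pixels, 6 background / 4 foreground, one flip in each direction
  truth <- c(rep(0L, 6), rep(1L, 4))
  pr <- truth
  pr[1] <- 1L   # background -> foreground
  pr[7] <- 0L   # foreground -> background
  expect_equal(unname(confusion(pr, truth)),
               matrix(c(5L, 1L, 1L, 3L), 2, 2, byrow = TRUE))

  m <- random_mask(5, 7)
  expect_equal(sum(confusion(random_mask(5, 7), m)), 35L)
  expect_error(confusion(matrix(2, 2, 2), matrix(0, 2, 2)), "out of range")
})

test_that("dice handles perfect, disjoint, partial and empty cases", {
  a <- matrix(0L, 4, 4); a[1:2, 1:2] <- 1L     # |X| = 4
  b <- matrix(0L, 4, 4); b[1:2, 2:3] <- 1L     # |Y| = 4, overlap 2
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, 1L - a), 0)
  expect_equal(dice(a, b), 0.5)
  expect_equal(dice(matrix(0L, 3, 3), matrix(0L, 3, 3)), 1)
})

test_that("miou and recall/accuracy match hand arithmetic", {
  cm <- matrix(c(5, 1, 1, 3), 2, 2, byrow = TRUE)
  mi <- miou(cm)
  expect_equal(mi$per_class_iou, c(5 / 7, 3 / 5))
  expect_equal(mi$miou, (5 / 7 + 3 / 5) / 2)

  ra <- mrecall_and_accuracy(cm)
  expect_equal(ra$mrecall, mean(c(5 / 6, 3 / 4)))
  expect_equal(ra$mrecall, 19 / 24)
  expect_equal(ra$accuracy_eq8, 8 / 12)   # each error is one FP + one FN
  expect_equal(ra$pixel_accuracy, 0.8)

  perfect <- matrix(c(7, 0, 0, 3), 2, 2, byrow = TRUE)
  expect_equal(miou(perfect)$miou, 1)
  expect_equal(mrecall_and_accuracy(perfect)$accuracy_eq8, 1)

  # foreground IoU from toy masks: |X ∩ Y| = 2, |X ∪ Y| = 6
  a <- matrix(0L, 4, 4); a[1, 1:4] <- 1L
  b <- matrix(0L, 4, 4); b[1, 3:4] <- 1L; b[2, 1:2] <- 1L
  expect_equal(miou(confusion(a, b))$per_class_iou[2], 1 / 3)
})

test_that("hd95 reproduces geometric cases and conventions", {
  m <- matrix(0L, 8, 8); m[3:5, 3:5] <- 1L
  expect_equal(hd95(m, m), 0)

  a <- matrix(0L, 8, 8); a[1, 1] <- 1L
  b <- matrix(0L, 8, 8); b[4, 5] <- 1L   # offset (3, 4): distance 5
  expect_equal(hd95(a, b), 5)

  # two horizontal 1-px segments offset vertically by 2 rows
  a <- matrix(0L, 8, 8); a[3, 2:7] <- 1L
  b <- matrix(0L, 8, 8); b[5, 2:7] <- 1L
  expect_equal(hd95(a, b), 2)

  z <- matrix(0L, 8, 8)
  expect_equal(hd95(z, z), 0)
  expect_equal(hd95(a, z), Inf)
  expect_equal(hd95(a, b, spacing = 0.5), 1)
})

test_that("ece matches closed-form single-bin cases", {
  # all pixels confident and correct
  p <- array(c(rep(0, 16), rep(1, 16)), c(4, 4, 2))
  t1 <- matrix(1L, 4, 4)
  expect_equal(ece(p, t1), 0)

  # all confidence 0.9, half correct
  p <- array(c(rep(0.1, 16), rep(0.9, 16)), c(4, 4, 2))
  t2 <- matrix(c(rep(1L, 8), rep(0L, 8)), 4, 4)
  expect_equal(ece(p, t2), abs(0.5 - 0.9))

  # confidence 0.8 with exactly 80% correct: perfectly calibrated
  p <- array(c(rep(0.2, 10), rep(0.8, 10)), c(2, 5, 2))
  t3 <- matrix(c(rep(1L, 8), rep(0L, 2)), 2, 5)
  expect_equal(ece(p, t3), 0, tolerance = 1e-12)
})

test_that("entropy map matches hand arithmetic and bounds", {
  p <- array(c(1, 0.5, 0.9, 0, 0.5, 0.1), c(3, 1, 2))
  e <- entropy_map(p)
  expect_equal(e[1, 1], 0)
  expect_equal(e[2, 1], log(2))
  expect_equal(e[3, 1], -0.9 * log(0.9) - 0.1 * log(0.1))
  expect_true(all(e >= 0 & e <= log(2) + 1e-12))
})

test_that("all metrics agree with brute-force oracles on random 8x8 pairs", {
  set.seed(7)
  for (i in 1:200) {
    pred <- random_mask(); truth <- random_mask()
    cm <- confusion(pred, truth)
    expect_equal(unname(cm), unname(oracle_confusion(pred, truth)))
    expect_equal(dice(pred, truth), oracle_dice(pred, truth),
                 tolerance = 1e-9)
    expect_equal(miou(cm)$per_class_iou, oracle_iou(cm), tolerance = 1e-9)
    expect_equal(hd95(pred, truth), oracle_hd95(pred, truth),
                 tolerance = 1e-9)
    pr <- random_probmap()
    expect_equal(ece(pr, truth), oracle_ece(pr, truth), tolerance = 1e-9)
    px <- pr[3, 5, ]
    expect_equal(entropy_map(pr)[3, 5], oracle_entropy(px),
                 tolerance = 1e-9)
  }
})

test_that("foreground F1 equals Dice and metrics respect their bounds", {
  set.seed(11)
  for (i in 1:25) {
    pred <- random_mask(12, 9); truth <- random_mask(12, 9)
    cm <- confusion(pred, truth)
    tp <- cm[2, 2]; fp <- cm[1, 2]; fn <- cm[2, 1]
    f1 <- if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
    expect_equal(f1, dice(pred, truth), tolerance = 1e-12)
    mi <- miou(cm); ra <- mrecall_and_accuracy(cm)
    expect_true(all(c(mi$per_class_iou, mi$miou, ra$mrecall,
                      ra$accuracy_eq8, ra$pixel_accuracy) >= 0))
    expect_true(all(c(mi$per_class_iou, mi$miou, ra$mrecall,
                      ra$accuracy_eq8, ra$pixel_accuracy) <= 1))
  }
})

test_that("confusion matrices accumulate over tiles", {
  set.seed(13)
  pred <- random_mask(8, 8); truth <- random_mask(8, 8)
  whole <- confusion(pred, truth)
  tiled <- confusion(pred[1:4, ], truth[1:4, ]) +
    confusion(pred[5:8, ], truth[5:8, ])
  expect_equal(whole, tiled)
})
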