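# Weak/strong view generators and the offline expansion operator.

test_that("policies enforce the weak/strong contract", {
  w <- augmentation_policy("weak")
  expect_identical(w$rotation_limit_deg, 0)
  expect_identical(w$saturation_delta, 0)
  expect_identical(w$hue_delta, 0)
  s <- augmentation_policy("strong")
  expect_identical(s$rotation_limit_deg, 20)
  expect_gt(s$saturation_delta, 0)
  expect_error(augmentation_policy("weak", rotation_limit_deg = 5),
               "weak policy")
})

test_that("augmentation is deterministic given the seed", {
  s <- tiny_sample_set(1, size = 32L)[[1]]
  expect_identical(weak_augment(s, 9L), weak_augment(s, 9L))
  expect_identical(strong_augment(s, 9L), strong_augment(s, 9L))
})

test_that("a forced horizontal flip mirrors the mask", {
  mask <- matrix(0L, 8, 8); mask[, 1:4] <- 1L    # left half foreground
  img <- array(100L, c(8, 8, 3))
  s <- lessnet:::new_image_sample("t", img, mask)
  pol <- augmentation_policy("weak", hflip_probability = 1,
                             brightness_delta = 0,
                             contrast_factor_range = c(1, 1))
  out <- weak_augment(s, 1L, pol)
  expect_identical(out$mask, mask[, 8:1])
  expect_true(all(out$mask[, 5:8] == 1L))
})

test_that("an all-identity policy is the identity map", {
  s <- tiny_sample_set(1, size = 32L, seed = 5L)[[1]]
  pol <- augmentation_policy("weak", hflip_probability = 0,
                             brightness_delta = 0,
                             contrast_factor_range = c(1, 1))
  out <- weak_augment(s, 123L, pol)
  expect_identical(out$image, s$image)
  expect_identical(out$mask, s$mask)
})

test_that("strong rotations stay within the limit and keep masks binary", {
  s <- tiny_sample_set(1, size = 32L, seed = 2L)[[1]]
  pol <- augmentation_policy("strong")
  angles <- vapply(1:1000, function(seed) {
    lessnet:::local_seed(seed, lessnet:::sample_policy_ops(pol)$angle)
  }, 1)
  expect_true(all(abs(angles) <= 20))
  expect_gt(max(abs(angles)), 15)   # the limit is actually exercised

  for (seed in 1:100) {
    out <- strong_augment(s, seed, pol)
    expect_true(all(out$mask %in% c(0L, 1L)))
    expect_identical(dim(out$image), dim(s$image))
  }
})

test_that("photometric ops never change the mask, geometry moves it", {
  s <- tiny_sample_set(1, size = 32L, seed = 8L)[[1]]
  out <- weak_augment(s, 4L)   # flip and/or photometric only
  expect_identical(sort(unique(as.vector(out$mask))),
                   sort(unique(as.vector(s$mask))))
  expect_identical(sum(out$mask), sum(s$mask))  # flips conserve area
})

test_that("weak and strong produce distinct views in general", {
  s <- tiny_sample_set(1, size = 32L, seed = 13L)[[1]]
  diffs <- vapply(1:5, function(seed) {
    !identical(weak_augment(s, seed), strong_augment(s, seed))
  }, TRUE)
  expect_true(any(diffs))
})

test_that("offline expansion multiplies counts by the factor", {
  expect_identical(expand_offline(list(), 1L), list())
  s <- tiny_sample_set(1, size = 32L)[[1]]
  out <- expand_offline(list(s), 1L)
  expect_length(out, 5L)
  expect_identical(out[[1]], s)
  expect_identical(vapply(out[-1], `[[`, "", "id"),
                   paste0(s$id, "-a", 1:4))
  for (v in out) expect_true(all(v$mask %in% c(0L, 1L)))

  nomask <- lessnet:::new_image_sample("x", array(0L, c(8, 8, 3)))
  expect_error(expand_offline(list(nomask), 1L), "mask")
})

test_that("expansion of several samples is deterministic and id-unique", {
  ss <- tiny_sample_set(3, size = 32L)
  a <- expand_offline(ss, 2L)
  b <- expand_offline(ss, 2L)
  expect_identical(a, b)
  expect_length(a, 15L)
  expect_false(anyDuplicated(vapply(a, `[[`, "", "id")) > 0)
})

test_that("view predictions align back to the original frame", {
  m <- matrix(0, 64, 64); m[20:40, 10:30] <- 1
  img <- array(rep(m, 3), c(64, 64, 3))
  for (trial in 1:10) {
    # full policy (geometry + photometrics): alignment undoes the geometry,
    # so the residual is bounded by the photometric shift plus edge blur
    ops <- lessnet:::local_seed(trial, lessnet:::sample_policy_ops(
      augmentation_policy("strong")))
    view <- lessnet:::apply_ops(img, NULL, ops)$image[, , 1]
    mp <- lessnet:::alignment_map(64L, 64L, ops)
    back <- lessnet:::apply_alignment(view, mp)
    valid <- matrix(mp$valid, 64, 64)
    expect_lt(mean(abs(back - m)[valid]), 0.2)

    # geometry-only ops: exact deep inside the lesion
    gops <- list(hflip = trial %% 2 == 0,
                 angle = lessnet:::local_seed(trial, stats::runif(1, -20, 20)))
    gview <- lessnet:::apply_ops(img, NULL, gops)$image[, , 1]
    gmp <- lessnet:::alignment_map(64L, 64L, gops)
    gback <- lessnet:::apply_alignment(gview, gmp)
    core <- matrix(FALSE, 64, 64)
    core[25:35, 15:25] <- TRUE        # deep inside the lesion
    core <- core & matrix(gmp$valid, 64, 64)
    expect_true(any(core))
    expect_lt(max(abs(gback - m)[core]), 1e-6)
  }
})

test_that("the batched warp op is linear and backpropagates exactly", {
  set.seed(4)
  ops <- list(hflip = TRUE, angle = 12)
  mp <- lessnet:::alignment_map(8L, 8L, ops)
  x <- lessnet:::tparam(array(rnorm(8 * 8 * 1 * 2), c(8, 8, 1, 2)))
  lessnet:::ad_record(TRUE)
  lessnet:::ad_reset_tape()
  y <- lessnet:::op_warp_batch(x, list(mp))
  l <- lessnet:::op_mean_all(lessnet:::op_square(y))
  lessnet:::ad_backward(l)
  lessnet:::ad_record(FALSE)
  eps <- 1e-6
  for (i in sample(length(x$v), 5)) {
    orig <- x$v[i]
    x$v[i] <- orig + eps
    lp <- lessnet:::op_mean_all(lessnet:::op_square(
      lessnet:::op_warp_batch(x, list(mp))))$v
    x$v[i] <- orig - eps
    lm <- lessnet:::op_mean_all(lessnet:::op_square(
      lessnet:::op_warp_batch(x, list(mp))))$v
    x$v[i] <- orig
    expect_equal(x$grad[i], (lp - lm) / (2 * eps), tolerance = 1e-5)
  }
  x$grad <- NULL
})
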