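# The automatic-differentiation engine: every operation's analytic
# gradient is validated against central finite differences.

fd_check <- function(build, shapes, eps = 1e-6, tol = 1e-6) {
  # build(params) -> scalar tnsr under recording; params are tparams
  params <- lapply(shapes, function(s) {
    lessnet:::tparam(array(stats::rnorm(prod(s)), s))
  })
  lessnet:::ad_record(TRUE)
  lessnet:::ad_reset_tape()
  loss <- build(params)
  lessnet:::ad_backward(loss)
  lessnet:::ad_record(FALSE)
  for (p in params) {
    idx <- sample(length(p$v), min(4L, length(p$v)))
    for (i in idx) {
      orig <- p$v[i]
      p$v[i] <- orig + eps
      lp <- build(params)$v
      p$v[i] <- orig - eps
      lm <- build(params)$v
      p$v[i] <- orig
      fd <- (lp - lm) / (2 * eps)
      g <- if (is.null(p$grad)) 0 else p$grad[i]
      expect_equal(g, fd, tolerance = max(tol, 1e-4 * abs(fd)))
    }
  }
  for (p in params) p$grad <- NULL
}

test_that("elementwise, matmul, softmax and loss ops backpropagate
           correctly", {
  set.seed(1)
  fd_check(function(p) {
    lessnet:::op_mean_all(lessnet:::op_square(lessnet:::op_sub(
      lessnet:::op_mul(p[[1]], p[[2]]), lessnet:::op_silu(p[[1]]))))
  }, list(c(3, 4, 1, 2), c(3, 4, 1, 2)))

  fd_check(function(p) {
    lessnet:::op_mean_all(lessnet:::op_sigmoid(
      lessnet:::op_matmul(p[[1]], p[[2]])))
  }, list(c(5, 3), c(3, 4)))

  tg <- array(sample(0:1, 12, TRUE), c(2, 2, 3))
  fd_check(function(p) {
    lessnet:::op_softmax_ce(p[[1]], tg)
  }, list(c(2, 2, 3, 2)), tol = 1e-5)

  fd_check(function(p) {
    lessnet:::op_mean_all(lessnet:::op_square(
      lessnet:::op_softmax_c(p[[1]])))
  }, list(c(2, 3, 1, 4)))
})

test_that("convolutions, depthwise convolutions and bilinear resizing
           backpropagate correctly", {
  set.seed(2)
  x <- lessnet:::tconst(array(rnorm(6 * 6 * 2 * 3), c(6, 6, 2, 3)))
  fd_check(function(p) {
    y <- lessnet:::op_conv2d(lessnet:::op_mul(x, p[[3]]), p[[1]], p[[2]],
                             3L, 3L, stride = 1L, pad = 1L)
    lessnet:::op_mean_all(lessnet:::op_square(y))
  }, list(c(27, 4), 4, c(6, 6, 2, 3)), tol = 1e-5)

  fd_check(function(p) {
    y <- lessnet:::op_dwconv(lessnet:::op_mul(x, p[[3]]), p[[1]], p[[2]],
                             3L, 3L, stride = 2L, pad = 1L)
    lessnet:::op_mean_all(lessnet:::op_square(y))
  }, list(c(3, 3, 3), 3, c(6, 6, 2, 3)), tol = 1e-5)

  fd_check(function(p) {
    lessnet:::op_mean_all(lessnet:::op_square(
      lessnet:::op_bilinear(p[[1]], 7L, 5L)))
  }, list(c(4, 4, 1, 2)))
  fd_check(function(p) {
    lessnet:::op_mean_all(lessnet:::op_square(
      lessnet:::op_bilinear(p[[1]], 3L, 3L)))
  }, list(c(5, 6, 1, 2)))
})

test_that("normalisation layers and attention backpropagate correctly", {
  set.seed(3)
  st <- new.env()
  st$running_mean <- numeric(3); st$running_var <- rep(1, 3)
  st$momentum <- 0.1; st$eps <- 1e-5
  fd_check(function(p) {
    y <- lessnet:::op_batchnorm(p[[1]], p[[2]], p[[3]], st, training = TRUE)
    lessnet:::op_mean_all(lessnet:::op_square(y))
  }, list(c(4, 4, 2, 3), 3, 3), tol = 1e-5)

  fd_check(function(p) {
    y <- lessnet:::op_layernorm(p[[1]], p[[2]], p[[3]])
    lessnet:::op_mean_all(lessnet:::op_square(y))
  }, list(c(6, 4), 4, 4), tol = 1e-5)

  fd_check(function(p) {
    a <- lessnet:::op_attention(p[[1]], p[[2]], p[[3]], slen = 4L,
                                heads = 2L)
    lessnet:::op_mean_all(lessnet:::op_square(a))
  }, list(c(8, 4), c(8, 4), c(8, 4)), tol = 1e-5)

  fd_check(function(p) {
    g <- lessnet:::op_gate(p[[1]], lessnet:::op_sigmoid(p[[2]]))
    g <- lessnet:::op_gate(g, lessnet:::op_sigmoid(p[[3]]))
    lessnet:::op_mean_all(lessnet:::op_square(g))
  }, list(c(4, 5, 2, 3), c(4, 1, 2, 3), c(1, 5, 2, 3)))

  fd_check(function(p) {
    pooled <- lessnet:::op_mean_axis(p[[1]], 1L)
    pooled2 <- lessnet:::op_mean_axis(p[[1]], 2L)
    lessnet:::op_add(
      lessnet:::op_mean_all(lessnet:::op_square(pooled)),
      lessnet:::op_mean_all(lessnet:::op_square(pooled2)))
  }, list(c(4, 5, 1, 2)))
})

test_that("bilinear resizing agrees with a hand-worked 2x upscale", {
  # 1x2 row (0, 1) upscaled to width 4 under half-pixel sampling:
  # source x = (j + 0.5)/2 - 0.5 for j = 0..3 -> -0.25, 0.25, 0.75, 1.25
  x <- lessnet:::tconst(array(c(0, 1), c(1, 2, 1, 1)))
  y <- lessnet:::op_bilinear(x, 1L, 4L)
  expect_equal(as.vector(y$v), c(0, 0.25, 0.75, 1))
})

test_that("the tape releases between steps and constants carry no
           gradient state", {
  lessnet:::ad_record(FALSE)
  a <- lessnet:::tconst(matrix(1, 2, 2))
  b <- lessnet:::op_add(a, a)
  expect_false(b$rg)
  expect_null(b$grad)
})
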