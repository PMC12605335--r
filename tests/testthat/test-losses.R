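# Supervised, triplet-consistency and total loss, with the lambda ramp.

test_that("cross-entropy matches closed forms", {
  # uniform logits: p = (0.5, 0.5) everywhere -> ln 2
  lg <- array(0, c(4, 4, 1, 2))
  mk <- array(sample(0:1, 16, replace = TRUE), c(4, 4, 1))
  expect_equal(supervised_loss(lg, mk), log(2), tolerance = 1e-12)

  # near-one-hot on the true class -> loss near 0
  lg2 <- array(0, c(4, 4, 1, 2))
  lg2[, , , 1] <- ifelse(mk == 0, 50, -50)
  lg2[, , , 2] <- -lg2[, , , 1]
  expect_lt(supervised_loss(lg2, mk), 1e-10)

  # 2 pixels, true classes (0, 1), p(true) = (0.8, 0.4)
  lg3 <- array(0, c(1, 2, 1, 2))
  lg3[1, 1, 1, ] <- c(log(0.8), log(0.2))
  lg3[1, 2, 1, ] <- c(log(0.6), log(0.4))
  mk3 <- array(c(0L, 1L), c(1, 2, 1))
  expect_equal(supervised_loss(lg3, mk3), -(log(0.8) + log(0.4)) / 2,
               tolerance = 1e-12)

  expect_error(supervised_loss(lg, array(2, c(4, 4, 1))), "\\{0, 1\\}")
  expect_error(supervised_loss(lg, array(0, c(3, 3, 1))), "disagree")
})

test_that("triplet loss reproduces the hand example and degenerate cases", {
  p <- array(runif(2 * 2 * 3 * 2), c(2, 2, 3, 2))
  expect_equal(triplet_consistency_loss(p, p, p), 0)

  # M = 1, one pixel, sum-form distances: 0.5 + 0.5 + 2.0 = 3.0
  po <- array(c(0.5, 0.5), c(1, 1, 1, 2))
  pw <- array(c(1, 0), c(1, 1, 1, 2))
  ps <- array(c(0, 1), c(1, 1, 1, 2))
  expect_equal(triplet_consistency_loss(po, pw, ps, distance = "sum"), 3)

  w0 <- loss_weights(alpha = 0, beta = 0, gamma = 0)
  expect_equal(triplet_consistency_loss(po, pw, ps, w0), 0)
  expect_error(triplet_consistency_loss(po, pw, array(0.5, c(1, 2, 1, 2))),
               "identical shapes")
  expect_error(loss_weights(alpha = -1), "non-negative")
})

test_that("triplet loss is linear in the weights and view-symmetric", {
  set.seed(3)
  for (i in 1:10) {
    mk <- function() {
      a <- array(runif(4 * 4 * 2), c(4, 4, 2, 1))
      array(c(a, 1 - a), c(4, 4, 2, 2))
    }
    po <- mk(); pw <- mk(); ps <- mk()
    w1 <- loss_weights(alpha = 0.3, beta = 0.9, gamma = 1.7)
    w2 <- loss_weights(alpha = 0.6, beta = 1.8, gamma = 3.4)
    l1 <- triplet_consistency_loss(po, pw, ps, w1)
    expect_gte(l1, 0)
    expect_equal(triplet_consistency_loss(po, pw, ps, w2), 2 * l1,
                 tolerance = 1e-12)
    # swapping the weak/strong views while swapping the two anchor
    # pairings alpha and beta (the weak-strong pair is symmetric)
    wsw <- loss_weights(alpha = w1$beta, beta = w1$alpha, gamma = w1$gamma)
    expect_equal(triplet_consistency_loss(po, ps, pw, wsw), l1,
                 tolerance = 1e-12)
  }
})

test_that("zero only at coincidence for positive weights", {
  po <- array(c(0.4, 0.6), c(1, 1, 1, 2))
  pw <- array(c(0.41, 0.59), c(1, 1, 1, 2))
  expect_gt(triplet_consistency_loss(po, pw, po), 0)
})

test_that("total loss combines components as stated", {
  expect_equal(total_loss(0.5, 3.0, 0.1), 0.8)
  expect_equal(total_loss(0.7, 5.0, 0), 0.7)
  expect_equal(total_loss(0.7, 0, 12), 0.7)
})

test_that("lambda schedule ramps monotonically to its plateau", {
  w <- loss_weights(lambda_u = 2, ramp_epochs = 10L)
  expect_lt(lambda_schedule(0, w), 0.01 * w$lambda_u)
  expect_identical(lambda_schedule(10, w), 2)
  expect_identical(lambda_schedule(250, w), 2)
  vals <- vapply(0:10, lambda_schedule, 1, weights = w)
  expect_true(all(diff(vals) >= 0))
  w0 <- loss_weights(lambda_u = 1.5, ramp_epochs = 0L)
  expect_identical(lambda_schedule(0, w0), 1.5)
})

test_that("autodiff gradient of the total loss passes a finite-difference
           check on a one-parameter model", {
  # one parameter theta scales a fixed logit template; total loss =
  # CE(labeled) + lambda * triplet(three softened views)
  set.seed(5)
  tmpl <- array(rnorm(4 * 4 * 1 * 2), c(4, 4, 1, 2))
  v1 <- tmpl + 0.3; v2 <- tmpl - 0.2
  mk <- array(sample(0:1, 16, TRUE), c(4, 4, 1))
  lam <- 0.7
  loss_at <- function(theta_node) {
    lg <- lessnet:::op_scale(theta_node, 1)       # reuse node
    f <- function(tp) lessnet:::op_softmax_c(
      lessnet:::op_mul(theta_node, lessnet:::tconst(tp)))
    ce <- lessnet:::op_softmax_ce(
      lessnet:::op_mul(theta_node, lessnet:::tconst(tmpl)), mk)
    po <- f(tmpl); pw <- f(v1); ps <- f(v2)
    tri <- lessnet:::op_add(
      lessnet:::op_add(
        lessnet:::op_mean_all(lessnet:::op_square(lessnet:::op_sub(po, pw))),
        lessnet:::op_mean_all(lessnet:::op_square(lessnet:::op_sub(po, ps)))),
      lessnet:::op_mean_all(lessnet:::op_square(lessnet:::op_sub(pw, ps))))
    lessnet:::op_add(ce, lessnet:::op_scale(tri, lam))
  }
  theta <- 0.8
  lessnet:::ad_record(TRUE)
  lessnet:::ad_reset_tape()
  tn <- lessnet:::tparam(array(theta, c(4, 4, 1, 2)))
  # tie all entries to one scalar by summing the gradient afterwards
  l <- loss_at(tn)
  lessnet:::ad_backward(l)
  g_analytic <- sum(tn$grad)
  lessnet:::ad_record(FALSE)
  num <- function(th) {
    tn2 <- lessnet:::tconst(array(th, c(4, 4, 1, 2)))
    loss_at(tn2)$v
  }
  eps <- 1e-5
  g_fd <- (num(theta + eps) - num(theta - eps)) / (2 * eps)
  expect_equal(g_analytic, g_fd, tolerance = 1e-4)
})
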