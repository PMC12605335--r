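# Training loop: bookkeeping identity, degenerate supervision, seeded
# determinism, checkpoint round-trip.

micro_split <- function(n = 12L, label_ratio = 0.5, seed = 21L) {
  samp <- tiny_sample_set(n, size = 64L, seed = seed)
  split_dataset(samp, test_fraction = 0.25, label_ratio = label_ratio,
                seed = seed)
}

micro_train <- function(split, lambda_u = 1, epochs = 2L, seed = 0L, ...) {
  lessnet(split,
          encoder_config("tiny-test"),
          decoder_config_tiny(),
          loss_weights(lambda_u = lambda_u, ramp_epochs = 0L),
          train_config(epochs = epochs, batch_size = 4L, seed = seed,
                       eval_every = epochs, ...))
}

test_that("fully supervised training with lambda = 0 has an identically
           zero unsupervised component", {
  sp <- micro_split(label_ratio = 1)
  fit <- micro_train(sp, lambda_u = 0)
  expect_true(all(fit$history$unsupervised == 0))
  expect_true(all(fit$history$lambda == 0))
  expect_equal(fit$history$total, fit$history$supervised)
})

test_that("the loss bookkeeping identity total = sup + lambda * unsup
           holds at every logged epoch", {
  sp <- micro_split(label_ratio = 0.5)
  fit <- micro_train(sp, lambda_u = 0.5, epochs = 3L)
  h <- fit$history
  expect_true(any(h$unsupervised > 0))
  expect_equal(h$total, h$supervised + h$lambda * h$unsupervised,
               tolerance = 1e-12)
})

test_that("training is deterministic given the seed", {
  sp <- micro_split()
  f1 <- micro_train(sp, epochs = 2L, seed = 3L)
  f2 <- micro_train(sp, epochs = 2L, seed = 3L)
  expect_equal(f1$history, f2$history, tolerance = 0)
  expect_identical(f1$final_state$params, f2$final_state$params)
})

test_that("training errors on unusable inputs", {
  sp <- micro_split()
  sp$labeled_ids <- character(0)
  expect_error(micro_train(sp), "labeled")
  sp2 <- micro_split()
  expect_error(
    lessnet(sp2, encoder_config("tiny-test"), decoder_config_tiny(),
            loss_weights(), train_config(batch_size = 1L, epochs = 1L)),
    "batch_size")
})

test_that("checkpoints round-trip to bit-identical evaluations", {
  sp <- micro_split()
  fit <- micro_train(sp, epochs = 2L)
  r1 <- evaluate(fit, sp$test, use = "final")
  path <- tempfile(fileext = ".rds")
  save_checkpoint(fit, path)
  back <- load_checkpoint(path)
  r2 <- evaluate(back, sp$test, use = "final")
  expect_identical(r1$confusion, r2$confusion)
  expect_identical(r1$dice, r2$dice)
  expect_identical(r1$ece, r2$ece)
  unlink(path)
})

test_that("evaluation demands masks and non-empty sample lists", {
  sp <- micro_split()
  fit <- micro_train(sp, epochs = 1L)
  expect_error(evaluate(fit, list()), "empty")
  nomask <- lessnet:::new_image_sample("x", sp$test[[1]]$image)
  expect_error(evaluate(fit, list(nomask)), "mask")
})

test_that("predictions are binary masks of the input size and probability
           maps normalise", {
  sp <- micro_split()
  fit <- micro_train(sp, epochs = 1L)
  pm <- predict(fit, sp$test[1:2], type = "mask")
  expect_length(pm, 2L)
  expect_true(all(pm[[1]] %in% c(0L, 1L)))
  expect_identical(dim(pm[[1]]), dim(sp$test[[1]]$mask))
  pp <- predict(fit, sp$test[[1]], type = "prob")
  expect_equal(range(pp[[1]][, , 1] + pp[[1]][, , 2]), c(1, 1),
               tolerance = 1e-6)
})

test_that("the report for a metric assembly on perfect and degenerate
           predictions follows the conventions", {
  masks <- lapply(1:3, function(i) {
    m <- matrix(0L, 8, 8); m[i + (1:2), 2:5] <- 1L; m
  })
  cm <- Reduce(`+`, lapply(masks, function(m) confusion(m, m)))
  rep <- lessnet:::new_metric_report(
    cm, vapply(masks, function(m) dice(m, m), 1),
    vapply(masks, function(m) hd95(m, m), 1), 0)
  expect_equal(rep$dice, 1)
  expect_equal(rep$miou, 1)
  expect_equal(rep$mrecall, 1)
  expect_equal(rep$hd95, 0)

  # all-background predictions: foreground recall is zero
  z <- matrix(0L, 8, 8)
  cm0 <- Reduce(`+`, lapply(masks, function(m) confusion(z, m)))
  rec <- cm0[2, 2] / (cm0[2, 2] + cm0[2, 1])
  expect_equal(rec, 0)
})
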