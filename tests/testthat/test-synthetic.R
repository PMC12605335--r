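# Synthetic data generator and split machinery.

test_that("generation handles the vacuous case and validates its config", {
  expect_identical(generate_dataset(0, synthetic_config(image_size = 32L)),
                   list())
  expect_error(synthetic_config(lesion_area_fraction_range = c(0, 0.1)),
               "lesion_area_fraction_range")
  expect_error(synthetic_config(lesion_area_fraction_range = c(0.2, 0.1)),
               "lesion_area_fraction_range")
  expect_error(synthetic_config(lesion_area_fraction_range = c(0.2, 1)),
               "lesion_area_fraction_range")
  expect_error(synthetic_config(reflection_probability = 1.4), "probabilities")
})

test_that("identical seeds give byte-identical samples", {
  cfg <- synthetic_config(image_size = 32L, seed = 7L)
  a <- generate_dataset(5, cfg)
  b <- generate_dataset(5, cfg)
  expect_identical(a, b)
  cfg2 <- synthetic_config(image_size = 32L, seed = 8L)
  expect_false(identical(generate_dataset(5, cfg2), a))
})

test_that("samples satisfy the image/mask invariants", {
  cfg <- synthetic_config(image_size = 48L, seed = 3L)
  for (s in generate_dataset(10, cfg)) {
    expect_identical(dim(s$image), c(48L, 48L, 3L))
    expect_identical(dim(s$mask), c(48L, 48L))
    expect_true(all(s$mask %in% c(0L, 1L)))
    expect_true(all(s$image >= 0L & s$image <= 255L))
    expect_gt(sum(s$mask), 0)   # lo > 0 forces foreground
  }
})

test_that("mask foreground fractions respect the configured interval", {
  cfg <- synthetic_config(image_size = 64L,
                          lesion_area_fraction_range = c(0.01, 0.10),
                          seed = 11L)
  fr <- vapply(generate_dataset(100, cfg), function(s) mean(s$mask), 1)
  expect_true(all(fr >= 0.01 - 1e-12))
  expect_true(all(fr <= 0.10 + 1e-12))
})

test_that("splits follow the published arithmetic", {
  samp <- lapply(seq_len(405), function(i) {
    lessnet:::new_image_sample(sprintf("s%03d", i),
                               array(0L, c(4, 4, 3)),
                               matrix(0L, 4, 4))
  })
  sp <- split_dataset(samp, test_fraction = 0.2, label_ratio = 0.5,
                      seed = 1L)
  expect_length(sp$train, 324L)
  expect_length(sp$test, 81L)
  expect_length(sp$labeled_ids, 162L)

  sp2 <- split_dataset(samp, 0.2, 0.05, seed = 1L)
  expect_length(sp2$labeled_ids, 16L)   # floor(16.2)

  # partition conservation and disjointness
  ids <- c(vapply(sp$train, `[[`, "", "id"), vapply(sp$test, `[[`, "", "id"))
  expect_length(ids, 405L)
  expect_false(anyDuplicated(ids) > 0)
  expect_true(all(sp$labeled_ids %in% vapply(sp$train, `[[`, "", "id")))
})

test_that("split is deterministic in the seed and errors are raised", {
  samp <- tiny_sample_set(10, size = 32L)
  a <- split_dataset(samp, 0.2, 0.5, seed = 5L)
  b <- split_dataset(samp, 0.2, 0.5, seed = 5L)
  expect_identical(vapply(a$train, `[[`, "", "id"),
                   vapply(b$train, `[[`, "", "id"))
  expect_identical(a$labeled_ids, b$labeled_ids)

  expect_error(split_dataset(list(), 0.2, 0.5), "empty")
  expect_error(split_dataset(samp, 1.2, 0.5), "test_fraction")
  expect_error(split_dataset(samp, 0.2, 0), "label_ratio")
  expect_error(split_dataset(samp, 0.2, 0.01), "zero labeled")
})

test_that("dataset directories round-trip through PNG and the manifest", {
  root <- tempfile("ds")
  samp <- tiny_sample_set(4, size = 32L)
  sp <- split_dataset(samp, 0.25, 1, seed = 2L)
  write_dataset(samp, root, sp)
  expect_length(list.files(file.path(root, "images")), 4L)
  expect_length(list.files(file.path(root, "masks")), 4L)
  back <- read_dataset(root)
  ids <- vapply(back$samples, `[[`, "", "id")
  for (s in samp) {
    r <- back$samples[[which(ids == s$id)]]
    expect_identical(r$image, s$image)
    expect_identical(r$mask + 0L, s$mask + 0L)
  }
  expect_setequal(back$split$labeled_ids, sp$labeled_ids)
  unlink(root, recursive = TRUE)
})
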