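test_that("layer size and parameter arithmetic match the closed forms", {
  expect_equal(conv_output_size(28, 3, 1, 1), 28L)
  expect_equal(conv_output_size(7, 3, 1, 1), 7L)
  for (I in c(5L, 17L, 28L)) {
    expect_equal(conv_output_size(I, 1, 0, 1), I)
    expect_equal(pool_output_size(I, 1, 0, 1), I)
  }
  expect_equal(pool_output_size(28, 2, 0, 2), 14L)
  expect_equal(pool_output_size(7, 2, 0, 2), 3L)  # flooring case
  expect_equal(pool_output_size(3, 2, 0, 2), 1L)

  expect_equal(conv_param_count(3, 3, 1, 16), 160L)
  expect_equal(conv_param_count(3, 3, 16, 32), 4640L)
  for (c in c(1L, 5L, 64L)) expect_equal(conv_param_count(1, 1, c, 1), c + 1L)

  expect_error(conv_output_size(3, 7, 0, 1), "non-positive")
})

test_that("the default configuration pools through 14, 7, 3, 1", {
  arch <- cnn_architecture(cnn_config(n_classes = 22L))
  pools <- arch$out_side[arch$type == "pool"]
  expect_equal(pools, c(14L, 7L, 3L, 1L))
  expect_equal(arch$params[arch$layer == "conv1"], 160L)
  expect_equal(arch$params[arch$layer == "conv2"], 4640L)
  # fully-connected output length equals the class count
  expect_equal(arch$channels[arch$layer == "fc"], 22L)

  # the alternative published configurations build without error
  expect_silent(arch1 <- cnn_architecture(cnn_config(n_classes = 22L,
                                                     table3_config = 1L)))
  expect_true(all(arch1$out_side > 0))
  expect_silent(arch2 <- cnn_architecture(cnn_config(n_classes = 22L,
                                                     table3_config = 2L)))
  expect_true(all(arch2$out_side > 0))
})

test_that("built networks satisfy the parameter-count invariant per block", {
  cfg <- cnn_config(n_classes = 5L)
  layers <- with_seed(1, build_layers(cfg))
  cin <- 1L
  for (ly in layers) {
    if (ly$type == "conv") {
      expect_equal(length(ly$W) + length(ly$b),
                   conv_param_count(ly$k, ly$k, cin, ncol(ly$W)))
      cin <- ncol(ly$W)
    }
  }
})

test_that("batch normalisation standardises and shifts as specified", {
  out <- batchnorm_forward(matrix(c(1, 3), 2, 1), gamma = 1, beta = 0)
  expect_equal(as.numeric(out), c(-1, 1), tolerance = 1e-4)

  const <- batchnorm_forward(matrix(5, 4, 1), gamma = 1, beta = 7)
  expect_equal(as.numeric(const), rep(7, 4))

  xh <- matrix(c(-1, 1), 2, 1)
  # affine map applied to an already-standardised batch: the batch stats
  # of xh are mean 0 / var 1, so gamma/beta act directly
  out2 <- batchnorm_forward(xh, gamma = 2, beta = 5, epsilon = 1e-12)
  expect_equal(as.numeric(out2), c(3, 7), tolerance = 1e-5)

  expect_error(batchnorm_forward(matrix(1:4, 2), mode = "infer"),
               "trained statistics")

  # train-mode output is standardised per channel before gamma/beta
  set.seed(9)
  x <- matrix(rnorm(500 * 3, mean = 4, sd = 3), 500, 3)
  z <- batchnorm_forward(x)
  expect_true(all(abs(colMeans(z)) < 1e-6))
  v <- colMeans(z^2) - colMeans(z)^2
  expect_true(all(abs(v - 1) < 1e-3))
})

test_that("training reduces the loss and is seed-reproducible", {
  ds <- tiny_image_dataset(per_class = 8, seed = 11)
  cfg <- cnn_config(epochs = 6, seed = 4)
  fit <- cnn_fit(ds, cfg)
  expect_s3_class(fit, "myxo_cnn")
  expect_lt(fit$training_log$loss[6], fit$training_log$loss[1])

  fit2 <- cnn_fit(ds, cfg)
  expect_identical(fit$training_log, fit2$training_log)
  expect_identical(fit$layers[[1]]$W, fit2$layers[[1]]$W)

  fit3 <- cnn_fit(ds, cnn_config(epochs = 6, seed = 5))
  expect_false(identical(fit$layers[[1]]$W, fit3$layers[[1]]$W))

  single <- ds[ds$genus == ds$genus[1]]
  expect_error(cnn_fit(single, cfg), "classes")
})

test_that("feature extraction yields one finite row per image, dim = classes", {
  ds <- tiny_image_dataset(per_class = 6, seed = 12)
  fit <- cnn_fit(ds, cnn_config(epochs = 2, seed = 1))
  feats <- extract_features(fit, ds)
  expect_equal(dim(feats), c(length(ds), length(fit$classes)))
  expect_true(all(is.finite(feats)))

  # duplicated image gives identical rows
  one <- ds[c(1, 1)]
  f2 <- extract_features(fit, one)
  expect_identical(f2[1, ], f2[2, ])

  # random-noise input stays finite
  noise <- matrix(runif(28 * 28, 0, 255), 28, 28)
  expect_true(all(is.finite(extract_features(fit, noise))))

  wrong <- matrix(0, 10, 10)
  expect_error(extract_features(fit, wrong), "expects")
})

test_that("softmax output is a probability simplex point with shift invariance", {
  ds <- tiny_image_dataset(per_class = 6, seed = 13)
  fit <- cnn_fit(ds, cnn_config(epochs = 2, seed = 2))
  p <- predict_softmax(fit, ds$images[[1]])
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_true(all(p > 0 & p <= 1))
  expect_named(p, fit$classes)

  probs <- predict(fit, ds, type = "prob")
  expect_equal(rowSums(probs), rep(1, length(ds)), tolerance = 1e-9)

  # shift invariance and symmetry of the softmax map itself
  sm <- myxoclass:::softmax_cols
  a <- matrix(rnorm(12), 4, 3)
  expect_equal(sm(a), sm(a + 5), tolerance = 1e-9)
  expect_equal(as.numeric(sm(matrix(2, 5, 1))), rep(1 / 5, 5))
})

test_that("model archives round-trip bit-exactly", {
  ds <- tiny_image_dataset(per_class = 4, seed = 14)
  fit <- cnn_fit(ds, cnn_config(epochs = 1, seed = 3))
  f <- withr::local_tempfile(fileext = ".myxo")
  write_model(fit, f)
  hdr <- read_model(f, header_only = TRUE)
  expect_equal(hdr$package, "myxoclass")
  expect_equal(hdr$n_classes, 3)
  back <- read_model(f)
  expect_identical(back, fit)

  bad <- withr::local_tempfile(fileext = ".myxo")
  writeLines("not a model", bad)
  expect_error(read_model(bad), "magic")
})
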