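test_that("the morphotype registry covers the taxonomy registry", {
  m <- make_morphotype_registry()
  expect_equal(nrow(m), 30)
  expect_setequal(m$genus, genus_registry()$genus)
  expect_true(all(m$size_lo > 0 & m$size_hi <= 0.9))
  expect_true(all(m$size_lo < m$size_hi | m$size_lo == m$size_hi))

  chond <- m[m$genus == "Chondromyces", ]
  expect_equal(chond$shape_family, "tree_stalked")
  expect_true(chond$has_stalk)

  arch <- m[m$genus == "Archangium", ]
  expect_false(arch$has_sporangioles)

  # stalked-tree morphotypes always carry the stalk flag
  expect_true(all(m$has_stalk[m$shape_family == "tree_stalked"]))
})

test_that("rendering is deterministic and shape families are geometrically
          distinct", {
  m <- make_morphotype_registry()
  sphere <- m[m$genus == "Hyalangium", ]

  a <- render_fruiting_body(sphere, side = 64, noise = 0, seed = 5)
  b <- render_fruiting_body(sphere, side = 64, noise = 0, seed = 5)
  expect_identical(a, b)
  c2 <- render_fruiting_body(sphere, side = 64, noise = 0, seed = 6)
  expect_false(identical(a, c2))

  # colour is incidental: channels are scalar multiples of one another
  r1 <- a[, , 1]; g1 <- a[, , 2]
  ratio <- g1[r1 > 0] / r1[r1 > 0]
  expect_lt(diff(range(ratio)), 1e-9)

  # a zero-noise sphere is one connected, nearly circular component
  gray <- to_gray(a)
  mask <- foreground_mask(gray)
  lab <- EBImage::bwlabel(EBImage::Image(t(mask)))
  expect_equal(max(lab), 1)
  feats <- shape_features(gray)
  expect_lt(feats[["eccentricity"]], 0.6)

  # a zero-noise stalked tree has a branched skeleton (>= 3 endpoints)
  tree <- m[m$genus == "Chondromyces", ]
  timg <- to_gray(render_fruiting_body(tree, side = 64, noise = 0, seed = 9))
  skel <- zhang_suen_thin(foreground_mask(timg))
  expect_gte(count_endpoints(skel), 3)

  expect_error(render_fruiting_body(list(shape_family = "blob",
                                         texture = "soft", size_lo = 0.2,
                                         size_hi = 0.3), side = 64),
               "unknown shape family")
  expect_error(render_fruiting_body(sphere, side = 10), ">= 28")
})

test_that("generated datasets follow the requested class-size profile", {
  ds <- generate_dataset(generator_profile("balanced", per_class = 4,
                                           seed = 3, noise = 0))
  expect_length(ds, 12)
  expect_length(ds$classes, 3)
  expect_equal(dim(ds$images[[1]]), c(28L, 28L))

  # full published profile: 322 images over 30 classes, Myxococcus 38
  prof <- generator_profile("table2", seed = 4)
  ds2 <- generate_dataset(prof)
  expect_length(ds2, 322)
  expect_length(ds2$classes, 30)
  expect_equal(sum(ds2$genus == "Myxococcus"), 38)

  # bit-exact reproducibility from the profile seed
  ds3 <- generate_dataset(generator_profile("balanced", per_class = 3,
                                            seed = 11))
  ds4 <- generate_dataset(generator_profile("balanced", per_class = 3,
                                            seed = 11))
  expect_identical(ds3$images, ds4$images)

  expect_error(generate_dataset(generator_profile("custom",
                                                  counts = c(Fake = 3))),
               "unknown genera")
})

test_that("written datasets round-trip through load_dataset", {
  out <- withr::local_tempdir()
  ds <- generate_dataset(generator_profile("balanced",
                                           genera = c("Myxococcus",
                                                      "Chondromyces"),
                                           per_class = 3, noise = 0,
                                           seed = 8),
                         out_dir = out)
  expect_true(file.exists(file.path(out, "manifest.csv")))
  expect_length(list.files(out, pattern = "\\.png$", recursive = TRUE), 6)

  back <- load_dataset(out)
  expect_equal(back$genus, ds$genus)
  expect_equal(back$suborder, ds$suborder)
  expect_equal(dim(back$images[[1]]), c(28L, 28L))
})

test_that("shape families are separable from plain geometric descriptors", {
  ds <- generate_dataset(generator_profile("balanced", per_class = 20,
                                           noise = 0, seed = 21),
                         stage = "archive")
  feats <- t(vapply(ds$images, shape_features, numeric(3)))
  df <- data.frame(feats, y = factor(ds$genus))
  fit <- nnet::multinom(y ~ ., df, trace = FALSE)
  acc <- mean(predict(fit, df) == df$y)
  expect_gte(acc, 0.80)
})
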