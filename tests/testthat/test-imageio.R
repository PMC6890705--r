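test_that("image write/load round-trips 8-bit pixels exactly", {
  set.seed(7)
  px <- matrix(sample(0:255, 100, replace = TRUE), 10, 10)
  f <- withr::local_tempfile(fileext = ".png")
  write_image(px, f)
  back <- load_image(f)
  expect_equal(dim(back), c(10L, 10L, 3L))
  expect_equal(back[, , 1], px, ignore_attr = TRUE)
  expect_equal(back[, , 2], px, ignore_attr = TRUE)  # gray replicated

  f2 <- withr::local_tempfile(fileext = ".png")
  write_image(matrix(0, 2, 2), f2)
  expect_true(all(load_image(f2) == 0))

  f3 <- withr::local_tempfile(fileext = ".png")
  write_image(matrix(255, 1, 1), f3)
  expect_equal(as.vector(load_image(f3)), c(255, 255, 255))

  expect_error(load_image(file.path(tempdir(), "no_such.png")), "not found")
})

test_that("grayscale conversion follows the luma weights and is linear", {
  rgb1 <- array(0, c(1, 1, 3))
  expect_equal(as.numeric(to_gray(rgb1)), 0)
  rgb1[] <- 255
  expect_equal(as.numeric(to_gray(rgb1)), 254.9745)
  red <- array(c(255, 0, 0), c(1, 1, 3))
  expect_equal(as.numeric(to_gray(red)), 76.2195)

  set.seed(1)
  img <- array(runif(4 * 4 * 3, 0, 255), c(4, 4, 3))
  for (a in c(0, 0.3, 0.9)) {
    expect_equal(to_gray(a * img), a * to_gray(img), tolerance = 1e-9)
  }
  expect_true(min(to_gray(img)) >= 0)
  expect_true(max(to_gray(img)) <= 254.9745 + 1e-6)
})

test_that("bilinear resize preserves constants, identity, and structure", {
  const <- matrix(42, 100, 100)
  expect_true(all(abs(resize_gray(const, 28) - 42) < 1e-9))

  set.seed(2)
  img28 <- matrix(runif(28 * 28, 0, 255), 28, 28)
  expect_identical(resize_gray(img28, 28), img28)

  halves <- cbind(matrix(0, 100, 50), matrix(200, 100, 50))
  small <- resize_gray(halves, 28)
  expect_lt(mean(small[, 1:14]), mean(small[, 15:28]))
  expect_gte(min(small), 0)
  expect_lte(max(small), 200)

  expect_error(resize_gray(img28, 0), "positive")
})

test_that("directory-per-class datasets load deterministically", {
  root <- withr::local_tempdir()
  set.seed(3)
  for (g in c("Myxococcus", "Sorangium")) {
    dir.create(file.path(root, g))
    for (i in 1:3) {
      write_image(matrix(sample(0:255, 40 * 40, TRUE), 40, 40),
                  file.path(root, g, sprintf("img%02d.png", i)))
    }
  }
  ds <- load_dataset(root)
  expect_s3_class(ds, "myxo_dataset")
  expect_length(ds, 6)
  expect_equal(sort(unique(ds$genus)), c("Myxococcus", "Sorangium"))
  expect_equal(dim(ds$images[[1]]), c(28L, 28L))
  expect_equal(ds$suborder[ds$genus == "Sorangium"][1], "Sorangiineae")

  ds2 <- load_dataset(root)
  expect_identical(ds$images, ds2$images)
  expect_identical(ds$paths, ds2$paths)

  dir.create(file.path(root, "NotAGenus"))
  writeLines("", file.path(root, "NotAGenus", "dummy.txt"))
  expect_error(load_dataset(root), "NotAGenus")
})

test_that("class-size filtering reproduces the published subset sizes", {
  ds <- profile_counts_dataset()
  expect_length(ds, 322)
  expect_length(ds$classes, 30)

  my25 <- filter_min_class_size(ds, 4)
  expect_length(my25$classes, 25)
  expect_length(my25, 313)

  my22 <- filter_min_class_size(ds, 8)
  expect_length(my22$classes, 22)

  expect_identical(filter_min_class_size(ds, 1), ds)

  # surviving samples and labels are untouched (subset property)
  keep <- ds$genus %in% my25$classes
  expect_identical(my25$genus, ds$genus[keep])
  expect_identical(my25$images, ds$images[keep])

  expect_error(filter_min_class_size(ds, 1000), "fewer than 2")
})

test_that("crop augmentation multiplies counts and is seed-deterministic", {
  ds <- tiny_image_dataset(per_class = 2, seed = 5)
  # archive-stage dataset for cropping
  ds100 <- generate_dataset(generator_profile("balanced", per_class = 2,
                                              seed = 5, noise = 0),
                            stage = "archive")
  expect_equal(dim(ds100$images[[1]]), c(100L, 100L))

  aug0 <- augment_by_cropping(ds100, 0, seed = 1)
  expect_length(aug0, length(ds100))

  aug1 <- augment_by_cropping(ds100, 1, seed = 1)
  expect_length(aug1, 2L * length(ds100))
  expect_equal(dim(aug1$images[[1]]), c(28L, 28L))
  expect_equal(table(aug1$genus)[[1]], 2L * table(ds100$genus)[[1]])

  aug1b <- augment_by_cropping(ds100, 1, seed = 1)
  expect_identical(aug1$images, aug1b$images)
  aug2 <- augment_by_cropping(ds100, 1, seed = 2)
  expect_false(identical(aug1$images, aug2$images))
})
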