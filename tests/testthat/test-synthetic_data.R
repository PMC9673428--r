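test_that("phantom generation is seed-deterministic and respects lesion counts", {
  pp <- phantom_params(size = c(64, 64), seed = 42)
  p1 <- generate_phantom(pp)
  p2 <- generate_phantom(pp)
  expect_identical(p1$image, p2$image)
  expect_identical(p1$mask, p2$mask)
  expect_true(all(p1$image >= 0 & p1$image <= 1))
  expect_true(all(p1$mask %in% 0:3))
  # zero lesions -> empty mask
  p0 <- generate_phantom(phantom_params(size = c(64, 64),
                                        lesions_per_image = c(0, 0), seed = 1))
  expect_true(all(p0$mask == 0L))
  # different seeds differ
  p3 <- generate_phantom(phantom_params(size = c(64, 64), seed = 43))
  expect_false(identical(p1$image, p3$image))
})

test_that("recorded ellipse area matches the rasterised pixel count", {
  phs <- generate_phantoms(30, phantom_params(size = c(64, 64),
                                              lesions_per_image = c(1, 1),
                                              seed = 11))
  for (p in phs) {
    les <- p$provenance$lesions[[1]]
    area_px <- sum(p$mask == les$class)
    a <- les$axes[1]; b <- les$axes[2]
    perimeter <- pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
    expect_lte(abs(area_px - les$area), perimeter)
  }
})

test_that("lesion class frequencies follow class_probs", {
  probs <- c(0.2, 0.3, 0.5)
  phs <- generate_phantoms(1000, phantom_params(size = c(32, 32),
                                                lesions_per_image = c(1, 1),
                                                class_probs = probs,
                                                axis_range = c(2, 4),
                                                seed = 99))
  cls <- vapply(phs, function(p) p$provenance$lesions[[1]]$class, 1L)
  n <- length(cls)
  for (c in 1:3) {
    se <- sqrt(probs[c] * (1 - probs[c]) / n)
    expect_lte(abs(mean(cls == c) - probs[c]), 3 * se)
  }
})

test_that("RGB mask codec round-trips and flags unknown colours", {
  set.seed(909)
  for (case in 1:20) {
    m <- matrix(sample(0:3, 64, TRUE), 8, 8)
    expect_identical(decode_mask_rgb(encode_mask_rgb(m)), m)
  }
  # canonical colour assignment
  m <- matrix(0L, 2, 2); m[1, 2] <- 3L
  rgb <- encode_mask_rgb(m)
  expect_equal(rgb[1, 2, ], c(255, 255, 0))
  expect_equal(rgb[1, 1, ], c(0, 0, 0))
  # all-background -> all black
  expect_true(all(encode_mask_rgb(matrix(0L, 4, 4)) == 0))
  bad <- rgb; bad[1, 1, ] <- c(12, 34, 56)
  expect_error(decode_mask_rgb(bad), "\\(12,34,56\\)")
})

test_that("train/test split is proportional, disjoint and exhaustive", {
  s <- make_split(110, c(10, 1), seed = 4)
  expect_length(s$train, 100)
  expect_length(s$test, 10)
  expect_length(intersect(s$train, s$test), 0)
  expect_setequal(c(s$train, s$test), 1:110)
  expect_identical(make_split(110, c(10, 1), seed = 4), s)
  expect_false(identical(make_split(110, c(10, 1), seed = 5), s))
  # remainder goes to the training side
  s2 <- make_split(25, c(10, 1), seed = 1)
  expect_length(s2$test, 2)
  expect_length(s2$train, 23)
  expect_error(make_split(5, c(10, 1)), "smaller")
})

test_that("phantom masks are consumable by the metric and loss modules", {
  ph <- fixture_phantoms(2, seed = 31)
  m <- ph[[1]]$mask
  expect_silent(overlap_metrics(confusion_matrix(m, m, 3)))
  C <- 4
  pr <- array(0, c(dim(m), C))
  for (c in 0:3) pr[, , c + 1][m == c] <- 1
  expect_equal(focal_dice_loss(pr, m)$total, 0, tolerance = 1e-5)
})

test_that("dataset round-trips through PNG files and the manifest", {
  dir <- withr::local_tempdir()
  write_phantom_dataset(dir, n = 12,
                        params = phantom_params(size = c(32, 32), seed = 2),
                        ratio = c(10, 1), seed = 3)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  ds <- read_phantom_dataset(dir)
  expect_length(ds$images, 12)
  phs <- generate_phantoms(12, phantom_params(size = c(32, 32), seed = 2))
  expect_identical(ds$masks[[1]], phs[[1]]$mask)
  # 8-bit quantisation bounds the PNG round-trip error at half a gray level
  expect_lt(max(abs(ds$images[[3]] - phs[[3]]$image)), 1 / 254)
  tr <- read_phantom_dataset(dir, "train")
  te <- read_phantom_dataset(dir, "test")
  expect_length(tr$images, 11)
  expect_length(te$images, 1)
})
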