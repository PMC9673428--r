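test_that("confusion matrix tabulates pixels correctly", {
  truth <- matrix(c(0L, 1L, 1L, 2L), 2, 2, byrow = TRUE)
  pred <- matrix(c(0L, 1L, 2L, 2L), 2, 2, byrow = TRUE)
  cm <- confusion_matrix(pred, truth, 2)
  expect_equal(sum(cm), 4)
  expect_equal(cm["0", "0"], 1)
  expect_equal(cm["1", "1"], 1)
  expect_equal(cm["1", "2"], 1)
  expect_equal(cm["2", "2"], 1)
  # identical masks give a diagonal matrix with trace = pixel count
  cm2 <- confusion_matrix(truth, truth, 2)
  expect_equal(sum(diag(cm2)), 4)
  expect_equal(sum(cm2) - sum(diag(cm2)), 0)
  # swapping the arguments transposes
  expect_equal(unclass(confusion_matrix(truth, pred, 2)), t(unclass(cm)),
               ignore_attr = TRUE)
  expect_error(confusion_matrix(pred, matrix(0L, 3, 3), 2), "shapes")
  expect_error(confusion_matrix(pred + 10L, truth, 2), "labels")
})

test_that("overlap metrics reproduce hand values and the perfect fixed point", {
  truth <- matrix(c(0L, 1L, 1L, 2L), 2, 2, byrow = TRUE)
  pred <- matrix(c(0L, 1L, 2L, 2L), 2, 2, byrow = TRUE)
  om <- overlap_metrics(confusion_matrix(pred, truth, 2))
  expect_equal(om$accuracy, 3 / 4)
  expect_equal(om$miou, mean(c(1, 1 / 2, 1 / 2)))
  perfect <- overlap_metrics(confusion_matrix(truth, truth, 2))
  for (f in c("miou", "mpa", "mprecision", "mdice", "accuracy"))
    expect_equal(perfect[[f]], 1)
})

test_that("overlap metrics equal the set-operation oracle on random masks", {
  set.seed(707)
  for (case in 1:1000) {
    k <- 3
    truth <- matrix(sample(0:k, 64, TRUE), 8, 8)
    pred <- matrix(sample(0:k, 64, TRUE), 8, 8)
    om <- overlap_metrics(confusion_matrix(pred, truth, k))
    oo <- oracle_overlap(pred, truth, k)
    for (f in names(oo))
      expect_equal(om[[f]], oo[[f]], tolerance = 1e-12, info = f)
  }
})

test_that("metrics stay within [0, 1] on random masks", {
  set.seed(708)
  for (case in 1:50) {
    truth <- matrix(sample(0:3, 100, TRUE), 10, 10)
    pred <- matrix(sample(0:3, 100, TRUE), 10, 10)
    om <- overlap_metrics(confusion_matrix(pred, truth, 3))
    for (f in c("miou", "mpa", "mprecision", "mdice", "accuracy")) {
      expect_gte(om[[f]], 0)
      expect_lte(om[[f]], 1)
    }
  }
})

test_that("boundary extraction follows the 4-neighbour + border convention", {
  # single pixel is its own boundary
  m <- matrix(0L, 5, 5); m[3, 3] <- 1L
  expect_equal(unclass(extract_boundary(m, 1)),
               matrix(c(2L, 2L), 1, dimnames = list(NULL, c("row", "col"))))
  # filled 4x4 square: the 12 perimeter pixels
  m <- matrix(0L, 6, 6); m[2:5, 2:5] <- 1L
  b <- extract_boundary(m, 1)
  expect_equal(nrow(b), 12)
  expect_false(any(b[, 1] == 2 & b[, 2] == 2))  # interior excluded (0-based (2,2))
  # full-image class: all border pixels
  m <- matrix(1L, 4, 4)
  expect_equal(nrow(extract_boundary(m, 1)), 12)
  expect_error(extract_boundary(m, 2), "absent")
})

test_that("Hausdorff and ASD match hand values and symmetry properties", {
  a <- matrix(c(0, 0), 1)
  b <- matrix(c(3, 4), 1)
  expect_equal(hausdorff95(a, b), 5)
  expect_equal(hausdorff95(a, a), 0)
  expect_equal(hausdorff95(a, b, spacing = 2), 10)
  seg <- matrix(c(0, 0, 0, 2), 2, 2, byrow = TRUE)
  expect_equal(asd(seg, a), 1)      # (0 + 2) / 2
  expect_equal(asd(a, a), 0)
  expect_error(hausdorff95(a, matrix(numeric(0), 0, 2)), "second")
})

test_that("boundary distances equal the all-pairs oracle", {
  set.seed(808)
  for (case in 1:200) {
    na <- sample(1:50, 1); nb <- sample(1:50, 1)
    a <- unique(cbind(sample(0:40, na, TRUE), sample(0:40, na, TRUE)))
    b <- unique(cbind(sample(0:40, nb, TRUE), sample(0:40, nb, TRUE)))
    o <- oracle_directed(a, b)
    expect_equal(hausdorff95(a, b),
                 max(quantile(o$da, .95, names = FALSE),
                     quantile(o$db, .95, names = FALSE)),
                 tolerance = 1e-10)
    expect_equal(asd(a, b), mean(o$da), tolerance = 1e-10)
    hd_max <- hausdorff95(a, b, percentile = 100)
    expect_equal(hd_max, max(o$da, o$db), tolerance = 1e-10)
    # the exact maximum is symmetric; the one-directional ASD need not be
    expect_equal(hd_max, hausdorff95(b, a, percentile = 100), tolerance = 1e-10)
  }
})

test_that("segmentation_report combines overlap and boundary metrics", {
  set.seed(809)
  ph <- fixture_phantoms(1, seed = 21)[[1]]
  rep <- segmentation_report(ph$mask, ph$mask, k = 3)
  expect_equal(rep$miou, 1)
  expect_equal(rep$mdice, 1)
  expect_equal(rep$hausdorff95, 0)
  expect_equal(rep$asd, 0)
})
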