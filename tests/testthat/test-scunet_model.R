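test_that("default-config shape table reproduces the published layer shapes", {
  st <- shape_summary(scunet_config())
  get <- function(nm) unlist(st[st$activation == nm, c("channels", "height", "width")])
  expect_equal(unname(get("feature1")), c(64, 512, 512))
  expect_equal(unname(get("feature2")), c(128, 256, 256))
  expect_equal(unname(get("feature3")), c(256, 128, 128))
  expect_equal(unname(get("feature4")), c(512, 64, 64))
  expect_equal(unname(get("feature5")), c(512, 32, 32))
  expect_equal(unname(get("up1")), c(64, 512, 512))
  expect_equal(unname(get("feature10")), c(512, 32, 32))
  expect_equal(unname(get("feature9")), c(512, 64, 64))
  expect_equal(unname(get("feature8")), c(256, 128, 128))
  expect_equal(unname(get("feature7")), c(128, 256, 256))
  expect_equal(unname(get("up9")), c(512, 64, 64))
  expect_equal(unname(get("up8")), c(256, 128, 128))
  expect_equal(unname(get("up7")), c(128, 256, 256))
  expect_equal(unname(get("prob")), c(4, 512, 512))
  # width scaling is linear in the channel column
  st8 <- shape_summary(scunet_config(layer_widths = c(64, 128, 256, 512, 512) / 8))
  expect_equal(st8$channels[st8$activation != "prob"],
               st$channels[st$activation != "prob"] / 8)
})

test_that("shape_summary agrees with real forward passes over random configs", {
  set.seed(202)
  for (case in 1:20) {
    sz <- sample(c(16L, 32L), 1)
    cfg <- scunet_config(input_size = c(sz, sz),
                         layer_widths = sample(2:6, 5, replace = TRUE),
                         num_classes = sample(2:5, 1),
                         upconv_kernel = sample(c(3L, 4L), 1))
    m <- scunet(cfg, seed = case)
    acts <- scunet_activations(m, matrix(runif(sz * sz), sz, sz))
    st <- shape_summary(cfg)
    for (r in seq_len(nrow(st))) {
      a <- acts[[st$activation[r]]]
      expect_false(is.null(a), info = st$activation[r])
      expect_equal(dim(a)[1:3],
                   c(st$height[r], st$width[r], st$channels[r]),
                   info = paste(st$activation[r], "case", case))
    }
  }
})

test_that("encoder halves resolution and follows the layer widths", {
  cfg <- scunet_config(input_size = c(64, 64), layer_widths = c(8, 16, 32, 64, 64))
  m <- scunet(cfg, seed = 1)
  f <- forward_encoder(m, matrix(runif(64 * 64), 64, 64))
  expect_named(f, paste0("feature", 1:5))
  expect_equal(dim(f$feature2)[1:3], c(32, 32, 16))
  expect_equal(dim(f$feature5)[1:3], c(4, 4, 64))
  u <- forward_decoder(m, f)
  expect_equal(dim(u$up1)[1:3], c(64, 64, 8))
  expect_equal(dim(u$up4)[1:3], c(8, 8, 64))
})

test_that("forward output is a proper per-pixel distribution and deterministic", {
  cfg <- small_fixture_config()
  m <- scunet(cfg, seed = 5)
  img <- matrix(runif(64 * 64), 64, 64)
  p1 <- scunet_forward(m, img)
  expect_equal(dim(p1), c(64, 64, 4))
  expect_gte(min(p1), 0)
  expect_equal(apply(p1, c(1, 2), sum), matrix(1, 64, 64), tolerance = 1e-5)
  p2 <- scunet_forward(scunet(cfg, seed = 5), img)
  expect_identical(p1, p2)
  # different seed, different parameters
  p3 <- scunet_forward(scunet(cfg, seed = 6), img)
  expect_false(identical(p1, p3))
})

test_that("bad inputs are rejected with informative errors", {
  expect_error(scunet_config(input_size = c(100, 100)), "divisible by 16")
  expect_error(scunet_config(layer_widths = 1:4), "five")
  expect_error(scunet_config(num_classes = 1), ">= 2")
  m <- scunet(small_fixture_config(), seed = 1)
  expect_error(scunet_forward(m, matrix(0, 60, 60)), "divisible by 16")
  expect_error(scunet_forward(m, array(0, c(64, 64, 2))), "channels")
})
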