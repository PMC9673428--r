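#' SCU-Net configuration
#'
#' SCU-Net is two VGG16-style encoder-decoder networks run in series: the
#' full-resolution output of the first decoder is the input of the second
#' encoder, and same-layer feature maps of the two networks are bridged by
#' channel concatenation followed by two 3x3 convolutions that restore the
#' layer width. Encoder convolutions are HDC groups (see [hdc_schedule()]);
#' decoders upsample with stride-2 transposed convolutions.
#'
#' @param input_size `c(H, W)` in pixels; both must be divisible by 16
#'   (four 2x2 poolings).
#' @param in_channels channels seen by the first convolution; grayscale
#'   images are replicated to this count (default 3).
#' @param layer_widths five channel widths, one per resolution level.
#' @param num_classes segmentation classes including background.
#' @param hdc the dilation schedule of every encoder HDC group.
#' @param upconv_kernel transposed-convolution kernel (4 gives exact x2
#'   upsampling without uneven overlap; 3 is also supported).
#' @return an object of class `scunet_config`.
#' @export
scunet_config <- function(input_size = c(512L, 512L), in_channels = 3L,
                          layer_widths = c(64L, 128L, 256L, 512L, 512L),
                          num_classes = 4L, hdc = hdc_schedule(),
                          upconv_kernel = 4L) {
  input_size <- as.integer(input_size)
  layer_widths <- as.integer(layer_widths)
  if (length(input_size) != 2L || any(input_size < 16L) ||
      any(input_size %% 16L != 0L))
    stop("input_size must be two values divisible by 16, got ",
         paste(input_size, collapse = " x "))
  if (length(layer_widths) != 5L || any(layer_widths < 1L))
    stop("layer_widths must be five positive integers")
  if (num_classes < 2L) stop("num_classes must be >= 2")
  stopifnot(inherits(hdc, "hdc_schedule"))
  structure(list(input_size = input_size, in_channels = as.integer(in_channels),
                 layer_widths = layer_widths, num_classes = as.integer(num_classes),
                 hdc = hdc, upconv_kernel = as.integer(upconv_kernel)),
            class = "scunet_config")
}

# The single source of truth for the serial wiring.  `ops` is either
# tape_ops() (training) or raw_ops() (inference); activations are returned
# under their published names ("feature1".."feature10", "up1".."up9",
# primed intermediates, and "prob").
scunet_core <- function(ops, x, cfg, keep = TRUE) {
  w <- cfg$layer_widths
  sch <- cfg$hdc
  uk <- cfg$upconv_kernel
  acts <- list()
  note <- function(name, nd) {
    if (keep) acts[[name]] <<- nd
    nd
  }
  hdc <- function(x, pfx, co) hdc_group_core(ops, x, pfx, sch, co)
  dc <- function(x, pfx, co) double_conv_core(ops, x, pfx, co)
  up <- function(x, pfx, co) ops$convT(x, pfx, co, K = uk)

  # encoder 1
  f1 <- note("feature1", hdc(x, "e1l1", w[1]))
  f2 <- note("feature2", hdc(ops$pool(f1), "e1l2", w[2]))
  f3 <- note("feature3", hdc(ops$pool(f2), "e1l3", w[3]))
  f4 <- note("feature4", hdc(ops$pool(f3), "e1l4", w[4]))
  f5 <- note("feature5", hdc(ops$pool(f4), "e1l5", w[5]))
  # decoder 1
  u4 <- note("up4", dc(ops$concat(up(f5, "d1l4.up", w[4]), f4), "d1l4", w[4]))
  u3 <- note("up3", dc(ops$concat(up(u4, "d1l3.up", w[3]), f3), "d1l3", w[3]))
  u2 <- note("up2", dc(ops$concat(up(u3, "d1l2.up", w[2]), f2), "d1l2", w[2]))
  u1 <- note("up1", dc(ops$concat(up(u2, "d1l1.up", w[1]), f1), "d1l1", w[1]))
  # encoder 2 (serial: input is up1) with cross-network concatenations
  f6  <- note("feature6", hdc(u1, "e2l1", w[1]))
  f7p <- note("feature7'", hdc(ops$pool(f6), "e2l2", w[2]))
  f7  <- note("feature7", dc(ops$concat(f7p, f2), "x2l2", w[2]))
  f8p <- note("feature8'", hdc(ops$pool(f7), "e2l3", w[3]))
  f8  <- note("feature8", dc(ops$concat(f8p, f3), "x2l3", w[3]))
  f9p <- note("feature9'", hdc(ops$pool(f8), "e2l4", w[4]))
  f9  <- note("feature9", dc(ops$concat(f9p, f4), "x2l4", w[4]))
  f10p <- note("feature10'", hdc(ops$pool(f9), "e2l5", w[5]))
  f10  <- note("feature10", dc(ops$concat(f10p, f5), "x2l5", w[5]))
  # decoder 2 with skips from both encoder 2 and decoder 1
  u9p <- note("up9'", dc(ops$concat(up(f10, "d2l4.up", w[4]), f9), "d2l4", w[4]))
  u9  <- note("up9", dc(ops$concat(u9p, u4), "y2l4", w[4]))
  u8p <- note("up8'", dc(ops$concat(up(u9, "d2l3.up", w[3]), f8), "d2l3", w[3]))
  u8  <- note("up8", dc(ops$concat(u8p, u3), "y2l3", w[3]))
  u7p <- note("up7'", dc(ops$concat(up(u8, "d2l2.up", w[2]), f7), "d2l2", w[2]))
  u7  <- note("up7", dc(ops$concat(u7p, u2), "y2l2", w[2]))
  u6  <- note("up6", dc(ops$concat(up(u7, "d2l1.up", w[1]), f6), "d2l1", w[1]))
  # classification head: 1x1 convolution to num_classes, then softmax
  z <- ops$conv(u6, "head", cfg$num_classes, K = 1L, rate = 1L, pad = 0L)
  prob <- note("prob", ops$softmax(z))
  list(acts = acts, prob = prob)
}

# Prepare an input image for the network: grayscale replication + batching.
prep_input <- function(image, cfg) {
  x <- as_hwcn(image)
  d <- dim(x)
  if (d[3L] == 1L && cfg$in_channels > 1L)
    x <- x[, , rep(1L, cfg$in_channels), , drop = FALSE]
  if (dim(x)[3L] != cfg$in_channels)
    stop("image has ", d[3L], " channels; the model expects ",
         cfg$in_channels, " (grayscale inputs are replicated automatically)")
  x
}

check_input_size <- function(image, cfg) {
  d <- dim(as_hwcn(image))
  if (any(d[1:2] %% 16L != 0L))
    stop("input spatial size ", d[1L], " x ", d[2L],
         " must be divisible by 16 (four 2x2 poolings); ",
         "use predict(), which reflection-pads automatically")
  invisible(TRUE)
}

#' Construct an SCU-Net model with freshly initialised parameters
#'
#' Convolution weights are He-uniform in the fan-in, biases zero, batch-norm
#' scale/shift 1/0 with unit running variance. Initialisation is fully
#' determined by `seed`.
#'
#' @param config a [scunet_config()].
#' @param seed integer RNG seed for the parameter draw.
#' @return an object of class `scunet` holding `config`, `params` (named
#'   list of arrays) and `bn` (running statistics).
#' @export
scunet <- function(config = scunet_config(), seed = 1L) {
  stopifnot(inherits(config, "scunet_config"))
  pe <- new.env(parent = emptyenv())
  pe$params <- list()
  pe$bn <- list()
  # dry run at the smallest legal size materialises every parameter shape
  with_seed(seed, {
    x0 <- array(0, c(16L, 16L, config$in_channels, 1L))
    invisible(scunet_core(raw_ops(pe), x0, config, keep = FALSE))
  })
  structure(list(config = config, params = pe$params, bn = pe$bn, seed = seed),
            class = "scunet")
}

model_env <- function(model) {
  pe <- new.env(parent = emptyenv())
  pe$params <- model$params
  pe$bn <- model$bn
  pe
}

#' Run a forward pass
#'
#' @param model a [scunet()] model (or a fitted `scunet_fit`).
#' @param image H x W grayscale matrix in `[0, 1]` (or H x W x C array
#'   matching `in_channels`); spatial size must be divisible by 16.
#' @return per-pixel class probabilities, an H x W x num_classes array whose
#'   channel sums are 1 at every pixel.
#' @export
scunet_forward <- function(model, image) {
  if (inherits(model, "scunet_fit")) model <- model$model
  stopifnot(inherits(model, "scunet"))
  cfg <- model$config
  check_input_size(image, cfg)
  x <- prep_input(image, cfg)
  out <- scunet_core(raw_ops(model_env(model)), x, cfg, keep = FALSE)
  p <- out$prob
  array(p, dim(p)[1:3])
}

#' Forward pass returning every named activation
#'
#' Runs the serial network and returns the full set of named feature maps
#' (`feature1`..`feature10` with primed intermediates, `up1`..`up9` with
#' primes, `up6`, and `prob`), each an (H, W, C, 1) array. Useful for
#' verifying the wiring against [shape_summary()].
#'
#' @inheritParams scunet_forward
#' @return named list of activation arrays in computation order.
#' @export
scunet_activations <- function(model, image) {
  if (inherits(model, "scunet_fit")) model <- model$model
  stopifnot(inherits(model, "scunet"))
  cfg <- model$config
  check_input_size(image, cfg)
  x <- prep_input(image, cfg)
  scunet_core(raw_ops(model_env(model)), x, cfg, keep = TRUE)$acts
}

#' Run one encoder over an image
#'
#' Applies the five-layer HDC encoder of the first network: each layer is an
#' HDC group followed by 2x2 max pooling into the next layer, so resolutions
#' halve (512 -> 256 -> 128 -> 64 -> 32 at defaults) while widths follow
#' `layer_widths`.
#'
#' @inheritParams scunet_forward
#' @return list of arrays `feature1`..`feature5`.
#' @export
forward_encoder <- function(model, image) {
  acts <- scunet_activations(model, image)
  acts[paste0("feature", 1:5)]
}

#' Run the first decoder over encoder features
#'
#' Each decoder step doubles resolution with a stride-2 transposed
#' convolution, concatenates the same-layer encoder feature, and restores the
#' layer width with two 3x3 convolutions.
#'
#' @param model a [scunet()] model.
#' @param features list `feature1`..`feature5` from [forward_encoder()].
#' @return list of arrays `up4`, `up3`, `up2`, `up1` in computation order
#'   (`up1` is the full-resolution output fed to the second encoder).
#' @export
forward_decoder <- function(model, features) {
  if (inherits(model, "scunet_fit")) model <- model$model
  stopifnot(inherits(model, "scunet"))
  cfg <- model$config
  w <- cfg$layer_widths
  ops <- raw_ops(model_env(model))
  f <- lapply(features, as_hwcn)
  up <- function(x, pfx, co) ops$convT(x, pfx, co, K = cfg$upconv_kernel)
  dc <- function(x, pfx, co) double_conv_core(ops, x, pfx, co)
  u4 <- dc(ops$concat(up(f[[5]], "d1l4.up", w[4]), f[[4]]), "d1l4", w[4])
  u3 <- dc(ops$concat(up(u4, "d1l3.up", w[3]), f[[3]]), "d1l3", w[3])
  u2 <- dc(ops$concat(up(u3, "d1l2.up", w[2]), f[[2]]), "d1l2", w[2])
  u1 <- dc(ops$concat(up(u2, "d1l1.up", w[1]), f[[1]]), "d1l1", w[1])
  list(up4 = u4, up3 = u3, up2 = u2, up1 = u1)
}

#' Analytic table of every named activation shape
#'
#' Computes the (channels, height, width) of every named feature map of the
#' serial network from the configuration alone, without running a forward
#' pass; [scunet_activations()] must (and, in the test suite, does) agree.
#'
#' @param config a [scunet_config()].
#' @return a data frame of class `shape_table` with columns `activation`,
#'   `channels`, `height`, `width`, in computation order.
#' @export
shape_summary <- function(config = scunet_config()) {
  stopifnot(inherits(config, "scunet_config"))
  w <- config$layer_widths
  H <- config$input_size[1L]; W <- config$input_size[2L]
  hl <- H %/% 2L^(0:4); wl <- W %/% 2L^(0:4)
  row <- function(name, ch, l) data.frame(activation = name, channels = ch,
                                          height = hl[l], width = wl[l],
                                          stringsAsFactors = FALSE)
  tab <- rbind(
    row("feature1", w[1], 1), row("feature2", w[2], 2), row("feature3", w[3], 3),
    row("feature4", w[4], 4), row("feature5", w[5], 5),
    row("up4", w[4], 4), row("up3", w[3], 3), row("up2", w[2], 2), row("up1", w[1], 1),
    row("feature6", w[1], 1),
    row("feature7'", w[2], 2), row("feature7", w[2], 2),
    row("feature8'", w[3], 3), row("feature8", w[3], 3),
    row("feature9'", w[4], 4), row("feature9", w[4], 4),
    row("feature10'", w[5], 5), row("feature10", w[5], 5),
    row("up9'", w[4], 4), row("up9", w[4], 4),
    row("up8'", w[3], 3), row("up8", w[3], 3),
    row("up7'", w[2], 2), row("up7", w[2], 2),
    row("up6", w[1], 1),
    row("prob", config$num_classes, 1))
  class(tab) <- c("shape_table", "data.frame")
  tab
}

#' @export
print.shape_table <- function(x, ...) {
  cat("SCU-Net activation shapes (channels x height x width):\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' @export
print.scunet_config <- function(x, ...) {
  cat("SCU-Net configuration\n")
  cat("  input: ", x$input_size[1], " x ", x$input_size[2], " x ",
      x$in_channels, "\n", sep = "")
  cat("  layer widths: ", paste(x$layer_widths, collapse = ", "), "\n", sep = "")
  cat("  classes: ", x$num_classes, "\n", sep = "")
  cat("  HDC rates: ", paste(x$hdc$rates, collapse = ", "),
      " (kernel ", x$hdc$kernel, ")\n", sep = "")
  cat("  upconv kernel: ", x$upconv_kernel, "\n", sep = "")
  invisible(x)
}

#' @export
print.scunet <- function(x, ...) {
  print(x$config)
  np <- sum(vapply(x$params, length, 1L))
  cat("  parameters: ", format(np, big.mark = ","), "\n", sep = "")
  invisible(x)
}
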