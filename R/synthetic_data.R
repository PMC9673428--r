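#' Parameters of the tumour-phantom generator
#'
#' Phantoms emulate single-slice grayscale brain MR images for developing and
#' testing the segmentation stack: a smooth textured "brain" disk on a dark
#' background, containing 0-2 elliptical lesions, each assigned one of three
#' tumour classes (1 = glioma, 2 = meningioma, 3 = pituitary) with a
#' class-specific brightness. The matching label mask uses 0 for background.
#'
#' @param size `c(H, W)` in pixels, both >= 32.
#' @param lesions_per_image inclusive integer range `c(min, max)` of lesions.
#' @param class_probs probabilities of the three tumour classes (sum 1).
#' @param axis_range ellipse semi-axis range in pixels; default
#'   `min(size) * c(1/16, 1/6)` (at least 2).
#' @param intensity per-class lesion brightness: list with `mean` (length 3)
#'   and `sd` of the per-lesion draw.
#' @param background_texture_scale length scale, in pixels, of the smooth
#'   background texture.
#' @param noise_sigma standard deviation of the additive Gaussian pixel
#'   noise (image clipped to `[0, 1]`).
#' @param seed integer seed; the phantom is a deterministic function of the
#'   parameters including the seed.
#' @return an object of class `phantom_params`.
#' @export
phantom_params <- function(size = c(512L, 512L), lesions_per_image = c(0L, 2L),
                           class_probs = rep(1, 3) / 3, axis_range = NULL,
                           intensity = list(mean = c(0.65, 0.8, 0.95), sd = 0.05),
                           background_texture_scale = NULL, noise_sigma = 0.02,
                           seed = 1L) {
  size <- as.integer(size)
  if (length(size) != 2L || any(size < 32L))
    stop("size must be two integers >= 32")
  lesions_per_image <- as.integer(lesions_per_image)
  if (length(lesions_per_image) != 2L || lesions_per_image[1L] < 0L ||
      lesions_per_image[2L] < lesions_per_image[1L])
    stop("lesions_per_image must be an increasing nonnegative range")
  if (length(class_probs) != 3L || any(class_probs < 0) ||
      abs(sum(class_probs) - 1) > 1e-9)
    stop("class_probs must be 3 nonnegative values summing to 1")
  if (is.null(axis_range))
    axis_range <- pmax(2, min(size) * c(1 / 16, 1 / 6))
  if (axis_range[2L] > min(size) / 2)
    stop("axis_range does not fit in the image")
  if (is.null(background_texture_scale))
    background_texture_scale <- min(size) / 8
  structure(list(size = size, lesions_per_image = lesions_per_image,
                 class_probs = class_probs, axis_range = axis_range,
                 intensity = intensity,
                 background_texture_scale = background_texture_scale,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_params")
}

# smooth random field: coarse Gaussian grid, bilinear-interpolated to H x W
smooth_field <- function(H, W, scale) {
  ch <- max(3L, ceiling(H / scale) + 1L)
  cw <- max(3L, ceiling(W / scale) + 1L)
  g <- matrix(stats::rnorm(ch * cw), ch, cw)
  ri <- seq(1, ch, length.out = H)
  ci <- seq(1, cw, length.out = W)
  r0 <- pmin(floor(ri), ch - 1L); rf <- ri - r0
  c0 <- pmin(floor(ci), cw - 1L); cf <- ci - c0
  a <- g[cbind(rep(r0, W), rep(c0, each = H))]
  b <- g[cbind(rep(r0 + 1L, W), rep(c0, each = H))]
  dd <- g[cbind(rep(r0, W), rep(c0 + 1L, each = H))]
  e <- g[cbind(rep(r0 + 1L, W), rep(c0 + 1L, each = H))]
  rfm <- rep(rf, W); cfm <- rep(cf, each = H)
  matrix((1 - rfm) * (1 - cfm) * a + rfm * (1 - cfm) * b +
           (1 - rfm) * cfm * dd + rfm * cfm * e, H, W)
}

# pixel-centre inside-ellipse test; 0-based centre coordinates
ellipse_mask <- function(H, W, cy, cx, a, b, theta) {
  y <- matrix(0:(H - 1L), H, W) - cy
  x <- matrix(0:(W - 1L), H, W, byrow = TRUE) - cx
  u <- cos(theta) * y + sin(theta) * x
  v <- -sin(theta) * y + cos(theta) * x
  (u / a)^2 + (v / b)^2 <= 1
}

#' Generate one phantom image/mask pair
#'
#' Deterministic in `params` (same seed gives bit-identical output). Lesions
#' are filled rotated ellipses rasterised by the pixel-centre rule; when
#' lesions overlap the later one wins. Each lesion must fit inside the brain
#' disk; placement retries up to 50 times before failing.
#'
#' @param params a [phantom_params()].
#' @return an object of class `phantom`: list with `image` (H x W matrix in
#'   `[0, 1]`), `mask` (integer H x W matrix over 0..3) and `provenance`
#'   (the parameters plus per-lesion ellipse ground truth).
#' @export
generate_phantom <- function(params = phantom_params()) {
  stopifnot(inherits(params, "phantom_params"))
  H <- params$size[1L]; W <- params$size[2L]
  with_seed(params$seed, {
    # brain: slightly elliptical disk, smooth texture inside
    cy <- (H - 1) / 2; cx <- (W - 1) / 2
    ba <- 0.45 * H * stats::runif(1, 0.9, 1); bb <- 0.45 * W * stats::runif(1, 0.9, 1)
    btheta <- stats::runif(1, 0, pi)
    brain <- ellipse_mask(H, W, cy, cx, ba, bb, btheta)
    tex <- smooth_field(H, W, params$background_texture_scale)
    img <- matrix(0.05, H, W)
    img[brain] <- 0.35 + 0.06 * tex[brain]
    mask <- matrix(0L, H, W)
    lr <- params$lesions_per_image
    nles <- lr[1L] + sample.int(lr[2L] - lr[1L] + 1L, 1L) - 1L
    lesions <- list()
    if (nles > 0) for (li in seq_len(nles)) {
      cls <- sample(3L, 1L, prob = params$class_probs)
      placed <- FALSE
      for (try in 1:50) {
        a <- stats::runif(1, params$axis_range[1L], params$axis_range[2L])
        b <- stats::runif(1, params$axis_range[1L], params$axis_range[2L])
        th <- stats::runif(1, 0, pi)
        r <- max(a, b)
        ly <- stats::runif(1, r + 1, H - r - 2)
        lx <- stats::runif(1, r + 1, W - r - 2)
        em <- ellipse_mask(H, W, ly, lx, a, b, th)
        if (all(brain[em])) { placed <- TRUE; break }
      }
      if (!placed)
        stop("could not place lesion ", li, " inside the brain after 50 tries")
      mu <- params$intensity$mean[cls]
      img[em] <- stats::rnorm(1, mu, params$intensity$sd)
      mask[em] <- cls
      lesions[[li]] <- list(class = cls, center = c(ly, lx), axes = c(a, b),
                            angle = th, area = pi * a * b)
    }
    img <- img + stats::rnorm(H * W, 0, params$noise_sigma)
    img <- pmin(pmax(img, 0), 1)
    structure(list(image = img, mask = mask,
                   provenance = list(params = params, lesions = lesions)),
              class = "phantom")
  })
}

#' Generate a set of phantoms
#'
#' Phantom `i` uses seed `params$seed + i - 1`, so the set is deterministic
#' and any element can be regenerated in isolation.
#'
#' @param n number of phantoms.
#' @param params a [phantom_params()]; per-item seeds are derived from its
#'   `seed`.
#' @return list of `phantom` objects.
#' @export
generate_phantoms <- function(n, params = phantom_params()) {
  lapply(seq_len(n), function(i) {
    p <- params
    p$seed <- params$seed + i - 1L
    generate_phantom(p)
  })
}

#' @export
print.phantom <- function(x, ...) {
  les <- x$provenance$lesions
  cat("phantom ", nrow(x$image), " x ", ncol(x$image), ", ",
      length(les), " lesion(s)", sep = "")
  if (length(les))
    cat(" of class ", paste(vapply(les, `[[`, 1L, "class"), collapse = ", "),
        sep = "")
  cat("\n")
  invisible(x)
}

#' @export
plot.phantom <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  show_img <- function(m, main) graphics::image(
    t(m)[, nrow(m):1], col = grDevices::gray.colors(256, 0, 1),
    axes = FALSE, main = main, useRaster = TRUE)
  show_img(x$image, "image")
  show_img(x$mask / 3, "mask")
  invisible(x)
}

mask_palette <- matrix(c(0, 0, 0,      # 0 background  black
                         255, 0, 0,    # 1 glioma      red
                         0, 255, 0,    # 2 meningioma  green
                         255, 255, 0), # 3 pituitary   yellow
                       nrow = 4L, byrow = TRUE,
                       dimnames = list(0:3, c("r", "g", "b")))

#' Encode a label mask as the canonical class colours
#'
#' Background is black, glioma red `(255,0,0)`, meningioma green
#' `(0,255,0)`, pituitary yellow `(255,255,0)`.
#'
#' @param mask integer label matrix over `{0..3}`.
#' @return an H x W x 3 array with values in `{0, 255}`.
#' @export
encode_mask_rgb <- function(mask) {
  mv <- as.integer(mask)
  if (any(mv < 0L | mv > 3L)) stop("mask labels must lie in {0..3}")
  out <- array(0, c(dim(mask), 3L))
  for (ch in 1:3) out[, , ch] <- matrix(mask_palette[mv + 1L, ch], nrow(mask))
  out
}

#' Decode a class-coloured image back to a label mask
#'
#' Inverse of [encode_mask_rgb()]; accepts values in `{0..255}` or `[0, 1]`
#' (PNG convention). Pixels whose colour is not one of the four canonical
#' class colours raise an error naming the offending colours.
#'
#' @param rgb H x W x 3 colour array.
#' @return integer label matrix over `{0..3}`.
#' @export
decode_mask_rgb <- function(rgb) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3L] != 3L)
    stop("expected an H x W x 3 colour array")
  if (max(rgb) <= 1) rgb <- rgb * 255
  rgb <- round(rgb)
  code <- rgb[, , 1L] * 65536 + rgb[, , 2L] * 256 + rgb[, , 3L]
  pal_code <- mask_palette[, 1L] * 65536 + mask_palette[, 2L] * 256 +
    mask_palette[, 3L]
  m <- match(code, pal_code)
  if (anyNA(m)) {
    bad <- unique(code[is.na(m)])
    bad_str <- sprintf("(%d,%d,%d)", bad %/% 65536, (bad %/% 256) %% 256,
                       bad %% 256)
    stop("unknown mask colours: ", paste(utils::head(bad_str, 5), collapse = ", "),
         if (length(bad_str) > 5) " ...")
  }
  matrix(m - 1L, nrow(code), ncol(code))
}

#' Deterministic train/test split
#'
#' Shuffles `1..n` with the seed and splits in proportion
#' `ratio[1]:ratio[2]`; the test share is `floor(n * ratio[2] / sum(ratio))`
#' and the remainder goes to the training set, so `n = 110` at the standard
#' 10:1 ratio yields 100 train / 10 test.
#'
#' @param n number of samples.
#' @param ratio `c(train, test)` proportion (default `c(10, 1)`).
#' @param seed shuffle seed.
#' @return list with disjoint, exhaustive integer vectors `train` and
#'   `test`.
#' @export
make_split <- function(n, ratio = c(10, 1), seed = 1L) {
  if (n < sum(ratio)) stop("n = ", n, " is smaller than the ratio total ",
                           sum(ratio))
  n_test <- floor(n * ratio[2L] / sum(ratio))
  idx <- with_seed(seed, sample.int(n))
  list(train = sort(idx[seq_len(n - n_test)]),
       test = sort(idx[n - n_test + seq_len(n_test)]))
}

#' Optional flip/rotation augmentation
#'
#' Mirrors the "image enhancement" used to enlarge the study data: appends
#' horizontally flipped and 90-degree-rotated copies of each phantom. Off by
#' default in all pipelines.
#'
#' @param phantoms list of `phantom` objects.
#' @param flips append left-right flips.
#' @param rotations append 90-degree rotations.
#' @return the augmented list.
#' @export
augment_phantoms <- function(phantoms, flips = TRUE, rotations = FALSE) {
  out <- phantoms
  fl <- function(m) m[, ncol(m):1]
  rot <- function(m) t(m)[, nrow(m):1]
  for (p in phantoms) {
    if (flips)
      out[[length(out) + 1L]] <- structure(
        list(image = fl(p$image), mask = fl(p$mask),
             provenance = c(p$provenance, transform = "fliplr")),
        class = "phantom")
    if (rotations)
      out[[length(out) + 1L]] <- structure(
        list(image = rot(p$image), mask = rot(p$mask),
             provenance = c(p$provenance, transform = "rot90")),
        class = "phantom")
  }
  out
}
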