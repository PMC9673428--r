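#' Write a phantom dataset to disk
#'
#' Writes `images/*.png` (8-bit grayscale), `masks/*.png` (labels 0-3 stored
#' as gray levels 0-3), `masks_rgb/*.png` (class colours) and a
#' `manifest.json` holding the generator parameters, the per-image lesion
#' ground truth and the train/test split.
#'
#' @param dir output directory (created if missing).
#' @param n number of phantoms.
#' @param params a [phantom_params()].
#' @param ratio train/test ratio passed to [make_split()].
#' @param seed split seed.
#' @return the manifest, invisibly.
#' @export
write_phantom_dataset <- function(dir, n, params = phantom_params(),
                                  ratio = c(10, 1), seed = 1L) {
  for (sub in c("images", "masks", "masks_rgb"))
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  phs <- generate_phantoms(n, params)
  entries <- vector("list", n)
  for (i in seq_len(n)) {
    nm <- sprintf("phantom_%04d.png", i)
    png::writePNG(phs[[i]]$image, file.path(dir, "images", nm))
    png::writePNG(phs[[i]]$mask / 255, file.path(dir, "masks", nm))
    png::writePNG(encode_mask_rgb(phs[[i]]$mask) / 255,
                  file.path(dir, "masks_rgb", nm))
    entries[[i]] <- list(file = nm, lesions = phs[[i]]$provenance$lesions)
  }
  split <- make_split(n, ratio, seed)
  manifest <- list(n = n, params = unclass(params), split = split,
                   images = entries)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a phantom dataset written by [write_phantom_dataset()]
#'
#' @param dir dataset directory.
#' @param subset `"all"`, `"train"` or `"test"` (per the manifest split).
#' @return list with `images` (matrices in `[0, 1]`) and `masks` (integer
#'   matrices), plus the parsed `manifest`.
#' @export
read_phantom_dataset <- function(dir, subset = c("all", "train", "test")) {
  subset <- match.arg(subset)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  files <- manifest$images$file
  idx <- switch(subset, all = seq_along(files),
                train = manifest$split$train, test = manifest$split$test)
  images <- lapply(files[idx], function(f)
    read_gray_png(file.path(dir, "images", f)))
  masks <- lapply(files[idx], function(f)
    read_mask_png(file.path(dir, "masks", f)))
  list(images = images, masks = masks, manifest = manifest)
}

#' Read a grayscale PNG as an intensity matrix
#'
#' @param path PNG file; colour files are reduced to their first channel.
#' @return H x W matrix in `[0, 1]`.
#' @export
read_gray_png <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img
}

#' Read an indexed label-mask PNG (labels stored as gray levels)
#'
#' @param path PNG file written by [write_phantom_dataset()].
#' @return integer label matrix.
#' @export
read_mask_png <- function(path) {
  if (!file.exists(path)) stop("cannot read mask: ", path)
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}

#' Load model/training configuration from a YAML file
#'
#' Flat keys mirror [scunet_config()], [train_config()], [loss_weights()]
#' and [hdc_schedule()]: e.g. `input_size`, `layer_widths`, `num_classes`,
#' `hdc: {kernel, rates}`, `loss: {omega1, omega2, gamma, focal_gamma}`,
#' `epochs`, `lr0`, `batch_size`, `seed`.
#'
#' @param path YAML file.
#' @return list with elements `model` (a `scunet_config`) and `train` (a
#'   `train_config`).
#' @export
read_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  pick <- function(name, default) y[[name]] %||% default
  hdc <- if (!is.null(y$hdc))
    hdc_schedule(kernel = y$hdc$kernel %||% 3L,
                 rates = unlist(y$hdc$rates) %||% c(1L, 2L, 3L))
  else hdc_schedule()
  model <- scunet_config(
    input_size = unlist(pick("input_size", c(512L, 512L))),
    in_channels = pick("in_channels", 3L),
    layer_widths = unlist(pick("layer_widths", c(64L, 128L, 256L, 512L, 512L))),
    num_classes = pick("num_classes", 4L),
    hdc = hdc,
    upconv_kernel = pick("upconv_kernel", 4L))
  lw <- if (!is.null(y$loss))
    loss_weights(omega1 = y$loss$omega1 %||% 4, omega2 = y$loss$omega2 %||% 1,
                 gamma = y$loss$gamma %||% 1,
                 focal_gamma = y$loss$focal_gamma %||% 2)
  else loss_weights()
  train <- train_config(
    epochs = pick("epochs", 50L), lr0 = pick("lr0", 1e-4),
    lr_min = pick("lr_min", 0), batch_size = pick("batch_size", 4L),
    loss = lw, seed = pick("seed", 1L), log_every = pick("log_every", 1L))
  list(model = model, train = train)
}
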