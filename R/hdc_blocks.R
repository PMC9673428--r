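#' Hybrid dilated convolution schedule
#'
#' A schedule is the ordered list of dilation rates (with per-rate paddings)
#' used by one HDC group: a stack of same-kernel dilated convolutions whose
#' rates are varied so that the union of their sampling grids leaves no holes
#' in the receptive field (no "gridding" artifact).
#'
#' @param kernel odd kernel size in pixels (default 3).
#' @param rates ordered positive integer dilation rates, one per convolution
#'   in the group. The default `c(1, 2, 3)` is the sawtooth pattern used in
#'   the encoder; `c(2, 3, 4)` is the wider ablation variant (see
#'   [hdc_presets()]).
#' @param paddings per-rate zero padding; defaults to `rate * (kernel - 1) / 2`
#'   so every convolution in the group preserves spatial size.
#' @return an object of class `hdc_schedule`.
#' @seealso [validate_schedule()], [hdc_group()]
#' @export
hdc_schedule <- function(kernel = 3L, rates = c(1L, 2L, 3L), paddings = NULL) {
  kernel <- as.integer(kernel)
  rates <- as.integer(rates)
  if (length(kernel) != 1L || kernel < 1L || kernel %% 2L == 0L)
    stop("kernel size must be a single odd positive integer, got ", kernel)
  if (length(rates) < 1L || any(rates < 1L))
    stop("all dilation rates must be >= 1")
  if (is.null(paddings)) paddings <- rates * (kernel - 1L) %/% 2L
  paddings <- as.integer(paddings)
  if (length(paddings) != length(rates))
    stop("need one padding per rate (", length(rates), "), got ", length(paddings))
  structure(list(kernel = kernel, rates = rates, paddings = paddings),
            class = "hdc_schedule")
}

#' Named HDC schedule presets
#'
#' @return a named list of [hdc_schedule()] objects: `default` (rates 1,2,3)
#'   used throughout the encoders, and `ablation` (rates 2,3,4 with paddings
#'   2,3,4), the variant used to probe HDC in a plain U-Net backbone.
#' @export
hdc_presets <- function() {
  list(default  = hdc_schedule(3L, c(1L, 2L, 3L)),
       ablation = hdc_schedule(3L, c(2L, 3L, 4L), paddings = c(2L, 3L, 4L)))
}

gcd2 <- function(a, b) {
  while (b != 0L) { t <- b; b <- a %% b; a <- t }
  a
}

#' Validate an HDC schedule against the gridding criterion
#'
#' Computes the maximum-distance sequence `M_i` of the stacked dilated
#' convolutions by the backward recurrence
#' `M_i = max(M_{i+1} - 2 r_i, M_{i+1} - 2 (M_{i+1} - r_i), r_i)` with
#' `M_n = r_n`, where `M_i` bounds the largest gap between two nonzero
#' positions in the effective kernel of layers `i..n`. The schedule is valid
#' when `M_2 <= kernel` (the bottom convolution can cover the holes left by
#' the layers above it) and the rates share no common divisor greater than 1.
#'
#' @param schedule an [hdc_schedule()] with at least two rates.
#' @return an object of class `hdc_schedule_report` with fields `M_values`
#'   (named `M_1..M_n`), `gcd_of_rates`, `valid` and `reasons` (character
#'   codes, empty when valid).
#' @examples
#' validate_schedule(hdc_schedule(3, c(1, 2, 3)))  # valid, M_2 = 2
#' validate_schedule(hdc_schedule(3, c(2, 4, 8)))  # invalid: gcd 2
#' validate_schedule(hdc_schedule(3, c(1, 2, 9)))  # invalid: M_2 = 5 > 3
#' @export
validate_schedule <- function(schedule) {
  stopifnot(inherits(schedule, "hdc_schedule"))
  r <- schedule$rates
  n <- length(r)
  if (n < 2L)
    stop("the M_i recurrence needs at least two rates, got ", n)
  M <- integer(n)
  M[n] <- r[n]
  for (i in seq(n - 1L, 1L))
    M[i] <- max(M[i + 1L] - 2L * r[i],
                M[i + 1L] - 2L * (M[i + 1L] - r[i]),
                r[i])
  names(M) <- paste0("M_", seq_len(n))
  g <- Reduce(gcd2, r)
  reasons <- character(0)
  if (M[2L] > schedule$kernel)
    reasons <- c(reasons, "max_gap_exceeds_kernel")
  if (g > 1L)
    reasons <- c(reasons, "gcd_of_rates_gt_1")
  structure(list(M_values = M, gcd_of_rates = g,
                 valid = length(reasons) == 0L, reasons = reasons,
                 schedule = schedule),
            class = "hdc_schedule_report")
}

#' @export
print.hdc_schedule_report <- function(x, ...) {
  s <- x$schedule
  cat("HDC schedule: kernel ", s$kernel, ", rates (",
      paste(s$rates, collapse = ", "), "), paddings (",
      paste(s$paddings, collapse = ", "), ")\n", sep = "")
  cat("  M values: ", paste(names(x$M_values), x$M_values, sep = " = ",
                            collapse = ", "), "\n", sep = "")
  cat("  gcd of rates: ", x$gcd_of_rates, "\n", sep = "")
  cat("  valid: ", x$valid,
      if (length(x$reasons)) paste0("  [", paste(x$reasons, collapse = ", "), "]"),
      "\n", sep = "")
  invisible(x)
}

#' @export
print.hdc_schedule <- function(x, ...) {
  cat("HDC schedule: kernel ", x$kernel, ", rates (",
      paste(x$rates, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

# Coerce input to an (H, W, C, N) array; remembers original rank via attr.
as_hwcn <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L, 1L))
  else if (length(dim(x)) == 3L) x <- array(x, c(dim(x), 1L))
  else if (length(dim(x)) != 4L) stop("expected a matrix or 3-D/4-D array")
  storage.mode(x) <- "double"
  x
}

#' Single-kernel 2-D dilated convolution
#'
#' Applies one real-valued square filter to each channel of `x` with the
#' given dilation rate: `y(p) = sum_{s + rate * t = p} x(s) k(t)`, where `t`
#' ranges over the filter support `[-r, r]^2` of a `(2r+1) x (2r+1)` kernel.
#' With `padding = rate * (2r) / 2` the output has the spatial size of the
#' input; rate 1 is ordinary convolution (cross-correlation orientation).
#'
#' @param x matrix (H x W) or array (H x W x C); each channel is filtered
#'   independently with the same kernel.
#' @param kernel odd-sized square numeric matrix of filter weights.
#' @param rate integer dilation rate >= 1.
#' @param padding zero padding on all sides; defaults to the size-preserving
#'   `rate * (nrow(kernel) - 1) / 2`.
#' @return filtered output with the same rank as `x`.
#' @export
dilated_conv2d <- function(x, kernel, rate = 1L, padding = NULL) {
  rate <- as.integer(rate)
  if (length(rate) != 1L || is.na(rate) || rate < 1L)
    stop("dilation rate must be a positive integer, got ", rate)
  kernel <- as.matrix(kernel)
  K <- nrow(kernel)
  if (K != ncol(kernel) || K %% 2L == 0L)
    stop("kernel must be square with odd size, got ", K, " x ", ncol(kernel))
  if (any(!is.finite(kernel))) stop("kernel weights must be finite")
  if (is.null(padding)) padding <- rate * (K - 1L) %/% 2L
  padding <- as.integer(padding)
  if (padding < 0L) stop("padding must be >= 0")
  rank_in <- if (is.matrix(x)) 2L else length(dim(x))
  xa <- as_hwcn(x)
  d <- dim(xa)
  # fold channels and batch into the image axis: one-channel conv per slice
  xa <- array(xa, c(d[1], d[2], 1L, d[3] * d[4]))
  w <- array(kernel, c(K, K, 1L, 1L))
  y <- cpp_conv2d_fwd(xa, w, 0, rate, padding, padding, padding, padding)
  dy <- dim(y)
  y <- array(y, c(dy[1], dy[2], d[3], d[4]))
  if (rank_in == 2L) y[, , 1L, 1L]
  else if (rank_in == 3L) y[, , , 1L, drop = FALSE][, , , 1L]
  else y
}

#' Apply one HDC group to a feature tensor
#'
#' An HDC group is `length(rates)` sequential units of dilated convolution,
#' batch normalisation and ReLU. The first unit maps the input channels to
#' `out_channels`; later units keep `out_channels`. With the default
#' size-preserving paddings the spatial size is unchanged. This is the
#' functional (single-call) form used for inspection; inside a network the
#' same group runs with trained parameters.
#'
#' @param x matrix or (H x W x C) array of input features.
#' @param schedule an [hdc_schedule()]; must validate unless
#'   `override = TRUE`.
#' @param out_channels number of output feature channels.
#' @param params optional parameter list as produced by a fitted model; when
#'   `NULL`, He-uniform weights are drawn from `seed`.
#' @param seed RNG seed for weight initialisation when `params` is `NULL`.
#' @param override apply an invalid schedule anyway.
#' @return an (H x W x out_channels) array of nonnegative activations.
#' @export
hdc_group <- function(x, schedule, out_channels, params = NULL, seed = 1L,
                      override = FALSE) {
  rep <- validate_schedule(schedule)
  if (!rep$valid && !override)
    stop("invalid HDC schedule (", paste(rep$reasons, collapse = ", "),
         "); pass override = TRUE to apply it anyway")
  xa <- as_hwcn(x)
  pe <- new.env(parent = emptyenv())
  pe$params <- if (is.null(params)) list() else params
  pe$bn <- list()
  with_seed(seed, {
    ops <- raw_ops(pe)
    out <- hdc_group_core(ops, xa, "hdc", schedule, out_channels)
  })
  out[, , , 1L, drop = FALSE][, , , 1L]
}
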