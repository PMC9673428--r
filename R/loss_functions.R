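#' Weights of the focal Dice compound loss
#'
#' The compound loss is
#' `omega1 * FocalLoss + omega2 * DiceLoss^gamma * log(cosh(DiceLoss))`:
#' a pixel-classification term and a smoothed overlap term whose weight
#' adapts to how poorly the current sample is segmented (the `DiceLoss^gamma`
#' factor grows with the Dice loss). The default `omega1:omega2 = 4:1`
#' follows the training setting of the serial network.
#'
#' @param omega1 weight of the focal (pixel classification) term.
#' @param omega2 weight of the adaptive log-cosh Dice term.
#' @param gamma exponent of the adaptive `DiceLoss^gamma` factor.
#' @param focal_gamma focusing exponent of the focal term.
#' @param focal_alpha per-class weights in `[0, 1]` (recycled; default
#'   uniform 1).
#' @return an object of class `loss_weights`.
#' @export
loss_weights <- function(omega1 = 4, omega2 = 1, gamma = 1,
                         focal_gamma = 2, focal_alpha = 1) {
  if (omega1 < 0 || omega2 < 0 || omega1 + omega2 <= 0)
    stop("omega1 and omega2 must be nonnegative with a positive sum")
  if (gamma < 0) stop("gamma must be >= 0")
  if (focal_gamma < 0) stop("focal_gamma must be >= 0")
  structure(list(omega1 = omega1, omega2 = omega2, gamma = gamma,
                 focal_gamma = focal_gamma, focal_alpha = focal_alpha),
            class = "loss_weights")
}

dice_eps <- 1e-6
prob_clamp <- 1e-7

# Align prob (H,W,C[,N]) and integer target (H,W[,N]); returns standardised
# 4-D prob, target vector (0-based labels in pixel order), and sizes.
check_prob_target <- function(prob, target) {
  p <- as_hwcn(prob)
  d <- dim(p)
  if (is.matrix(target)) target <- array(target, c(dim(target), 1L))
  if (length(dim(target)) != 3L)
    stop("target must be an integer label matrix (H x W) or array (H x W x N)")
  dt <- dim(target)
  if (dt[1L] != d[1L] || dt[2L] != d[2L] || dt[3L] != d[4L])
    stop("prediction (", paste(d, collapse = "x"), ") and target (",
         paste(dt, collapse = "x"), ") shapes do not match")
  tv <- as.integer(target)
  if (any(tv < 0L) || any(tv >= d[3L]))
    stop("target labels must lie in [0, ", d[3L] - 1L, "]")
  list(p = p, tv = tv, H = d[1L], W = d[2L], C = d[3L], N = d[4L])
}

# linear indices of the true-class probability of every pixel
true_class_index <- function(ct) {
  hw <- ct$H * ct$W
  rep(seq_len(hw), ct$N) + hw * ct$tv + hw * ct$C * rep(0:(ct$N - 1L), each = hw)
}

# per-class sufficient statistics of the soft Dice overlap
dice_stats <- function(ct) {
  Sp <- if (ct$N == 1L) colSums(matrix(ct$p, ncol = ct$C))
        else colSums(chan_mat(ct$p))
  Sq <- tabulate(ct$tv + 1L, nbins = ct$C)
  pt <- ct$p[true_class_index(ct)]
  S1 <- vapply(seq_len(ct$C) - 1L,
               function(c) sum(pt[ct$tv == c]), numeric(1))
  list(Sp = Sp, Sq = Sq, S1 = S1)
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(p * y) + eps) / (sum(p) + sum(y) + eps)` per foreground
#' class, averaged over the foreground classes; `y` is the one-hot target.
#' The smoothing `eps` makes empty classes well defined (a class absent from
#' both target and prediction contributes 0).
#'
#' @param prob class-probability array (H x W x C, or H x W x C x N for a
#'   batch) with per-pixel channel sums 1.
#' @param target integer label matrix/array with values in `[0, C - 1]`.
#' @param eps smoothing constant.
#' @return a value in `[0, 1]`; 0 for a perfect one-hot prediction.
#' @export
soft_dice_loss <- function(prob, target, eps = dice_eps) {
  ct <- check_prob_target(prob, target)
  st <- dice_stats(ct)
  fg <- seq(2L, ct$C)  # foreground classes 1..C-1 (index 1 is background)
  mean(1 - (2 * st$S1[fg] + eps) / (st$Sp[fg] + st$Sq[fg] + eps))
}

#' Log-cosh transform of a Dice loss
#'
#' `log(cosh(x))` with `cosh(x) = (exp(x) + exp(-x)) / 2`, the smooth convex
#' surrogate applied to the Dice loss; zero at zero and monotone increasing
#' on the nonnegative axis.
#'
#' @param dice_loss nonnegative Dice-loss value(s).
#' @return `log(cosh(dice_loss))`, elementwise.
#' @export
log_cosh_dice_loss <- function(dice_loss) {
  if (any(dice_loss < 0)) stop("dice_loss must be >= 0")
  log(cosh(dice_loss))
}

#' Focal loss
#'
#' Mean over pixels of `-alpha_c * (1 - p_t)^focal_gamma * log(p_t)`, where
#' `p_t` is the predicted probability of the pixel's true class (clamped to
#' `[1e-7, 1]` before the log). With `focal_gamma = 0` and uniform `alpha`
#' this is mean cross-entropy; larger `focal_gamma` down-weights easy pixels.
#'
#' @inheritParams soft_dice_loss
#' @param weights a [loss_weights()] (uses `focal_gamma` and `focal_alpha`).
#' @return nonnegative scalar.
#' @export
focal_loss <- function(prob, target, weights = loss_weights()) {
  ct <- check_prob_target(prob, target)
  alpha <- rep_len(weights$focal_alpha, ct$C)
  pt <- pmax(ct$p[true_class_index(ct)], prob_clamp)
  mean(-alpha[ct$tv + 1L] * (1 - pt)^weights$focal_gamma * log(pt))
}

#' Combine focal and Dice losses into the compound total
#'
#' `omega1 * focal + omega2 * dice^gamma * log(cosh(dice))`. Exposed
#' separately so the composition can be used on externally computed
#' components.
#'
#' @param focal focal-loss value.
#' @param dice Dice-loss value in `[0, 1]`.
#' @param weights a [loss_weights()].
#' @return the scalar compound loss.
#' @export
focal_dice_combine <- function(focal, dice, weights = loss_weights()) {
  weights$omega1 * focal +
    weights$omega2 * dice^weights$gamma * log_cosh_dice_loss(dice)
}

#' Focal Dice loss
#'
#' The compound training loss: a focal pixel-classification term plus an
#' adaptive log-cosh Dice term whose weight `DiceLoss^gamma` grows when the
#' sample is poorly segmented. See [loss_weights()] for the parameters.
#'
#' @inheritParams focal_loss
#' @return a list of class `loss_value` with `total` and `components`
#'   (`focal`, `dice`, `log_cosh_dice`, `focal_dice_term`).
#' @export
focal_dice_loss <- function(prob, target, weights = loss_weights()) {
  fl <- focal_loss(prob, target, weights)
  dl <- soft_dice_loss(prob, target)
  lc <- log_cosh_dice_loss(dl)
  term <- dl^weights$gamma * lc
  structure(list(total = weights$omega1 * fl + weights$omega2 * term,
                 components = list(focal = fl, dice = dl,
                                   log_cosh_dice = lc, focal_dice_term = term)),
            class = "loss_value")
}

#' @export
print.loss_value <- function(x, ...) {
  cat("focal Dice loss: ", format(x$total), "\n  focal = ",
      format(x$components$focal), ", dice = ", format(x$components$dice),
      ", log-cosh dice = ", format(x$components$log_cosh_dice), "\n", sep = "")
  invisible(x)
}

# Loss value plus gradient w.r.t. the probability array (training path).
focal_dice_grad <- function(prob, target, weights = loss_weights()) {
  ct <- check_prob_target(prob, target)
  npix <- ct$H * ct$W * ct$N
  idx <- true_class_index(ct)
  alpha <- rep_len(weights$focal_alpha, ct$C)[ct$tv + 1L]
  g <- weights$focal_gamma
  pt_raw <- ct$p[idx]
  pt <- pmax(pt_raw, prob_clamp)
  fl <- mean(-alpha * (1 - pt)^g * log(pt))
  # d/dpt of -alpha (1-pt)^g log pt; zero where the clamp is active
  dfl_dpt <- ifelse(pt_raw >= prob_clamp,
                    alpha * (g * (1 - pt)^(pmax(g - 1, 0)) * log(pt) -
                               (1 - pt)^g / pt) / npix,
                    0)
  st <- dice_stats(ct)
  fg <- seq(2L, ct$C)
  den <- st$Sp[fg] + st$Sq[fg] + dice_eps
  num <- 2 * st$S1[fg] + dice_eps
  dl <- mean(1 - num / den)
  lc <- log_cosh_dice_loss(dl)
  term <- dl^weights$gamma * lc
  total <- weights$omega1 * fl + weights$omega2 * term
  # chain factor through the adaptive log-cosh term
  dtot_ddl <- weights$omega2 *
    (weights$gamma * dl^(max(weights$gamma - 1, 0)) * lc +
       dl^weights$gamma * tanh(dl))
  dprob <- array(0, dim(ct$p))
  # Dice term: d(dl)/dp_c = -(2 y_c den_c - num_c) / den_c^2 / n_fg
  nfg <- length(fg)
  hw <- ct$H * ct$W
  for (k in seq_along(fg)) {
    cls <- fg[k] - 1L
    y <- as.numeric(ct$tv == cls)
    dD <- -(2 * y * den[k] - num[k]) / den[k]^2 / nfg
    sel <- rep(seq_len(hw), ct$N) + hw * cls +
      hw * ct$C * rep(0:(ct$N - 1L), each = hw)
    dprob[sel] <- dprob[sel] + dtot_ddl * dD
  }
  dprob[idx] <- dprob[idx] + weights$omega1 * dfl_dpt
  list(total = total,
       components = list(focal = fl, dice = dl, log_cosh_dice = lc,
                         focal_dice_term = term),
       dprob = dprob)
}
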