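#' Pixel confusion matrix
#'
#' Tabulates `p_ij`, the number of pixels whose true class is `i` and
#' predicted class is `j`, over the `k + 1` classes (background = 0 plus `k`
#' foreground classes). Rows index the truth, columns the prediction.
#'
#' @param pred,truth integer label matrices of the same shape with values in
#'   `[0, k]`.
#' @param k number of foreground classes.
#' @return a `(k+1) x (k+1)` integer matrix of class `confusion_matrix`,
#'   with `dimnames` `0..k`.
#' @export
confusion_matrix <- function(pred, truth, k) {
  if (!all(dim(pred) == dim(truth)))
    stop("pred (", paste(dim(pred), collapse = "x"), ") and truth (",
         paste(dim(truth), collapse = "x"), ") shapes differ")
  pv <- as.integer(pred); tv <- as.integer(truth)
  k <- as.integer(k)
  if (any(pv < 0L) || any(pv > k) || any(tv < 0L) || any(tv > k))
    stop("labels must lie in [0, ", k, "]")
  m <- matrix(tabulate(tv * (k + 1L) + pv + 1L, nbins = (k + 1L)^2),
              k + 1L, k + 1L, byrow = TRUE)
  dimnames(m) <- list(truth = 0:k, pred = 0:k)
  class(m) <- c("confusion_matrix", class(m))
  m
}

#' Overlap metrics from a confusion matrix
#'
#' Per-class means over the `k + 1` classes of:
#' * MIoU: `p_ii / (sum_j p_ij + sum_j p_ji - p_ii)`
#' * MPA: `p_ii / sum_j p_ij`
#' * mPrecision: `TP / (TP + FP)`
#' * mDice: `2 TP / (2 TP + FP + FN)`
#'
#' plus overall accuracy `trace / total`. Classes absent from both truth and
#' prediction are skipped from the means (their ratios are 0/0); a class
#' absent from the truth but predicted contributes 0 to MIoU/mDice and is
#' skipped from MPA (its row is empty).
#'
#' @param cm a [confusion_matrix()].
#' @param include_background include class 0 in the per-class means
#'   (default `TRUE`, matching the `k + 1`-class averages).
#' @return a list of class `metric_report` with fields `miou`, `mpa`,
#'   `mprecision`, `mdice`, `accuracy`.
#' @export
overlap_metrics <- function(cm, include_background = TRUE) {
  cm <- unclass(cm)
  total <- sum(cm)
  if (total <= 0) stop("empty confusion matrix")
  nk <- nrow(cm)
  tp <- diag(cm)
  rs <- rowSums(cm)  # truth pixels per class (TP + FN)
  cs <- colSums(cm)  # predicted pixels per class (TP + FP)
  keep <- rs + cs > 0
  if (!include_background) keep[1L] <- FALSE
  rat <- function(num, den) {
    ok <- keep & den > 0
    mean(num[ok] / den[ok])
  }
  structure(list(
    miou = rat(tp, rs + cs - tp),
    mpa = rat(tp, rs),
    mprecision = rat(tp, cs),
    mdice = rat(2 * tp, rs + cs),
    accuracy = sum(tp) / total), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  fields <- c(miou = "MIoU", mpa = "MPA", mprecision = "mPrecision",
              mdice = "mDice", accuracy = "accuracy",
              hausdorff95 = "Hausdorff95", asd = "ASD")
  for (f in names(fields))
    if (!is.null(x[[f]]) && !is.na(x[[f]]))
      cat(sprintf("  %-12s %.4f\n", fields[f], x[[f]]))
  invisible(x)
}

#' Extract the boundary pixels of one class
#'
#' A pixel belongs to the boundary of class `cls` when it carries that label
#' and at least one of its 4-neighbours does not (the image border counts as
#' outside the class).
#'
#' @param mask integer label matrix.
#' @param cls class label to trace.
#' @return a 2-column matrix of 0-based `(row, col)` coordinates of class
#'   `boundary_set`; errors when `cls` is absent from the mask.
#' @export
extract_boundary <- function(mask, cls) {
  m <- mask == cls
  if (!any(m)) stop("class ", cls, " is absent from the mask")
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- m
  inner <- pad[2:(H + 1L), 2:(W + 1L)] &
    pad[1:H, 2:(W + 1L)] & pad[3:(H + 2L), 2:(W + 1L)] &
    pad[2:(H + 1L), 1:W] & pad[2:(H + 1L), 3:(W + 2L)]
  b <- which(m & !inner, arr.ind = TRUE) - 1L
  colnames(b) <- c("row", "col")
  class(b) <- c("boundary_set", class(b))
  b
}

# Exact squared Euclidean distance transform (two-pass lower-envelope
# algorithm), O(H * W).  f is a matrix of squared distances (0 at sites,
# Inf elsewhere); returns the squared distance to the nearest site.
edt_sq <- function(f) {
  dt1 <- function(v) {
    n <- length(v)
    if (n == 1L || all(is.infinite(v))) return(v)
    k <- 1L
    vtx <- integer(n); vtx[1L] <- 1L
    z <- c(-Inf, Inf, numeric(n - 1L))
    for (q in 2:n) {
      if (is.infinite(v[q])) next
      repeat {
        p <- vtx[k]
        if (is.infinite(v[p])) { s <- -Inf } else {
          s <- ((v[q] + q * q) - (v[p] + p * p)) / (2 * q - 2 * p)
        }
        if (s <= z[k] && k > 1L) k <- k - 1L else break
      }
      k <- k + 1L
      vtx[k] <- q
      z[k] <- s
      z[k + 1L] <- Inf
    }
    d <- numeric(n)
    k <- 1L
    for (q in 1:n) {
      while (z[k + 1L] < q) k <- k + 1L
      d[q] <- (q - vtx[k])^2 + v[vtx[k]]
    }
    d
  }
  for (j in seq_len(ncol(f))) f[, j] <- dt1(f[, j])
  for (i in seq_len(nrow(f))) f[i, ] <- dt1(f[i, ])
  f
}

boundary_points <- function(x, side) {
  x <- unclass(x)
  if (is.null(dim(x))) x <- matrix(x, ncol = 2L)
  if (nrow(x) == 0L) stop("empty boundary set on the ", side, " side")
  x
}

directed_distances <- function(from, to) {
  # distance of every `from` point to the nearest `to` point, via an exact
  # Euclidean distance transform over the joint bounding grid
  H <- max(from[, 1L], to[, 1L]) + 1L
  W <- max(from[, 2L], to[, 2L]) + 1L
  f <- matrix(Inf, H, W)
  f[to + 1L] <- 0
  sqrt(edt_sq(f)[from + 1L])
}

#' 95th-percentile Hausdorff distance between two boundaries
#'
#' Directed point-to-set distances `d(x, S) = min ||x - s||` are computed in
#' both directions; the reported value is the larger of the two
#' `percentile`-th percentiles, scaled by the pixel spacing. `percentile =
#' 100` gives the exact (maximum) Hausdorff distance, which is symmetric in
#' its arguments; the 95th-percentile default is robust to outlier pixels.
#'
#' @param a,b boundary point sets ([extract_boundary()] output, or any
#'   2-column 0-based coordinate matrix).
#' @param spacing isotropic pixel spacing (distance units per pixel).
#' @param percentile percentile of the directed distance distributions.
#' @return nonnegative scalar distance.
#' @export
hausdorff95 <- function(a, b, spacing = 1, percentile = 95) {
  a <- boundary_points(a, "first"); b <- boundary_points(b, "second")
  da <- directed_distances(a, b)
  db <- directed_distances(b, a)
  q <- percentile / 100
  spacing * max(stats::quantile(da, q, names = FALSE),
                stats::quantile(db, q, names = FALSE))
}

#' Average surface distance
#'
#' Mean distance from each point of the segmented boundary to the nearest
#' point of the ground-truth boundary:
#' `(1 / |B_AS|) * sum_{x in B_AS} d(x, B_GT)`. One-directional by default
#' (not symmetric in its arguments); `symmetric = TRUE` pools both
#' directions.
#'
#' @param seg segmented-boundary point set.
#' @param gt ground-truth boundary point set.
#' @inheritParams hausdorff95
#' @param symmetric pool distances from both directions.
#' @return nonnegative scalar distance.
#' @export
asd <- function(seg, gt, spacing = 1, symmetric = FALSE) {
  seg <- boundary_points(seg, "segmentation"); gt <- boundary_points(gt, "ground-truth")
  d <- directed_distances(seg, gt)
  if (symmetric) d <- c(d, directed_distances(gt, seg))
  spacing * mean(d)
}

#' Full per-image segmentation report
#'
#' Overlap metrics from the pixel confusion matrix plus boundary metrics
#' (Hausdorff95, ASD) averaged over the classes present in both masks.
#' Classes present in the truth but entirely missed by the prediction (or
#' vice versa) have no boundary to measure and are skipped from the boundary
#' averages.
#'
#' @inheritParams confusion_matrix
#' @param spacing isotropic pixel spacing for the boundary metrics.
#' @param include_background include class 0 in the per-class overlap means.
#' @param boundary_classes classes over which boundary metrics are averaged;
#'   defaults to the foreground classes `1..k`.
#' @return a `metric_report` with `miou`, `mpa`, `mprecision`, `mdice`,
#'   `accuracy`, `hausdorff95`, `asd` (boundary fields are `NA` when no
#'   class admits a boundary comparison).
#' @export
segmentation_report <- function(pred, truth, k, spacing = 1,
                                include_background = TRUE,
                                boundary_classes = seq_len(k)) {
  rep <- overlap_metrics(confusion_matrix(pred, truth, k), include_background)
  hds <- c(); asds <- c()
  for (cls in boundary_classes) {
    if (!any(truth == cls) || !any(pred == cls)) next
    bt <- extract_boundary(truth, cls)
    bp <- extract_boundary(pred, cls)
    hds <- c(hds, hausdorff95(bp, bt, spacing))
    asds <- c(asds, asd(bp, bt, spacing))
  }
  rep$hausdorff95 <- if (length(hds)) mean(hds) else NA_real_
  rep$asd <- if (length(asds)) mean(asds) else NA_real_
  rep
}
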