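# Brute-force reference implementations used as independent oracles.

# direct nested-loop dilated convolution of a single-channel image
oracle_conv <- function(x, k, rate, pad) {
  K <- nrow(k); H <- nrow(x); W <- ncol(x)
  Ho <- H + 2 * pad - rate * (K - 1)
  Wo <- W + 2 * pad - rate * (K - 1)
  out <- matrix(0, Ho, Wo)
  for (i in seq_len(Ho)) for (j in seq_len(Wo)) {
    s <- 0
    for (a in seq_len(K)) for (b in seq_len(K)) {
      ii <- i + (a - 1) * rate - pad
      jj <- j + (b - 1) * rate - pad
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
        s <- s + x[ii, jj] * k[a, b]
    }
    out[i, j] <- s
  }
  out
}

# per-class set-operation metrics (skipping classes absent from both masks)
oracle_overlap <- function(pred, truth, k) {
  ious <- pas <- precs <- dices <- c()
  for (c in 0:k) {
    X <- truth == c; Y <- pred == c
    if (!any(X) && !any(Y)) next
    ious <- c(ious, sum(X & Y) / sum(X | Y))
    if (any(X)) pas <- c(pas, sum(X & Y) / sum(X))
    if (any(Y)) precs <- c(precs, sum(X & Y) / sum(Y))
    dices <- c(dices, 2 * sum(X & Y) / (sum(X) + sum(Y)))
  }
  list(miou = mean(ious), mpa = mean(pas), mprecision = mean(precs),
       mdice = mean(dices), accuracy = mean(pred == truth))
}

# all-pairs directed Euclidean distances between two 0-based point sets
oracle_directed <- function(a, b) {
  d <- sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2)
  list(da = apply(d, 1, min), db = apply(d, 2, min))
}

# largest hole in the 1-D receptive-field support of stacked dilated
# convolutions i..n (kernel size K): the gridding quantity the M_i
# recurrence bounds
oracle_max_gap <- function(rates, K) {
  half <- (K - 1) / 2
  support <- 0
  for (r in rev(rates)) {
    support <- unique(as.vector(outer(support, r * (-half:half), "+")))
  }
  support <- sort(support)
  max(diff(support))
}

random_prob <- function(H, W, C) {
  p <- array(stats::runif(H * W * C), c(H, W, C))
  p / array(rep(apply(p, c(1, 2), sum), C), c(H, W, C))
}

small_fixture_config <- function() {
  scunet_config(input_size = c(64L, 64L), layer_widths = c(8L, 16L, 32L, 64L, 64L))
}

fixture_phantoms <- function(n = 8, seed = 1, size = c(64, 64)) {
  generate_phantoms(n, phantom_params(size = size,
                                      lesions_per_image = c(1L, 2L),
                                      seed = seed))
}
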