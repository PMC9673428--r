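# Reverse-mode tape over the C++ primitives.  Nodes are environments holding
# $value, $grad and a backward closure that scatters the incoming gradient to
# the node's parents; the tape replays closures in reverse creation order.
# Two interchangeable op sets share the network wiring code: tape_ops()
# records gradients for training, raw_ops() computes values only (inference)
# so intermediates can be garbage-collected as references drop.

tape_new <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 64L)
  e$n <- 0L
  e
}

tp_add <- function(tape, value, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backward <- backward
  n <- tape$n + 1L
  if (n > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

nd_accum <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

tp_backward <- function(tape, root, grad = 1) {
  root$grad <- grad
  for (k in seq(tape$n, 1L)) {
    nd <- tape$nodes[[k]]
    if (is.null(nd$backward)) next       # leaves keep their gradient
    if (!is.null(nd$grad)) nd$backward(nd$grad)
    # free consumed gradients/closures to bound memory during the sweep
    nd$grad <- NULL
    nd$backward <- NULL
  }
  invisible(NULL)
}

# Evaluate expr with a private RNG stream, restoring the caller's afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Parameter store: pe$params (named arrays) and pe$bn (running statistics).
# Parameters are created on first use so the wiring code is the single
# source of truth for every tensor shape in the network.
ensure_conv_param <- function(pe, name, K, Ci, Co) {
  wn <- paste0(name, ".w"); bn <- paste0(name, ".b")
  if (is.null(pe$params[[wn]])) {
    limit <- sqrt(6 / (K * K * Ci))  # He-uniform fan-in
    pe$params[[wn]] <- array(stats::runif(K * K * Ci * Co, -limit, limit),
                             c(K, K, Ci, Co))
    pe$params[[bn]] <- numeric(Co)
  }
  list(w = wn, b = bn)
}

ensure_bn_param <- function(pe, name, C) {
  gn <- paste0(name, ".gamma"); bn <- paste0(name, ".beta")
  if (is.null(pe$params[[gn]])) {
    pe$params[[gn]] <- rep(1, C)
    pe$params[[bn]] <- rep(0, C)
    pe$bn[[name]] <- list(mean = rep(0, C), var = rep(1, C))
  }
  list(gamma = gn, beta = bn)
}

# channel-major matrix view of an (H,W,C,N) array: rows = H*W*N, cols = C
chan_mat <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1L, 2L, 4L, 3L)), ncol = d[3L])
}
chan_unmat <- function(m, d) {
  aperm(array(m, c(d[1L], d[2L], d[4L], d[3L])), c(1L, 2L, 4L, 3L))
}

bn_eps <- 1e-5
bn_momentum <- 0.1

# Transposed-convolution geometry: stride 2, output exactly doubles the
# input.  Implemented as zero-insertion upsampling followed by a padded
# convolution with the spatially flipped kernel; pad_before = K - 1 - p,
# pad_after = p + 1 with p = (K-2)/2 (even K) or (K-1)/2 (odd K).
convT_pads <- function(K) {
  p <- if (K %% 2L == 0L) (K - 2L) %/% 2L else (K - 1L) %/% 2L
  c(before = K - 1L - p, after = p + 1L)
}

flip_kernel <- function(w) {
  K1 <- dim(w)[1L]; K2 <- dim(w)[2L]
  w[K1:1, K2:1, , , drop = FALSE]
}

# ---- tape ops (training) ---------------------------------------------------

tape_ops <- function(tape, pe, training = TRUE) {
  param_node <- function(name) {
    if (is.null(pe$pnodes[[name]])) {
      nd <- tp_add(tape, pe$params[[name]])
      nd$pname <- name
      pe$pnodes[[name]] <- nd
    }
    pe$pnodes[[name]]
  }

  conv <- function(x, name, Co, K = 3L, rate = 1L, pad = NULL) {
    Ci <- dim(x$value)[3L]
    nm <- ensure_conv_param(pe, name, K, Ci, Co)
    if (is.null(pad)) pad <- rate * (K - 1L) %/% 2L
    wn <- param_node(nm$w); bnn <- param_node(nm$b)
    val <- cpp_conv2d_fwd(x$value, wn$value, bnn$value, rate, pad, pad, pad, pad)
    tp_add(tape, val, backward = function(g) {
      gr <- cpp_conv2d_bwd(x$value, wn$value, g, rate, pad, pad, pad, pad)
      nd_accum(x, gr$gx); nd_accum(wn, gr$gw); nd_accum(bnn, gr$gb)
    })
  }

  convT <- function(x, name, Co, K = 4L) {
    Ci <- dim(x$value)[3L]
    nm <- ensure_conv_param(pe, name, K, Ci, Co)
    wn <- param_node(nm$w); bnn <- param_node(nm$b)
    pd <- convT_pads(K)
    up <- cpp_upsample_zeros(x$value)
    val <- cpp_conv2d_fwd(up, flip_kernel(wn$value), bnn$value, 1L,
                          pd[1L], pd[1L], pd[2L], pd[2L])
    tp_add(tape, val, backward = function(g) {
      gr <- cpp_conv2d_bwd(up, flip_kernel(wn$value), g, 1L,
                           pd[1L], pd[1L], pd[2L], pd[2L])
      nd_accum(x, cpp_upsample_zeros_bwd(gr$gx))
      nd_accum(wn, flip_kernel(gr$gw))
      nd_accum(bnn, gr$gb)
    })
  }

  bn <- function(x, name) {
    d <- dim(x$value)
    C <- d[3L]
    nm <- ensure_bn_param(pe, name, C)
    gn <- param_node(nm$gamma); btn <- param_node(nm$beta)
    if (training) {
      m <- chan_mat(x$value)
      mu <- colMeans(m)
      xc <- sweep(m, 2L, mu)
      v <- colMeans(xc * xc)                 # biased, as normalisation uses
      inv <- 1 / sqrt(v + bn_eps)
      xhat <- sweep(xc, 2L, inv, `*`)
      y <- sweep(sweep(xhat, 2L, gn$value, `*`), 2L, btn$value, `+`)
      st <- pe$bn[[name]]
      pe$bn[[name]] <- list(
        mean = (1 - bn_momentum) * st$mean + bn_momentum * mu,
        var  = (1 - bn_momentum) * st$var + bn_momentum * v)
      tp_add(tape, chan_unmat(y, d), backward = function(g) {
        gm <- chan_mat(g)
        nd_accum(gn, colSums(gm * xhat))
        nd_accum(btn, colSums(gm))
        dxhat <- sweep(gm, 2L, gn$value, `*`)
        mdx <- colMeans(dxhat)
        mdxx <- colMeans(dxhat * xhat)
        dx <- sweep(dxhat, 2L, mdx) - sweep(xhat, 2L, mdxx, `*`)
        dx <- sweep(dx, 2L, inv, `*`)
        nd_accum(x, chan_unmat(dx, d))
      })
    } else {
      st <- pe$bn[[name]]
      sc <- gn$value / sqrt(st$var + bn_eps)
      sh <- btn$value - st$mean * sc
      m <- chan_mat(x$value)
      y <- sweep(sweep(m, 2L, sc, `*`), 2L, sh, `+`)
      tp_add(tape, chan_unmat(y, d), backward = function(g) {
        gm <- chan_mat(g)
        nd_accum(gn, colSums(gm * sweep(sweep(m, 2L, st$mean),
                                        2L, sqrt(st$var + bn_eps), `/`)))
        nd_accum(btn, colSums(gm))
        nd_accum(x, chan_unmat(sweep(gm, 2L, sc, `*`), d))
      })
    }
  }

  relu <- function(x) {
    mask <- x$value > 0
    tp_add(tape, x$value * mask, backward = function(g) nd_accum(x, g * mask))
  }

  pool <- function(x) {
    r <- cpp_maxpool2_fwd(x$value)
    d <- dim(x$value)
    tp_add(tape, r$y, backward = function(g)
      nd_accum(x, cpp_maxpool2_bwd(g, r$idx, d[1L], d[2L])))
  }

  concat <- function(a, b) {
    da <- dim(a$value); db <- dim(b$value)
    if (any(da[c(1L, 2L, 4L)] != db[c(1L, 2L, 4L)]))
      stop("cannot concatenate feature maps of shapes ",
           paste(da, collapse = "x"), " and ", paste(db, collapse = "x"))
    val <- array(0, c(da[1L], da[2L], da[3L] + db[3L], da[4L]))
    val[, , seq_len(da[3L]), ] <- a$value
    val[, , da[3L] + seq_len(db[3L]), ] <- b$value
    tp_add(tape, val, backward = function(g) {
      nd_accum(a, g[, , seq_len(da[3L]), , drop = FALSE])
      nd_accum(b, g[, , da[3L] + seq_len(db[3L]), , drop = FALSE])
    })
  }

  softmax <- function(x) {
    z <- x$value
    d <- dim(z)
    rep4 <- function(m) aperm(array(rep(m, times = d[3L]),
                                    c(d[1L], d[2L], d[4L], d[3L])),
                              c(1L, 2L, 4L, 3L))
    ez <- exp(z - rep4(apply(z, c(1L, 2L, 4L), max)))
    p <- ez / rep4(apply(ez, c(1L, 2L, 4L), sum))
    tp_add(tape, p, backward = function(g) {
      dot <- apply(g * p, c(1L, 2L, 4L), sum)
      nd_accum(x, p * (g - rep4(dot)))
    })
  }

  leaf <- function(value) tp_add(tape, value)

  list(conv = conv, convT = convT, bn = bn, relu = relu, pool = pool,
       concat = concat, softmax = softmax, leaf = leaf,
       value = function(nd) nd$value, is_tape = TRUE)
}

# ---- raw ops (inference; plain arrays) -------------------------------------

raw_ops <- function(pe) {
  conv <- function(x, name, Co, K = 3L, rate = 1L, pad = NULL) {
    Ci <- dim(x)[3L]
    nm <- ensure_conv_param(pe, name, K, Ci, Co)
    if (is.null(pad)) pad <- rate * (K - 1L) %/% 2L
    cpp_conv2d_fwd(x, pe$params[[nm$w]], pe$params[[nm$b]],
                   rate, pad, pad, pad, pad)
  }
  convT <- function(x, name, Co, K = 4L) {
    Ci <- dim(x)[3L]
    nm <- ensure_conv_param(pe, name, K, Ci, Co)
    pd <- convT_pads(K)
    cpp_conv2d_fwd(cpp_upsample_zeros(x), flip_kernel(pe$params[[nm$w]]),
                   pe$params[[nm$b]], 1L, pd[1L], pd[1L], pd[2L], pd[2L])
  }
  bn <- function(x, name) {
    d <- dim(x)
    nm <- ensure_bn_param(pe, name, d[3L])
    st <- pe$bn[[name]]
    sc <- pe$params[[nm$gamma]] / sqrt(st$var + bn_eps)
    sh <- pe$params[[nm$beta]] - st$mean * sc
    chan_unmat(sweep(sweep(chan_mat(x), 2L, sc, `*`), 2L, sh, `+`), d)
  }
  relu <- function(x) { x[x < 0] <- 0; x }
  pool <- function(x) cpp_maxpool2_fwd(x)$y
  concat <- function(a, b) {
    da <- dim(a); db <- dim(b)
    if (any(da[c(1L, 2L, 4L)] != db[c(1L, 2L, 4L)]))
      stop("cannot concatenate feature maps of shapes ",
           paste(da, collapse = "x"), " and ", paste(db, collapse = "x"))
    val <- array(0, c(da[1L], da[2L], da[3L] + db[3L], da[4L]))
    val[, , seq_len(da[3L]), ] <- a
    val[, , da[3L] + seq_len(db[3L]), ] <- b
    val
  }
  softmax <- function(x) {
    d <- dim(x)
    zmax <- apply(x, c(1L, 2L, 4L), max)
    rep4 <- function(m) aperm(array(rep(m, times = d[3L]),
                                    c(d[1L], d[2L], d[4L], d[3L])),
                              c(1L, 2L, 4L, 3L))
    ez <- exp(x - rep4(zmax))
    ez / rep4(apply(ez, c(1L, 2L, 4L), sum))
  }
  list(conv = conv, convT = convT, bn = bn, relu = relu, pool = pool,
       concat = concat, softmax = softmax, leaf = identity,
       value = identity, is_tape = FALSE)
}

# ---- shared wiring helpers -------------------------------------------------

hdc_group_core <- function(ops, x, prefix, schedule, out_channels) {
  K <- schedule$kernel
  for (u in seq_along(schedule$rates)) {
    nm <- paste0(prefix, ".u", u)
    x <- ops$conv(x, nm, out_channels, K = K, rate = schedule$rates[u],
                  pad = schedule$paddings[u])
    x <- ops$bn(x, paste0(nm, ".bn"))
    x <- ops$relu(x)
  }
  x
}

double_conv_core <- function(ops, x, prefix, out_channels) {
  for (u in 1:2) {
    nm <- paste0(prefix, ".c", u)
    x <- ops$conv(x, nm, out_channels, K = 3L, rate = 1L, pad = 1L)
    x <- ops$bn(x, paste0(nm, ".bn"))
    x <- ops$relu(x)
  }
  x
}
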