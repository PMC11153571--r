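# Internal neural-network primitives.
#
# All image tensors are column-major R arrays (H, W, C, N) in double
# precision; convolution weights are (kh*kw*Cin) x Cout matrices whose rows
# are ordered (kernel row, kernel col, channel) fastest-to-slowest to match
# the im2col kernel. Every layer exposes a forward returning (out, cache)
# and a backward consuming (cache, dout); gradients have the same shapes as
# the parameters.

zero_pad_hw <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  xp
}

conv_out_dim <- function(n, k, pad, stride) (n + 2L * pad - k) %/% stride + 1L

conv_init <- function(cin, cout, k = 3L) {
  fan_in <- k * k * cin
  list(W = matrix(stats::rnorm(fan_in * cout, sd = sqrt(2 / fan_in)),
                  fan_in, cout),
       b = numeric(cout), k = k)
}

conv_fwd <- function(x, p, stride = 1L) {
  d <- dim(x)
  k <- p$k
  pad <- if (k == 3L) 1L else 0L
  ho <- conv_out_dim(d[1], k, pad, stride)
  wo <- conv_out_dim(d[2], k, pad, stride)
  cout <- ncol(p$W)
  n <- d[4]
  out <- array(0, c(ho, wo, cout, n))
  for (i in seq_len(n)) {
    xp <- zero_pad_hw(array(x[, , , i], d[1:3]), pad)
    cols <- im2col_cpp(xp, d[1] + 2L * pad, d[2] + 2L * pad, d[3], k, k, stride)
    out[, , , i] <- cols %*% p$W + rep(p$b, each = ho * wo)
  }
  list(out = out, cache = list(x = x, stride = stride, pad = pad, k = k,
                               ho = ho, wo = wo))
}

conv_bwd <- function(cache, p, dout) {
  x <- cache$x
  d <- dim(x)
  k <- cache$k; pad <- cache$pad; stride <- cache$stride
  ho <- cache$ho; wo <- cache$wo
  cout <- ncol(p$W)
  n <- d[4]
  dW <- matrix(0, nrow(p$W), cout)
  db <- numeric(cout)
  dx <- array(0, d)
  hp <- d[1] + 2L * pad; wp <- d[2] + 2L * pad
  for (i in seq_len(n)) {
    xp <- zero_pad_hw(array(x[, , , i], d[1:3]), pad)
    cols <- im2col_cpp(xp, hp, wp, d[3], k, k, stride)
    dyi <- matrix(dout[, , , i], ho * wo, cout)
    dW <- dW + crossprod(cols, dyi)
    db <- db + colSums(dyi)
    dcols <- dyi %*% t(p$W)
    dxp <- col2im_cpp(dcols, hp, wp, d[3], k, k, stride)
    dim(dxp) <- c(hp, wp, d[3])
    dx[, , , i] <- if (pad > 0L)
      dxp[pad + seq_len(d[1]), pad + seq_len(d[2]), , drop = FALSE]
    else dxp
  }
  list(dx = dx, grads = list(W = dW, b = db))
}

bn_init <- function(c) {
  list(gamma = rep(1, c), beta = numeric(c),
       rmean = numeric(c), rvar = rep(1, c))
}

# Batch norm over (H, W, N) per channel. Running statistics are updated in
# place by the caller (train loop) from the returned batch moments.
bn_fwd <- function(x, p, training, eps = 1e-5) {
  d <- dim(x)
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
  } else {
    mu <- p$rmean
    v <- p$rvar
  }
  sig <- sqrt(v + eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, sig, "/")
  out <- sweep(sweep(xhat, 2, p$gamma, "*"), 2, p$beta, "+")
  dim(out) <- c(d[1], d[2], d[4], d[3])
  list(out = aperm(out, c(1, 2, 4, 3)),
       cache = list(xhat = xhat, sig = sig, d = d, training = training),
       batch_mean = if (training) mu else NULL,
       batch_var = if (training) v else NULL)
}

bn_bwd <- function(cache, p, dout) {
  d <- cache$d
  dym <- matrix(aperm(dout, c(1, 2, 4, 3)), ncol = d[3])
  xhat <- cache$xhat
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  if (cache$training) {
    m <- nrow(dym)
    t1 <- sweep(dym, 2, dbeta / m)
    t2 <- sweep(xhat, 2, dgamma / m, "*")
    dxm <- sweep(t1 - t2, 2, p$gamma / cache$sig, "*")
  } else {
    dxm <- sweep(dym, 2, p$gamma / cache$sig, "*")
  }
  dim(dxm) <- c(d[1], d[2], d[4], d[3])
  list(dx = aperm(dxm, c(1, 2, 4, 3)),
       grads = list(gamma = dgamma, beta = dbeta))
}

relu_fwd <- function(x) {
  m <- x > 0
  list(out = x * m, cache = m)
}

relu_bwd <- function(cache, dout) dout * cache

# Spatial (per-channel) dropout; inverted scaling so eval needs no rescale.
dropout_fwd <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(out = x, cache = NULL))
  d <- dim(x)
  keep <- stats::rbinom(d[3] * d[4], 1L, 1 - rate) / (1 - rate)
  mask <- array(rep(keep, each = d[1] * d[2]), d)
  list(out = x * mask, cache = mask)
}

dropout_bwd <- function(cache, dout) {
  if (is.null(cache)) dout else dout * cache
}

upsample2_fwd <- function(x) {
  d <- dim(x)
  ri <- rep(seq_len(d[1]), each = 2L)
  ci <- rep(seq_len(d[2]), each = 2L)
  list(out = x[ri, ci, , , drop = FALSE], cache = d)
}

upsample2_bwd <- function(cache, dout) {
  d <- cache
  o1 <- seq(1L, 2L * d[1], by = 2L)
  o2 <- seq(1L, 2L * d[2], by = 2L)
  dout[o1, o2, , , drop = FALSE] + dout[o1 + 1L, o2, , , drop = FALSE] +
    dout[o1, o2 + 1L, , , drop = FALSE] + dout[o1 + 1L, o2 + 1L, , , drop = FALSE]
}

# --- residual unit: 2 subunits of (BN -> ReLU -> 3x3 conv), identity
# shortcut, 1x1 projection when shape changes ---

resblock_init <- function(cin, cout, stride) {
  p <- list(bn1 = bn_init(cin), conv1 = conv_init(cin, cout, 3L),
            bn2 = bn_init(cout), conv2 = conv_init(cout, cout, 3L))
  if (cin != cout || stride != 1L) p$proj <- conv_init(cin, cout, 1L)
  p
}

resblock_fwd <- function(x, p, stride, training, dropout_rate) {
  b1 <- bn_fwd(x, p$bn1, training)
  r1 <- relu_fwd(b1$out)
  c1 <- conv_fwd(r1$out, p$conv1, stride)
  b2 <- bn_fwd(c1$out, p$bn2, training)
  r2 <- relu_fwd(b2$out)
  dp <- dropout_fwd(r2$out, dropout_rate, training)
  c2 <- conv_fwd(dp$out, p$conv2, 1L)
  if (!is.null(p$proj)) {
    sc <- conv_fwd(x, p$proj, stride)
    out <- c2$out + sc$out
    sc_cache <- sc$cache
  } else {
    out <- c2$out + x
    sc_cache <- NULL
  }
  list(out = out,
       cache = list(b1 = b1$cache, r1 = r1$cache, c1 = c1$cache,
                    b2 = b2$cache, r2 = r2$cache, dp = dp$cache,
                    c2 = c2$cache, sc = sc_cache, stride = stride),
       moments = list(bn1 = b1[c("batch_mean", "batch_var")],
                      bn2 = b2[c("batch_mean", "batch_var")]))
}

resblock_bwd <- function(cache, p, dout) {
  g <- list()
  c2b <- conv_bwd(cache$c2, p$conv2, dout)
  g$conv2 <- c2b$grads
  dr2 <- relu_bwd(cache$r2, dropout_bwd(cache$dp, c2b$dx))
  b2b <- bn_bwd(cache$b2, p$bn2, dr2)
  g$bn2 <- b2b$grads
  c1b <- conv_bwd(cache$c1, p$conv1, b2b$dx)
  g$conv1 <- c1b$grads
  dr1 <- relu_bwd(cache$r1, c1b$dx)
  b1b <- bn_bwd(cache$b1, p$bn1, dr1)
  g$bn1 <- b1b$grads
  dx <- b1b$dx
  if (!is.null(p$proj)) {
    scb <- conv_bwd(cache$sc, p$proj, dout)
    g$proj <- scb$grads
    dx <- dx + scb$dx
  } else {
    dx <- dx + dout
  }
  list(dx = dx, grads = g)
}

# --- parameter-tree utilities (Adam, copies, counting) ---

TRAINABLE <- c("W", "b", "gamma", "beta")

# Paths are lists mixing names (named components) and integer positions
# (unnamed list elements), so parameter and gradient trees only need to
# agree structurally, not on names at every level.
tree_walk_names <- function(tree, path = list()) {
  out <- list()
  nms <- names(tree)
  for (i in seq_along(tree)) {
    nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else i
    node <- tree[[i]]
    if (is.list(node)) {
      out <- c(out, tree_walk_names(node, c(path, list(nm))))
    } else if (is.character(nm) && nm %in% TRAINABLE && is.numeric(node)) {
      out <- c(out, list(c(path, list(nm))))
    }
  }
  out
}

tree_get <- function(tree, path) {
  for (p in path) tree <- tree[[p]]
  tree
}

tree_set <- function(tree, path, value) {
  if (length(path) == 1L) {
    tree[[path[[1L]]]] <- value
    return(tree)
  }
  tree[[path[[1L]]]] <- tree_set(tree[[path[[1L]]]], path[-1L], value)
  tree
}

adam_init <- function(params) {
  paths <- tree_walk_names(params)
  list(paths = paths,
       m = lapply(paths, function(p) tree_get(params, p) * 0),
       v = lapply(paths, function(p) tree_get(params, p) * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (i in seq_along(state$paths)) {
    path <- state$paths[[i]]
    g <- tree_get(grads, path)
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g^2
    mhat <- state$m[[i]] / (1 - beta1^state$t)
    vhat <- state$v[[i]] / (1 - beta2^state$t)
    val <- tree_get(params, path) - lr * mhat / (sqrt(vhat) + eps)
    params <- tree_set(params, path, val)
  }
  list(params = params, state = state)
}

# Evaluate with a local RNG stream, restoring the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
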