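# Minimal CNN engine in base R.
#
# Activations are 4-D arrays (batch, height, width, channel); classifier
# activations are (batch, units) matrices. Layers are environments so that
# batch-norm running statistics, gradients and optimizer state can be updated
# in place; forward passes return their caches functionally so snapshots of a
# model stay cheap. Convolutions use im2col + matrix multiply with "same"
# padding; strided convolutions subsample the output grid.

new_nn_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  e
}

nn_conv_layer <- function(cin, cout, k = 3L, stride = 1L) {
  # He (fan-in) initialization; caller wraps in with_seed for determinism
  W <- matrix(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
              k * k * cin, cout)
  new_nn_layer("conv", cin = cin, cout = cout, k = k, stride = stride,
               W = W, b = numeric(cout))
}

nn_bn_layer <- function(c, eps = 1e-5, momentum = 0.9) {
  new_nn_layer("bn", c = c, eps = eps, momentum = momentum,
               gamma = rep(1, c), beta = rep(0, c),
               run_mean = rep(0, c), run_var = rep(1, c))
}

nn_fc_layer <- function(nin, nout) {
  W <- matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
  new_nn_layer("fc", nin = nin, nout = nout, W = W, b = numeric(nout))
}

nn_simple_layer <- function(type) new_nn_layer(type)

# --- primitive forward/backward -------------------------------------------

conv_fwd <- function(layer, x) {
  d <- dim(x); n <- d[1]; h <- d[2]; w <- d[3]; cin <- d[4]
  k <- layer$k; s <- layer$stride; p <- (k - 1L) %/% 2L
  if (p > 0L) {
    xp <- array(0, c(n, h + 2 * p, w + 2 * p, cin))
    xp[, p + seq_len(h), p + seq_len(w), ] <- x
  } else {
    xp <- x
  }
  oi <- seq(1L, h, by = s); oj <- seq(1L, w, by = s)
  ho <- length(oi); wo <- length(oj)
  N <- n * ho * wo
  cols <- matrix(0, N, k * k * cin)
  col <- 1L
  for (dj in 0:(k - 1L)) for (di in 0:(k - 1L)) {
    slab <- xp[, oi + di, oj + dj, , drop = FALSE]
    dim(slab) <- c(N, cin)
    cols[, col:(col + cin - 1L)] <- slab
    col <- col + cin
  }
  y <- cols %*% layer$W + rep(layer$b, each = N)
  dim(y) <- c(n, ho, wo, layer$cout)
  list(out = y, cache = list(cols = cols, in_dim = d, oi = oi, oj = oj, p = p))
}

conv_bwd <- function(layer, dout, cache) {
  d <- cache$in_dim; n <- d[1]; h <- d[2]; w <- d[3]; cin <- d[4]
  k <- layer$k; p <- cache$p
  oi <- cache$oi; oj <- cache$oj
  N <- n * length(oi) * length(oj)
  dym <- dout; dim(dym) <- c(N, layer$cout)
  layer$gW <- crossprod(cache$cols, dym)
  layer$gb <- colSums(dym)
  dcols <- dym %*% t(layer$W)
  dxp <- array(0, c(n, h + 2 * p, w + 2 * p, cin))
  col <- 1L
  for (dj in 0:(k - 1L)) for (di in 0:(k - 1L)) {
    slab <- dcols[, col:(col + cin - 1L)]
    dim(slab) <- c(n, length(oi), length(oj), cin)
    cur <- dxp[, oi + di, oj + dj, , drop = FALSE]
    dxp[, oi + di, oj + dj, ] <- cur + slab
    col <- col + cin
  }
  if (p > 0L) dxp[, p + seq_len(h), p + seq_len(w), , drop = FALSE] else dxp
}

as_channel_matrix <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) == 2L) return(list(m = x, d = dim(x) %||% c(length(x), 1L)))
  m <- x; dim(m) <- c(prod(d[-length(d)]), d[length(d)])
  list(m = m, d = d)
}

bn_fwd <- function(layer, x, training) {
  v <- as_channel_matrix(x); xm <- v$m; N <- nrow(xm)
  if (training) {
    mu <- colMeans(xm)
    xc <- xm - rep(mu, each = N)
    varc <- colMeans(xc * xc)
    layer$run_mean <- layer$momentum * layer$run_mean + (1 - layer$momentum) * mu
    layer$run_var <- layer$momentum * layer$run_var + (1 - layer$momentum) * varc
  } else {
    mu <- layer$run_mean
    varc <- layer$run_var
    xc <- xm - rep(mu, each = N)
  }
  ivar <- 1 / sqrt(varc + layer$eps)
  xhat <- xc * rep(ivar, each = N)
  y <- xhat * rep(layer$gamma, each = N) + rep(layer$beta, each = N)
  dim(y) <- v$d
  list(out = y, cache = list(xhat = xhat, ivar = ivar, d = v$d,
                             training = training))
}

bn_bwd <- function(layer, dout, cache) {
  N <- nrow(cache$xhat)
  dy <- dout; dim(dy) <- dim(cache$xhat)
  layer$ggamma <- colSums(dy * cache$xhat)
  layer$gbeta <- colSums(dy)
  dxhat <- dy * rep(layer$gamma, each = N)
  if (cache$training) {
    t1 <- rep(colMeans(dxhat), each = N)
    t2 <- cache$xhat * rep(colMeans(dxhat * cache$xhat), each = N)
    dx <- (dxhat - t1 - t2) * rep(cache$ivar, each = N)
  } else {
    dx <- dxhat * rep(cache$ivar, each = N)
  }
  dim(dx) <- cache$d
  dx
}

pool_slices <- function(x) {
  d <- dim(x)
  stopifnot(d[2] %% 2L == 0L, d[3] %% 2L == 0L)
  ri <- seq(1L, d[2], by = 2L); ci <- seq(1L, d[3], by = 2L)
  list(ri = ri, ci = ci,
       s = list(x[, ri, ci, , drop = FALSE], x[, ri + 1L, ci, , drop = FALSE],
                x[, ri, ci + 1L, , drop = FALSE],
                x[, ri + 1L, ci + 1L, , drop = FALSE]))
}

maxpool_fwd <- function(x) {
  ps <- pool_slices(x)
  y <- pmax(ps$s[[1]], ps$s[[2]], ps$s[[3]], ps$s[[4]])
  taken <- array(FALSE, dim(y))
  masks <- vector("list", 4L)
  for (i in 1:4) {
    masks[[i]] <- (ps$s[[i]] == y) & !taken
    taken <- taken | masks[[i]]
  }
  list(out = y, cache = list(ri = ps$ri, ci = ps$ci, masks = masks,
                             in_dim = dim(x)))
}

maxpool_bwd <- function(dout, cache) {
  dx <- array(0, cache$in_dim)
  off <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  for (i in 1:4) {
    dx[, cache$ri + off[[i]][1], cache$ci + off[[i]][2], ] <-
      dout * cache$masks[[i]]
  }
  dx
}

avgpool_fwd <- function(x) {
  ps <- pool_slices(x)
  y <- (ps$s[[1]] + ps$s[[2]] + ps$s[[3]] + ps$s[[4]]) / 4
  list(out = y, cache = list(ri = ps$ri, ci = ps$ci, in_dim = dim(x)))
}

avgpool_bwd <- function(dout, cache) {
  dx <- array(0, cache$in_dim)
  g <- dout / 4
  off <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  for (i in 1:4) {
    dx[, cache$ri + off[[i]][1], cache$ci + off[[i]][2], ] <- g
  }
  dx
}

gap_fwd <- function(x) {
  d <- dim(x); n <- d[1]; hw <- d[2] * d[3]; c <- d[4]
  x2 <- x; dim(x2) <- c(n, hw, c)
  xp <- aperm(x2, c(2, 1, 3)); dim(xp) <- c(hw, n * c)
  y <- matrix(colMeans(xp), n, c)
  list(out = y, cache = d)
}

gap_bwd <- function(dout, cache) {
  d <- cache; n <- d[1]; hw <- d[2] * d[3]; c <- d[4]
  g <- as.vector(dout) / hw                       # length n*c, (i, l) order
  dx <- array(rep(g, each = hw), c(hw, n, c))     # (m, i, l)
  dx <- aperm(dx, c(2, 1, 3))
  dim(dx) <- d
  dx
}

# --- composite blocks ------------------------------------------------------

run_chain <- function(layers, x, training) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- nn_fwd(layers[[i]], x, training)
    x <- r$out
    caches[[i]] <- r$cache
  }
  list(out = x, caches = caches)
}

back_chain <- function(layers, dout, caches) {
  for (i in rev(seq_along(layers))) {
    dout <- nn_bwd(layers[[i]], dout, caches[[i]])
  }
  dout
}

nn_res_block <- function(cin, width, projection = FALSE, stride = 1L) {
  sub <- list(nn_bn_layer(cin), nn_simple_layer("relu"),
              nn_conv_layer(cin, width, 3L, stride),
              nn_bn_layer(width), nn_simple_layer("relu"),
              nn_conv_layer(width, width, 3L, 1L))
  proj <- if (projection) nn_conv_layer(cin, width, 1L, stride) else NULL
  if (!projection && (stride != 1L || cin != width)) {
    stop("identity_skip residual block must preserve shape", call. = FALSE)
  }
  new_nn_layer("res_block", sub = sub, proj = proj)
}

res_fwd <- function(layer, x, training) {
  # pre-activation: branch = BN-ReLU-conv-BN-ReLU-conv; projection shortcut
  # (when present) consumes the pre-activated input, identity shortcut the
  # raw input.
  r1 <- nn_fwd(layer$sub[[1]], x, training)
  r2 <- nn_fwd(layer$sub[[2]], r1$out, training)
  a1 <- r2$out
  rest <- run_chain(layer$sub[3:6], a1, training)
  if (is.null(layer$proj)) {
    out <- rest$out + x
    pcache <- NULL
  } else {
    pr <- nn_fwd(layer$proj, a1, training)
    out <- rest$out + pr$out
    pcache <- pr$cache
  }
  list(out = out, cache = list(c1 = r1$cache, c2 = r2$cache,
                               rest = rest$caches, pcache = pcache))
}

res_bwd <- function(layer, dout, cache) {
  d_a1 <- back_chain(layer$sub[3:6], dout, cache$rest)
  if (!is.null(layer$proj)) {
    d_a1 <- d_a1 + nn_bwd(layer$proj, dout, cache$pcache)
  }
  dx <- nn_bwd(layer$sub[[1]], nn_bwd(layer$sub[[2]], d_a1, cache$c2),
               cache$c1)
  if (is.null(layer$proj)) dx <- dx + dout
  dx
}

nn_dense_unit <- function(cin, growth, bottleneck = TRUE) {
  if (bottleneck) {
    list(nn_bn_layer(cin), nn_simple_layer("relu"),
         nn_conv_layer(cin, 4L * growth, 1L, 1L),
         nn_bn_layer(4L * growth), nn_simple_layer("relu"),
         nn_conv_layer(4L * growth, growth, 3L, 1L))
  } else {
    list(nn_bn_layer(cin), nn_simple_layer("relu"),
         nn_conv_layer(cin, growth, 3L, 1L))
  }
}

nn_dense_block <- function(cin, n_layers, growth, bottleneck = TRUE) {
  units <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    units[[l]] <- nn_dense_unit(cin + (l - 1L) * growth, growth, bottleneck)
  }
  new_nn_layer("dense_block", units = units, cin = cin, growth = growth)
}

dense_fwd <- function(layer, x, training) {
  ucaches <- vector("list", length(layer$units))
  for (l in seq_along(layer$units)) {
    r <- run_chain(layer$units[[l]], x, training)
    d <- dim(x)
    x <- array(c(x, r$out), c(d[1], d[2], d[3], d[4] + dim(r$out)[4]))
    ucaches[[l]] <- r$caches
  }
  list(out = x, cache = ucaches)
}

dense_bwd <- function(layer, dout, cache) {
  g <- layer$growth
  for (l in rev(seq_along(layer$units))) {
    d <- dim(dout)
    cprev <- d[4] - g
    d_t <- dout[, , , cprev + seq_len(g), drop = FALSE]
    dout <- dout[, , , seq_len(cprev), drop = FALSE]
    dout <- dout + back_chain(layer$units[[l]], d_t, cache[[l]])
  }
  dout
}

nn_transition <- function(cin, compression = 0.5) {
  cout <- as.integer(floor(cin * compression))
  new_nn_layer("transition",
               sub = list(nn_bn_layer(cin), nn_simple_layer("relu"),
                          nn_conv_layer(cin, cout, 1L, 1L)),
               cout = cout)
}

# --- dispatch --------------------------------------------------------------

nn_fwd <- function(layer, x, training = FALSE) {
  switch(layer$type,
    conv = conv_fwd(layer, x),
    bn = bn_fwd(layer, x, training),
    relu = list(out = pmax(x, 0), cache = x > 0),
    sigmoid = {
      p <- 1 / (1 + exp(-x))
      list(out = p, cache = p)
    },
    maxpool = maxpool_fwd(x),
    avgpool = avgpool_fwd(x),
    gap = gap_fwd(x),
    flatten = {
      d <- dim(x); y <- x; dim(y) <- c(d[1], prod(d[-1]))
      list(out = y, cache = d)
    },
    fc = {
      y <- x %*% layer$W + rep(layer$b, each = nrow(x))
      list(out = y, cache = x)
    },
    res_block = res_fwd(layer, x, training),
    dense_block = dense_fwd(layer, x, training),
    transition = {
      r <- run_chain(layer$sub, x, training)
      pr <- avgpool_fwd(r$out)
      list(out = pr$out, cache = list(sub = r$caches, pool = pr$cache))
    },
    stop(sprintf("unknown nn layer type: %s", layer$type))
  )
}

nn_bwd <- function(layer, dout, cache) {
  switch(layer$type,
    conv = conv_bwd(layer, dout, cache),
    bn = bn_bwd(layer, dout, cache),
    relu = dout * cache,
    sigmoid = dout * cache * (1 - cache),
    maxpool = maxpool_bwd(dout, cache),
    avgpool = avgpool_bwd(dout, cache),
    gap = gap_bwd(dout, cache),
    flatten = {
      dim(dout) <- cache
      dout
    },
    fc = {
      layer$gW <- crossprod(cache, dout)
      layer$gb <- colSums(dout)
      dout %*% t(layer$W)
    },
    res_block = res_bwd(layer, dout, cache),
    dense_block = dense_bwd(layer, dout, cache),
    transition = {
      d <- avgpool_bwd(dout, cache$pool)
      back_chain(layer$sub, d, cache$sub)
    },
    stop(sprintf("unknown nn layer type: %s", layer$type))
  )
}

# --- parameter traversal / optimizer ---------------------------------------

PARAM_NAMES <- list(conv = c("W", "b"), fc = c("W", "b"),
                    bn = c("gamma", "beta"))

# all primitive layers holding parameters, in deterministic traversal order
param_layers <- function(layers) {
  out <- list()
  for (ly in layers) {
    if (ly$type %in% names(PARAM_NAMES)) {
      out[[length(out) + 1L]] <- ly
    } else if (ly$type == "res_block") {
      out <- c(out, param_layers(ly$sub))
      if (!is.null(ly$proj)) out <- c(out, param_layers(list(ly$proj)))
    } else if (ly$type == "dense_block") {
      for (u in ly$units) out <- c(out, param_layers(u))
    } else if (ly$type == "transition") {
      out <- c(out, param_layers(ly$sub))
    }
  }
  out
}

grad_name <- function(pname) {
  c(W = "gW", b = "gb", gamma = "ggamma", beta = "gbeta")[[pname]]
}

adam_init <- function(players) {
  for (ly in players) {
    ly$opt <- lapply(PARAM_NAMES[[ly$type]], function(p) {
      list(m = 0 * get(p, envir = ly), v = 0 * get(p, envir = ly))
    })
    names(ly$opt) <- PARAM_NAMES[[ly$type]]
  }
  invisible(players)
}

adam_step <- function(players, t, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (ly in players) {
    for (p in PARAM_NAMES[[ly$type]]) {
      g <- get(grad_name(p), envir = ly)
      st <- ly$opt[[p]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      assign(p, get(p, envir = ly) - lr * mhat / (sqrt(vhat) + eps), envir = ly)
      ly$opt[[p]] <- st
    }
  }
  invisible(players)
}
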