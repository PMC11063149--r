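# A compact reverse-mode CNN engine on dense base-R arrays.
#
# Tensors are channel-first arrays of dim (C, H, W, N). Every convolution is
# stride 1 (downsampling is done by pooling) and is evaluated as a
# shift-and-multiply sum: for each kernel offset (kh, kw) a contiguous slice
# of the zero-padded input is contracted with a (Cout x Cin) weight slice via
# BLAS. The input gradient scatter-adds through the same slices, so no
# explicit im2col buffers are needed.

# conv weights: array (Cout, Cin, k, k); returns y of dim (Cout, Ho, Wo, N)
pf_pad_input <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1L], d[2L] + 2L * pad, d[3L] + 2L * pad, d[4L]))
  xp[, pad + seq_len(d[2L]), pad + seq_len(d[3L]), ] <- x
  xp
}

pf_conv_fwd <- function(x, W, b, k, pad, keep = FALSE) {
  d <- dim(x)
  cin <- d[1L]; H <- d[2L]; Wd <- d[3L]; N <- d[4L]
  cout <- dim(W)[1L]
  Ho <- H + 2L * pad - k + 1L
  Wo <- Wd + 2L * pad - k + 1L
  xp <- pf_pad_input(x, pad)
  M <- Ho * Wo * N
  acc <- matrix(0, cout, M)
  for (kw in seq_len(k)) {
    for (kh in seq_len(k)) {
      s <- xp[, kh:(kh + Ho - 1L), kw:(kw + Wo - 1L), , drop = FALSE]
      dim(s) <- c(cin, M)
      wk <- W[, , kh, kw, drop = FALSE]
      dim(wk) <- c(cout, cin)
      acc <- acc + wk %*% s
    }
  }
  acc <- acc + b
  dim(acc) <- c(cout, Ho, Wo, N)
  if (keep) list(y = acc, xp = xp) else list(y = acc)
}

pf_conv_bwd <- function(dy, xp, W, b, k, pad) {
  dd <- dim(dy)
  cout <- dd[1L]; Ho <- dd[2L]; Wo <- dd[3L]; N <- dd[4L]
  cin <- dim(W)[2L]
  M <- Ho * Wo * N
  dym <- dy
  dim(dym) <- c(cout, M)
  db <- rowSums(dym)
  dW <- array(0, dim(W))
  for (kw in seq_len(k)) {
    for (kh in seq_len(k)) {
      s <- xp[, kh:(kh + Ho - 1L), kw:(kw + Wo - 1L), , drop = FALSE]
      dim(s) <- c(cin, M)
      dW[, , kh, kw] <- tcrossprod(dym, s)
    }
  }
  # input gradient = stride-1 correlation of dy with flipped, transposed kernels
  Wt <- aperm(W, c(2L, 1L, 3L, 4L))
  Wt <- Wt[, , rev(seq_len(k)), rev(seq_len(k)), drop = FALSE]
  dx <- pf_conv_fwd(dy, Wt, 0, k, k - 1L - pad)$y
  list(dx = dx, dW = dW, db = db)
}

pf_bn_fwd <- function(x, g, b, rm, rv, train, mom = 0.1, eps = 1e-5) {
  d <- dim(x)
  C <- d[1L]
  xm <- x
  dim(xm) <- c(C, d[2L] * d[3L] * d[4L])
  if (train) {
    mu <- rowMeans(xm)
    xc <- xm - mu
    v <- rowMeans(xc * xc)
    m <- ncol(xm)
    rm2 <- (1 - mom) * rm + mom * mu
    rv2 <- (1 - mom) * rv + mom * v * m / max(1, m - 1)
  } else {
    mu <- rm; v <- rv; rm2 <- rm; rv2 <- rv
    xc <- xm - mu
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * istd
  y <- xhat * g + b
  dim(y) <- d
  list(y = y, cache = list(xhat = xhat, istd = istd, d = d, train = train),
       rm = rm2, rv = rv2)
}

pf_bn_bwd <- function(dy, cache, g) {
  d <- cache$d
  dym <- dy
  dim(dym) <- c(d[1L], d[2L] * d[3L] * d[4L])
  dg <- rowSums(dym * cache$xhat)
  db <- rowSums(dym)
  dxhat <- dym * g
  if (cache$train) {
    m <- ncol(dym)
    t1 <- rowSums(dxhat)
    t2 <- rowSums(dxhat * cache$xhat)
    dxm <- (dxhat - t1 / m - cache$xhat * (t2 / m)) * cache$istd
  } else {
    dxm <- dxhat * cache$istd
  }
  dim(dxm) <- d
  list(dx = dxm, dg = dg, db = db)
}

# Separable adaptive average pooling with window boundaries
# floor(i*n_in/n_out) .. ceiling((i+1)*n_in/n_out): any input size maps to any
# output grid (larger grids replicate pixels, as in adaptive pooling layers).
pf_pool_mat <- function(n_in, n_out) {
  P <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    s <- floor((i - 1) * n_in / n_out)
    e <- ceiling(i * n_in / n_out)
    P[i, (s + 1):e] <- 1 / (e - s)
  }
  P
}

# x (C, H, W, N) -> (C, gh, gw, N): Y = Ph X Pw' applied per channel/sample
pf_pool_fwd <- function(x, gh, gw) {
  d <- dim(x)
  Ph <- pf_pool_mat(d[2L], gh)
  Pw <- pf_pool_mat(d[3L], gw)
  a <- aperm(x, c(2L, 1L, 3L, 4L))          # (H, C, W, N)
  dim(a) <- c(d[2L], d[1L] * d[3L] * d[4L])
  a <- Ph %*% a
  dim(a) <- c(gh, d[1L], d[3L], d[4L])
  a <- aperm(a, c(3L, 2L, 1L, 4L))          # (W, C, gh, N)
  dim(a) <- c(d[3L], d[1L] * gh * d[4L])
  a <- Pw %*% a
  dim(a) <- c(gw, d[1L], gh, d[4L])
  list(y = aperm(a, c(2L, 3L, 1L, 4L)), d = d)
}

pf_pool_bwd <- function(dy, d, gh, gw) {
  Ph <- pf_pool_mat(d[2L], gh)
  Pw <- pf_pool_mat(d[3L], gw)
  a <- aperm(dy, c(3L, 1L, 2L, 4L))         # (gw, C, gh, N)
  dim(a) <- c(gw, d[1L] * gh * d[4L])
  a <- crossprod(Pw, a)
  dim(a) <- c(d[3L], d[1L], gh, d[4L])
  a <- aperm(a, c(3L, 2L, 1L, 4L))          # (gh, C, W, N)
  dim(a) <- c(gh, d[1L] * d[3L] * d[4L])
  a <- crossprod(Ph, a)
  dim(a) <- c(d[2L], d[1L], d[3L], d[4L])
  aperm(a, c(2L, 1L, 3L, 4L))
}

# ---- layer dispatch -------------------------------------------------------

pf_layer_fwd <- function(ly, x, params, buffers, train, keep) {
  switch(ly$type,
    conv = {
      r <- pf_conv_fwd(x, params[[ly$W]], params[[ly$b]], ly$k, ly$pad,
                       keep = keep)
      list(y = r$y, cache = if (keep) list(xp = r$xp), buffers = buffers)
    },
    bn = {
      r <- pf_bn_fwd(x, params[[ly$g]], params[[ly$b]],
                     buffers[[ly$rm]], buffers[[ly$rv]], train)
      if (train) {
        buffers[[ly$rm]] <- r$rm
        buffers[[ly$rv]] <- r$rv
      }
      list(y = r$y, cache = if (keep) r$cache, buffers = buffers)
    },
    relu = {
      y <- x * (x > 0)
      list(y = y, cache = if (keep) list(mask = x > 0), buffers = buffers)
    },
    pool_half = {
      d <- dim(x)
      gh <- as.integer(ceiling(d[2L] / 2))
      gw <- as.integer(ceiling(d[3L] / 2))
      r <- pf_pool_fwd(x, gh, gw)
      list(y = r$y, cache = if (keep) list(d = r$d, gh = gh, gw = gw),
           buffers = buffers)
    },
    resblock = {
      h <- x
      main_caches <- vector("list", length(ly$main))
      for (i in seq_along(ly$main)) {
        r <- pf_layer_fwd(ly$main[[i]], h, params, buffers, train, keep)
        h <- r$y
        main_caches[[i]] <- r$cache
        buffers <- r$buffers
      }
      if (is.null(ly$skip)) {
        s <- x
        skip_caches <- NULL
      } else {
        s <- x
        skip_caches <- vector("list", length(ly$skip))
        for (i in seq_along(ly$skip)) {
          r <- pf_layer_fwd(ly$skip[[i]], s, params, buffers, train, keep)
          s <- r$y
          skip_caches[[i]] <- r$cache
          buffers <- r$buffers
        }
      }
      z <- h + s
      list(y = z * (z > 0),
           cache = if (keep) list(main = main_caches, skip = skip_caches,
                                  mask = z > 0),
           buffers = buffers)
    },
    stop("unknown layer type: ", ly$type)
  )
}

pf_layer_bwd <- function(ly, dy, cache, params, grads) {
  switch(ly$type,
    conv = {
      r <- pf_conv_bwd(dy, cache$xp, params[[ly$W]], params[[ly$b]],
                       ly$k, ly$pad)
      grads[[ly$W]] <- (grads[[ly$W]] %||% 0) + r$dW
      grads[[ly$b]] <- (grads[[ly$b]] %||% 0) + r$db
      list(dx = r$dx, grads = grads)
    },
    bn = {
      r <- pf_bn_bwd(dy, cache, params[[ly$g]])
      grads[[ly$g]] <- (grads[[ly$g]] %||% 0) + r$dg
      grads[[ly$b]] <- (grads[[ly$b]] %||% 0) + r$db
      list(dx = r$dx, grads = grads)
    },
    relu = list(dx = dy * cache$mask, grads = grads),
    pool_half = list(dx = pf_pool_bwd(dy, cache$d, cache$gh, cache$gw),
                     grads = grads),
    resblock = {
      dz <- dy * cache$mask
      dh <- dz
      for (i in rev(seq_along(ly$main))) {
        r <- pf_layer_bwd(ly$main[[i]], dh, cache$main[[i]], params, grads)
        dh <- r$dx
        grads <- r$grads
      }
      if (is.null(ly$skip)) {
        ds <- dz
      } else {
        ds <- dz
        for (i in rev(seq_along(ly$skip))) {
          r <- pf_layer_bwd(ly$skip[[i]], ds, cache$skip[[i]], params, grads)
          ds <- r$dx
          grads <- r$grads
        }
      }
      list(dx = dh + ds, grads = grads)
    },
    stop("unknown layer type: ", ly$type)
  )
}

# ---- whole-network forward/backward --------------------------------------

pf_forward <- function(net, x, train = FALSE, keep = FALSE) {
  stopifnot(length(dim(x)) == 4L)
  caches <- vector("list", length(net$layers))
  h <- x
  buffers <- net$buffers
  for (i in seq_along(net$layers)) {
    r <- pf_layer_fwd(net$layers[[i]], h, net$params, buffers, train, keep)
    h <- r$y
    caches[[i]] <- r$cache
    buffers <- r$buffers
  }
  if (length(net$layers) == 0L) {
    feats <- x
  } else if (net$input_skip) {
    d <- dim(h)
    cx <- dim(x)[1L]
    feats <- array(0, c(d[1L] + cx, d[2L], d[3L], d[4L]))
    feats[seq_len(d[1L]), , , ] <- h
    feats[d[1L] + seq_len(cx), , , ] <- x
  } else {
    feats <- h
  }
  g <- net$pool_grid
  pool <- pf_pool_fwd(feats, g, g)
  z <- pool$y
  N <- dim(feats)[4L]
  din <- dim(feats)[1L] * g * g
  dim(z) <- c(din, 1L, 1L, N)
  hbn_cache <- NULL
  if (!is.null(net$head_bn)) {
    hb <- net$head_bn
    r <- pf_bn_fwd(z, net$params[[hb$g]], net$params[[hb$b]],
                   buffers[[hb$rm]], buffers[[hb$rv]], train)
    if (train) {
      buffers[[hb$rm]] <- r$rm
      buffers[[hb$rv]] <- r$rv
    }
    z <- r$y
    hbn_cache <- if (keep) r$cache
  }
  dim(z) <- c(din, N)
  logits <- net$params[[net$fc$W]] %*% z + net$params[[net$fc$b]]
  list(logits = logits, buffers = buffers,
       cache = if (keep) list(layers = caches, pool_d = pool$d, z = z,
                              hbn = hbn_cache,
                              back_channels = if (length(net$layers)) dim(h)[1L] else 0L,
                              in_channels = dim(x)[1L]))
}

pf_backward <- function(net, cache, dlogits) {
  grads <- list()
  grads[[net$fc$W]] <- tcrossprod(dlogits, cache$z)
  grads[[net$fc$b]] <- rowSums(dlogits)
  dz <- crossprod(net$params[[net$fc$W]], dlogits)
  if (!is.null(net$head_bn)) {
    hb <- net$head_bn
    dim(dz) <- c(nrow(dz), 1L, 1L, ncol(dlogits))
    r <- pf_bn_bwd(dz, cache$hbn, net$params[[hb$g]])
    grads[[hb$g]] <- r$dg
    grads[[hb$b]] <- r$db
    dz <- r$dx
  }
  g <- net$pool_grid
  cfeat <- cache$pool_d[1L]
  dim(dz) <- c(cfeat, g, g, ncol(dlogits))
  dfeats <- pf_pool_bwd(dz, cache$pool_d, g, g)
  if (length(net$layers) == 0L) {
    return(list(dx = dfeats, grads = grads))
  }
  if (net$input_skip) {
    cb <- cache$back_channels
    dh <- dfeats[seq_len(cb), , , , drop = FALSE]
    dxin <- dfeats[cb + seq_len(cache$in_channels), , , , drop = FALSE]
  } else {
    dh <- dfeats
    dxin <- NULL
  }
  for (i in rev(seq_along(net$layers))) {
    r <- pf_layer_bwd(net$layers[[i]], dh, cache$layers[[i]], net$params, grads)
    dh <- r$dx
    grads <- r$grads
  }
  dx <- if (is.null(dxin)) dh else dh + dxin
  list(dx = dx, grads = grads)
}

# Softmax cross-entropy over logits (K x N) with 0-based integer targets.
pf_softmax_xent <- function(logits, y) {
  N <- ncol(logits)
  mx <- apply(logits, 2L, max)
  ex <- exp(sweep(logits, 2L, mx))
  Z <- colSums(ex)
  p <- sweep(ex, 2L, Z, `/`)
  idx <- cbind(as.integer(y) + 1L, seq_len(N))
  loss <- mean(log(Z) + mx - logits[idx])
  dl <- p
  dl[idx] <- dl[idx] - 1
  list(loss = loss, dlogits = dl / N, prob = p)
}

# ---- Adam -----------------------------------------------------------------

pf_adam_init <- function(lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         weight_decay = 0) {
  list(m = list(), v = list(), t = 0L, lr = lr, beta1 = beta1, beta2 = beta2,
       eps = eps, weight_decay = weight_decay)
}

pf_adam_step <- function(state, params, grads) {
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  c1 <- 1 - b1^state$t
  c2 <- 1 - b2^state$t
  for (nm in names(grads)) {
    gr <- grads[[nm]]
    m <- state$m[[nm]]
    v <- state$v[[nm]]
    if (is.null(m)) { m <- gr * 0; v <- gr * 0 }
    m <- b1 * m + (1 - b1) * gr
    v <- b2 * v + (1 - b2) * gr * gr
    state$m[[nm]] <- m
    state$v[[nm]] <- v
    upd <- state$lr * (m / c1) / (sqrt(v / c2) + state$eps)
    # decoupled weight decay on weight matrices only (not biases/BN scales)
    if (state$weight_decay > 0 && endsWith(nm, ".W")) {
      upd <- upd + state$lr * state$weight_decay * params[[nm]]
    }
    params[[nm]] <- params[[nm]] - upd
  }
  list(state = state, params = params)
}
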