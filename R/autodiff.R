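## Reverse-mode automatic differentiation on dense arrays.
##
## Conventions (batch axis always last):
##   spatial feature maps:  array (H, W, C, N)
##   feature vectors:       matrix (F, N)
##   feature sequences:     array (F, L, N)
##
## A tape records nodes in creation order; ad_backward walks it in reverse.
## Each node is an environment holding `value`, accumulated `grad`, its
## `parents`, and a `backfn(node)` returning one gradient per parent.

ad_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 512L)
  e$n <- 0L
  class(e) <- "ad_tape"
  e
}

ad_node <- function(tape, value, parents = list(), backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backfn <- backfn
  if (!is.null(tape) && length(parents)) {
    tape$n <- tape$n + 1L
    if (tape$n > length(tape$nodes))
      tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    tape$nodes[[tape$n]] <- nd
  }
  nd
}

ad_leaf <- function(value) ad_node(NULL, value)

ad_backward <- function(tape, loss) {
  loss$grad <- array(1, dim = dim(loss$value) %||% 1)
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backfn)) next
    gs <- nd$backfn(nd)
    for (j in seq_along(nd$parents)) {
      g <- gs[[j]]
      if (is.null(g)) next
      p <- nd$parents[[j]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(NULL)
}

## ---- elementwise ops -------------------------------------------------------

ad_add <- function(tape, a, b) {
  ad_node(tape, a$value + b$value, list(a, b),
          function(nd) list(nd$grad, nd$grad))
}

ad_mul <- function(tape, a, b) {
  ad_node(tape, a$value * b$value, list(a, b),
          function(nd) list(nd$grad * b$value, nd$grad * a$value))
}

ad_relu <- function(tape, x) {
  mask <- x$value > 0
  ad_node(tape, x$value * mask, list(x), function(nd) list(nd$grad * mask))
}

ad_sigmoid <- function(tape, x) {
  y <- 1 / (1 + exp(-x$value))
  ad_node(tape, y, list(x), function(nd) list(nd$grad * y * (1 - y)))
}

ad_tanh <- function(tape, x) {
  y <- tanh(x$value)
  ad_node(tape, y, list(x), function(nd) list(nd$grad * (1 - y * y)))
}

## ---- dense / matmul --------------------------------------------------------

## y = W x (+ b); x (F, N), W (O, F), b (O) or NULL
ad_dense <- function(tape, x, W, b = NULL) {
  y <- W$value %*% x$value
  if (!is.null(b)) y <- y + b$value
  parents <- if (is.null(b)) list(x, W) else list(x, W, b)
  ad_node(tape, y, parents, function(nd) {
    g <- nd$grad
    out <- list(crossprod(W$value, g), tcrossprod(g, x$value))
    if (!is.null(b)) out[[3]] <- rowSums(g)
    out
  })
}

## ---- 2-D convolution (im2col), asymmetric zero padding ---------------------

## pad = c(top, bottom, left, right); W (kh, kw, Cin, F), b (F) or NULL
ad_conv2d <- function(tape, x, W, b = NULL, pad = c(0L, 0L, 0L, 0L)) {
  v <- x$value
  d <- dim(v)
  H <- d[1]; Wd <- d[2]; C <- d[3]; N <- d[4]
  kd <- dim(W$value)
  kh <- kd[1]; kw <- kd[2]; F <- kd[4]
  if (kd[3] != C) stopf("conv2d: input has %d channels, kernel expects %d", C, kd[3])
  Hp <- H + pad[1] + pad[2]; Wp <- Wd + pad[3] + pad[4]
  Ho <- Hp - kh + 1L; Wo <- Wp - kw + 1L
  if (Ho < 1 || Wo < 1)
    stopf("conv2d: %dx%d input (padded %dx%d) smaller than %dx%d kernel",
          H, Wd, Hp, Wp, kh, kw)
  ## channel-first padded copy so the im2col slabs need no per-offset aperm
  xp2 <- array(0, c(C, Hp, Wp, N))
  xp2[, pad[1] + seq_len(H), pad[3] + seq_len(Wd), ] <- aperm(v, c(3, 1, 2, 4))

  kk <- kh * kw
  cols <- matrix(0, kk * C, Ho * Wo * N)
  q <- 0L
  for (j in seq_len(kw)) for (i in seq_len(kh)) {
    q <- q + 1L
    blk <- xp2[, i:(i + Ho - 1L), j:(j + Wo - 1L), , drop = FALSE]
    dim(blk) <- c(C, Ho * Wo * N)
    cols[((q - 1L) * C + 1L):(q * C), ] <- blk
  }
  Wmat <- aperm(W$value, c(3, 1, 2, 4))
  dim(Wmat) <- c(kk * C, F)
  out <- crossprod(Wmat, cols)                    # (F, Ho*Wo*N)
  if (!is.null(b)) out <- out + b$value
  y <- aperm(array(out, c(F, Ho, Wo, N)), c(2, 3, 1, 4))

  parents <- if (is.null(b)) list(x, W) else list(x, W, b)
  ad_node(tape, y, parents, function(nd) {
    gmat <- aperm(nd$grad, c(3, 1, 2, 4))
    dim(gmat) <- c(F, Ho * Wo * N)
    dWmat <- tcrossprod(cols, gmat)                         # (kk*C, F)
    dW <- aperm(array(dWmat, c(C, kh, kw, F)), c(2, 3, 1, 4))
    dcols <- Wmat %*% gmat                                  # (kk*C, Ho*Wo*N)
    dxp2 <- array(0, c(C, Hp, Wp, N))
    q <- 0L
    for (j in seq_len(kw)) for (i in seq_len(kh)) {
      q <- q + 1L
      blk <- dcols[((q - 1L) * C + 1L):(q * C), , drop = FALSE]
      dim(blk) <- c(C, Ho, Wo, N)
      ri <- i:(i + Ho - 1L); rj <- j:(j + Wo - 1L)
      dxp2[, ri, rj, ] <- dxp2[, ri, rj, , drop = FALSE] + blk
    }
    dx <- aperm(dxp2[, pad[1] + seq_len(H), pad[3] + seq_len(Wd), ,
                     drop = FALSE], c(2, 3, 1, 4))
    out <- list(dx, dW)
    if (!is.null(b)) out[[3]] <- rowSums(gmat)
    out
  })
}

## asymmetric same-padding amounts for a kernel length (left/top, right/bottom)
pad_same <- function(k) c(floor((k - 1) / 2), ceiling((k - 1) / 2))

## ---- 1-D convolution along the channel axis of a (C, N) matrix -------------
## single in/out channel, odd kernel length, zero same-padding (the ECA conv)
ad_conv1d_channels <- function(tape, x, w) {
  v <- x$value
  C <- nrow(v); N <- ncol(v)
  k <- length(w$value)
  if (k %% 2 != 1) stopf("ECA 1-D kernel length must be odd, got %d", k)
  p <- (k - 1L) / 2L
  xp <- rbind(matrix(0, p, N), v, matrix(0, p, N))
  y <- matrix(0, C, N)
  for (j in seq_len(k)) y <- y + w$value[j] * xp[j:(j + C - 1L), , drop = FALSE]
  ad_node(tape, y, list(x, w), function(nd) {
    g <- nd$grad
    dxp <- matrix(0, C + 2L * p, N)
    dw <- numeric(k)
    for (j in seq_len(k)) {
      idx <- j:(j + C - 1L)
      dxp[idx, ] <- dxp[idx, , drop = FALSE] + w$value[j] * g
      dw[j] <- sum(g * xp[idx, , drop = FALSE])
    }
    list(dxp[(p + 1L):(p + C), , drop = FALSE], dw)
  })
}

## ---- batch normalization ----------------------------------------------------

## Per-feature-channel batch normalization. Channel axis: dim 3 for 4-D
## spatial maps, dim 1 for (F, L, N) sequences and (F, N) vectors. Training
## mode normalizes by batch statistics and updates the running averages stored
## in `state[[key]]`; inference mode uses the running averages.
ad_bn <- function(tape, x, gamma, beta, state, key, training,
                  momentum = 0.1, eps = 1e-5) {
  v <- x$value
  d <- dim(v)
  to_mat <- from_mat <- NULL
  if (length(d) == 4) {
    C <- d[3]
    to_mat <- function(a) matrix(aperm(a, c(3, 1, 2, 4)), C)
    from_mat <- function(m) aperm(array(m, c(C, d[1], d[2], d[4])), c(2, 3, 1, 4))
  } else {
    C <- d[1]
    to_mat <- function(a) matrix(a, C)
    from_mat <- function(m) array(m, d)
  }
  M <- to_mat(v)
  m <- ncol(M)
  st <- get0(key, envir = state, inherits = FALSE,
             ifnotfound = list(mean = numeric(C), var = rep(1, C)))
  if (training) {
    mu <- rowMeans(M)
    va <- rowMeans(M * M) - mu * mu
    assign(key, list(mean = (1 - momentum) * st$mean + momentum * mu,
                     var = (1 - momentum) * st$var + momentum * va),
           envir = state)
  } else {
    mu <- st$mean
    va <- st$var
  }
  ivar <- 1 / sqrt(va + eps)
  xhat <- (M - mu) * ivar
  y <- gamma$value * xhat + beta$value
  ad_node(tape, from_mat(y), list(x, gamma, beta), function(nd) {
    g <- to_mat(nd$grad)
    dgamma <- rowSums(g * xhat)
    dbeta <- rowSums(g)
    dxhat <- g * gamma$value
    if (training) {
      dM <- (ivar / m) * (m * dxhat - rowSums(dxhat) - xhat * rowSums(dxhat * xhat))
    } else {
      dM <- dxhat * ivar
    }
    list(from_mat(dM), dgamma, dbeta)
  })
}

## ---- pooling ----------------------------------------------------------------

## global average pool over the spatial plane: (H,W,C,N) -> (C,N)
ad_gap_sp <- function(tape, x) {
  v <- x$value
  d <- dim(v)
  hw <- d[1] * d[2]
  y <- colSums(v, dims = 2) / hw
  ad_node(tape, y, list(x), function(nd) {
    list(array(rep(nd$grad / hw, each = hw), d))
  })
}

## global max pool over the spatial plane: (H,W,C,N) -> (C,N)
ad_gmp_sp <- function(tape, x) {
  v <- x$value
  d <- dim(v)
  hw <- d[1] * d[2]
  mm <- matrix(v, hw, d[3] * d[4])
  idx <- max.col(t(mm), ties.method = "first")
  sel <- cbind(idx, seq_along(idx))
  y <- matrix(mm[sel], d[3], d[4])
  ad_node(tape, y, list(x), function(nd) {
    dmm <- matrix(0, hw, d[3] * d[4])
    dmm[sel] <- nd$grad
    list(array(dmm, d))
  })
}

## mean over the channel axis: (H,W,C,N) -> (H,W,1,N)
ad_chmean <- function(tape, x) {
  v <- x$value
  d <- dim(v)
  C <- d[3]
  y <- rowSums(aperm(v, c(1, 2, 4, 3)), dims = 3) / C
  ad_node(tape, array(y, c(d[1], d[2], 1, d[4])), list(x), function(nd) {
    g <- array(nd$grad, c(d[1], d[2], d[4])) / C
    list(aperm(array(rep(g, C), c(d[1], d[2], d[4], C)), c(1, 2, 4, 3)))
  })
}

## max over the channel axis: (H,W,C,N) -> (H,W,1,N)
ad_chmax <- function(tape, x) {
  v <- x$value
  d <- dim(v)
  C <- d[3]
  mm <- matrix(aperm(v, c(3, 1, 2, 4)), C)      # (C, H*W*N)
  idx <- max.col(t(mm), ties.method = "first")
  sel <- cbind(idx, seq_along(idx))
  y <- array(mm[sel], c(d[1], d[2], 1, d[4]))
  ad_node(tape, y, list(x), function(nd) {
    dmm <- matrix(0, C, ncol(mm))
    dmm[sel] <- nd$grad
    list(aperm(array(dmm, c(C, d[1], d[2], d[4])), c(2, 3, 1, 4)))
  })
}

## adaptive average pooling of the spatial plane to (oh, ow)
ad_adaptive_avgpool <- function(tape, x, oh, ow) {
  v <- x$value
  d <- dim(v)
  bins <- function(n_in, n_out) {
    lapply(seq_len(n_out), function(i) {
      (floor((i - 1) * n_in / n_out) + 1L):ceiling(i * n_in / n_out)
    })
  }
  bh <- bins(d[1], oh); bw <- bins(d[2], ow)
  y <- array(0, c(oh, ow, d[3], d[4]))
  for (i in seq_len(oh)) for (j in seq_len(ow)) {
    blk <- v[bh[[i]], bw[[j]], , , drop = FALSE]
    y[i, j, , ] <- colSums(blk, dims = 2) / (length(bh[[i]]) * length(bw[[j]]))
  }
  ad_node(tape, y, list(x), function(nd) {
    dx <- array(0, d)
    for (i in seq_len(oh)) for (j in seq_len(ow)) {
      len <- length(bh[[i]]) * length(bw[[j]])
      add <- array(rep(nd$grad[i, j, , ] / len,
                       each = len),
                   c(length(bh[[i]]), length(bw[[j]]), d[3], d[4]))
      dx[bh[[i]], bw[[j]], , ] <- dx[bh[[i]], bw[[j]], , , drop = FALSE] + add
    }
    list(dx)
  })
}

## ---- structural ops ---------------------------------------------------------

## concatenate spatial maps along the channel axis
ad_concat_ch <- function(tape, xs) {
  ds <- lapply(xs, function(x) dim(x$value))
  Cs <- vapply(ds, `[`, numeric(1), 3)
  d1 <- ds[[1]]
  y <- array(0, c(d1[1], d1[2], sum(Cs), d1[4]))
  off <- 0L
  for (x in xs) {
    ci <- dim(x$value)[3]
    y[, , off + seq_len(ci), ] <- x$value
    off <- off + ci
  }
  ad_node(tape, y, xs, function(nd) {
    out <- vector("list", length(xs))
    off <- 0L
    for (i in seq_along(xs)) {
      ci <- Cs[i]
      out[[i]] <- nd$grad[, , off + seq_len(ci), , drop = FALSE]
      off <- off + ci
    }
    out
  })
}

## concatenate feature vectors along the feature axis (rbind)
ad_concat_rows <- function(tape, xs) {
  Fs <- vapply(xs, function(x) nrow(x$value), numeric(1))
  y <- do.call(rbind, lapply(xs, function(x) x$value))
  ad_node(tape, y, xs, function(nd) {
    out <- vector("list", length(xs))
    off <- 0L
    for (i in seq_along(xs)) {
      out[[i]] <- nd$grad[off + seq_len(Fs[i]), , drop = FALSE]
      off <- off + Fs[i]
    }
    out
  })
}

ad_rows <- function(tape, x, idx) {
  d <- dim(x$value)
  ad_node(tape, x$value[idx, , drop = FALSE], list(x), function(nd) {
    dx <- matrix(0, d[1], d[2])
    dx[idx, ] <- nd$grad
    list(dx)
  })
}

## extract time step t from a sequence (F, L, N) -> (F, N)
ad_slice_time <- function(tape, x, t) {
  d <- dim(x$value)
  y <- matrix(x$value[, t, ], d[1], d[3])
  ad_node(tape, y, list(x), function(nd) {
    dx <- array(0, d)
    dx[, t, ] <- nd$grad
    list(dx)
  })
}

ad_reshape <- function(tape, x, newdim) {
  d <- dim(x$value)
  y <- x$value
  dim(y) <- newdim
  ad_node(tape, y, list(x), function(nd) {
    g <- nd$grad
    dim(g) <- d
    list(g)
  })
}

## ---- attention rescaling ----------------------------------------------------

## multiply spatial map (H,W,C,N) by per-channel weights (C,N)
ad_scale_ch <- function(tape, x, w) {
  d <- dim(x$value)
  hw <- d[1] * d[2]
  wb <- array(rep(w$value, each = hw), d)
  ad_node(tape, x$value * wb, list(x, w), function(nd) {
    list(nd$grad * wb, colSums(nd$grad * x$value, dims = 2))
  })
}

## multiply spatial map (H,W,C,N) by a spatial mask (H,W,1,N)
ad_scale_sp <- function(tape, x, m) {
  d <- dim(x$value)
  C <- d[3]
  mv <- array(m$value, c(d[1], d[2], d[4]))
  mb <- aperm(array(rep(mv, C), c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  ad_node(tape, x$value * mb, list(x, m), function(nd) {
    dm <- rowSums(aperm(nd$grad * x$value, c(1, 2, 4, 3)), dims = 3)
    list(nd$grad * mb, array(dm, c(d[1], d[2], 1, d[4])))
  })
}

## ---- LSTM (fused op with hand-written backpropagation through time) ---------

## x (F, L, N); Wx (4U, F), Wh (4U, U), b (4U); gate row order i, f, o, g.
## Returns the final hidden state (U, N). A fused op keeps the tape small and
## makes BPTT a tight reverse loop instead of thousands of micro-nodes.
ad_lstm <- function(tape, x, Wx, Wh, b, U) {
  v <- x$value
  d <- dim(v)
  F <- d[1]; L <- d[2]; N <- d[3]
  ii <- 1:U; fi <- (U + 1):(2 * U); oi <- (2 * U + 1):(3 * U); gi <- (3 * U + 1):(4 * U)
  h <- matrix(0, U, N)
  cc <- matrix(0, U, N)
  gates <- vector("list", L)    # post-activation gates (4U, N)
  cs <- vector("list", L)       # cell states
  tanhc <- vector("list", L)
  hs <- vector("list", L + 1)   # h_{t-1} per step (hs[[1]] = 0)
  hs[[1]] <- h
  for (t in seq_len(L)) {
    xt <- matrix(v[, t, ], F, N)
    a <- Wx$value %*% xt + Wh$value %*% h + b$value
    a[c(ii, fi, oi), ] <- 1 / (1 + exp(-a[c(ii, fi, oi), , drop = FALSE]))
    a[gi, ] <- tanh(a[gi, , drop = FALSE])
    cc <- a[fi, , drop = FALSE] * cc + a[ii, , drop = FALSE] * a[gi, , drop = FALSE]
    tc <- tanh(cc)
    h <- a[oi, , drop = FALSE] * tc
    gates[[t]] <- a; cs[[t]] <- cc; tanhc[[t]] <- tc; hs[[t + 1]] <- h
  }
  ad_node(tape, h, list(x, Wx, Wh, b), function(nd) {
    dh <- nd$grad
    dc <- matrix(0, U, N)
    dWx <- array(0, dim(Wx$value)); dWh <- array(0, dim(Wh$value))
    db <- numeric(4 * U)
    dx <- array(0, d)
    for (t in rev(seq_len(L))) {
      a <- gates[[t]]
      i <- a[ii, , drop = FALSE]; f <- a[fi, , drop = FALSE]
      o <- a[oi, , drop = FALSE]; g <- a[gi, , drop = FALSE]
      tc <- tanhc[[t]]
      dc <- dc + dh * o * (1 - tc * tc)
      c_prev <- if (t > 1) cs[[t - 1]] else matrix(0, U, N)
      da <- rbind(dc * g * i * (1 - i),
                  dc * c_prev * f * (1 - f),
                  dh * tc * o * (1 - o),
                  dc * i * (1 - g * g))
      xt <- matrix(v[, t, ], F, N)
      dWx <- dWx + tcrossprod(da, xt)
      dWh <- dWh + tcrossprod(da, hs[[t]])
      db <- db + rowSums(da)
      dx[, t, ] <- crossprod(Wx$value, da)
      dh <- crossprod(Wh$value, da)
      dc <- dc * f
    }
    list(dx, dWx, dWh, db)
  })
}

## ---- dropout ----------------------------------------------------------------

## inverted dropout; identity when not training or p = 0
ad_dropout <- function(tape, x, p, training) {
  if (!training || p <= 0) return(x)
  mask <- (stats::runif(length(x$value)) >= p) / (1 - p)
  dim(mask) <- dim(x$value)
  ad_node(tape, x$value * mask, list(x), function(nd) list(nd$grad * mask))
}

## ---- losses -----------------------------------------------------------------

softmax_cols <- function(z) {
  z <- z - rep(apply(z, 2, max), each = nrow(z))
  e <- exp(z)
  e / rep(colSums(e), each = nrow(z))
}

## mean cross-entropy of softmax(logits) against one-hot targets (K, N)
ad_softmax_ce <- function(tape, logits, y_onehot) {
  p <- softmax_cols(logits$value)
  N <- ncol(p)
  loss <- -sum(y_onehot * log(pmax(p, 1e-12))) / N
  ad_node(tape, loss, list(logits), function(nd) {
    list((p - y_onehot) / N * as.numeric(nd$grad))
  })
}
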