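# Minimal reverse-mode automatic differentiation on dense arrays.
#
# Feature maps use the layout H x W x N x C (height, width, batch,
# channels). Channels-last keeps every convolution window a contiguous
# (H*W*N) x C matrix view — a plain dim<- reshape, no permutation — so the
# whole engine reduces to BLAS matmuls plus elementwise kernels. Channel
# descriptors (pooled features) are C x N matrices. Every operator builds a
# graph node holding the forward value, parent nodes and a backward closure
# that scatters the incoming gradient to its parents; ad_backward() runs
# the closures in reverse topological order. All backward passes are
# checked against central finite differences in the test suite.

.ad_env <- new.env(parent = emptyenv())
.ad_env$next_id <- 1L

ad_tensor <- function(value, requires_grad = FALSE, parents = list(),
                      backward = NULL) {
  node <- new.env(parent = emptyenv())
  node$id <- .ad_env$next_id
  .ad_env$next_id <- .ad_env$next_id + 1L
  node$value <- value
  node$grad <- NULL
  node$requires_grad <- requires_grad ||
    any(vapply(parents, function(p) p$requires_grad, logical(1)))
  node$parents <- parents
  node$backward <- backward
  class(node) <- "ad_tensor"
  node
}

ad_param <- function(value) ad_tensor(value, requires_grad = TRUE)
ad_const <- function(value) ad_tensor(value, requires_grad = FALSE)

is_ad <- function(x) inherits(x, "ad_tensor")
ad_value <- function(x) if (is_ad(x)) x$value else x

ad_accum <- function(node, g) {
  if (!node$requires_grad) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

# Reverse pass from a scalar root. Gradients accumulate in node$grad.
ad_backward <- function(root) {
  stopifnot(length(root$value) == 1L)
  order <- vector("list", 256L)
  n_ord <- 0L
  seen <- new.env(parent = emptyenv())
  visit <- function(node) {
    key <- as.character(node$id)
    if (!is.null(seen[[key]])) return(invisible(NULL))
    assign(key, TRUE, envir = seen)
    for (p in node$parents) if (p$requires_grad) visit(p)
    n_ord <<- n_ord + 1L
    if (n_ord > length(order)) length(order) <<- 2L * n_ord
    order[[n_ord]] <<- node
    invisible(NULL)
  }
  visit(root)
  root$grad <- 1
  for (i in rev(seq_len(n_ord))) {
    node <- order[[i]]
    if (!is.null(node$backward) && !is.null(node$grad)) node$backward(node)
  }
  invisible(root)
}

ad_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# reshape without changing data order
.reshape <- function(x, d) { dim(x) <- d; x }

## ---- elementwise ----------------------------------------------------------

ad_add <- function(a, b) {
  ad_tensor(a$value + b$value, parents = list(a, b), backward = function(node) {
    ad_accum(a, node$grad)
    ad_accum(b, node$grad)
  })
}

ad_sub <- function(a, b) {
  ad_tensor(a$value - b$value, parents = list(a, b), backward = function(node) {
    ad_accum(a, node$grad)
    ad_accum(b, -node$grad)
  })
}

ad_mul <- function(a, b) {
  ad_tensor(a$value * b$value, parents = list(a, b), backward = function(node) {
    ad_accum(a, node$grad * b$value)
    ad_accum(b, node$grad * a$value)
  })
}

ad_relu <- function(x) {
  pos <- x$value > 0
  ad_tensor(x$value * pos, parents = list(x), backward = function(node) {
    ad_accum(x, node$grad * pos)
  })
}

ad_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$value))
  ad_tensor(s, parents = list(x), backward = function(node) {
    ad_accum(x, node$grad * s * (1 - s))
  })
}

ad_one_minus <- function(x) {
  ad_tensor(1 - x$value, parents = list(x), backward = function(node) {
    ad_accum(x, -node$grad)
  })
}

## ---- convolution ----------------------------------------------------------

# Same-padding stride-1 convolution. x: H x W x N x Cin, w: kh x kw x Cin
# x Cout (kh, kw odd), b: length Cout. im2col over the zero-padded input
# with precomputed linear indices (one fast vector gather per kernel tap),
# then a single BLAS matmul; the column matrix is cached for the backward
# pass.
ad_conv2d <- function(x, w, b = NULL, cache = NULL) {
  xv <- x$value; wv <- w$value
  d <- dim(xv); H <- d[1]; W <- d[2]; N <- d[3]; C <- d[4]
  kh <- dim(wv)[1]; kw <- dim(wv)[2]; Cout <- dim(wv)[4]
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  HWN <- H * W * N
  Hp <- H + 2L * ph; Wp <- W + 2L * pw
  key <- paste(c(d, kh, kw), collapse = ".")
  if (!is.null(cache) && identical(cache$key, key)) {
    inner <- cache$inner; idx0 <- cache$idx0; offs <- cache$offs
  } else {
    # linear indices of the unpadded region, of the (i=1, j=1) window
    # (both ordered (h, w, n, c)), and per-tap offsets
    inner <- rep(ph + seq_len(H), times = W) +
      rep((pw + seq_len(W) - 1L) * Hp, each = H)
    inner <- rep(inner, times = N * C) +
      rep((seq_len(N * C) - 1L) * (Hp * Wp), each = H * W)
    idx0 <- rep(seq_len(H), times = W) + rep((seq_len(W) - 1L) * Hp, each = H)
    idx0 <- rep(idx0, times = N * C) +
      rep((seq_len(N * C) - 1L) * (Hp * Wp), each = H * W)
    offs <- rep(seq_len(kh) - 1L, times = kw) +
      rep((seq_len(kw) - 1L) * Hp, each = kh)
    if (!is.null(cache)) {
      cache$key <- key; cache$inner <- inner; cache$idx0 <- idx0
      cache$offs <- offs
    }
  }
  khw <- kh * kw
  xp <- numeric(Hp * Wp * N * C)
  xp[inner] <- xv
  cols <- im2col_gather(xp, idx0, offs, HWN, C)
  # weight matrix with rows ordered (c fastest, then kernel tap)
  wmat <- matrix(aperm(wv, c(3L, 1L, 2L, 4L)), khw * C, Cout)
  ymat <- cols %*% wmat
  if (!is.null(b)) ymat <- ymat + rep(as.vector(b$value), each = HWN)
  parents <- c(list(x, w), if (!is.null(b)) list(b))
  ad_tensor(.reshape(ymat, c(H, W, N, Cout)), parents = parents,
            backward = function(node) {
    gmat <- .reshape(node$grad, c(HWN, Cout))
    if (!is.null(b) && b$requires_grad) ad_accum(b, colSums(gmat))
    if (w$requires_grad) {
      gwmat <- crossprod(cols, gmat)
      ad_accum(w, aperm(.reshape(gwmat, c(C, kh, kw, Cout)),
                        c(2L, 3L, 1L, 4L)))
    }
    if (x$requires_grad) {
      gcols <- gmat %*% t(wmat)
      gxp <- col2im_scatter(gcols, idx0, offs, Hp * Wp * N * C)
      ad_accum(x, .reshape(gxp[inner], c(H, W, N, C)))
    }
  })
}

# 2x2 stride-2 transposed convolution (doubles H and W). The stride equals
# the kernel size so output positions partition over the four kernel taps.
ad_conv_transpose2 <- function(x, w, b = NULL) {
  xv <- x$value; wv <- w$value
  d <- dim(xv); H <- d[1]; W <- d[2]; N <- d[3]; C <- d[4]
  Cout <- dim(wv)[4]
  HWN <- H * W * N
  xmat <- .reshape(xv, c(HWN, C))
  yv <- array(0, c(2L * H, 2L * W, N, Cout))
  for (j in 1:2) for (i in 1:2) {
    ym <- xmat %*% matrix(wv[i, j, , ], C, Cout)
    yv[seq(i, 2L * H, 2L), seq(j, 2L * W, 2L), , ] <-
      .reshape(ym, c(H, W, N, Cout))
  }
  if (!is.null(b))
    yv <- yv + rep(as.vector(b$value), each = 4L * HWN)
  parents <- c(list(x, w), if (!is.null(b)) list(b))
  ad_tensor(yv, parents = parents, backward = function(node) {
    g <- node$grad
    gx_mat <- NULL
    if (w$requires_grad) gw <- array(0, dim(wv))
    for (j in 1:2) for (i in 1:2) {
      gij <- g[seq(i, 2L * H, 2L), seq(j, 2L * W, 2L), , , drop = FALSE]
      gm <- .reshape(gij, c(HWN, Cout))
      if (w$requires_grad) gw[i, j, , ] <- crossprod(xmat, gm)
      if (!is.null(b) && b$requires_grad) ad_accum(b, colSums(gm))
      if (x$requires_grad) {
        contrib <- gm %*% t(matrix(wv[i, j, , ], C, Cout))
        gx_mat <- if (is.null(gx_mat)) contrib else gx_mat + contrib
      }
    }
    if (w$requires_grad) ad_accum(w, gw)
    if (x$requires_grad) ad_accum(x, .reshape(gx_mat, c(H, W, N, C)))
  })
}

## ---- pooling --------------------------------------------------------------

ad_maxpool2 <- function(x) {
  xv <- x$value
  d <- dim(xv); H <- d[1]; W <- d[2]
  stopifnot(H %% 2L == 0L, W %% 2L == 0L)
  ri <- seq(1L, H, 2L); ci <- seq(1L, W, 2L)
  s11 <- xv[ri, ci, , , drop = FALSE]
  s21 <- xv[ri + 1L, ci, , , drop = FALSE]
  s12 <- xv[ri, ci + 1L, , , drop = FALSE]
  s22 <- xv[ri + 1L, ci + 1L, , , drop = FALSE]
  m <- pmax(s11, s21, s12, s22)
  e11 <- s11 == m
  e21 <- s21 == m & !e11
  e12 <- s12 == m & !e11 & !e21
  e22 <- !e11 & !e21 & !e12
  ad_tensor(m, parents = list(x), backward = function(node) {
    g <- node$grad
    gx <- array(0, dim(xv))
    gx[ri, ci, , ] <- g * e11
    gx[ri + 1L, ci, , ] <- g * e21
    gx[ri, ci + 1L, , ] <- g * e12
    gx[ri + 1L, ci + 1L, , ] <- g * e22
    ad_accum(x, gx)
  })
}

# Global average / max pooling: H x W x N x C -> C x N.
ad_global_avgpool <- function(x) {
  xv <- x$value
  d <- dim(xv); H <- d[1]; W <- d[2]; N <- d[3]; C <- d[4]
  v <- colMeans(.reshape(xv, c(H * W, N * C)))  # ordered (n, c)
  ad_tensor(t(matrix(v, N, C)), parents = list(x), backward = function(node) {
    vnc <- as.vector(t(node$grad))  # back to (n, c) order
    ad_accum(x, array(rep(vnc, each = H * W) / (H * W), c(H, W, N, C)))
  })
}

ad_global_maxpool <- function(x) {
  xv <- x$value
  d <- dim(xv); H <- d[1]; W <- d[2]; N <- d[3]; C <- d[4]
  m <- .reshape(xv, c(H * W, N * C))
  idx <- max.col(t(m), ties.method = "first")
  v <- m[cbind(idx, seq_len(N * C))]
  ad_tensor(t(matrix(v, N, C)), parents = list(x), backward = function(node) {
    vnc <- as.vector(t(node$grad))
    gx <- numeric(H * W * N * C)
    gx[(seq_len(N * C) - 1L) * (H * W) + idx] <- vnc
    ad_accum(x, array(gx, c(H, W, N, C)))
  })
}

# Channel-wise mean / max maps: H x W x N x C -> H x W x N x 1.
ad_channel_mean <- function(x) {
  xv <- x$value
  d <- dim(xv); H <- d[1]; W <- d[2]; N <- d[3]; C <- d[4]
  yv <- .reshape(rowMeans(.reshape(xv, c(H * W * N, C))), c(H, W, N, 1L))
  ad_tensor(yv, parents = list(x), backward = function(node) {
    ad_accum(x, array(rep(as.vector(node$grad), times = C) / C,
                      c(H, W, N, C)))
  })
}

ad_channel_max <- function(x) {
  xv <- x$value
  d <- dim(xv); H <- d[1]; W <- d[2]; N <- d[3]; C <- d[4]
  m <- .reshape(xv, c(H * W * N, C))
  idx <- max.col(m, ties.method = "first")
  rows <- seq_len(H * W * N)
  yv <- .reshape(m[cbind(rows, idx)], c(H, W, N, 1L))
  ad_tensor(yv, parents = list(x), backward = function(node) {
    gm <- matrix(0, H * W * N, C)
    gm[cbind(rows, idx)] <- as.vector(node$grad)
    ad_accum(x, .reshape(gm, c(H, W, N, C)))
  })
}

## ---- broadcast scaling and concatenation ----------------------------------

# x: H x W x N x C scaled by per-channel weights s: C x N.
ad_channel_scale <- function(x, s) {
  xv <- x$value; sv <- s$value
  d <- dim(xv); H <- d[1]; W <- d[2]; N <- d[3]; C <- d[4]
  sb <- array(rep(as.vector(t(sv)), each = H * W), c(H, W, N, C))
  ad_tensor(xv * sb, parents = list(x, s), backward = function(node) {
    g <- node$grad
    ad_accum(x, g * sb)
    if (s$requires_grad) {
      gs <- colSums(.reshape(g * xv, c(H * W, N * C)))
      ad_accum(s, t(matrix(gs, N, C)))
    }
  })
}

# x scaled by a spatial map s: H x W x N x 1 (broadcast over channels).
ad_spatial_scale <- function(x, s) {
  xv <- x$value; sv <- s$value
  d <- dim(xv); H <- d[1]; W <- d[2]; N <- d[3]; C <- d[4]
  sb <- array(rep(as.vector(sv), times = C), c(H, W, N, C))
  ad_tensor(xv * sb, parents = list(x, s), backward = function(node) {
    g <- node$grad
    ad_accum(x, g * sb)
    if (s$requires_grad) {
      gs <- rowSums(.reshape(g * xv, c(H * W * N, C)))
      ad_accum(s, .reshape(gs, c(H, W, N, 1L)))
    }
  })
}

ad_concat_channels <- function(a, b) {
  av <- a$value; bv <- b$value
  da <- dim(av); db <- dim(bv)
  stopifnot(all(da[1:3] == db[1:3]))
  yv <- array(0, c(da[1], da[2], da[3], da[4] + db[4]))
  yv[, , , seq_len(da[4])] <- av
  yv[, , , da[4] + seq_len(db[4])] <- bv
  ad_tensor(yv, parents = list(a, b), backward = function(node) {
    g <- node$grad
    ad_accum(a, g[, , , seq_len(da[4]), drop = FALSE])
    ad_accum(b, g[, , , da[4] + seq_len(db[4]), drop = FALSE])
  })
}

## ---- dense and batch normalization ----------------------------------------

# x: in x N, w: out x in, b: length out.
ad_dense <- function(x, w, b = NULL) {
  xv <- x$value; wv <- w$value
  yv <- wv %*% xv
  if (!is.null(b)) yv <- yv + as.vector(b$value)
  parents <- c(list(x, w), if (!is.null(b)) list(b))
  ad_tensor(yv, parents = parents, backward = function(node) {
    g <- node$grad
    if (w$requires_grad) ad_accum(w, g %*% t(xv))
    if (!is.null(b) && b$requires_grad) ad_accum(b, rowSums(g))
    if (x$requires_grad) ad_accum(x, crossprod(wv, g))
  })
}

# Batch normalization over (H, W, N) per channel. `state` is an environment
# with running_mean / running_var, updated in training mode and used
# verbatim in inference mode (stored-statistics mode, used by
# single-sample oracles).
ad_batchnorm2d <- function(x, gamma, beta, state, training = TRUE,
                           momentum = 0.1, eps = 1e-5) {
  xv <- x$value
  d <- dim(xv); H <- d[1]; W <- d[2]; N <- d[3]; C <- d[4]
  xm <- .reshape(xv, c(H * W * N, C))
  if (training) {
    mu <- colMeans(xm)
    va <- colMeans(xm^2) - mu^2
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var + momentum * va
  } else {
    mu <- state$running_mean
    va <- state$running_var
  }
  istd <- 1 / sqrt(va + eps)
  gv0 <- as.vector(gamma$value)
  ym <- colscale_shift(xm, gv0 * istd,
                       as.vector(beta$value) - mu * gv0 * istd)
  ad_tensor(.reshape(ym, c(H, W, N, C)), parents = list(x, gamma, beta),
            backward = function(node) {
    gm <- .reshape(node$grad, c(H * W * N, C))
    xhat <- colscale_shift(xm, istd, -mu * istd)
    if (gamma$requires_grad) ad_accum(gamma, colSums(gm * xhat))
    if (beta$requires_grad) ad_accum(beta, colSums(gm))
    if (x$requires_grad) {
      gv <- as.vector(gamma$value)
      if (training) {
        gx <- colscale(gm - colscale_shift(xhat, colMeans(gm * xhat),
                                           colMeans(gm)),
                       gv * istd)
      } else {
        gx <- colscale(gm, gv * istd)
      }
      ad_accum(x, .reshape(gx, c(H, W, N, C)))
    }
  })
}

# 1-D batch normalization for d x N descriptors (selective-kernel fuse
# stage). Falls back to stored statistics for single-sample inputs.
ad_batchnorm1d <- function(x, gamma, beta, state, training = TRUE,
                           momentum = 0.1, eps = 1e-5) {
  xv <- x$value
  N <- ncol(xv)
  if (training && N > 1L) {
    mu <- rowMeans(xv)
    va <- rowMeans(xv^2) - mu^2
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var + momentum * va
    train_stats <- TRUE
  } else {
    mu <- state$running_mean
    va <- state$running_var
    train_stats <- FALSE
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- (xv - mu) * istd
  yv <- xhat * as.vector(gamma$value) + as.vector(beta$value)
  ad_tensor(yv, parents = list(x, gamma, beta), backward = function(node) {
    g <- node$grad
    if (gamma$requires_grad) ad_accum(gamma, rowSums(g * xhat))
    if (beta$requires_grad) ad_accum(beta, rowSums(g))
    if (x$requires_grad) {
      gv <- as.vector(gamma$value)
      if (train_stats) {
        gx <- (g - rowMeans(g) - xhat * rowMeans(g * xhat)) * gv * istd
      } else {
        gx <- g * gv * istd
      }
      ad_accum(x, gx)
    }
  })
}

## ---- losses ----------------------------------------------------------------

# Fused softmax cross-entropy + soft multi-class Dice loss with an analytic
# gradient in the logits. logits: H x W x N x K; target: H x W x N integer
# labels in 0..K-1. Returns a scalar node.
ad_ce_dice_loss <- function(logits, target, w_ce = 0.5, w_dice = 0.5,
                            smooth = 1e-6) {
  zv <- logits$value
  d <- dim(zv); H <- d[1]; W <- d[2]; N <- d[3]; K <- d[4]
  tv <- as.integer(target)
  if (any(tv < 0L | tv >= K)) stop("target labels must lie in [0, K)")
  npix <- H * W * N
  zm <- .reshape(zv, c(npix, K))
  rowmax <- do.call(pmax, lapply(seq_len(K), function(k) zm[, k]))
  zm <- zm - rowmax
  ez <- exp(zm)
  p <- ez / rowSums(ez)
  tmat <- matrix(0, npix, K)
  tmat[cbind(seq_len(npix), tv + 1L)] <- 1
  ce <- -mean(log(pmax(p[cbind(seq_len(npix), tv + 1L)], 1e-12)))
  num <- 2 * colSums(p * tmat) + smooth
  den <- colSums(p) + colSums(tmat) + smooth
  dice <- num / den
  loss <- w_ce * ce + w_dice * (1 - mean(dice))
  ad_tensor(loss, parents = list(logits), backward = function(node) {
    gout <- as.numeric(node$grad)
    gce <- (p - tmat) / npix
    # dDice_k/dp_k(pixel) = (2*t - dice_k) / den_k ; loss term is
    # -mean_k dice_k
    gdice_p <- -(2 * tmat - rep(dice, each = npix)) *
      rep(1 / den, each = npix) / K
    gp <- w_dice * gdice_p
    # chain through softmax: gz = p * (gp - rowSums(gp * p))
    gz <- p * (gp - rowSums(gp * p))
    gz <- gz + w_ce * gce
    gz <- gz * gout
    ad_accum(logits, .reshape(gz, c(H, W, N, K)))
  })
}
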