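# Independent scalar oracles used across the suite. Everything here is
# written with plain nested loops (or set arithmetic), deliberately
# avoiding the package's vectorized code paths, so agreement between the
# two is evidence of correctness rather than shared bugs.

sigmoid_s <- function(x) 1 / (1 + exp(-x))

# Direct same-padding convolution by quadruple loop.
# x: H x W x Cin, w: kh x kw x Cin x Cout, b: length Cout.
conv2d_loop <- function(x, w, b = NULL) {
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]
  kh <- dim(w)[1]; kw <- dim(w)[2]; Cout <- dim(w)[4]
  ph <- (kh - 1) %/% 2; pw <- (kw - 1) %/% 2
  y <- array(0, c(H, W, Cout))
  for (o in seq_len(Cout)) for (r in seq_len(H)) for (cc in seq_len(W)) {
    acc <- if (is.null(b)) 0 else b[o]
    for (i in seq_len(kh)) for (j in seq_len(kw)) for (ci in seq_len(Cin)) {
      rr <- r + i - 1 - ph; cj <- cc + j - 1 - pw
      if (rr >= 1 && rr <= H && cj >= 1 && cj <= W)
        acc <- acc + x[rr, cj, ci] * w[i, j, ci, o]
    }
    y[r, cc, o] <- acc
  }
  y
}

# Channel attention by scalar loops: pooled descriptors, shared MLP
# (W1 relu(W0 v)), summed, sigmoid.
channel_attention_loop <- function(f, w0, w1) {
  C <- dim(f)[3]
  hid <- nrow(w0)
  pool <- function(v) {
    out <- numeric(C)
    for (c in seq_len(C)) out[c] <- v(f[, , c])
    out
  }
  mlp <- function(v) {
    h <- numeric(hid)
    for (a in seq_len(hid)) {
      s <- 0
      for (c in seq_len(C)) s <- s + w0[a, c] * v[c]
      h[a] <- max(s, 0)
    }
    o <- numeric(C)
    for (c in seq_len(C)) {
      s <- 0
      for (a in seq_len(hid)) s <- s + w1[c, a] * h[a]
      o[c] <- s
    }
    o
  }
  sigmoid_s(mlp(pool(mean)) + mlp(pool(max)))
}

# Spatial attention by scalar loops: channel mean/max maps, direct
# convolution, sigmoid.
spatial_attention_loop <- function(f, kernel, bias = 0) {
  H <- dim(f)[1]; W <- dim(f)[2]
  maps <- array(0, c(H, W, 2))
  for (r in seq_len(H)) for (cc in seq_len(W)) {
    maps[r, cc, 1] <- mean(f[r, cc, ])
    maps[r, cc, 2] <- max(f[r, cc, ])
  }
  sigmoid_s(conv2d_loop(maps, kernel, bias)[, , 1])
}

cbam_loop <- function(f, params) {
  H <- dim(f)[1]; W <- dim(f)[2]; C <- dim(f)[3]
  mc <- channel_attention_loop(f, params$ca$w0, params$ca$w1)
  f1 <- f
  for (c in seq_len(C)) f1[, , c] <- f[, , c] * mc[c]
  ms <- spatial_attention_loop(f1, params$spatial_kernel,
                               if (is.null(params$spatial_bias)) 0
                               else params$spatial_bias)
  f2 <- f1
  for (c in seq_len(C)) f2[, , c] <- f1[, , c] * ms
  f2
}

# Selective-kernel attention, equation by equation, with stored-statistics
# batch normalization.
sk_attention_loop <- function(x, p) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  u1 <- conv2d_loop(x, p$w_branch1, p$b_branch1)
  u2 <- conv2d_loop(x, p$w_branch2, p$b_branch2)
  u <- u1 + u2
  s <- numeric(C)
  for (c in seq_len(C)) s[c] <- mean(u[, , c])
  d <- nrow(p$w_fuse)
  z <- numeric(d)
  for (a in seq_len(d)) {
    acc <- 0
    for (c in seq_len(C)) acc <- acc + p$w_fuse[a, c] * s[c]
    bn <- (acc - p$bn_mean[a]) / sqrt(p$bn_var[a] + 1e-5) *
      p$bn_gamma[a] + p$bn_beta[a]
    z[a] <- max(bn, 0)
  }
  v <- array(0, c(H, W, C))
  ab <- matrix(0, C, 2)
  for (c in seq_len(C)) {
    l1 <- sum(p$w_select1[c, ] * z)
    l2 <- sum(p$w_select2[c, ] * z)
    a_w <- exp(l1) / (exp(l1) + exp(l2))
    ab[c, ] <- c(a_w, 1 - a_w)
    v[, , c] <- a_w * u1[, , c] + (1 - a_w) * u2[, , c]
  }
  attr(v, "branch_weights") <- ab
  v
}

# Random parameter draws for the attention operators.
random_ca_params <- function(C, r = 2) {
  ca_params(w0 = matrix(rnorm(C / r * C), C / r, C),
            w1 = matrix(rnorm(C * C / r), C, C / r), reduction = r)
}

random_cbam_params <- function(C, r = 2, k = 3) {
  list(ca = random_ca_params(C, r),
       spatial_kernel = array(rnorm(k * k * 2), c(k, k, 2, 1)),
       spatial_bias = rnorm(1))
}

random_sk_params <- function(C, d = 2, k1 = 3, k2 = 5) {
  sk_params(w_branch1 = array(rnorm(k1 * k1 * C * C, sd = 0.3),
                              c(k1, k1, C, C)),
            w_branch2 = array(rnorm(k2 * k2 * C * C, sd = 0.3),
                              c(k2, k2, C, C)),
            b_branch1 = rnorm(C), b_branch2 = rnorm(C),
            w_fuse = matrix(rnorm(d * C), d, C),
            bn_gamma = runif(d, 0.5, 1.5), bn_beta = rnorm(d, 0, 0.2),
            bn_mean = rnorm(d, 0, 0.2), bn_var = runif(d, 0.5, 1.5),
            w_select1 = matrix(rnorm(C * d), C, d),
            w_select2 = matrix(rnorm(C * d), C, d))
}

# Strict-interior membership test for convex polygons: the point must be
# strictly on the same side of every (counter-clockwise) edge.
convex_pip_oracle <- function(px, py, xs, ys) {
  n <- length(xs)
  # orient counter-clockwise via the shoelace sign
  area2 <- sum(xs * ys[c(2:n, 1)] - xs[c(2:n, 1)] * ys)
  if (area2 < 0) { xs <- rev(xs); ys <- rev(ys) }
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cross <- (xs[j] - xs[i]) * (py - ys[i]) - (ys[j] - ys[i]) * (px - xs[i])
    if (cross <= 0) return(FALSE)
  }
  TRUE
}

# Random convex polygon: points on a noisy circle, ordered by angle.
random_convex_polygon <- function(cx, cy, r, n = 6) {
  th <- sort(runif(n, 0, 2 * pi))
  list(x = cx + r * cos(th), y = cy + r * sin(th))
}

# Binary morphology by set arithmetic over explicit pixel sets.
dilate_set <- function(bin, se) {
  H <- nrow(bin); W <- ncol(bin)
  r <- (nrow(se) - 1) %/% 2
  out <- matrix(0L, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (bin[i, j] == 1L) {
      for (di in -r:r) for (dj in -r:r) {
        if (se[di + r + 1, dj + r + 1] == 1) {
          ii <- i + di; jj <- j + dj
          if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) out[ii, jj] <- 1L
        }
      }
    }
  }
  out
}

erode_set <- function(bin, se) {
  H <- nrow(bin); W <- ncol(bin)
  r <- (nrow(se) - 1) %/% 2
  out <- matrix(0L, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    keep <- TRUE
    for (di in -r:r) for (dj in -r:r) {
      if (se[di + r + 1, dj + r + 1] == 1) {
        ii <- i + di; jj <- j + dj
        inside <- ii >= 1 && ii <= H && jj >= 1 && jj <= W
        if (!inside || bin[ii, jj] != 1L) { keep <- FALSE; break }
      }
      if (!keep) break
    }
    if (keep) out[i, j] <- 1L
  }
  out
}

# Closing/opening on the infinite plane (everything outside the canvas is
# background, but dilation mass beyond the border is tracked): operate on
# a zero-padded canvas and crop back.
.with_pad <- function(bin, se, f) {
  r <- (nrow(se) - 1) %/% 2
  p <- 2 * r
  H <- nrow(bin); W <- ncol(bin)
  mp <- matrix(0L, H + 2 * p, W + 2 * p)
  mp[p + seq_len(H), p + seq_len(W)] <- bin
  f(mp, se)[p + seq_len(H), p + seq_len(W)]
}

closing_set <- function(bin, se)
  .with_pad(bin, se, function(m, k) erode_set(dilate_set(m, k), k))
opening_set <- function(bin, se)
  .with_pad(bin, se, function(m, k) dilate_set(erode_set(m, k), k))

# Per-pixel scalar membership oracle for the synthetic shapes.
carcass_membership_oracle <- function(shapes, H, W) {
  lab <- matrix(0L, H, W)
  inside_ellipse <- function(x, y, e)
    ((x - e$cx) / e$a)^2 + ((y - e$cy) / e$b)^2 < 1
  inside_circle <- function(x, y, h)
    (x - h$x)^2 + (y - h$y)^2 < h$r^2
  inside_capsule <- function(x, y, lg) {
    vx <- lg$x1 - lg$x0; vy <- lg$y1 - lg$y0
    tt <- ((x - lg$x0) * vx + (y - lg$y0) * vy) / (vx^2 + vy^2)
    tt <- min(1, max(0, tt))
    (x - lg$x0 - tt * vx)^2 + (y - lg$y0 - tt * vy)^2 < (lg$w / 2)^2
  }
  for (r in seq_len(H)) for (cc in seq_len(W)) {
    x <- cc - 0.5; y <- r - 0.5
    if (inside_ellipse(x, y, shapes$torso)) lab[r, cc] <- 1L
    for (lg in shapes$legs) if (inside_capsule(x, y, lg)) lab[r, cc] <- 3L
    if (inside_circle(x, y, shapes$head)) lab[r, cc] <- 2L
  }
  lab
}

# Confusion counts by per-pixel loop.
confusion_loop <- function(pred, gt, K) {
  out <- matrix(0, K, 4, dimnames = list(0:(K - 1), c("TP", "FP", "FN", "TN")))
  for (k in 0:(K - 1)) {
    for (i in seq_along(pred)) {
      p <- pred[i] == k; g <- gt[i] == k
      if (p && g) out[k + 1, "TP"] <- out[k + 1, "TP"] + 1
      else if (p && !g) out[k + 1, "FP"] <- out[k + 1, "FP"] + 1
      else if (!p && g) out[k + 1, "FN"] <- out[k + 1, "FN"] + 1
      else out[k + 1, "TN"] <- out[k + 1, "TN"] + 1
    }
  }
  out
}

# Central finite-difference gradient of a scalar function.
numeric_grad <- function(fn, x, eps = 1e-5) {
  g <- array(0, dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (fn(xp) - fn(xm)) / (2 * eps)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Tiny synthetic samples on a 32 px canvas for fast training-property
# tests.
tiny_samples <- function(n, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    sp <- carcass_spec(carcass_id = sprintf("T%03d", i),
                       s = runif(1, 0.9, 1.05), torso_a = 6.2, torso_b = 4,
                       head_r = 2, leg_len = 7, leg_w = 2.4,
                       views = "ventral", sigma_pos = 0.3, sigma_tex = 8,
                       px_per_cm = 1, canvas = c(32, 32))
    car <- generate_carcass(sp, seed = seed * 1000 + i, replicates = 1)
    car$ventral$replicates[[1]]
  })
}
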