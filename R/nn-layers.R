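# Parameter store and layer constructors for the segmentation network.
# A "store" collects named parameter tensors (for the optimizer and the
# parameter-count oracle) and batch-norm state environments (for running
# statistics, serialized with checkpoints). Layer constructors return
# forward closures over autodiff nodes; `training` toggles batch-norm mode.

new_param_store <- function() {
  e <- new.env(parent = emptyenv())
  e$params <- list()
  e$states <- list()
  e
}

store_add_param <- function(store, name, value) {
  if (!is.null(store$params[[name]])) stop("duplicate parameter name: ", name)
  p <- ad_param(value)
  store$params[[name]] <- p
  p
}

store_add_state <- function(store, name, C) {
  s <- new.env(parent = emptyenv())
  s$running_mean <- numeric(C)
  s$running_var <- rep(1, C)
  store$states[[name]] <- s
  s
}

# He-normal initialization for ReLU stacks.
init_conv_w <- function(kh, kw, cin, cout) {
  array(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}

init_dense_w <- function(nout, nin) {
  matrix(stats::rnorm(nout * nin, sd = sqrt(2 / nin)), nout, nin)
}

layer_conv <- function(store, name, kh, kw, cin, cout, bias = TRUE) {
  w <- store_add_param(store, paste0(name, ".w"), init_conv_w(kh, kw, cin, cout))
  b <- if (bias) store_add_param(store, paste0(name, ".b"), numeric(cout)) else NULL
  idx_cache <- new.env(parent = emptyenv())
  function(x) ad_conv2d(x, w, b, cache = idx_cache)
}

layer_conv_transpose <- function(store, name, cin, cout) {
  w <- store_add_param(store, paste0(name, ".w"),
                       array(stats::rnorm(4 * cin * cout, sd = sqrt(2 / (4 * cin))),
                             c(2, 2, cin, cout)))
  b <- store_add_param(store, paste0(name, ".b"), numeric(cout))
  function(x) ad_conv_transpose2(x, w, b)
}

layer_bn2d <- function(store, name, C) {
  gamma <- store_add_param(store, paste0(name, ".gamma"), rep(1, C))
  beta <- store_add_param(store, paste0(name, ".beta"), numeric(C))
  state <- store_add_state(store, name, C)
  function(x, training) ad_batchnorm2d(x, gamma, beta, state, training)
}

layer_bn1d <- function(store, name, D) {
  gamma <- store_add_param(store, paste0(name, ".gamma"), rep(1, D))
  beta <- store_add_param(store, paste0(name, ".beta"), numeric(D))
  state <- store_add_state(store, name, D)
  function(x, training) ad_batchnorm1d(x, gamma, beta, state, training)
}

layer_dense <- function(store, name, nout, nin, bias = TRUE) {
  w <- store_add_param(store, paste0(name, ".w"), init_dense_w(nout, nin))
  b <- if (bias) store_add_param(store, paste0(name, ".b"), numeric(nout)) else NULL
  function(x) ad_dense(x, w, b)
}

# Recurrent convolutional layer: a feed-forward 3x3 convolution whose output
# is refined t times by a recurrent 3x3 convolution on the evolving state:
#   y_0 = relu(a),  y_s = relu(a + BN(conv_rec(y_{s-1}))),  a = BN(conv_ff(x)).
layer_rcl <- function(store, name, cin, cout) {
  conv_ff <- layer_conv(store, paste0(name, ".ff"), 3, 3, cin, cout)
  bn_ff <- layer_bn2d(store, paste0(name, ".ff.bn"), cout)
  conv_rec <- layer_conv(store, paste0(name, ".rec"), 3, 3, cout, cout)
  bn_rec <- layer_bn2d(store, paste0(name, ".rec.bn"), cout)
  function(x, t, training) {
    a <- bn_ff(conv_ff(x), training)
    y <- ad_relu(a)
    if (t > 0) for (s in seq_len(t)) {
      y <- ad_relu(ad_add(a, bn_rec(conv_rec(y), training)))
    }
    y
  }
}

# Recurrent-residual block: two stacked recurrent convolutional layers plus
# a shortcut (1x1 convolution when the channel count changes).
layer_rr_block <- function(store, name, cin, cout) {
  rcl1 <- layer_rcl(store, paste0(name, ".rcl1"), cin, cout)
  rcl2 <- layer_rcl(store, paste0(name, ".rcl2"), cout, cout)
  shortcut <- if (cin != cout) {
    layer_conv(store, paste0(name, ".shortcut"), 1, 1, cin, cout)
  } else {
    identity
  }
  function(x, t, training) {
    h <- rcl2(rcl1(x, t, training), t, training)
    ad_add(h, shortcut(x))
  }
}

# CBAM: channel attention (shared two-layer MLP over average- and max-pooled
# channel descriptors, sigmoid gate), then spatial attention (7x7 convolution
# over the channel-wise mean/max maps, sigmoid gate).
layer_cbam <- function(store, name, C, reduction = 16, spatial_kernel = 7) {
  if (C %% reduction != 0L)
    stop("channel attention reduction ratio ", reduction,
         " does not divide C = ", C)
  hidden <- C %/% reduction
  fc0 <- layer_dense(store, paste0(name, ".fc0"), hidden, C, bias = FALSE)
  fc1 <- layer_dense(store, paste0(name, ".fc1"), C, hidden, bias = FALSE)
  conv_sp <- layer_conv(store, paste0(name, ".spconv"),
                        spatial_kernel, spatial_kernel, 2, 1)
  function(x, training) {
    mlp <- function(v) fc1(ad_relu(fc0(v)))
    mc <- ad_sigmoid(ad_add(mlp(ad_global_avgpool(x)),
                            mlp(ad_global_maxpool(x))))
    x1 <- ad_channel_scale(x, mc)
    sp <- ad_concat_channels(ad_channel_mean(x1), ad_channel_max(x1))
    ms <- ad_sigmoid(conv_sp(sp))
    ad_spatial_scale(x1, ms)
  }
}

# Selective-kernel attention with exactly two branches: split (3x3 and 5x5
# convolutions), fuse (sum, global average pool, bottleneck FC with BN+ReLU),
# select (per-channel softmax over branch logits; weights sum to one).
layer_sk <- function(store, name, C, kernels = c(3, 5), reduction = 16,
                     d_min = 4) {
  if (length(kernels) != 2L)
    stop("selective-kernel attention supports exactly two branches")
  d <- max(C %/% reduction, d_min)
  conv1 <- layer_conv(store, paste0(name, ".branch1"), kernels[1], kernels[1], C, C)
  conv2 <- layer_conv(store, paste0(name, ".branch2"), kernels[2], kernels[2], C, C)
  fuse <- layer_dense(store, paste0(name, ".fuse"), d, C, bias = FALSE)
  bn <- layer_bn1d(store, paste0(name, ".fuse.bn"), d)
  sel1 <- layer_dense(store, paste0(name, ".sel1"), C, d, bias = FALSE)
  sel2 <- layer_dense(store, paste0(name, ".sel2"), C, d, bias = FALSE)
  function(x, training) {
    u1 <- conv1(x)
    u2 <- conv2(x)
    u <- ad_add(u1, u2)
    s <- ad_global_avgpool(u)
    z <- ad_relu(bn(fuse(s), training))
    # two-way softmax: a = exp(l1)/(exp(l1)+exp(l2)) = sigmoid(l1 - l2)
    a <- ad_sigmoid(ad_sub(sel1(z), sel2(z)))
    b <- ad_one_minus(a)
    ad_add(ad_channel_scale(u1, a), ad_channel_scale(u2, b))
  }
}
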