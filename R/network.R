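# AR2U-AttnNet assembly: encoder-decoder with recurrent-residual blocks,
# selective-kernel attention after each encoder block, CBAM on skip
# connections, and a 1x1 K-class head.

#' Segmentation network configuration
#'
#' @param depth Number of encoder levels (the last is the bottleneck).
#' @param base_width Channels at the first level; doubled per level.
#' @param recurrence Recurrence steps `t` of each recurrent convolutional
#'   layer (`t = 0` reduces to a plain double convolution).
#' @param n_classes Number of output classes `K` (background included).
#' @param in_channels Input channels (3 for RGB).
#' @param use_cbam Apply CBAM to each skip connection.
#' @param use_sk Apply selective-kernel attention after each encoder block.
#' @param sk_kernels Two odd branch kernel sizes.
#' @param ca_reduction,sk_reduction Reduction ratios of the attention
#'   bottlenecks (capped at the channel count of small configurations).
#' @param input_size Expected input size in pixels; must be divisible by
#'   `2^(depth - 1)`.
#' @return An object of class `net_config`.
#' @export
net_config <- function(depth = 5, base_width = 64, recurrence = 2,
                       n_classes = 4, in_channels = 3, use_cbam = TRUE,
                       use_sk = TRUE, sk_kernels = c(3, 5),
                       ca_reduction = 16, sk_reduction = 16,
                       input_size = 640) {
  stopifnot(depth >= 2, base_width >= 1, recurrence >= 0, n_classes >= 2)
  if (any(input_size %% 2^(depth - 1) != 0))
    stop("input size ", paste(input_size, collapse = "x"),
         " is not divisible by 2^(depth-1) = ", 2^(depth - 1))
  structure(list(depth = depth, base_width = base_width,
                 recurrence = recurrence, n_classes = n_classes,
                 in_channels = in_channels, use_cbam = use_cbam,
                 use_sk = use_sk, sk_kernels = sk_kernels,
                 ca_reduction = ca_reduction, sk_reduction = sk_reduction,
                 input_size = input_size),
            class = "net_config")
}

#' Build the segmentation model
#'
#' Assembles the attention-enhanced recurrent-residual U-Net: each encoder
#' level is a recurrent-residual block (optionally followed by
#' selective-kernel attention), levels are linked by 2x2 max pooling with
#' channel doubling, skip connections are refined by CBAM before decoder
#' concatenation, and the decoder upsamples with 2x2 transposed
#' convolutions. A 1x1 convolution emits `n_classes` logits per pixel.
#'
#' @param config A [net_config()] object.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `ar2u_model` with elements `store` (parameter
#'   tensors and batch-norm state), `config` and `forward(x, training)`.
#' @export
build_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "net_config"))
  set.seed(seed)
  store <- new_param_store()
  D <- config$depth
  t_rec <- config$recurrence
  ch <- config$base_width * 2^(seq_len(D) - 1L)
  cap <- function(r, C) max(1L, min(r, C))

  enc <- vector("list", D)
  sk <- vector("list", D)
  prev <- config$in_channels
  for (lev in seq_len(D)) {
    enc[[lev]] <- layer_rr_block(store, sprintf("enc%d", lev), prev, ch[lev])
    if (config$use_sk)
      sk[[lev]] <- layer_sk(store, sprintf("sk%d", lev), ch[lev],
                            kernels = config$sk_kernels,
                            reduction = cap(config$sk_reduction, ch[lev]))
    prev <- ch[lev]
  }
  cb <- vector("list", D - 1L)
  up <- vector("list", D - 1L)
  dec <- vector("list", D - 1L)
  for (lev in seq_len(D - 1L)) {
    if (config$use_cbam)
      cb[[lev]] <- layer_cbam(store, sprintf("cbam%d", lev), ch[lev],
                              reduction = cap(config$ca_reduction, ch[lev]))
    up[[lev]] <- layer_conv_transpose(store, sprintf("up%d", lev),
                                      ch[lev + 1L], ch[lev])
    dec[[lev]] <- layer_rr_block(store, sprintf("dec%d", lev),
                                 2L * ch[lev], ch[lev])
  }
  head <- layer_conv(store, "head", 1, 1, ch[1], config$n_classes)

  forward <- function(x, training = FALSE) {
    if (!is_ad(x)) x <- ad_const(x)
    d <- dim(x$value)
    if (d[4] != config$in_channels)
      stop("input has ", d[4], " channels; model expects ",
           config$in_channels)
    if (any(c(d[1], d[2]) %% 2^(D - 1L) != 0))
      stop("input size ", d[1], "x", d[2],
           " is not divisible by 2^(depth-1) = ", 2^(D - 1L))
    skips <- vector("list", D - 1L)
    h <- x
    for (lev in seq_len(D)) {
      h <- enc[[lev]](h, t_rec, training)
      if (config$use_sk) h <- sk[[lev]](h, training)
      if (lev < D) {
        skips[[lev]] <- h
        h <- ad_maxpool2(h)
      }
    }
    for (lev in rev(seq_len(D - 1L))) {
      h <- up[[lev]](h)
      s <- skips[[lev]]
      if (config$use_cbam) s <- cb[[lev]](s, training)
      h <- dec[[lev]](ad_concat_channels(s, h), t_rec, training)
    }
    head(h)
  }

  structure(list(store = store, config = config, seed = seed,
                 forward = forward),
            class = "ar2u_model")
}

#' Count trainable parameters
#'
#' @param model An `ar2u_model`.
#' @return Total number of trainable scalar parameters.
#' @export
count_params <- function(model) {
  sum(vapply(model$store$params, function(p) length(p$value), numeric(1)))
}

#' Predict a label mask for one image
#'
#' Runs the network in inference mode (stored batch-norm statistics) and
#' takes the per-pixel argmax over the class logits.
#'
#' @param model An `ar2u_model`.
#' @param image `H x W x 3` array with intensities in 0..255 (a `ViewImage`
#'   pixel array), or a list of such arrays (segmented as one batch).
#' @param class_map Named integer label set for the returned mask.
#' @return A [label_mask()] (or a list of masks for a list input).
#' @export
predict_mask <- function(model, image, class_map = default_class_map()) {
  single <- !is.list(image)
  imgs <- if (single) list(image) else image
  d0 <- dim(imgs[[1]])
  x <- array(0, c(d0[1], d0[2], length(imgs), d0[3]))
  for (n in seq_along(imgs)) x[, , n, ] <- imgs[[n]] / 255
  logits <- model$forward(ad_const(x), training = FALSE)$value
  d <- dim(logits)
  masks <- lapply(seq_len(d[3]), function(n) {
    lm <- matrix(logits[, , n, ], d[1] * d[2], d[4])
    label_mask(matrix(max.col(lm, ties.method = "first") - 1L, d[1], d[2]),
               class_map)
  })
  if (single) masks[[1]] else masks
}

#' Standalone recurrent-residual block
#'
#' Value-level evaluation of one recurrent-residual block with
#' caller-supplied convolution weights (no normalization), for use as an
#' oracle-testable operator. `t = 0` reduces each recurrent layer to its
#' feed-forward convolution.
#'
#' @param x Input feature map, `H x W x C` array.
#' @param params List with per-layer elements `ff_w`, `ff_b`, `rec_w`,
#'   `rec_b` for `rcl1` and `rcl2`, and optional `shortcut_w`, `shortcut_b`
#'   (1x1) when the channel count changes.
#' @param t Recurrence steps, non-negative integer.
#' @return Output feature map array.
#' @export
recurrent_residual_block <- function(x, params, t = 2) {
  if (t < 0) stop("recurrence t must be non-negative")
  xa <- .as_hw1c(x)
  run_rcl <- function(inp, p) {
    a <- ad_conv2d(inp, ad_const(p$ff_w), ad_const(p$ff_b))
    y <- ad_relu(a)
    if (t > 0) for (s in seq_len(t)) {
      y <- ad_relu(ad_add(a, ad_conv2d(y, ad_const(p$rec_w),
                                       ad_const(p$rec_b))))
    }
    y
  }
  xn <- ad_const(xa)
  h <- run_rcl(run_rcl(xn, params$rcl1), params$rcl2)
  sc <- if (!is.null(params$shortcut_w)) {
    ad_conv2d(xn, ad_const(params$shortcut_w), ad_const(params$shortcut_b))
  } else {
    xn
  }
  out <- ad_add(h, sc)
  d <- dim(out$value)
  array(out$value, c(d[1], d[2], d[4]))
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores all parameter values, batch-norm running
#' statistics, the full network configuration and the initialization seed.
#'
#' @param model An `ar2u_model`.
#' @param path File path.
#' @param meta Optional named list of extra metadata (e.g. epoch).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns a rebuilt `ar2u_model`.
#' @export
save_checkpoint <- function(model, path, meta = list()) {
  ck <- list(
    config = model$config,
    seed = model$seed,
    params = lapply(model$store$params, function(p) p$value),
    states = lapply(model$store$states, function(s)
      list(running_mean = s$running_mean, running_var = s$running_var)),
    meta = meta
  )
  saveRDS(ck, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$config, seed = ck$seed)
  for (nm in names(ck$params)) model$store$params[[nm]]$value <- ck$params[[nm]]
  for (nm in names(ck$states)) {
    model$store$states[[nm]]$running_mean <- ck$states[[nm]]$running_mean
    model$store$states[[nm]]$running_var <- ck$states[[nm]]$running_var
  }
  model
}
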