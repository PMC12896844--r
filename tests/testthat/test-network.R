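# Network assembly: shape contract, analytic parameter count, ablation
# ordering, recurrent-residual block semantics, and inference
# determinism.

# Closed-form parameter count per layer for the analytic oracle.
analytic_param_count <- function(cfg) {
  conv_n <- function(k, cin, cout, bias = TRUE)
    k * k * cin * cout + if (bias) cout else 0
  bn_n <- function(C) 2 * C
  rcl_n <- function(cin, cout)
    conv_n(3, cin, cout) + bn_n(cout) + conv_n(3, cout, cout) + bn_n(cout)
  rr_n <- function(cin, cout)
    rcl_n(cin, cout) + rcl_n(cout, cout) +
    if (cin != cout) conv_n(1, cin, cout) else 0
  cap <- function(r, C) max(1, min(r, C))
  cbam_n <- function(C) {
    hid <- C %/% cap(cfg$ca_reduction, C)
    hid * C + C * hid + conv_n(7, 2, 1)
  }
  sk_n <- function(C) {
    d <- max(C %/% cap(cfg$sk_reduction, C), 4)
    conv_n(cfg$sk_kernels[1], C, C) + conv_n(cfg$sk_kernels[2], C, C) +
      d * C + bn_n(d) + C * d + C * d
  }
  D <- cfg$depth
  ch <- cfg$base_width * 2^(seq_len(D) - 1)
  total <- 0
  prev <- cfg$in_channels
  for (lev in seq_len(D)) {
    total <- total + rr_n(prev, ch[lev])
    if (cfg$use_sk) total <- total + sk_n(ch[lev])
    prev <- ch[lev]
  }
  for (lev in seq_len(D - 1)) {
    if (cfg$use_cbam) total <- total + cbam_n(ch[lev])
    total <- total + conv_n(2, ch[lev + 1], ch[lev])        # upsample
    total <- total + rr_n(2 * ch[lev], ch[lev])             # decoder block
  }
  total + conv_n(1, ch[1], cfg$n_classes)                   # head
}

test_that("forward output shape is K x H x W across a config grid", {
  for (depth in 2:3) for (base in c(4, 8)) {
    cfg <- net_config(depth = depth, base_width = base, input_size = 32)
    m <- build_model(cfg, seed = 1)
    for (hw in c(32, 64)) {
      x <- array(runif(hw * hw * 1 * 3), c(hw, hw, 1, 3))
      out <- m$forward(x)
      expect_equal(dim(out$value), c(hw, hw, 1, 4))
    }
  }
})

test_that("reported parameter totals equal the closed-form layer sum", {
  for (depth in 2:3) for (base in c(4, 8)) {
    for (flags in list(c(TRUE, TRUE), c(FALSE, FALSE), c(TRUE, FALSE))) {
      cfg <- net_config(depth = depth, base_width = base,
                        use_cbam = flags[1], use_sk = flags[2],
                        input_size = 32)
      m <- build_model(cfg, seed = 1)
      expect_equal(count_params(m), analytic_param_count(cfg))
    }
  }
})

test_that("ablation ordering: baseline < +CBAM < +CBAM+SK parameters", {
  mk <- function(cb, sk) count_params(build_model(
    net_config(depth = 3, base_width = 8, use_cbam = cb, use_sk = sk,
               input_size = 64), seed = 1))
  p_base <- mk(FALSE, FALSE)
  p_cbam <- mk(TRUE, FALSE)
  p_full <- mk(TRUE, TRUE)
  expect_lt(p_base, p_cbam)
  expect_lt(p_cbam, p_full)
})

test_that("invalid input sizes and configs are rejected", {
  expect_error(net_config(depth = 4, input_size = 100), "divisible")
  m <- build_model(net_config(depth = 3, base_width = 4, input_size = 64),
                   seed = 1)
  expect_error(m$forward(array(0, c(30, 30, 1, 3))), "divisible")
  expect_error(m$forward(array(0, c(32, 32, 1, 5))), "channels")
})

test_that("recurrent-residual block reduces to double conv at t = 0 and
          matches a manual unroll at t = 2", {
  set.seed(21)
  C <- 2
  x <- array(rnorm(4 * 4 * C), c(4, 4, C))
  mk_rcl <- function(cin, cout) list(
    ff_w = array(rnorm(9 * cin * cout, sd = 0.4), c(3, 3, cin, cout)),
    ff_b = rnorm(cout),
    rec_w = array(rnorm(9 * cout * cout, sd = 0.4), c(3, 3, cout, cout)),
    rec_b = rnorm(cout))
  params <- list(rcl1 = mk_rcl(C, C), rcl2 = mk_rcl(C, C))
  # t = 0: two plain convolutions plus the identity shortcut
  got0 <- recurrent_residual_block(x, params, t = 0)
  relu <- function(z) pmax(z, 0)
  y1 <- relu(conv2d_loop(x, params$rcl1$ff_w, params$rcl1$ff_b))
  y2 <- relu(conv2d_loop(y1, params$rcl2$ff_w, params$rcl2$ff_b))
  expect_equal(got0, y2 + x, tolerance = 1e-8)
  # t = 2: manual unroll y_s = relu(a + conv_rec(y_{s-1}))
  unroll <- function(inp, p, t) {
    a <- conv2d_loop(inp, p$ff_w, p$ff_b)
    y <- relu(a)
    for (s in seq_len(t)) y <- relu(a + conv2d_loop(y, p$rec_w, p$rec_b))
    y
  }
  got2 <- recurrent_residual_block(x, params, t = 2)
  want2 <- unroll(unroll(x, params$rcl1, 2), params$rcl2, 2) + x
  expect_equal(got2, want2, tolerance = 1e-8)
  # zero weights with identity shortcut pass the input through
  zero <- list(rcl1 = lapply(params$rcl1, function(v) v * 0),
               rcl2 = lapply(params$rcl2, function(v) v * 0))
  expect_equal(recurrent_residual_block(x, zero, t = 2), x)
  expect_error(recurrent_residual_block(x, params, t = -1), "non-negative")
})

test_that("mask prediction is deterministic and batch-consistent", {
  m <- build_model(net_config(depth = 2, base_width = 4, input_size = 32),
                   seed = 7)
  set.seed(1)
  img1 <- array(sample(0:255, 32 * 32 * 3, TRUE), c(32, 32, 3))
  img2 <- array(sample(0:255, 32 * 32 * 3, TRUE), c(32, 32, 3))
  a <- predict_mask(m, img1)
  b <- predict_mask(m, img1)
  expect_identical(unclass(a), unclass(b))
  # batch of one equals the single-image path; batch of two equals both
  expect_identical(unclass(predict_mask(m, list(img1))[[1]]), unclass(a))
  pair <- predict_mask(m, list(img1, img2))
  expect_identical(unclass(pair[[1]]), unclass(a))
  expect_identical(unclass(pair[[2]]), unclass(predict_mask(m, img2)))
})

test_that("a head biased to background yields an all-background mask", {
  m <- build_model(net_config(depth = 2, base_width = 4, input_size = 32),
                   seed = 7)
  m$store$params[["head.w"]]$value <- m$store$params[["head.w"]]$value * 0
  m$store$params[["head.b"]]$value <- c(10, 0, 0, 0)
  img <- array(runif(32 * 32 * 3, 0, 255), c(32, 32, 3))
  expect_true(all(unclass(predict_mask(m, img)) == 0L))
})

test_that("checkpoints round-trip weights, config and evaluation", {
  m <- build_model(net_config(depth = 2, base_width = 4, input_size = 32),
                   seed = 3)
  samples <- tiny_samples(2, seed = 4)
  ev1 <- evaluate_model(m, samples)
  p <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, p, meta = list(epoch = 0))
  m2 <- load_checkpoint(p)
  expect_equal(m2$config, m$config)
  ev2 <- evaluate_model(m2, samples)
  expect_identical(ev1$miou, ev2$miou)
  expect_identical(ev1$counts, ev2$counts)
})
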