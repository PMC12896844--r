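# Standalone attention operators on plain arrays.
#
# Feature maps are H x W x C numeric arrays (image-style layout). These
# functions evaluate the same vectorized kernels the network uses, with
# caller-supplied weights, so they can be checked against independent scalar
# loop oracles. Batch normalization inside the selective-kernel operator runs
# in stored-statistics mode here (deterministic for a single sample).

# H x W x C array -> internal single-sample H x W x 1 x C layout (data
# order is unchanged, so this is a plain reshape).
.as_hw1c <- function(x) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  stopifnot(length(dim(x)) == 3L)
  d <- dim(x)
  dim(x) <- c(d[1], d[2], 1L, d[3])
  x
}

#' Channel-attention parameters
#'
#' Weights of the shared two-layer perceptron used by channel attention.
#'
#' @param w0 First layer weights, `(C/r) x C`.
#' @param w1 Second layer weights, `C x (C/r)`.
#' @param reduction Reduction ratio `r`; must divide the channel count.
#' @return An object of class `ca_params`.
#' @export
ca_params <- function(w0, w1, reduction = 16) {
  stopifnot(is.matrix(w0), is.matrix(w1), nrow(w1) == ncol(w0),
            ncol(w1) == nrow(w0))
  structure(list(w0 = w0, w1 = w1, reduction = reduction),
            class = "ca_params")
}

#' Channel attention gate
#'
#' Computes per-channel attention weights
#' `Mc = sigmoid(MLP(avgpool(F)) + MLP(maxpool(F)))`, where the two-layer
#' perceptron `MLP(v) = W1 relu(W0 v)` is shared between the average- and
#' max-pooled channel descriptors.
#'
#' @param f Feature map, `H x W x C` array.
#' @param params A [ca_params()] object; `ncol(w0)` must equal `C` and the
#'   reduction ratio must divide `C`.
#' @return Numeric vector of length `C` with entries in (0, 1).
#' @export
channel_attention <- function(f, params) {
  x <- .as_hw1c(f)
  C <- dim(x)[4]
  if (C %% params$reduction != 0L)
    stop("reduction ratio ", params$reduction, " does not divide C = ", C)
  if (ncol(params$w0) != C)
    stop("w0 has ", ncol(params$w0), " columns but the feature map has ",
         C, " channels")
  xn <- ad_const(x)
  w0 <- ad_const(params$w0); w1 <- ad_const(params$w1)
  mlp <- function(v) ad_dense(ad_relu(ad_dense(v, w0)), w1)
  mc <- ad_sigmoid(ad_add(mlp(ad_global_avgpool(xn)),
                          mlp(ad_global_maxpool(xn))))
  as.vector(mc$value)
}

#' Spatial attention gate
#'
#' Concatenates the channel-wise mean and max maps of a feature map and
#' convolves them (same padding) with a single-output kernel, followed by a
#' sigmoid, yielding one attention weight per pixel.
#'
#' @param f Feature map, `H x W x C` array.
#' @param kernel Convolution weights, `k x k x 2 x 1` array (default kernel
#'   size is 7).
#' @param bias Scalar bias added before the sigmoid.
#' @param strict If `TRUE`, refuse kernels that are not 7x7.
#' @return `H x W` matrix with entries in (0, 1).
#' @export
spatial_attention <- function(f, kernel, bias = 0, strict = FALSE) {
  x <- .as_hw1c(f)
  kd <- dim(kernel)
  if (length(kd) != 4L || kd[3] != 2L || kd[4] != 1L)
    stop("kernel must be k x k x 2 x 1")
  if (strict && !(kd[1] == 7L && kd[2] == 7L))
    stop("strict mode requires a 7x7 kernel")
  xn <- ad_const(x)
  sp <- ad_concat_channels(ad_channel_mean(xn), ad_channel_max(xn))
  conv <- ad_conv2d(sp, ad_const(kernel), ad_const(bias))
  ms <- ad_sigmoid(conv)
  matrix(ms$value, dim(x)[1], dim(x)[2])
}

#' Convolutional block attention (CBAM)
#'
#' Applies channel attention then spatial attention to a feature map:
#' `F' = Mc(F) * F` (broadcast over pixels), `F'' = Ms(F') * F'` (broadcast
#' over channels). Because both gates lie in (0, 1), no element's magnitude
#' increases.
#'
#' @param f Feature map, `H x W x C` array.
#' @param params List with elements `ca` (a [ca_params()] object),
#'   `spatial_kernel` (`k x k x 2 x 1` array) and optionally `spatial_bias`.
#' @return Refined feature map, same shape as `f`.
#' @export
cbam <- function(f, params) {
  x <- .as_hw1c(f)
  mc <- channel_attention(f, params$ca)
  x1 <- x * array(rep(mc, each = dim(x)[1] * dim(x)[2]), dim(x))
  ms <- spatial_attention(array(x1, dim(f)), params$spatial_kernel,
                          bias = params$spatial_bias %||% 0)
  out <- x1 * array(as.vector(ms), dim(x))
  array(out, dim(f))
}

#' Selective-kernel attention parameters
#'
#' @param w_branch1,w_branch2 Branch convolution weights, `k x k x C x C`
#'   arrays with odd `k` (defaults 3 and 5 in the network).
#' @param b_branch1,b_branch2 Branch biases, length `C`.
#' @param w_fuse Fuse-stage bottleneck weights, `d x C`.
#' @param bn_gamma,bn_beta,bn_mean,bn_var Batch-norm parameters and stored
#'   statistics of the fuse stage, length `d`.
#' @param w_select1,w_select2 Per-branch selection weights, `C x d`.
#' @return An object of class `sk_params`.
#' @export
sk_params <- function(w_branch1, w_branch2, b_branch1, b_branch2, w_fuse,
                      bn_gamma = NULL, bn_beta = NULL, bn_mean = NULL,
                      bn_var = NULL, w_select1, w_select2) {
  d <- nrow(w_fuse)
  structure(list(
    w_branch1 = w_branch1, w_branch2 = w_branch2,
    b_branch1 = b_branch1, b_branch2 = b_branch2,
    w_fuse = w_fuse,
    bn_gamma = bn_gamma %||% rep(1, d), bn_beta = bn_beta %||% numeric(d),
    bn_mean = bn_mean %||% numeric(d), bn_var = bn_var %||% rep(1, d),
    w_select1 = w_select1, w_select2 = w_select2
  ), class = "sk_params")
}

#' Selective-kernel attention
#'
#' Split-fuse-select over exactly two convolution branches: the branch
#' outputs `U1`, `U2` are summed, globally average-pooled to a channel
#' descriptor `s`, compressed to `z = relu(BN(W s))`, and per-channel softmax
#' weights `a + b = 1` over the two branch logits recombine the branches as
#' `V = a U1 + b U2`.
#'
#' @param x Feature map, `H x W x C` array.
#' @param params An [sk_params()] object.
#' @param n_branches Must be 2; other values raise an unsupported
#'   configuration error.
#' @param return_weights If `TRUE`, attach the branch weight matrix
#'   (`C x 2`) as attribute `"branch_weights"`.
#' @return Feature map `V`, same shape as `x`.
#' @export
sk_attention <- function(x, params, n_branches = 2, return_weights = FALSE) {
  if (n_branches != 2)
    stop("unsupported configuration: selective-kernel attention is only ",
         "applicable to two branches")
  xa <- .as_hw1c(x)
  xn <- ad_const(xa)
  u1 <- ad_conv2d(xn, ad_const(params$w_branch1), ad_const(params$b_branch1))
  u2 <- ad_conv2d(xn, ad_const(params$w_branch2), ad_const(params$b_branch2))
  u <- ad_add(u1, u2)
  s <- ad_global_avgpool(u)
  st <- new.env(parent = emptyenv())
  st$running_mean <- params$bn_mean
  st$running_var <- params$bn_var
  z <- ad_relu(ad_batchnorm1d(ad_dense(s, ad_const(params$w_fuse)),
                              ad_const(params$bn_gamma),
                              ad_const(params$bn_beta), st,
                              training = FALSE))
  a <- ad_sigmoid(ad_sub(ad_dense(z, ad_const(params$w_select1)),
                         ad_dense(z, ad_const(params$w_select2))))
  b <- ad_one_minus(a)
  v <- ad_add(ad_channel_scale(u1, a), ad_channel_scale(u2, b))
  out <- array(v$value, c(dim(xa)[1], dim(xa)[2], dim(xa)[4]))
  if (return_weights)
    attr(out, "branch_weights") <- cbind(a = as.vector(a$value),
                                         b = as.vector(b$value))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
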