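# Building blocks: residual convolution, hybrid attention block (HAB) and
# dilated convolution block (DCB).
#
# Each block is a list of parameter nodes created by a `block_*()`
# constructor and applied on an autodiff tape by a `forward_*()` function.
# The exported `residual_conv()`, `channel_mask()`, `spatial_mask()`,
# `hab()` and `dcb()` wrappers run a block in evaluation mode on a single
# feature map given channels-first (C, H, W), the conventional layout for a
# single unbatched map.

kaiming_sd <- function(fan_in) sqrt(2 / fan_in)

make_conv <- function(kh, kw, cin, cout, init = "kaiming") {
  n <- kh * kw * cin * cout
  w <- if (init == "zero") numeric(n) else stats::rnorm(n, 0, kaiming_sd(kh * kw * cin))
  list(w = mm_param(array(w, c(kh, kw, cin, cout))), b = mm_param(numeric(cout)))
}

make_deconv <- function(cin, cout, init = "kaiming") {
  n <- 4 * cin * cout
  w <- if (init == "zero") numeric(n) else stats::rnorm(n, 0, kaiming_sd(4 * cin))
  list(w = mm_param(array(w, c(2, 2, cin, cout))), b = mm_param(numeric(cout)))
}

make_bn <- function(c) {
  st <- new.env(parent = emptyenv())
  st$running_mean <- numeric(c)
  st$running_var <- rep(1, c)
  list(gamma = mm_param(rep(1, c)), beta = mm_param(numeric(c)), state = st)
}

make_dense <- function(cin, cout, init = "kaiming") {
  w <- if (init == "zero") numeric(cin * cout) else stats::rnorm(cin * cout, 0, kaiming_sd(cin))
  list(w = mm_param(matrix(w, cout, cin)), b = mm_param(numeric(cout)))
}

# ---- residual convolution -------------------------------------------------

#' Create a residual convolution block
#'
#' Two successive 3x3 convolutions (each followed by batch normalization and
#' ReLU) learn the residual; a 1x1 convolution projects the block input to
#' `out_ch` channels so the two can be added element-wise.  Spatial size is
#' preserved (padding 1).
#'
#' @param in_ch,out_ch input and output channel counts.
#' @param init `"kaiming"` (default) or `"zero"` weight initialization.
#' @return a block object usable with [residual_conv()].
#' @export
block_residual <- function(in_ch, out_ch, init = "kaiming") {
  structure(list(
    conv1 = make_conv(3, 3, in_ch, out_ch, init), bn1 = make_bn(out_ch),
    conv2 = make_conv(3, 3, out_ch, out_ch, init), bn2 = make_bn(out_ch),
    shortcut = make_conv(1, 1, in_ch, out_ch, init),
    in_ch = in_ch, out_ch = out_ch
  ), class = "mm_block_residual")
}

forward_residual <- function(tape, blk, x, training = FALSE) {
  h <- op_relu(tape, op_bn(tape, op_conv2d(tape, x, blk$conv1$w, blk$conv1$b),
                           blk$bn1$gamma, blk$bn1$beta, blk$bn1$state, training))
  h <- op_relu(tape, op_bn(tape, op_conv2d(tape, h, blk$conv2$w, blk$conv2$b),
                           blk$bn2$gamma, blk$bn2$beta, blk$bn2$state, training))
  s <- op_conv2d(tape, x, blk$shortcut$w, blk$shortcut$b)
  op_add(tape, h, s)
}

# ---- hybrid attention block ----------------------------------------------

#' Create a hybrid attention block
#'
#' Channel attention: global average, max and range pooling over the spatial
#' plane feed a shared two-layer MLP (hidden width `channels / reduction`);
#' the three outputs are added and sigmoid-normalized into a per-channel
#' mask.  Spatial attention: per-pixel mean, max and range across channels
#' are concatenated and reduced by a single 7x7 convolution to a sigmoid
#' spatial mask.  The two masks multiply the feature map according to
#' `order`: `"channel_first"` (serial, default), `"spatial_first"` (serial)
#' or `"parallel"` (both masks computed from the input and applied jointly).
#'
#' @param channels feature-map channel count.
#' @param reduction MLP reduction ratio r (hidden width `channels / r`).
#' @param order mask application order.
#' @inheritParams block_residual
#' @export
block_hab <- function(channels, reduction = 1, order = "channel_first", init = "kaiming") {
  hidden <- channels / reduction
  if (hidden != round(hidden) || hidden < 1)
    stop("channels must be divisible by the reduction ratio")
  if (!order %in% c("channel_first", "spatial_first", "parallel"))
    stop("unknown attention order '", order,
         "'; valid: channel_first, spatial_first, parallel")
  structure(list(
    mlp1 = make_dense(channels, hidden, init),
    mlp2 = make_dense(hidden, channels, init),
    spconv = make_conv(7, 7, 3, 1, init),
    channels = channels, order = order
  ), class = "mm_block_hab")
}

forward_mlp <- function(tape, blk, v) {
  op_dense(tape, op_relu(tape, op_dense(tape, v, blk$mlp1$w, blk$mlp1$b)),
           blk$mlp2$w, blk$mlp2$b)
}

forward_channel_mask <- function(tape, blk, x) {
  avg <- op_gap_c(tape, x)
  mx <- op_gmp_c(tape, x)
  rg <- op_sub(tape, mx, op_gmp_c(tape, x, minimum = TRUE))
  s <- op_add(tape, op_add(tape, forward_mlp(tape, blk, avg),
                           forward_mlp(tape, blk, mx)),
              forward_mlp(tape, blk, rg))
  op_sigmoid(tape, s)
}

forward_spatial_mask <- function(tape, blk, x) {
  avg <- op_pool_s(tape, x, "mean")
  mx <- op_pool_s(tape, x, "max")
  rg <- op_sub(tape, mx, op_pool_s(tape, x, "min"))
  cat3 <- op_concat_c(tape, list(avg, mx, rg))
  op_sigmoid(tape, op_conv2d(tape, cat3, blk$spconv$w, blk$spconv$b, dilation = 1L, pad = 3L))
}

forward_hab <- function(tape, blk, x) {
  switch(blk$order,
    channel_first = {
      g <- op_cmul(tape, x, forward_channel_mask(tape, blk, x))
      op_smul(tape, g, forward_spatial_mask(tape, blk, g))
    },
    spatial_first = {
      g <- op_smul(tape, x, forward_spatial_mask(tape, blk, x))
      op_cmul(tape, g, forward_channel_mask(tape, blk, g))
    },
    parallel = {
      g <- op_cmul(tape, x, forward_channel_mask(tape, blk, x))
      op_smul(tape, g, forward_spatial_mask(tape, blk, x))
    },
    stop("unknown attention order '", blk$order, "'")
  )
}

# ---- dilated convolution block --------------------------------------------

#' Create a dilated convolution block
#'
#' Five parallel channel-preserving branches: a 1x1 convolution; 3x3
#' convolutions with dilation rates 1 and 3; two stacked 3x3 convolutions
#' with dilation rate 2; and global average pooling broadcast back over the
#' plane.  The branches are concatenated (5C channels) and reduced back to C
#' by a final 1x1 convolution.  Spatial size is always preserved.
#'
#' @param channels feature-map channel count C.
#' @inheritParams block_residual
#' @export
block_dcb <- function(channels, init = "kaiming") {
  structure(list(
    phi1 = make_conv(1, 1, channels, channels, init),
    phi2 = make_conv(3, 3, channels, channels, init),
    phi3 = make_conv(3, 3, channels, channels, init),
    phi4a = make_conv(3, 3, channels, channels, init),
    phi4b = make_conv(3, 3, channels, channels, init),
    phi5 = make_conv(1, 1, 5 * channels, channels, init),
    channels = channels
  ), class = "mm_block_dcb")
}

forward_dcb <- function(tape, blk, x) {
  d <- dim4(x$val)
  b1 <- op_conv2d(tape, x, blk$phi1$w, blk$phi1$b)
  b2 <- op_conv2d(tape, x, blk$phi2$w, blk$phi2$b, dilation = 1L)
  b3 <- op_conv2d(tape, x, blk$phi3$w, blk$phi3$b, dilation = 3L)
  b4 <- op_conv2d(tape, op_conv2d(tape, x, blk$phi4a$w, blk$phi4a$b, dilation = 2L),
                  blk$phi4b$w, blk$phi4b$b, dilation = 2L)
  b5 <- op_broadcast_c(tape, op_gap_c(tape, x), d[1], d[2])
  op_conv2d(tape, op_concat_c(tape, list(b1, b2, b3, b4, b5)), blk$phi5$w, blk$phi5$b)
}

# ---- channels-first single-map wrappers -----------------------------------

chw_to_hwcn <- function(f) {
  d <- dim(f)
  if (length(d) != 3L) stop("expected a (channels, height, width) array")
  array(aperm(f, c(2, 3, 1)), c(d[2], d[3], d[1], 1))
}

hwcn_to_chw <- function(y) {
  d <- dim(y)
  aperm(array(y, d[1:3]), c(3, 1, 2))
}

run_eval <- function(fn) {
  tape <- mm_tape()
  fn(tape)
}

#' Apply a residual convolution block to one feature map
#'
#' @param f numeric array (channels, height, width).
#' @param block a block from [block_residual()].
#' @return array (out_ch, height, width); batch normalization runs in
#'   evaluation mode (running statistics).
#' @export
residual_conv <- function(f, block) {
  x <- mm_node(NULL, chw_to_hwcn(f))
  hwcn_to_chw(run_eval(function(tp) forward_residual(tp, block, x))$val)
}

#' Channel attention mask of a hybrid attention block
#'
#' @param f numeric array (channels, height, width).
#' @param block a block from [block_hab()].
#' @return numeric vector of per-channel mask values in (0, 1).
#' @export
channel_mask <- function(f, block) {
  x <- mm_node(NULL, chw_to_hwcn(f))
  as.vector(run_eval(function(tp) forward_channel_mask(tp, block, x))$val)
}

#' Spatial attention mask of a hybrid attention block
#'
#' @inheritParams channel_mask
#' @return numeric matrix (height, width) with entries in (0, 1).
#' @export
spatial_mask <- function(f, block) {
  x <- mm_node(NULL, chw_to_hwcn(f))
  y <- run_eval(function(tp) forward_spatial_mask(tp, block, x))$val
  matrix(y, dim(y)[1], dim(y)[2])
}

#' Apply a hybrid attention block to one feature map
#'
#' @inheritParams channel_mask
#' @return array of the same shape as `f`.
#' @export
hab <- function(f, block) {
  x <- mm_node(NULL, chw_to_hwcn(f))
  hwcn_to_chw(run_eval(function(tp) forward_hab(tp, block, x))$val)
}

#' Apply a dilated convolution block to one feature map
#'
#' @param f numeric array (channels, height, width).
#' @param block a block from [block_dcb()].
#' @return array of the same shape as `f`.
#' @export
dcb <- function(f, block) {
  x <- mm_node(NULL, chw_to_hwcn(f))
  hwcn_to_chw(run_eval(function(tp) forward_dcb(tp, block, x))$val)
}

block_params <- function(blk) {
  out <- list()
  walk <- function(x) {
    if (is.environment(x)) {
      if (isTRUE(x$param)) out[[length(out) + 1L]] <<- x
    } else if (is.list(x)) {
      for (el in x) walk(el)
    }
  }
  walk(unclass(blk))
  out
}
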