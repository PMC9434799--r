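# Building blocks against naive loop-based oracles.

bn_eval <- function(x, eps = 1e-5) x / sqrt(1 + eps)   # fresh BN in eval mode

test_that("residual conv with zero main weights and identity shortcut passes input through", {
  blk <- block_residual(2, 2, init = "zero")
  # identity 1x1 shortcut
  blk$shortcut$w$val[1, 1, 1, 1] <- 1
  blk$shortcut$w$val[1, 1, 2, 2] <- 1
  f <- abs(toy_map(2, 5, 6, seed = 2))
  expect_equal(residual_conv(f, blk), f, tolerance = 1e-12)
})

test_that("residual conv maps channels in->out and preserves spatial size", {
  blk <- block_residual(3, 5)
  f <- toy_map(3, 6, 9, seed = 3)
  y <- residual_conv(f, blk)
  expect_identical(dim(y), c(5L, 6L, 9L))
})

test_that("residual conv matches a sliding-window convolution oracle", {
  set.seed(10)
  blk <- block_residual(1, 2)
  f <- toy_map(1, 4, 4, seed = 4)
  x <- aperm(array(f, c(1, 4, 4)), c(2, 3, 1))
  dim(x) <- c(4, 4, 1, 1)
  h <- conv2d_oracle(x, blk$conv1$w$val, blk$conv1$b$val)
  h <- pmax(bn_eval(h), 0)
  h <- conv2d_oracle(h, blk$conv2$w$val, blk$conv2$b$val)
  h <- pmax(bn_eval(h), 0)
  s <- conv2d_oracle(x, blk$shortcut$w$val, blk$shortcut$b$val, pad = 0)
  expected <- aperm(array(h + s, c(4, 4, 2)), c(3, 1, 2))
  expect_equal(residual_conv(f, blk), expected, tolerance = 1e-6)
})

test_that("channel mask is 0.5 everywhere under zero MLP weights", {
  blk <- block_hab(3, init = "zero")
  m <- channel_mask(toy_map(3, 5, 5), blk)
  expect_equal(m, rep(0.5, 3))
})

test_that("channel mask matches hand-computed sigmoid of pooled statistics", {
  # identity MLP (r = 1): phi1 = phi2 = I, so MLP(v) = relu(v)
  blk <- block_hab(2, reduction = 1, init = "zero")
  blk$mlp1$w$val <- diag(2)
  blk$mlp2$w$val <- diag(2)
  f <- array(c(1, 3, 2, 6, -1, 4, 0, 2), c(2, 2, 2))   # 2 channels, 2x2
  pooled <- t(apply(array(f, c(2, 4)), 1, function(v)
    c(mean(v), max(v), max(v) - min(v))))
  expected <- 1 / (1 + exp(-(pmax(pooled[, 1], 0) + pmax(pooled[, 2], 0) +
                              pmax(pooled[, 3], 0))))
  expect_equal(channel_mask(f, blk), expected, tolerance = 1e-12)
  # a constant channel has GAP = GMP = c and GRP = 0
  g <- array(2, c(1, 3, 3))
  blk1 <- block_hab(1, init = "zero")
  blk1$mlp1$w$val <- matrix(1); blk1$mlp2$w$val <- matrix(1)
  expect_equal(channel_mask(g, blk1), 1 / (1 + exp(-(2 + 2 + 0))))
})

test_that("spatial mask has spatial shape, lies in (0,1), matches 7x7 conv oracle", {
  set.seed(11)
  blk <- block_hab(1)
  f <- toy_map(1, 8, 8, seed = 12)
  m <- spatial_mask(f, blk)
  expect_identical(dim(m), c(8L, 8L))
  expect_true(all(m > 0 & m < 1))
  # oracle: pooled maps (mean/max/range over the single channel are all f)
  x <- array(0, c(8, 8, 3, 1))
  x[, , 1, 1] <- f[1, , ]; x[, , 2, 1] <- f[1, , ]; x[, , 3, 1] <- 0
  z <- conv2d_oracle(x, blk$spconv$w$val, blk$spconv$b$val, pad = 3)
  expect_equal(m, 1 / (1 + exp(-z[, , 1, 1])), tolerance = 1e-6)
  # zero conv weights give a flat 0.5 mask
  blk0 <- block_hab(2, init = "zero")
  expect_equal(unique(as.vector(spatial_mask(toy_map(2, 6, 6), blk0))), 0.5)
})

test_that("hybrid attention equals the manual composition of its masks and attenuates", {
  set.seed(13)
  for (ord in c("channel_first", "spatial_first", "parallel")) {
    blk <- block_hab(3, order = ord)
    f <- toy_map(3, 6, 6, seed = 14)
    out <- hab(f, blk)
    expect_identical(dim(out), dim(f))
    expect_true(all(abs(out) < abs(f) | f == 0))    # masks strictly < 1
    manual <- switch(ord,
      channel_first = {
        g <- f * channel_mask(f, blk)               # (C,H,W) * C recycles by channel
        g * rep(spatial_mask(g, blk), each = 3)
      },
      spatial_first = {
        g <- f * rep(spatial_mask(f, blk), each = 3)
        g * channel_mask(g, blk)
      },
      parallel = {
        g <- f * channel_mask(f, blk)
        g * rep(spatial_mask(f, blk), each = 3)
      })
    expect_equal(out, manual, tolerance = 1e-8)
  }
})

test_that("hybrid attention with all-zero weights quarters the input", {
  blk <- block_hab(2, init = "zero")
  f <- toy_map(2, 5, 5, seed = 15)
  expect_equal(hab(f, blk), 0.25 * f, tolerance = 1e-12)
})

test_that("unknown attention ordering is rejected", {
  expect_error(block_hab(4, order = "diagonal"), "diagonal")
})

test_that("DCB preserves shape and reduces to its phi5 bias under zero weights", {
  blk <- block_dcb(3, init = "zero")
  blk$phi5$b$val <- c(1, -2, 0.5)
  f <- toy_map(3, 7, 5, seed = 16)
  y <- dcb(f, blk)
  expect_identical(dim(y), dim(f))
  for (cc in 1:3) expect_equal(unique(as.vector(y[cc, , ])), blk$phi5$b$val[cc])
  # random weights, odd small sizes still fine (zero padding, never an error)
  blk2 <- block_dcb(2)
  expect_identical(dim(dcb(toy_map(2, 3, 3), blk2)), c(2L, 3L, 3L))
})

test_that("DCB matches the oracle composition of its five branches", {
  set.seed(17)
  blk <- block_dcb(2)
  f <- toy_map(2, 8, 8, seed = 18)
  x <- aperm(f, c(2, 3, 1)); dim(x) <- c(8, 8, 2, 1)
  b1 <- conv2d_oracle(x, blk$phi1$w$val, blk$phi1$b$val, pad = 0)
  b2 <- conv2d_oracle(x, blk$phi2$w$val, blk$phi2$b$val, dil = 1)
  b3 <- conv2d_oracle(x, blk$phi3$w$val, blk$phi3$b$val, dil = 3)
  b4 <- conv2d_oracle(conv2d_oracle(x, blk$phi4a$w$val, blk$phi4a$b$val, dil = 2),
                      blk$phi4b$w$val, blk$phi4b$b$val, dil = 2)
  gapv <- apply(x[, , , 1], 3, mean)
  b5 <- array(rep(gapv, each = 64), c(8, 8, 2, 1))
  cat5 <- array(0, c(8, 8, 10, 1))
  cat5[, , 1:2, ] <- b1; cat5[, , 3:4, ] <- b2; cat5[, , 5:6, ] <- b3
  cat5[, , 7:8, ] <- b4; cat5[, , 9:10, ] <- b5
  expected <- conv2d_oracle(cat5, blk$phi5$w$val, blk$phi5$b$val, pad = 0)
  got <- dcb(f, blk)
  expect_equal(got, aperm(expected[, , , 1], c(3, 1, 2)), tolerance = 1e-5)
})

test_that("DCB impulse responses span 7x7 (dilation 3) and 9x9 (stacked dilation 2)", {
  impulse_support <- function(branch) {
    blk <- block_dcb(1, init = "zero")
    one <- function(cv) { cv$w$val[] <- 1; cv }
    if (branch == "phi3") blk$phi3 <- one(blk$phi3)
    if (branch == "phi4") { blk$phi4a <- one(blk$phi4a); blk$phi4b <- one(blk$phi4b) }
    # phi5 picks out the branch (channel 3 = phi3, channel 4 = phi4)
    blk$phi5$w$val[1, 1, if (branch == "phi3") 3 else 4, 1] <- 1
    f <- array(0, c(1, 13, 13)); f[1, 7, 7] <- 1
    nz <- which(dcb(f, blk)[1, , ] != 0, arr.ind = TRUE)
    c(diff(range(nz[, 1])) + 1, diff(range(nz[, 2])) + 1)
  }
  expect_equal(impulse_support("phi3"), c(7, 7))
  expect_equal(impulse_support("phi4"), c(9, 9))
})
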