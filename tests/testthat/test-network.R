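# Network assembly: shapes, variants, parameter accounting, serialization.

# closed-form parameter count, written independently of the builder
count_oracle <- function(cfg) {
  conv <- function(ci, co, k) ci * co * k * k + co
  bn <- function(c) 2 * c
  res <- function(ci, co) conv(ci, co, 3) + bn(co) + conv(co, co, 3) + bn(co) + conv(ci, co, 1)
  W <- cfg$base_channels * 2^(0:(cfg$depth - 1))
  M <- cfg$modalities
  enc <- M * sum(mapply(res, c(1, W[-cfg$depth]), W))
  habp <- if (cfg$hab_enabled) {
    M * sum(sapply(W, function(C) {
      h <- C / cfg$hab_reduction
      C * h + h + h * C + C + 7 * 7 * 3 * 1 + 1
    }))
  } else 0
  dcbp <- if (cfg$dcb_enabled) {
    C <- W[if (cfg$dcb_position == "after_stage2") 2 else cfg$depth]
    M * (conv(C, C, 1) + 3 * conv(C, C, 3) + conv(C, C, 3) + conv(5 * C, C, 1))
  } else 0
  fused <- M * W[cfg$depth]
  bneck <- conv(fused, fused, 3) + bn(fused) + conv(fused, 2 * fused, 3) + bn(2 * fused)
  deconv <- function(ci, co) 4 * ci * co + co
  dec <- 0
  for (s in rev(seq_len(cfg$depth))) {
    cprev <- if (s == cfg$depth) 2 * fused else M * W[s + 1]
    dec <- dec + deconv(cprev, cprev) + res(cprev + M * W[s], M * W[s])
  }
  outl <- conv(M * W[1], cfg$classes, cfg$final_kernel)
  enc + habp + dcbp + bneck + dec + outl
}

test_that("forward output matches the input spatial size and class count", {
  cfg <- make_variant("full", input_size = 32L, base_channels = 4L)
  net <- build_network(cfg, seed = 2)
  x <- array(rnorm(32 * 32 * 4 * 2), c(32, 32, 4, 2))
  y <- forward(net, x)
  expect_identical(dim(y), c(32L, 32L, 4L, 2L))
  expect_true(all(is.finite(y)))
  # fully convolutional: another divisible-by-16 size works with the same net
  y2 <- forward(net, array(rnorm(48 * 48 * 4), c(48, 48, 4)))
  expect_identical(dim(y2), c(48L, 48L, 4L, 1L))
  expect_error(forward(net, array(0, c(32, 32, 3, 1))), "4 modality")
})

test_that("cases in a batch do not couple in evaluation mode", {
  cfg <- make_variant("full", input_size = 16L, base_channels = 2L)
  net <- build_network(cfg, seed = 5)
  x <- array(rnorm(16 * 16 * 4 * 3), c(16, 16, 4, 3))
  y <- forward(net, x)
  perm <- c(3, 1, 2)
  yp <- forward(net, x[, , , perm, drop = FALSE])
  expect_equal(yp, y[, , , perm, drop = FALSE], tolerance = 1e-12)
})

test_that("named variants configure the blocks as documented", {
  b <- make_variant("baseline")
  expect_false(b$hab_enabled); expect_false(b$dcb_enabled)
  f <- make_variant("full")
  expect_true(f$hab_enabled && f$dcb_enabled)
  expect_equal(f$hab_order, "channel_first")
  expect_equal(f$dcb_position, "after_stage2")
  d4 <- make_variant("dcb_after_stage4")
  expect_true(d4$dcb_enabled)
  expect_equal(d4$dcb_position, "after_stage4")
  expect_equal(make_variant("spatial_first")$hab_order, "spatial_first")
  expect_equal(make_variant("parallel_attention")$hab_order, "parallel")
  expect_error(make_variant("resunet"), "baseline")
})

test_that("parameter counts match the closed-form oracle across variants and scales", {
  for (v in c("baseline", "dcb_only", "hab_only", "full", "dcb_after_stage4")) {
    for (base in c(4L, 8L)) {
      cfg <- make_variant(v, input_size = 32L, base_channels = base)
      net <- build_network(cfg, init = "zero")
      expect_equal(count_parameters(net), count_oracle(cfg),
                   info = paste(v, base))
    }
  }
  # a lone 1x1 conv, 1 -> 1 channel with bias, holds 2 scalars
  ad <- asNamespace("mmunet")
  cv <- ad$make_conv(1, 1, 1, 1, "zero")
  expect_equal(length(cv$w$val) + length(cv$b$val), 2)
})

test_that("parameter-count ordering: full > single-block variants > baseline", {
  n <- sapply(c("baseline", "dcb_only", "hab_only", "full"), function(v)
    count_parameters(build_network(make_variant(v, input_size = 32L,
                                                base_channels = 4L), init = "zero")))
  expect_true(n["full"] > n["dcb_only"] && n["dcb_only"] > n["baseline"])
  expect_true(n["full"] > n["hab_only"] && n["hab_only"] > n["baseline"])
})

test_that("with both blocks disabled the forward pass ignores hab_order", {
  x <- array(rnorm(16 * 16 * 4), c(16, 16, 4))
  outs <- lapply(c("channel_first", "spatial_first", "parallel"), function(ord) {
    cfg <- network_config(input_size = 16L, base_channels = 2L,
                          hab_enabled = FALSE, dcb_enabled = FALSE, hab_order = ord)
    forward(build_network(cfg, seed = 11), x)
  })
  expect_equal(outs[[1]], outs[[2]])
  expect_equal(outs[[1]], outs[[3]])
})

test_that("invalid configurations are rejected", {
  expect_error(network_config(input_size = 100L), "divisible")
  expect_error(network_config(dcb_position = "after_stage3"), "after_stage2")
  expect_error(network_config(final_kernel = 5L), "1 or 3")
})

test_that("weights round-trip through save/load", {
  cfg <- make_variant("full", input_size = 16L, base_channels = 2L)
  net <- build_network(cfg, seed = 21)
  x <- array(rnorm(16 * 16 * 4), c(16, 16, 4))
  y <- forward(net, x)
  path <- tempfile(fileext = ".rds")
  save_weights(net, path)
  net2 <- build_network(cfg, init = "zero")
  load_weights(net2, path)
  expect_equal(forward(net2, x), y, tolerance = 1e-15)
})

test_that("the model summary reproduces the reference layer table at full scale", {
  sm <- model_summary(make_variant("full"))
  enc <- sm$shape[sm$path == "encoder"]
  expect_equal(enc, c("4@160*160*1", "4@160*160*32", "4@80*80*32",
                      "4@80*80*64", "4@40*40*64", "4@40*40*128", "4@20*20*128",
                      "4@20*20*256", "4@10*10*256", "10*10*1,024"))
  dec <- sm$shape[sm$path == "decoder"]
  expect_equal(dec, c("10*10*2,048", "20*20*2,048", "20*20*1,024",
                      "40*40*1,024", "40*40*512", "80*80*512", "80*80*256",
                      "160*160*256", "160*160*128", "160*160*4"))
})
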