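# Loop-based oracles independent of the package's im2col/gemm path, plus
# small fixture builders shared across the test files.

conv2d_oracle <- function(x, w, b, dil = 1, pad = NULL) {
  d <- dim(x); dw <- dim(w)
  if (is.null(pad)) pad <- dil * (dw[1] - 1) / 2
  y <- array(0, c(d[1], d[2], dw[4], d[4]))
  for (n in seq_len(d[4])) for (co in seq_len(dw[4]))
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      s <- b[co]
      for (a in seq_len(dw[1])) for (bb in seq_len(dw[2])) for (c in seq_len(dw[3])) {
        ii <- i + dil * (a - 1) - pad
        jj <- j + dil * (bb - 1) - pad
        if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2])
          s <- s + x[ii, jj, c, n] * w[a, bb, c, co]
      }
      y[i, j, co, n] <- s
    }
  y
}

# brute-force 95th-percentile Hausdorff over boundary pixels
hd95_oracle <- function(pred, gt) {
  boundary <- function(m) {
    d <- dim(m)
    keep <- matrix(FALSE, d[1], d[2])
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      if (!m[i, j]) next
      nb <- c(if (i > 1) m[i - 1, j] else FALSE,
              if (i < d[1]) m[i + 1, j] else FALSE,
              if (j > 1) m[i, j - 1] else FALSE,
              if (j < d[2]) m[i, j + 1] else FALSE)
      keep[i, j] <- !all(nb)
    }
    keep
  }
  pa <- which(boundary(pred), arr.ind = TRUE)
  ga <- which(boundary(gt), arr.ind = TRUE)
  directed <- function(a, b) {
    mins <- apply(a, 1, function(p) min(sqrt((p[1] - b[, 1])^2 + (p[2] - b[, 2])^2)))
    quantile(mins, 0.95, names = FALSE)
  }
  max(directed(pa, ga), directed(ga, pa))
}

tiny_phantom_spec <- function(size = 32L, seed = 5L, ...) {
  phantom_spec(image_size = size, region_radii = c(10, 6, 3), noise_sd = 3,
               seed = seed, ...)
}

# single feature map (C,H,W) filled from a seeded stream
toy_map <- function(C, H, W, seed = 1) {
  set.seed(seed)
  array(rnorm(C * H * W), c(C, H, W))
}
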