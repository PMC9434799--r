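# Minimal reverse-mode autodiff tape.
#
# Feature maps are stored as column-major arrays (H, W, C, N); convolution
# weights as (kh, kw, Cin, Cout).  A node is an environment holding the value,
# the accumulated gradient and a backward closure that scatters the incoming
# gradient onto the node's parents.  Parameters are nodes that live outside
# the tape and persist across steps.

mm_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

mm_node <- function(tape, val, bw = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$bw <- bw
  nd$param <- FALSE
  if (!is.null(tape)) {
    tape$n <- tape$n + 1L
    if (tape$n > length(tape$nodes)) tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    tape$nodes[[tape$n]] <- nd
  }
  nd
}

mm_param <- function(val) {
  nd <- mm_node(NULL, val)
  nd$param <- TRUE
  nd
}

mm_acc <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

#' @keywords internal
mm_backward <- function(tape, loss) {
  loss$grad <- 1
  for (k in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[k]]
    if (!is.null(nd$grad) && !is.null(nd$bw)) nd$bw(nd$grad)
  }
  invisible(NULL)
}

dim4 <- function(v) {
  d <- dim(v)
  stopifnot(length(d) == 4L)
  d
}

# ---- convolution / pooling ops -------------------------------------------

op_conv2d <- function(tape, x, w, b, dilation = 1L, pad = NULL) {
  kh <- dim(w$val)[1]
  if (is.null(pad)) pad <- as.integer(dilation * (kh - 1L) / 2L)
  y <- .cpp_conv2d_fw(x$val, w$val, b$val, as.integer(dilation), as.integer(pad))
  mm_node(tape, y, bw = function(g) {
    r <- .cpp_conv2d_bw(x$val, w$val, g, as.integer(dilation), as.integer(pad))
    mm_acc(x, r$gx); mm_acc(w, r$gw); mm_acc(b, r$gb)
  })
}

op_convt2d <- function(tape, x, w, b) {
  y <- .cpp_convt2d_fw(x$val, w$val, b$val)
  mm_node(tape, y, bw = function(g) {
    r <- .cpp_convt2d_bw(x$val, w$val, g)
    mm_acc(x, r$gx); mm_acc(w, r$gw); mm_acc(b, r$gb)
  })
}

op_maxpool2 <- function(tape, x) {
  r <- .cpp_maxpool2_fw(x$val)
  din <- dim4(x$val)
  mm_node(tape, r$y, bw = function(g) {
    mm_acc(x, .cpp_maxpool2_bw(r$idx, g, as.integer(din)))
  })
}

# ---- elementwise ops ------------------------------------------------------

op_relu <- function(tape, x) {
  y <- x$val
  y[y < 0] <- 0
  mm_node(tape, y, bw = function(g) mm_acc(x, g * (x$val > 0)))
}

op_sigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-x$val))
  mm_node(tape, s, bw = function(g) mm_acc(x, g * s * (1 - s)))
}

op_add <- function(tape, a, b) {
  mm_node(tape, a$val + b$val, bw = function(g) { mm_acc(a, g); mm_acc(b, g) })
}

op_sub <- function(tape, a, b) {
  mm_node(tape, a$val - b$val, bw = function(g) { mm_acc(a, g); mm_acc(b, -g) })
}

# multiply a feature map (H,W,C,N) by a per-channel mask (C,N)
op_cmul <- function(tape, x, m) {
  d <- dim4(x$val); HW <- d[1] * d[2]
  mrep <- array(rep(m$val, each = HW), d)
  mm_node(tape, x$val * mrep, bw = function(g) {
    mm_acc(x, g * mrep)
    gm <- colSums(matrix(g * x$val, HW, d[3] * d[4]))
    mm_acc(m, matrix(gm, d[3], d[4]))
  })
}

# multiply a feature map (H,W,C,N) by a spatial mask (H,W,1,N)
op_smul <- function(tape, x, m) {
  d <- dim4(x$val); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  mrep <- array(m$val[, , rep(1L, C), , drop = FALSE], d)
  mm_node(tape, x$val * mrep, bw = function(g) {
    mm_acc(x, g * mrep)
    tmp <- g * x$val
    dim(tmp) <- c(HW, C, N)
    gm <- colSums(aperm(tmp, c(2L, 1L, 3L)))      # sum over channels
    mm_acc(m, array(gm, c(d[1], d[2], 1L, N)))
  })
}

op_concat_c <- function(tape, xs) {
  d1 <- dim4(xs[[1]]$val)
  chans <- vapply(xs, function(x) dim4(x$val)[3], numeric(1))
  Ctot <- sum(chans)
  y <- array(0, c(d1[1], d1[2], Ctot, d1[4]))
  at <- 0L
  for (x in xs) {
    C <- dim4(x$val)[3]
    y[, , at + seq_len(C), ] <- x$val
    at <- at + C
  }
  mm_node(tape, y, bw = function(g) {
    at <- 0L
    for (x in xs) {
      C <- dim4(x$val)[3]
      mm_acc(x, g[, , at + seq_len(C), , drop = FALSE])
      at <- at + C
    }
  })
}

# ---- global pooling over the spatial plane (one value per channel) --------

op_gap_c <- function(tape, x) {
  d <- dim4(x$val); HW <- d[1] * d[2]
  m <- matrix(colMeans(matrix(x$val, HW, d[3] * d[4])), d[3], d[4])
  mm_node(tape, m, bw = function(g) {
    mm_acc(x, array(rep(g / HW, each = HW), d))
  })
}

op_gmp_c <- function(tape, x, minimum = FALSE) {
  d <- dim4(x$val); HW <- d[1] * d[2]; CN <- d[3] * d[4]
  M <- matrix(x$val, HW, CN)
  if (minimum) M <- -M
  idx <- max.col(t(M), ties.method = "first")
  v <- M[cbind(idx, seq_len(CN))]
  if (minimum) v <- -v
  mm_node(tape, matrix(v, d[3], d[4]), bw = function(g) {
    gx <- array(0, d)
    gx[idx + (seq_len(CN) - 1L) * HW] <- g
    mm_acc(x, gx)
  })
}

# ---- pooling across the channel axis (one value per pixel) ----------------

op_pool_s <- function(tape, x, type = c("mean", "max", "min")) {
  type <- match.arg(type)
  d <- dim4(x$val); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  tmp <- x$val
  dim(tmp) <- c(HW, C, N)
  P <- aperm(tmp, c(2L, 1L, 3L))                  # (C, HW, N)
  M <- matrix(P, C, HW * N)
  if (type == "mean") {
    v <- colMeans(M)
    nd <- mm_node(tape, array(v, c(d[1], d[2], 1L, N)), bw = function(g) {
      gr <- array(as.vector(g) / C, c(HW, N))
      gx <- array(0, c(HW, C, N))
      for (cc in seq_len(C)) gx[, cc, ] <- gr
      dim(gx) <- d
      mm_acc(x, gx)
    })
    return(nd)
  }
  Mm <- if (type == "min") -M else M
  idx <- max.col(t(Mm), ties.method = "first")    # argmax channel per (pixel, image)
  v <- Mm[cbind(idx, seq_len(HW * N))]
  if (type == "min") v <- -v
  mm_node(tape, array(v, c(d[1], d[2], 1L, N)), bw = function(g) {
    gx <- array(0, c(C, HW, N))
    gx[idx + (seq_len(HW * N) - 1L) * C] <- as.vector(g)
    gx <- aperm(gx, c(2L, 1L, 3L))
    dim(gx) <- d
    mm_acc(x, gx)
  })
}

# ---- dense layer on channel vectors (Cin, N) ------------------------------

op_dense <- function(tape, x, w, b) {
  y <- w$val %*% x$val + b$val
  mm_node(tape, y, bw = function(g) {
    mm_acc(w, g %*% t(x$val))
    mm_acc(b, rowSums(g))
    mm_acc(x, t(w$val) %*% g)
  })
}

# broadcast a per-channel vector (C, N) back to (H, W, C, N)
op_broadcast_c <- function(tape, x, H, W) {
  d <- dim(x$val); HW <- H * W
  y <- array(rep(x$val, each = HW), c(H, W, d[1], d[2]))
  mm_node(tape, y, bw = function(g) {
    mm_acc(x, matrix(colSums(matrix(g, HW, d[1] * d[2])), d[1], d[2]))
  })
}

# ---- batch normalization --------------------------------------------------

# state: environment with running_mean / running_var (length C)
op_bn <- function(tape, x, gamma, beta, state, training, momentum = 0.1, eps = 1e-5) {
  d <- dim4(x$val); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  m <- HW * N
  bc <- function(vc) {            # per-channel vector -> (H,W,C,N) broadcast
    array(rep(rep(vc, each = HW), times = N), d)
  }
  csum <- function(a) {           # sum over (H,W,N) per channel
    tmp <- a; dim(tmp) <- c(HW, C, N)
    rowSums(colSums(tmp))
  }
  if (training) {
    mu <- csum(x$val) / m
    xc <- x$val - bc(mu)
    va <- csum(xc * xc) / m
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var  <- (1 - momentum) * state$running_var +
      momentum * va * m / max(m - 1, 1)
  } else {
    mu <- state$running_mean
    va <- state$running_var
    xc <- x$val - bc(mu)
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- xc * bc(istd)
  y <- xhat * bc(gamma$val) + bc(beta$val)
  mm_node(tape, y, bw = function(g) {
    mm_acc(gamma, csum(g * xhat))
    mm_acc(beta, csum(g))
    gxhat <- g * bc(gamma$val)
    if (training) {
      gvar <- csum(gxhat * xc) * (-0.5) * istd^3
      gmu <- -csum(gxhat) * istd + gvar * (-2) * csum(xc) / m
      gx <- gxhat * bc(istd) + bc(gvar) * 2 * xc / m + bc(gmu / m)
      mm_acc(x, gx)
    } else {
      mm_acc(x, gxhat * bc(istd))
    }
  })
}

# ---- softmax over the class (channel) axis --------------------------------

op_softmax_c <- function(tape, x) {
  d <- dim4(x$val); C <- d[3]
  mx <- x$val[, , 1, , drop = FALSE]
  for (cc in seq_len(C)[-1]) mx <- pmax(mx, x$val[, , cc, , drop = FALSE])
  e <- exp(x$val - array(mx[, , rep(1L, C), , drop = FALSE], d))
  s <- e[, , 1, , drop = FALSE]
  for (cc in seq_len(C)[-1]) s <- s + e[, , cc, , drop = FALSE]
  p <- e / array(s[, , rep(1L, C), , drop = FALSE], d)
  mm_node(tape, p, bw = function(g) {
    dot <- g[, , 1, , drop = FALSE] * p[, , 1, , drop = FALSE]
    for (cc in seq_len(C)[-1]) dot <- dot + g[, , cc, , drop = FALSE] * p[, , cc, , drop = FALSE]
    mm_acc(x, p * (g - array(dot[, , rep(1L, C), , drop = FALSE], d)))
  })
}
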