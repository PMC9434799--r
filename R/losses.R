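# Compound segmentation objective: Dice loss + focal loss, averaged over
# the classification categories.

#' Loss configuration
#'
#' @param alpha weight of the Dice term.
#' @param beta weight of the focal term.
#' @param gamma focal modulating exponent.
#' @param epsilon Dice smoothing constant guarding the empty-empty case.
#' @param prob_floor clipping floor keeping predictions away from 0 and 1
#'   inside the focal log terms.
#' @param include_background whether the background class participates in
#'   the per-category average.
#' @export
loss_config <- function(alpha = 0.1, beta = 0.9, gamma = 2, epsilon = 1e-5,
                        prob_floor = 1e-7, include_background = TRUE) {
  stopifnot(alpha >= 0, beta >= 0, gamma >= 0, epsilon > 0,
            prob_floor > 0, prob_floor < 0.5)
  list(alpha = alpha, beta = beta, gamma = gamma, epsilon = epsilon,
       prob_floor = prob_floor, include_background = isTRUE(include_background))
}

#' Dice loss for one class plane
#'
#' `1 - (2 * sum(y * p) + eps) / (sum(y) + sum(p) + eps)`; the smoothing
#' constant makes the loss 0 when both prediction and truth are empty.
#'
#' @param y ground-truth indicator values.
#' @param p predicted probabilities, same length.
#' @param epsilon smoothing constant.
#' @export
dice_loss <- function(y, p, epsilon = 1e-5) {
  stopifnot(length(y) == length(p))
  1 - (2 * sum(y * p) + epsilon) / (sum(y) + sum(p) + epsilon)
}

#' Focal loss for one class plane
#'
#' `sum(-y (1-p)^gamma log p - (1-y) p^gamma log(1-p))`, summed over pixels.
#' At `gamma = 0` this is the summed binary cross-entropy.  Predictions are
#' clipped to `[floor, 1 - floor]` before the logarithms.
#'
#' @inheritParams dice_loss
#' @param gamma modulating exponent.
#' @param prob_floor clipping floor.
#' @export
focal_loss <- function(y, p, gamma = 2, prob_floor = 1e-7) {
  stopifnot(length(y) == length(p))
  p <- pmin(pmax(p, prob_floor), 1 - prob_floor)
  sum(-y * (1 - p)^gamma * log(p) - (1 - y) * p^gamma * log(1 - p))
}

#' Combined per-image loss
#'
#' For each class plane the weighted sum `alpha * Dice + beta * Focal` is
#' computed, then averaged over the classes.
#'
#' @param prob predicted class probabilities, array (H, W, classes).
#' @param onehot one-hot ground truth of identical shape.
#' @param cfg a [loss_config()].
#' @export
combined_loss <- function(prob, onehot, cfg = loss_config()) {
  stopifnot(identical(dim(prob), dim(onehot)))
  C <- dim(prob)[3]
  cls <- if (cfg$include_background) seq_len(C) else seq_len(C)[-1]
  per <- vapply(cls, function(cc) {
    y <- as.vector(onehot[, , cc]); p <- as.vector(prob[, , cc])
    cfg$alpha * dice_loss(y, p, cfg$epsilon) +
      cfg$beta * focal_loss(y, p, cfg$gamma, cfg$prob_floor)
  }, numeric(1))
  mean(per)
}

# gradient of alpha*dice + beta*focal wrt the probability plane
loss_grad_plane <- function(y, p, cfg) {
  sy <- sum(y); sp <- sum(p); syp <- sum(y * p)
  den <- sy + sp + cfg$epsilon
  gdice <- -(2 * y * den - (2 * syp + cfg$epsilon)) / den^2
  fl <- cfg$prob_floor
  inside <- p > fl & p < 1 - fl
  pc <- pmin(pmax(p, fl), 1 - fl)
  g <- cfg$gamma
  # d/dp [-y (1-p)^g log p]  and  d/dp [-(1-y) p^g log(1-p)]
  t1 <- -y * (-g * (1 - pc)^(g - 1) * log(pc) + (1 - pc)^g / pc)
  t2 <- -(1 - y) * (g * pc^(g - 1) * log(1 - pc) - pc^g / (1 - pc))
  gfocal <- t1 + t2
  gfocal[!inside] <- 0
  cfg$alpha * gdice + cfg$beta * gfocal
}

# tape op: mean over images and classes of the combined loss, on a
# probability node (H, W, C, N) against a one-hot array of the same shape
op_seg_loss <- function(tape, prob, onehot, cfg) {
  d <- dim4(prob$val)
  C <- d[3]; N <- d[4]
  cls <- if (cfg$include_background) seq_len(C) else seq_len(C)[-1]
  tot <- 0
  for (n in seq_len(N)) for (cc in cls) {
    y <- as.vector(onehot[, , cc, n]); p <- as.vector(prob$val[, , cc, n])
    tot <- tot + cfg$alpha * dice_loss(y, p, cfg$epsilon) +
      cfg$beta * focal_loss(y, p, cfg$gamma, cfg$prob_floor)
  }
  val <- tot / (length(cls) * N)
  mm_node(tape, val, bw = function(g) {
    gp <- array(0, d)
    for (n in seq_len(N)) for (cc in cls) {
      y <- as.vector(onehot[, , cc, n]); p <- as.vector(prob$val[, , cc, n])
      gp[, , cc, n] <- loss_grad_plane(y, p, cfg) / (length(cls) * N)
    }
    mm_acc(prob, g * gp)
  })
}

#' One-hot encode a label map
#'
#' @param labels integer matrix with values in `0:(classes-1)`.
#' @param classes number of classes.
#' @return array (H, W, classes).
#' @export
one_hot <- function(labels, classes = 4L) {
  d <- dim(labels)
  out <- array(0, c(d[1], d[2], classes))
  for (cc in seq_len(classes)) out[, , cc] <- (labels == cc - 1L)
  out
}
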