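# Seeded training and evaluation loops.

#' Training configuration
#'
#' Defaults follow the reference optimization protocol: Adam with learning
#' rate 1e-5, batch size 8, 15 epochs; no augmentation, scheduler or weight
#' decay.
#'
#' @param batch_size minibatch size.
#' @param epochs number of passes over the dataset.
#' @param learning_rate Adam step size.
#' @param seed seed controlling shuffling (weights are seeded at build).
#' @param loss a [loss_config()].
#' @param max_steps optional cap on the total number of optimization steps.
#' @param checkpoint_path optional path; when set, weights are saved there
#'   after the final step.
#' @export
train_config <- function(batch_size = 8L, epochs = 15L, learning_rate = 1e-5,
                         seed = 1L, loss = loss_config(), max_steps = NULL,
                         checkpoint_path = NULL) {
  stopifnot(batch_size >= 1, epochs >= 1, learning_rate > 0)
  list(batch_size = as.integer(batch_size), epochs = as.integer(epochs),
       learning_rate = learning_rate, seed = as.integer(seed), loss = loss,
       max_steps = max_steps, checkpoint_path = checkpoint_path)
}

adam_state <- function(params) {
  list(m = lapply(params, function(p) p$val * 0),
       v = lapply(params, function(p) p$val * 0),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- p$grad
    if (is.null(g)) next
    st$m[[i]] <- beta1 * st$m[[i]] + (1 - beta1) * g
    st$v[[i]] <- beta2 * st$v[[i]] + (1 - beta2) * g * g
    p$val <- p$val - lr * (st$m[[i]] / bc1) / (sqrt(st$v[[i]] / bc2) + eps)
  }
  st
}

batch_arrays <- function(dataset, idx, classes) {
  d <- dim(dataset[[idx[1]]]$images)
  x <- array(0, c(d[1], d[2], d[3], length(idx)))
  y <- array(0, c(d[1], d[2], classes, length(idx)))
  for (j in seq_along(idx)) {
    sp <- dataset[[idx[j]]]
    x[, , , j] <- sp$images
    y[, , , j] <- one_hot(sp$labels, classes)
  }
  list(x = x, y = y)
}

#' Train a network
#'
#' Runs seeded minibatch optimization of the combined Dice + focal loss
#' with Adam.  Data order is reshuffled each epoch from the configured
#' seed; two runs with identical seeds give identical loss histories.
#'
#' @param net an `mm_network` from [build_network()].
#' @param dataset nonempty list of slice pairs (see [extract_slices()] /
#'   [phantom_slice()]).
#' @param cfg a [train_config()].
#' @param verbose print one line per epoch.
#' @return the network, invisibly modified in place, with a `history`
#'   attribute: data frame of per-step losses (`step`, `epoch`, `loss`).
#' @export
train_network <- function(net, dataset, cfg = train_config(), verbose = FALSE) {
  if (length(dataset) == 0) stop("empty training dataset")
  classes <- net$config$classes
  params <- network_params(net)
  st <- adam_state(params)
  set.seed(cfg$seed)
  hist <- list()
  step <- 0L
  done <- FALSE
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(length(dataset))
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    ep_losses <- c()
    for (bi in batches) {
      ba <- batch_arrays(dataset, bi, classes)
      tape <- mm_tape()
      scores <- forward(net, ba$x, training = TRUE, tape = tape, as_node = TRUE)
      prob <- op_softmax_c(tape, scores)
      loss <- op_seg_loss(tape, prob, ba$y, cfg$loss)
      for (p in params) p$grad <- NULL
      mm_backward(tape, loss)
      st <- adam_step(params, st, cfg$learning_rate)
      step <- step + 1L
      hist[[step]] <- data.frame(step = step, epoch = ep, loss = loss$val)
      ep_losses <- c(ep_losses, loss$val)
      if (!is.null(cfg$max_steps) && step >= cfg$max_steps) { done <- TRUE; break }
    }
    if (verbose)
      message(sprintf("epoch %d  mean loss %.5f", ep, mean(ep_losses)))
    if (done) break
  }
  if (!is.null(cfg$checkpoint_path)) save_weights(net, cfg$checkpoint_path)
  attr(net, "history") <- do.call(rbind, hist)
  invisible(net)
}

#' Predict label maps
#'
#' @param net an `mm_network`.
#' @param dataset list of slice pairs.
#' @return list of integer label matrices (argmax over class scores).
#' @export
predict_labels <- function(net, dataset) {
  lapply(dataset, function(sp) {
    sc <- forward(net, sp$images, training = FALSE)
    d <- dim(sc)
    lab <- matrix(0L, d[1], d[2])
    best <- sc[, , 1, 1]
    for (cc in seq_len(d[3])[-1]) {
      m <- sc[, , cc, 1]
      upd <- m > best
      lab[upd] <- cc - 1L
      best[upd] <- m[upd]
    }
    lab
  })
}

#' Evaluate a network on a dataset
#'
#' Applies [score_case()] to the argmax prediction of every slice.
#'
#' @param net an `mm_network`.
#' @param dataset nonempty list of slice pairs.
#' @return data frame of per-slice, per-region records.
#' @export
evaluate_network <- function(net, dataset) {
  if (length(dataset) == 0) stop("empty evaluation dataset")
  preds <- predict_labels(net, dataset)
  do.call(rbind, lapply(seq_along(dataset), function(i) {
    sp <- dataset[[i]]
    score_case(preds[[i]], sp$labels,
               case = paste0(sp$case, "_s", sp$slice))
  }))
}
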