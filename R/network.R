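# Assembly of the four-encoder / single-decoder segmentation network.
#
# Encoder (per modality): residual conv -> [HAB tap for the skip] -> 2x2 max
# pool, repeated over `depth` stages with channel widths base, 2*base, ...
# The DCB is inserted per encoder path after the configured pooling stage.
# The four encoder bottoms are fused by channel concatenation, expanded by a
# plain double conv bottleneck, and decoded stage-by-stage: channel-
# preserving 2x2 stride-2 deconvolution, concatenation with the four
# (attention-refined) skip features, then a residual double conv back to the
# stage width with a 1x1-projected shortcut.  A final 1x1 convolution maps
# to the class scores.

#' Network configuration
#'
#' @param modalities number of imaging modalities / encoders (4).
#' @param classes number of output classes (4).
#' @param base_channels first-stage channel width; widths double per stage.
#' @param depth number of encoder stages.
#' @param hab_enabled,hab_order,hab_reduction hybrid attention switches:
#'   enable flag, mask order (`"channel_first"`, `"spatial_first"`,
#'   `"parallel"`) and MLP reduction ratio r.
#' @param dcb_enabled,dcb_position dilated-convolution-block switch and
#'   insertion point (`"after_stage2"` or `"after_stage4"`).
#' @param final_kernel output-layer kernel size, 1 or 3.
#' @param input_size nominal square input size; must be divisible by
#'   `2^depth`.
#' @return a validated `mm_config` list.
#' @export
network_config <- function(modalities = 4L, classes = 4L, base_channels = 32L,
                           depth = 4L, hab_enabled = TRUE,
                           hab_order = "channel_first", hab_reduction = 1L,
                           dcb_enabled = TRUE, dcb_position = "after_stage2",
                           final_kernel = 1L, input_size = 160L) {
  cfg <- list(modalities = as.integer(modalities), classes = as.integer(classes),
              base_channels = as.integer(base_channels), depth = as.integer(depth),
              hab_enabled = isTRUE(hab_enabled), hab_order = hab_order,
              hab_reduction = as.integer(hab_reduction),
              dcb_enabled = isTRUE(dcb_enabled), dcb_position = dcb_position,
              final_kernel = as.integer(final_kernel),
              input_size = as.integer(input_size))
  if (cfg$input_size %% 2^cfg$depth != 0)
    stop("input_size must be divisible by ", 2^cfg$depth)
  if (!cfg$dcb_position %in% c("after_stage2", "after_stage4"))
    stop("dcb_position must be 'after_stage2' or 'after_stage4'")
  if (!cfg$hab_order %in% c("channel_first", "spatial_first", "parallel"))
    stop("hab_order must be one of channel_first, spatial_first, parallel")
  if (!cfg$final_kernel %in% c(1L, 3L)) stop("final_kernel must be 1 or 3")
  if (cfg$base_channels < 1) stop("base_channels must be positive")
  cfg$widths <- cfg$base_channels * 2^(seq_len(cfg$depth) - 1L)
  structure(cfg, class = "mm_config")
}

#' Named architecture variants
#'
#' `"baseline"` disables HAB and DCB; `"dcb_only"` / `"hab_only"` enable one
#' block; `"full"` enables both (channel-first attention, DCB after the
#' second downsampling); `"spatial_first"`, `"parallel_attention"` and
#' `"dcb_after_stage4"` are the control-experiment variants.
#'
#' @param name variant name.
#' @param ... overrides passed on to [network_config()] (e.g.
#'   `base_channels`, `input_size` for desk-scale runs).
#' @export
make_variant <- function(name, ...) {
  valid <- c("baseline", "dcb_only", "hab_only", "full", "spatial_first",
             "parallel_attention", "dcb_after_stage4")
  if (!name %in% valid)
    stop("unknown variant '", name, "'; valid: ", paste(valid, collapse = ", "))
  args <- switch(name,
    baseline = list(hab_enabled = FALSE, dcb_enabled = FALSE),
    dcb_only = list(hab_enabled = FALSE, dcb_enabled = TRUE),
    hab_only = list(hab_enabled = TRUE, dcb_enabled = FALSE),
    full = list(),
    spatial_first = list(hab_order = "spatial_first"),
    parallel_attention = list(hab_order = "parallel"),
    dcb_after_stage4 = list(dcb_position = "after_stage4"))
  do.call(network_config, utils::modifyList(args, list(...)))
}

#' Build the network
#'
#' @param config an `mm_config` from [network_config()] or [make_variant()].
#' @param init `"kaiming"` or `"zero"` weight initialization.
#' @param seed integer seed for the weight initialization stream.
#' @return an `mm_network` holding all parameter nodes.
#' @export
build_network <- function(config, init = "kaiming", seed = 1L) {
  stopifnot(inherits(config, "mm_config"))
  set.seed(seed)
  W <- config$widths
  depth <- config$depth
  enc <- lapply(seq_len(config$modalities), function(m) {
    stages <- lapply(seq_len(depth), function(s) {
      st <- list(res = block_residual(if (s == 1) 1L else W[s - 1], W[s], init))
      if (config$hab_enabled)
        st$hab <- block_hab(W[s], config$hab_reduction, config$hab_order, init)
      st
    })
    if (config$dcb_enabled) {
      ds <- if (config$dcb_position == "after_stage2") 2L else depth
      stages[[ds]]$dcb <- block_dcb(W[ds], init)
    }
    stages
  })
  fused <- config$modalities * W[depth]                 # channels after fusion
  bneck <- list(conv1 = make_conv(3, 3, fused, fused, init), bn1 = make_bn(fused),
                conv2 = make_conv(3, 3, fused, 2 * fused, init), bn2 = make_bn(2 * fused))
  dec <- lapply(rev(seq_len(depth)), function(s) {
    cprev <- if (s == depth) 2 * fused else config$modalities * W[s + 1]
    skip <- config$modalities * W[s]
    out <- config$modalities * W[s]                    # decoder stage widths 4*W
    list(up = make_deconv(cprev, cprev, init),
         res = block_residual(cprev + skip, out, init),
         stage = s)
  })
  outc <- make_conv(config$final_kernel, config$final_kernel,
                    config$modalities * W[1], config$classes, init)
  net <- structure(list(config = config, encoders = enc, bottleneck = bneck,
                        decoder = dec, out = outc), class = "mm_network")
  net
}

#' Forward pass
#'
#' @param net an `mm_network`.
#' @param x input batch: numeric array (H, W, modalities, N) with the
#'   modality axis ordered (T1, T1c, T2, FLAIR).  A single (H, W,
#'   modalities) stack is promoted to a batch of one.
#' @param training logical; `TRUE` uses batch statistics in batch
#'   normalization, `FALSE` the running statistics.
#' @param tape optional autodiff tape (used by the training loop).
#' @param as_node return the output node instead of its value.
#' @return class-score array (H, W, classes, N), same spatial size as the
#'   input.
#' @export
forward <- function(net, x, training = FALSE, tape = NULL, as_node = FALSE) {
  cfg <- net$config
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  if (d[3] != cfg$modalities)
    stop("expected ", cfg$modalities, " modality channels, got ", d[3])
  if (d[1] %% 2^cfg$depth != 0 || d[2] %% 2^cfg$depth != 0)
    stop("spatial size must be divisible by ", 2^cfg$depth)
  if (is.null(tape)) tape <- mm_tape()
  skips <- vector("list", cfg$depth)           # skips[[s]][[m]]
  for (s in seq_len(cfg$depth)) skips[[s]] <- vector("list", cfg$modalities)
  bottoms <- vector("list", cfg$modalities)
  for (m in seq_len(cfg$modalities)) {
    f <- mm_node(tape, x[, , m, , drop = FALSE])
    for (s in seq_len(cfg$depth)) {
      st <- net$encoders[[m]][[s]]
      f <- forward_residual(tape, st$res, f, training)
      skips[[s]][[m]] <- if (cfg$hab_enabled) forward_hab(tape, st$hab, f) else f
      f <- op_maxpool2(tape, f)
      if (!is.null(st$dcb)) f <- forward_dcb(tape, st$dcb, f)
    }
    bottoms[[m]] <- f
  }
  f <- op_concat_c(tape, bottoms)
  f <- op_relu(tape, op_bn(tape, op_conv2d(tape, f, net$bottleneck$conv1$w, net$bottleneck$conv1$b),
                           net$bottleneck$bn1$gamma, net$bottleneck$bn1$beta,
                           net$bottleneck$bn1$state, training))
  f <- op_relu(tape, op_bn(tape, op_conv2d(tape, f, net$bottleneck$conv2$w, net$bottleneck$conv2$b),
                           net$bottleneck$bn2$gamma, net$bottleneck$bn2$beta,
                           net$bottleneck$bn2$state, training))
  for (stg in net$decoder) {
    f <- op_convt2d(tape, f, stg$up$w, stg$up$b)
    skip <- op_concat_c(tape, skips[[stg$stage]])
    f <- forward_residual(tape, stg$res, op_concat_c(tape, list(f, skip)), training)
  }
  out <- op_conv2d(tape, f, net$out$w, net$out$b)
  if (as_node) out else out$val
}

#' All parameter nodes of a network
#' @keywords internal
network_params <- function(net) {
  out <- list()
  walk <- function(x) {
    if (is.environment(x)) {
      if (isTRUE(x$param)) out[[length(out) + 1L]] <<- x
    } else if (is.list(x)) for (el in x) walk(el)
  }
  walk(list(net$encoders, net$bottleneck, net$decoder, net$out))
  out
}

#' Count learnable parameters
#'
#' Counts every learnable scalar: convolution and deconvolution kernels and
#' biases, batch-norm scale/shift, and attention MLP weights.
#'
#' @param net an `mm_network`.
#' @return integer-valued double.
#' @export
count_parameters <- function(net) {
  sum(vapply(network_params(net), function(p) length(p$val), numeric(1)))
}

#' Per-stage shape summary
#'
#' Reports the output shape of every encoder and decoder operation for the
#' configured input size, using the `modalities@H*W*C` notation for the
#' per-modality encoder paths and `H*W*C` once the modalities are fused.
#'
#' @param net an `mm_network` (or an `mm_config`).
#' @return data frame with columns `stage`, `path`, `op`, `shape`.
#' @export
model_summary <- function(net) {
  cfg <- if (inherits(net, "mm_config")) net else net$config
  sz <- cfg$input_size
  M <- cfg$modalities
  W <- cfg$widths
  fused <- M * W[cfg$depth]
  fmt <- function(h, w, c, m = NULL) {
    s <- paste0(h, "*", w, "*", format(c, big.mark = ",", trim = TRUE))
    if (is.null(m)) s else paste0(m, "@", s)
  }
  rows <- list()
  add <- function(stage, path, op, shape)
    rows[[length(rows) + 1L]] <<- data.frame(stage = stage, path = path,
                                             op = op, shape = shape)
  add(1, "encoder", "Input", fmt(sz, sz, 1, M))
  s_sz <- sz
  for (s in seq_len(cfg$depth)) {
    add(s, "encoder", "Conv2D [3*3, BatchNorm, ReLU] Conv2D [3*3, BatchNorm, ReLU]",
        fmt(s_sz, s_sz, W[s], M))
    s_sz <- s_sz / 2
    add(s, "encoder", "Max Pooling [2*2]", fmt(s_sz, s_sz, W[s], M))
  }
  add(5, "encoder", "Multimodal Fusion", fmt(s_sz, s_sz, fused))
  add(5, "decoder", "Conv2D [3*3, BatchNorm, ReLU] Conv2D [3*3, BatchNorm, ReLU]",
      fmt(s_sz, s_sz, 2 * fused))
  for (s in rev(seq_len(cfg$depth))) {
    cprev <- if (s == cfg$depth) 2 * fused else M * W[s + 1]
    add(s, "decoder", "Upsampling (Deconvolution layer) [2*2, strides = 2*2]",
        fmt(2 * s_sz, 2 * s_sz, cprev))
    s_sz <- 2 * s_sz
    add(s, "decoder", "Conv2D [3*3, BatchNorm, ReLU] Conv2D [3*3, BatchNorm, ReLU]",
        fmt(s_sz, s_sz, M * W[s]))
  }
  add(1, "decoder", sprintf("Conv2D [output Layer] [%d*%d]", cfg$final_kernel, cfg$final_kernel),
      fmt(sz, sz, cfg$classes))
  do.call(rbind, rows)
}

#' Save / load network weights
#'
#' Weights, biases and batch-norm running statistics are serialized to a
#' single RDS archive.
#' @param net an `mm_network`.
#' @param path file path.
#' @export
save_weights <- function(net, path) {
  ps <- network_params(net)
  bn <- collect_bn_states(net)
  saveRDS(list(params = lapply(ps, function(p) p$val),
               bn = lapply(bn, function(st) list(mean = st$running_mean,
                                                 var = st$running_var))), path)
  invisible(path)
}

#' @rdname save_weights
#' @export
load_weights <- function(net, path) {
  arch <- readRDS(path)
  ps <- network_params(net)
  if (length(ps) != length(arch$params)) stop("weight archive does not match the network")
  for (i in seq_along(ps)) {
    if (!identical(dim(ps[[i]]$val), dim(arch$params[[i]])) &&
        length(ps[[i]]$val) != length(arch$params[[i]]))
      stop("parameter ", i, " shape mismatch")
    ps[[i]]$val <- arch$params[[i]]
  }
  bn <- collect_bn_states(net)
  for (i in seq_along(bn)) {
    bn[[i]]$running_mean <- arch$bn[[i]]$mean
    bn[[i]]$running_var <- arch$bn[[i]]$var
  }
  invisible(net)
}

collect_bn_states <- function(net) {
  out <- list()
  walk <- function(x) {
    if (is.environment(x)) {
      if (!is.null(x$running_mean)) out[[length(out) + 1L]] <<- x
    } else if (is.list(x)) for (el in x) walk(el)
  }
  walk(list(net$encoders, net$bottleneck, net$decoder, net$out))
  out
}
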