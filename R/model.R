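#' Model configuration for the segmentation U-Net
#'
#' The network pairs a ResNet34-topology descending arc (7x7 stem
#' convolution, max pooling, then four stages of 3/4/6/3 basic residual
#' blocks) with a custom ascending arc that upsamples by pixel shuffling
#' (r = 2 per stage) and concatenates one skip connection per resolution
#' level. The full-depth encoder downsamples by a factor of 32, so input
#' sides must be divisible by 32. `width_multiplier` scales every channel
#' count (and `encoder_depth` can drop trailing stages) for CPU-scale runs;
#' the defaults reproduce the full topology.
#'
#' @param input_channels Number of input channels (default 3).
#' @param n_classes Number of output classes; must be 2 (cell, background).
#' @param width_multiplier Multiplies every stage width; default 1.
#' @param encoder_depth Number of residual stages (1-4, default 4).
#' @param base_width Stem width before multiplication (ResNet34: 64).
#' @return A `model_config` list.
#' @export
model_config <- function(input_channels = 3, n_classes = 2,
                         width_multiplier = 1, encoder_depth = 4,
                         base_width = 64) {
  if (n_classes != 2)
    stop_substacks("n_classes must be 2 (cell, background)",
                   "substacks_invalid_config")
  if (!encoder_depth %in% 1:4)
    stop_substacks("encoder_depth must be in 1..4", "substacks_invalid_config")
  widths <- pmax(4L, as.integer(round(base_width * width_multiplier *
                                        c(1, 1, 2, 4, 8))))
  widths <- widths[seq_len(encoder_depth + 1)]  # stem + stages
  structure(list(input_channels = as.integer(input_channels),
                 n_classes = 2L,
                 width_multiplier = width_multiplier,
                 encoder_depth = as.integer(encoder_depth),
                 base_width = as.integer(base_width),
                 widths = widths,
                 blocks_per_stage = c(3L, 4L, 6L, 3L)[seq_len(encoder_depth)],
                 downsample_factor = as.integer(4 * 2^(encoder_depth - 1))),
            class = "model_config")
}

#' Build the segmentation network
#'
#' Constructs the encoder-decoder network described by a [model_config()].
#' Encoder parameters are tagged as a group so they can be frozen together
#' during phase-1 training; parameters also carry a learning-rate group
#' index (earliest encoder stages lowest, decoder and head highest) used by
#' the discriminative 1-cycle schedule. Weights are randomly initialised
#' (He-normal); a previously saved checkpoint, including one holding only
#' user-supplied encoder weights, can be loaded with [load_checkpoint()].
#'
#' @param config A [model_config()].
#' @param seed Integer seed for weight initialisation.
#' @return A `seg_model` object.
#' @export
build_model <- function(config = model_config(), seed = 1L) {
  with_rng(seed, build_model_impl(config))
}

build_model_impl <- function(config) {
  w <- config$widths
  depth <- config$encoder_depth
  m <- new.env(parent = emptyenv())
  m$config <- config

  # ---- descending arc (encoder) ----
  m$stem_conv <- nn_conv(config$input_channels, w[1], 7, 2, 3,
                         arc = "encoder", lr_group = 1L)
  m$stem_bn <- nn_bn(w[1], arc = "encoder", lr_group = 1L)
  m$stem_relu <- nn_relu()
  m$pool <- nn_maxpool(3, 2, 1)
  m$stages <- vector("list", depth)
  for (s in seq_len(depth)) {
    cin <- if (s == 1) w[1] else w[s]
    cout <- w[s + 1]
    stride <- if (s == 1) 1 else 2
    grp <- min(s, 4L)
    blocks <- list(nn_basic_block(cin, cout, stride, "encoder", grp))
    for (b in seq_len(config$blocks_per_stage[s] - 1))
      blocks[[b + 1]] <- nn_basic_block(cout, cout, 1, "encoder", grp)
    m$stages[[s]] <- do.call(nn_seq, blocks)
  }

  # ---- ascending arc (decoder): pixel-shuffle upsampling + skip concat ----
  dec_grp <- 5L
  up_block <- function(cin, cout) {
    list(conv = nn_conv(cin, cout * 4, 1, 1, 0, "decoder", dec_grp),
         shuf = nn_shuffle(2),
         bn = nn_bn(cout, arc = "decoder", lr_group = dec_grp),
         relu = nn_relu())
  }
  merge_block <- function(cin, cout) {
    list(conv = nn_conv(cin, cout, 3, 1, 1, "decoder", dec_grp),
         bn = nn_bn(cout, arc = "decoder", lr_group = dec_grp),
         relu = nn_relu())
  }
  # skip widths, deepest first: stage depth-1 .. stage1, then stem
  skips <- c(rev(w[seq_len(depth)][-1]), w[1], w[1])
  m$ups <- list(); m$merges <- list()
  cin <- w[depth + 1]
  for (i in seq_len(depth)) {
    cout <- skips[i]
    m$ups[[i]] <- up_block(cin, cout)
    m$merges[[i]] <- merge_block(cout + skips[i], cout)
    cin <- cout
  }
  # final upsample back to input resolution (no skip at full resolution)
  m$ups[[depth + 1]] <- up_block(cin, w[1])
  m$head_conv <- nn_conv(w[1], w[1], 3, 1, 1, "decoder", dec_grp)
  m$head_bn <- nn_bn(w[1], arc = "decoder", lr_group = dec_grp)
  m$head_relu <- nn_relu()
  m$head_out <- nn_conv(w[1], config$n_classes, 1, 1, 0, "decoder", dec_grp)

  collect <- function(x) x$params
  m$params <- c(
    m$stem_conv$params, m$stem_bn$params,
    unlist(lapply(m$stages, collect), recursive = FALSE),
    unlist(lapply(m$ups, function(u)
      c(u$conv$params, u$bn$params)), recursive = FALSE),
    unlist(lapply(m$merges, function(u)
      c(u$conv$params, u$bn$params)), recursive = FALSE),
    m$head_conv$params, m$head_bn$params, m$head_out$params)

  class(m) <- "seg_model"
  m
}

#' @export
print.seg_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, function(p) length(p$v), numeric(1)))
  cat(sprintf(
    "<seg_model> depth %d, widths %s, %s parameters (downsample x%d)\n",
    x$config$encoder_depth, paste(x$config$widths, collapse = "/"),
    format(n_par, big.mark = ","), x$config$downsample_factor))
  invisible(x)
}

check_input_size <- function(model, d) {
  f <- model$config$downsample_factor
  if (d[1] %% f != 0 || d[2] %% f != 0)
    stop_substacks(sprintf(
      "input %d x %d not divisible by the encoder downsampling factor %d; pad the input to a multiple of %d",
      d[1], d[2], f, f), "substacks_bad_input_size")
  invisible(TRUE)
}

#' Forward pass: per-pixel class logits
#'
#' @param model A `seg_model`.
#' @param x Input array (H, W, C) or (H, W, C, N), sides divisible by the
#'   encoder downsampling factor.
#' @param training Use batch statistics and cache activations for a
#'   subsequent backward pass (`TRUE`), or running statistics (`FALSE`).
#' @return Logit array (H, W, n_classes, N); class channel 1 is `cell`,
#'   channel 2 `background`.
#' @export
model_forward <- function(model, x, training = FALSE) {
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1)
  check_input_size(model, dim(x))
  depth <- model$config$encoder_depth
  f0 <- model$stem_relu$forward(
    model$stem_bn$forward(model$stem_conv$forward(x, training), training),
    training)
  feats <- list()
  h <- model$pool$forward(f0, training)
  for (s in seq_len(depth)) {
    h <- model$stages[[s]]$forward(h, training)
    feats[[s]] <- h
  }
  # decoder: skips are stage depth-1, ..., stage1, then the stem feature
  skip_feats <- c(rev(feats[-depth]), list(f0), list(NULL))
  model$skip_widths <- integer(depth)
  for (i in seq_len(depth + 1)) {
    u <- model$ups[[i]]
    h <- u$relu$forward(u$bn$forward(u$shuf$forward(
      u$conv$forward(h, training), training), training), training)
    if (i <= depth) {
      sk <- skip_feats[[i]]
      model$skip_widths[i] <- dim(h)[3]
      h <- concat_channels(h, sk)
      mg <- model$merges[[i]]
      h <- mg$relu$forward(mg$bn$forward(mg$conv$forward(h, training),
                                         training), training)
    }
  }
  h <- model$head_relu$forward(
    model$head_bn$forward(model$head_conv$forward(h, training), training),
    training)
  model$head_out$forward(h, training)
}

# Backward pass for the full network; returns nothing (gradients accumulate
# in the parameter environments).
model_backward <- function(model, dlogits) {
  depth <- model$config$encoder_depth
  dh <- model$head_conv$backward(model$head_bn$backward(
    model$head_relu$backward(model$head_out$backward(dlogits))))
  dskips <- vector("list", depth)
  for (i in rev(seq_len(depth + 1))) {
    if (i <= depth) {
      mg <- model$merges[[i]]
      dh <- mg$conv$backward(mg$bn$backward(mg$relu$backward(dh)))
      c1 <- model$skip_widths[i]
      d <- dim(dh)
      dskips[[i]] <- dh[, , (c1 + 1):d[3], , drop = FALSE]
      dh <- dh[, , seq_len(c1), , drop = FALSE]
    }
    u <- model$ups[[i]]
    dh <- u$conv$backward(u$shuf$backward(u$bn$backward(
      u$relu$backward(dh))))
  }
  # dh now flows into stage `depth`; add stored skip gradients stage by stage
  dstem <- NULL
  for (s in rev(seq_len(depth))) {
    if (s < depth) dh <- dh + dskips[[depth - s]]
    dh <- model$stages[[s]]$backward(dh)
  }
  dstem_extra <- dskips[[depth]]          # gradient into f0 via the skip
  dh <- model$pool$backward(dh)
  dh <- dh + dstem_extra
  model$stem_conv$backward(model$stem_bn$backward(
    model$stem_relu$backward(dh)))
  invisible(NULL)
}

#' Predict a binary mask for one subimage stack
#'
#' Runs the network in inference mode and takes the per-pixel argmax over
#' the two class logits. Ties are assigned to background, biasing against
#' false-positive cell pixels.
#'
#' @param model A `seg_model`.
#' @param sub A `subimage_stack` or (H, W, C) array.
#' @return An H x W 0/1 integer mask.
#' @export
predict_mask <- function(model, sub) {
  x <- subimage_pixels(sub)
  logits <- model_forward(model, x, training = FALSE)
  logits_to_mask(logits[, , , 1])
}

# argmax with ties to background (channel 1 = cell, 2 = background)
logits_to_mask <- function(logits_hw2) {
  m <- 1L * (logits_hw2[, , 1] > logits_hw2[, , 2])
  storage.mode(m) <- "integer"
  m
}

# ---- checkpoints ------------------------------------------------------------

#' Save / load model checkpoints
#'
#' A checkpoint is a single RDS file holding the `model_config`, all
#' parameter values, and the batch-norm running statistics. Loading with
#' `encoder_only = TRUE` copies just the descending-arc parameters into a
#' freshly built model — the hook for user-supplied pretrained encoders.
#'
#' @param model A `seg_model`.
#' @param path File path.
#' @return `load_checkpoint()`: a `seg_model`.
#' @export
save_checkpoint <- function(model, path) {
  state <- list(config = model$config,
                values = lapply(model$params, function(p) p$v),
                arcs = vapply(model$params, function(p) p$arc, character(1)),
                bn = collect_bn_stats(model))
  saveRDS(state, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param encoder_only Copy only encoder ("descending arc") parameters.
#' @param seed Initialisation seed for parameters not present in the file.
#' @export
load_checkpoint <- function(path, encoder_only = FALSE, seed = 1L) {
  state <- readRDS(path)
  model <- build_model(state$config, seed = seed)
  for (i in seq_along(model$params)) {
    if (encoder_only && state$arcs[i] != "encoder") next
    model$params[[i]]$v <- state$values[[i]]
  }
  restore_bn_stats(model, state$bn, encoder_only)
  model
}

bn_layers <- function(model) {
  depth <- model$config$encoder_depth
  bns <- list(model$stem_bn)
  for (s in seq_len(depth))
    for (bl in model$stages[[s]]$layers)
      bns <- c(bns, list(bl$bn1, bl$bn2), if (bl$project) list(bl$bnp))
  for (u in model$ups) bns <- c(bns, list(u$bn))
  for (mg in model$merges) bns <- c(bns, list(mg$bn))
  c(bns, list(model$head_bn))
}

collect_bn_stats <- function(model)
  lapply(bn_layers(model), function(b) list(m = b$run_mean, v = b$run_var))

restore_bn_stats <- function(model, stats, encoder_only = FALSE) {
  bns <- bn_layers(model)
  for (i in seq_along(bns)) {
    if (encoder_only && bns[[i]]$gamma$arc != "encoder") next
    bns[[i]]$run_mean <- stats[[i]]$m
    bns[[i]]$run_var <- stats[[i]]$v
  }
  invisible(model)
}

# Snapshot / restore all parameter values (used by tests and the trainer).
param_snapshot <- function(model, arc = NULL) {
  keep <- if (is.null(arc)) seq_along(model$params)
  else which(vapply(model$params, function(p) p$arc, character(1)) == arc)
  lapply(model$params[keep], function(p) p$v)
}
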