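#' Class weights for the segmentation loss
#'
#' The cross-entropy loss is scaled per pixel by the weight of the pixel's
#' true class. The default halves the background weight: lower background
#' weights produce conservative segmentations with fewer false-positive
#' cell pixels, and 0.5 minimises false positives without materially
#' hurting overall accuracy.
#'
#' @param cell,background Strictly positive weights.
#' @return A named numeric vector.
#' @export
class_weights <- function(cell = 1, background = 0.5) {
  if (cell <= 0 || background <= 0)
    stop_substacks("class weights must be strictly positive",
                   "substacks_invalid_config")
  c(cell = cell, background = background)
}

#' Weighted cross-entropy loss on per-pixel logits
#'
#' Per pixel with true class `cls`,
#' `loss(x, cls) = weight[cls] * (-x[cls] + log(sum_j exp(x[j])))`,
#' evaluated with a numerically stabilised log-sum-exp and aggregated as the
#' arithmetic mean of the weighted per-pixel losses, so a single-pixel loss
#' equals the printed formula exactly.
#'
#' @param logits Array (H, W, 2) or (H, W, 2, N); class channel 1 is cell,
#'   channel 2 background.
#' @param target Binary mask matrix (H, W) or array (H, W, N); 1 = cell.
#' @param weights A [class_weights()] vector.
#' @return Nonnegative scalar loss.
#' @export
#' @examples
#' lg <- array(0, dim = c(1, 1, 2))
#' weighted_cross_entropy(lg, matrix(1, 1, 1))  # log(2)
weighted_cross_entropy <- function(logits, target, weights = class_weights()) {
  wce_loss_grad(logits, target, weights, want_grad = FALSE)$loss
}

wce_loss_grad <- function(logits, target, weights = class_weights(),
                          want_grad = TRUE) {
  if (length(dim(logits)) == 3) dim(logits) <- c(dim(logits), 1)
  d <- dim(logits)
  if (d[3] != 2)
    stop_substacks("logits must have 2 class channels",
                   "substacks_shape_mismatch")
  tv <- as.vector(target)
  if (!all(tv %in% c(0, 1)))
    stop_substacks("target mask must be binary", "substacks_nonbinary_mask")
  if (length(tv) != d[1] * d[2] * d[4])
    stop_substacks("logits and target shapes differ",
                   "substacks_shape_mismatch")
  if (any(weights <= 0))
    stop_substacks("class weights must be strictly positive",
                   "substacks_invalid_config")
  x1 <- as.vector(logits[, , 1, ])             # cell
  x2 <- as.vector(logits[, , 2, ])             # background
  mx <- pmax(x1, x2)
  lse <- mx + log(exp(x1 - mx) + exp(x2 - mx))
  w <- ifelse(tv == 1, weights[["cell"]], weights[["background"]])
  xc <- ifelse(tv == 1, x1, x2)
  n_px <- length(tv)
  loss <- sum(w * (lse - xc)) / n_px
  if (!want_grad) return(list(loss = loss))
  p1 <- exp(x1 - lse)
  p2 <- exp(x2 - lse)
  g1 <- w * (p1 - (tv == 1)) / n_px
  g2 <- w * (p2 - (tv == 0)) / n_px
  grad <- array(c(g1, g2), dim = c(d[1], d[2], d[4], 2))
  grad <- aperm(grad, c(1, 2, 4, 3))
  list(loss = loss, grad = grad)
}

# ---- datasets ---------------------------------------------------------------

#' In-memory synthetic dataset
#'
#' Generates `n` hyper-labeled stacks with masks without touching disk —
#' the fast path for training runs and tests. [generate_dataset()] is the
#' on-disk equivalent (same generator, same seeds).
#'
#' @param config A [sim_config()].
#' @param n Number of images.
#' @param seed Integer seed.
#' @return A `stack_dataset`.
#' @export
simulate_dataset <- function(config, n, seed = config$seed) {
  items <- lapply(seq_len(n), function(i) {
    ex <- generate_hyperstack(config, seed = mix_seed(seed, 7000, i))
    list(stack = ex$stack, mask = ex$mask, is_negative = ex$is_negative)
  })
  structure(list(items = items), class = "stack_dataset")
}

n_items <- function(dataset) {
  if (inherits(dataset, "stack_dataset")) length(dataset$items)
  else nrow(dataset)
}

get_item <- function(dataset, i) {
  if (inherits(dataset, "stack_dataset")) return(dataset$items[[i]])
  p <- manifest_paths(dataset, i)
  list(stack = read_hyperstack(p$image), mask = read_mask(p$mask),
       is_negative = dataset$is_negative[i])
}

subset_items <- function(dataset, idx) {
  if (inherits(dataset, "stack_dataset"))
    return(structure(list(items = dataset$items[idx]),
                     class = "stack_dataset"))
  out <- dataset[idx, , drop = FALSE]
  attr(out, "root") <- attr(dataset, "root")
  out
}

#' Split a dataset into train and validation parts
#'
#' Disjoint, exhaustive random partition with `round(fraction * N)` items in
#' the training side. The same `split_seed` always yields the identical
#' partition; keeping splits consistent across models within a replicate is
#' what makes their accuracies comparable.
#'
#' @param dataset A manifest tibble or `stack_dataset`.
#' @param fraction Training fraction, strictly between 0 and 1 (default 0.8).
#' @param split_seed Integer seed for the partition.
#' @return List with `train` and `val` subsets (same type as input) and the
#'   index vectors `train_idx`, `val_idx`.
#' @export
split_dataset <- function(dataset, fraction = 0.8, split_seed = 1L) {
  n <- n_items(dataset)
  if (n < 2)
    stop_substacks("dataset must have at least 2 items to split",
                   "substacks_invalid_config")
  n_train <- round(fraction * n)
  if (n_train < 1 || n_train >= n)
    stop_substacks(sprintf(
      "fraction %.3f leaves an empty split side for N = %d", fraction, n),
      "substacks_invalid_config")
  perm <- with_rng(split_seed, sample.int(n))
  train_idx <- sort(perm[seq_len(n_train)])
  val_idx <- sort(perm[(n_train + 1):n])
  list(train = subset_items(dataset, train_idx),
       val = subset_items(dataset, val_idx),
       train_idx = train_idx, val_idx = val_idx)
}

# ---- learning-rate schedules ------------------------------------------------

#' 1-cycle learning-rate schedule
#'
#' Cosine warmup from `max_lr / div` to exactly `max_lr` over
#' `warmup_frac` of the iterations, then cosine annealing to
#' `max_lr / final_div`. With `lr_range` given, returns a matrix whose
#' columns are per-parameter-group schedules scaled geometrically so the
#' group peaks span exactly `[lr_range[1], lr_range[2]]`.
#'
#' @param max_lr Peak learning rate (> 0).
#' @param total_iters Total iterations (>= 2).
#' @param warmup_frac Fraction of iterations spent warming up.
#' @param div Initial divisor (`start = max_lr / div`).
#' @param final_div Final divisor (`end = max_lr / final_div`).
#' @param lr_range Optional `c(low, high)` peak range across groups; when
#'   given, `max_lr` is ignored and `high` is the top group's peak.
#' @param n_groups Number of parameter groups for `lr_range`.
#' @return Numeric vector of length `total_iters`, or a
#'   `total_iters x n_groups` matrix when `lr_range` is given.
#' @export
one_cycle_schedule <- function(max_lr, total_iters, warmup_frac = 0.25,
                               div = 25, final_div = 1e4,
                               lr_range = NULL, n_groups = NULL) {
  if (!is.null(lr_range)) {
    if (any(lr_range <= 0))
      stop_substacks("lr_range must be positive", "substacks_invalid_config")
    base <- one_cycle_schedule(lr_range[2], total_iters, warmup_frac,
                               div, final_div)
    mults <- group_lr_mults(lr_range[1], lr_range[2], n_groups)
    return(outer(base, mults))
  }
  if (max_lr <= 0)
    stop_substacks("max_lr must be positive", "substacks_invalid_config")
  if (total_iters < 2)
    stop_substacks("total_iters must be >= 2", "substacks_invalid_config")
  k <- max(1L, round(warmup_frac * (total_iters - 1)))
  lr0 <- max_lr / div
  lr_end <- max_lr / final_div
  up <- lr0 + (max_lr - lr0) * (1 - cos(pi * (0:k) / k)) / 2
  n_down <- total_iters - k - 1
  down <- if (n_down > 0)
    lr_end + (max_lr - lr_end) *
      (1 + cos(pi * (1:n_down) / n_down)) / 2
  else numeric(0)
  c(up, down)
}

# Geometric interpolation of per-group lr multipliers: group 1 (earliest
# encoder stages) lowest, last group (decoder + head) = 1.
group_lr_mults <- function(lo, hi, n_groups) {
  if (n_groups == 1) return(1)
  ratio <- lo / hi
  ratio^((n_groups - seq_len(n_groups)) / (n_groups - 1))
}

#' Learning-rate range test (generic engine)
#'
#' Ramps the learning rate geometrically from `min_lr` to `max_lr` over
#' `n_iters` steps, calling `step_fn(lr)` (which performs one optimisation
#' step and returns the training loss), records an exponentially smoothed
#' loss, and suggests the lr at the steepest negative slope of the smoothed
#' loss occurring before the loss exceeds `divergence_factor` times the best
#' smoothed loss. The ramp aborts early on divergence.
#'
#' @param step_fn Function of one argument (lr) returning a scalar loss.
#' @param min_lr,max_lr Ramp endpoints (geometric spacing).
#' @param n_iters Number of ramp steps.
#' @param smooth Exponential smoothing factor for the loss trace.
#' @param divergence_factor Abort once smoothed loss exceeds this multiple
#'   of the best smoothed loss.
#' @return A list with `trace` (tibble of `iter`, `lr`, `loss`,
#'   `smoothed_loss`) and `suggestion` (lr, or `NA` with a warning when the
#'   loss never decreases).
#' @export
lr_find_core <- function(step_fn, min_lr = 1e-7, max_lr = 1e-1,
                         n_iters = 100, smooth = 0.98,
                         divergence_factor = 4) {
  lrs <- min_lr * (max_lr / min_lr)^((seq_len(n_iters) - 1) / (n_iters - 1))
  losses <- numeric(0)
  smoothed <- numeric(0)
  avg <- 0
  best <- Inf
  for (i in seq_len(n_iters)) {
    loss <- step_fn(lrs[i])
    if (!is.finite(loss)) {
      if (i == 1)
        stop_substacks(sprintf("loss is not finite at the first lr (%.3g)",
                               lrs[1]), "substacks_divergence")
      break
    }
    avg <- smooth * avg + (1 - smooth) * loss
    sm <- avg / (1 - smooth^i)
    losses <- c(losses, loss)
    smoothed <- c(smoothed, sm)
    best <- min(best, sm)
    if (sm > divergence_factor * best && i > 5) break
  }
  n <- length(losses)
  trace <- tibble::tibble(iter = seq_len(n), lr = lrs[seq_len(n)],
                          loss = losses, smoothed_loss = smoothed)
  suggestion <- NA_real_
  if (n >= 3) {
    slope <- diff(smoothed) / diff(log(lrs[seq_len(n)]))
    # a genuinely negative slope, not floating-point dither on a flat trace
    tol <- 1e-9 * max(1, abs(smoothed[1]))
    if (any(slope < -tol)) suggestion <- lrs[which.min(slope) + 1]
  }
  if (is.na(suggestion))
    warning("loss never decreased during the lr ramp; no suggestion")
  list(trace = trace, suggestion = suggestion)
}

#' Learning-rate range test for a segmentation model
#'
#' Runs [lr_find_core()] with real optimisation steps: batches are drawn
#' cyclically from the training split, assembled through the loading code
#' and augmented exactly as in [train_model()].
#'
#' @param model A `seg_model` (modified in place during the ramp; build a
#'   fresh model before real training).
#' @param dataset A dataset (manifest or `stack_dataset`).
#' @param config A [train_config()].
#' @inheritParams lr_find_core
#' @return As [lr_find_core()].
#' @export
lr_find <- function(model, dataset, config, min_lr = 1e-7, max_lr = 1e-1,
                    n_iters = 100, divergence_factor = 4) {
  n <- n_items(dataset)
  iter <- 0L
  step_fn <- function(lr) {
    iter <<- iter + 1L
    idx <- ((iter - 1L) * config$batch_size + seq_len(config$batch_size) - 1L) %% n + 1L
    batch <- make_batch(dataset, idx, config, epoch = iter,
                        base_seed = config$run_seed)
    zero_grads(model$params)
    logits <- model_forward(model, batch$x, training = TRUE)
    lg <- wce_loss_grad(logits, batch$y, config$class_weights)
    model_backward(model, lg$grad)
    adam_step(model$params, rep(1, 5), lr, iter)
    lg$loss
  }
  lr_find_core(step_fn, min_lr, max_lr, n_iters,
               divergence_factor = divergence_factor)
}

# ---- training loop ----------------------------------------------------------

#' Training configuration
#'
#' Two-phase schedule: `frozen_epochs` with the descending arc frozen at
#' `max_lr_phase1`, then `unfrozen_epochs` with all parameters and
#' discriminative group learning rates spanning `lr_range_phase2`
#' geometrically (earliest encoder stages lowest, decoder and head highest).
#' Defaults: 5 + 100 epochs, peak 2e-4 in phase 1, 2e-6 to 1e-4 in phase 2.
#'
#' @param code A [loading_code()] for subimage assembly.
#' @param frozen_epochs,unfrozen_epochs Epochs per phase (>= 1 and >= 0).
#' @param max_lr_phase1 Peak lr of phase 1.
#' @param lr_range_phase2 `c(low, high)` peak lr range across parameter
#'   groups in phase 2.
#' @param batch_size Minibatch size.
#' @param split_fraction,split_seed Train/validation split (default 80:20).
#' @param run_seed Seed for shuffling, loading-code resolution and
#'   augmentation draws.
#' @param class_weights A [class_weights()] vector.
#' @param augment An [augment_params()]; its `target_size` fixes the network
#'   input size.
#' @param val_channel_dropout,val_merge_dropout Optional overrides of the
#'   dropout rates used when assembling validation subimages; `NULL` keeps
#'   the training rates (validation randomness stays active but uses fixed
#'   per-(epoch, sample) seeds shared across models).
#' @param renormalize Merge semantics switch, see [ch_merge()].
#' @param track_train_accuracy Also record per-epoch training pixel accuracy
#'   (from the training-pass logits).
#' @param deterministic Pin every RNG stream (always on in this
#'   implementation; the flag is kept for config compatibility).
#' @return A `train_config` list.
#' @export
train_config <- function(code,
                         frozen_epochs = 5, unfrozen_epochs = 100,
                         max_lr_phase1 = 2e-4,
                         lr_range_phase2 = c(2e-6, 1e-4),
                         batch_size = 4,
                         split_fraction = 0.8, split_seed = 42L,
                         run_seed = 1L,
                         class_weights = substacks::class_weights(),
                         augment = augment_params(),
                         val_channel_dropout = NULL,
                         val_merge_dropout = NULL,
                         renormalize = FALSE,
                         track_train_accuracy = FALSE,
                         deterministic = TRUE) {
  if (frozen_epochs < 1)
    stop_substacks("frozen_epochs must be >= 1", "substacks_invalid_config")
  if (split_fraction <= 0 || split_fraction >= 1)
    stop_substacks("split_fraction must be in (0, 1)",
                   "substacks_invalid_config")
  if (max_lr_phase1 <= 0 || any(lr_range_phase2 <= 0))
    stop_substacks("learning rates must be positive",
                   "substacks_invalid_config")
  structure(list(code = code, frozen_epochs = as.integer(frozen_epochs),
                 unfrozen_epochs = as.integer(unfrozen_epochs),
                 max_lr_phase1 = max_lr_phase1,
                 lr_range_phase2 = lr_range_phase2,
                 batch_size = as.integer(batch_size),
                 split_fraction = split_fraction,
                 split_seed = as.integer(split_seed),
                 run_seed = as.integer(run_seed),
                 class_weights = class_weights,
                 augment = augment,
                 val_channel_dropout = val_channel_dropout,
                 val_merge_dropout = val_merge_dropout,
                 renormalize = renormalize,
                 track_train_accuracy = track_train_accuracy,
                 deterministic = deterministic),
            class = "train_config")
}

# Assemble + augment a training minibatch into (H, W, C, B) input and
# (H, W, B) target arrays. Loading-code randomness is re-rolled per sample
# per epoch (dropout as augmentation, not a fixed dataset attribute).
make_batch <- function(dataset, idx, config, epoch, base_seed,
                       validation = FALSE, code = config$code) {
  ts <- config$augment$target_size
  B <- length(idx)
  C <- length(code$specs)
  x <- array(0, dim = c(ts, ts, C, B))
  y <- array(0L, dim = c(ts, ts, B))
  for (j in seq_len(B)) {
    it <- get_item(dataset, idx[j])
    sub <- assemble_subimage(it$stack, code,
                             seed = mix_seed(base_seed, epoch, idx[j], 11),
                             renormalize = config$renormalize)
    pair <- if (validation)
      validation_transform(sub, it$mask, target_size = ts)
    else
      augment_pair(sub, it$mask, config$augment,
                   seed = mix_seed(base_seed, epoch, idx[j], 13))
    x[, , , j] <- pair$sub$pixels
    y[, , j] <- pair$mask
  }
  list(x = x, y = y)
}

validation_code <- function(config) {
  code <- config$code
  if (!is.null(config$val_channel_dropout) || !is.null(config$val_merge_dropout))
    code <- override_dropout(code,
                             channel_dropout = config$val_channel_dropout,
                             merge_dropout = config$val_merge_dropout)
  code
}

# Mean per-image validation pixel accuracy of `model` under `config`'s
# validation policy. Validation subimage randomness uses a fixed base seed
# (777) so that accuracies are comparable across models and runs.
evaluate_model <- function(model, val_set, config, epoch = 0L,
                           code = validation_code(config)) {
  n <- n_items(val_set)
  accs <- numeric(n)
  bs <- max(1L, config$batch_size)
  for (start in seq(1L, n, by = bs)) {
    idx <- start:min(start + bs - 1L, n)
    b <- make_batch(val_set, idx, config, epoch, base_seed = 777L,
                    validation = TRUE, code = code)
    logits <- model_forward(model, b$x, training = FALSE)
    for (j in seq_along(idx)) {
      pred <- logits_to_mask(logits[, , , j])
      accs[idx[j]] <- pixel_accuracy(pred, b$y[, , j])
    }
  }
  mean(accs)
}

#' Train a segmentation model under the two-phase 1-cycle protocol
#'
#' Phase 1 trains for `frozen_epochs` with every descending-arc (encoder)
#' parameter frozen, under a 1-cycle schedule peaking at `max_lr_phase1`.
#' Phase 2 trains the whole network for `unfrozen_epochs` with
#' discriminative group learning rates whose peaks span `lr_range_phase2`
#' geometrically. Subimage assembly (loading-code randomness, dropout) is
#' re-rolled for every sample at every epoch; validation uses the
#' deterministic centre-crop transform, active loading-code randomness with
#' fixed per-(epoch, sample) seeds, and an optional dropout-rate override.
#' Every epoch logs the mean training loss and validation pixel accuracy.
#' Fully reproducible given (`split_seed`, `run_seed`, model init seed).
#'
#' @param model A `seg_model` (updated in place and returned).
#' @param dataset A manifest tibble or `stack_dataset`.
#' @param config A [train_config()].
#' @return A list of class `trained_model`: `model`, `history` (a
#'   `training_history` tibble with `epoch`, `phase`, `train_loss`,
#'   `val_pixel_accuracy`, and optionally `train_pixel_accuracy`),
#'   `lr_trace`, and the `split` index vectors.
#' @export
train_model <- function(model, dataset, config) {
  split <- split_dataset(dataset, config$split_fraction, config$split_seed)
  if (n_items(split$train) < 1 || n_items(split$val) < 1)
    stop_substacks("both split sides must be nonempty",
                   "substacks_invalid_config")
  n_train <- n_items(split$train)
  iters_per_epoch <- max(1L, ceiling(n_train / config$batch_size))
  total_epochs <- config$frozen_epochs + config$unfrozen_epochs

  sched1 <- one_cycle_schedule(config$max_lr_phase1,
                               max(2L, config$frozen_epochs * iters_per_epoch))
  sched2 <- if (config$unfrozen_epochs > 0)
    one_cycle_schedule(NA, max(2L, config$unfrozen_epochs * iters_per_epoch),
                       lr_range = config$lr_range_phase2, n_groups = 5)
  else NULL

  history <- vector("list", total_epochs)
  lr_trace <- numeric(0)
  iter_global <- 0L
  adam_iter <- 0L

  for (epoch in seq_len(total_epochs)) {
    phase <- if (epoch <= config$frozen_epochs) 1L else 2L
    if (phase == 2L && epoch == config$frozen_epochs + 1L) {
      for (p in model$params) { p$m <- NULL; p$s <- NULL }  # fresh optimiser
      adam_iter <- 0L
    }
    order_idx <- with_rng(mix_seed(config$run_seed, epoch, 3),
                          sample.int(n_train))
    ep_loss <- 0
    ep_acc_num <- 0; ep_acc_den <- 0
    for (b in seq_len(iters_per_epoch)) {
      lo <- (b - 1L) * config$batch_size + 1L
      hi <- min(b * config$batch_size, n_train)
      idx <- order_idx[lo:hi]
      batch <- make_batch(split$train, idx, config, epoch,
                          base_seed = config$run_seed)
      zero_grads(model$params)
      logits <- model_forward(model, batch$x, training = TRUE)
      lg <- wce_loss_grad(logits, batch$y, config$class_weights)
      if (!is.finite(lg$loss))
        stop_substacks(sprintf(
          "training diverged (non-finite loss) at epoch %d, iteration %d",
          epoch, b), "substacks_divergence")
      model_backward(model, lg$grad)
      adam_iter <- adam_iter + 1L
      iter_global <- iter_global + 1L
      if (phase == 1L) {
        k <- min(adam_iter, length(sched1))
        lr <- sched1[k]
        adam_step(model$params, rep(1, 5), lr, adam_iter,
                  skip_arc = "encoder")
      } else {
        k <- min(adam_iter, nrow(sched2))
        lr <- sched2[k, 5]
        adam_step(model$params, sched2[k, ] / sched2[k, 5], lr, adam_iter)
      }
      lr_trace <- c(lr_trace, lr)
      ep_loss <- ep_loss + lg$loss * length(idx)
      if (config$track_train_accuracy) {
        pred <- 1L * (logits[, , 1, ] > logits[, , 2, ])
        ep_acc_num <- ep_acc_num + sum(pred == batch$y)
        ep_acc_den <- ep_acc_den + length(batch$y)
      }
    }
    val_acc <- evaluate_model(model, split$val, config, epoch)
    row <- tibble::tibble(epoch = epoch, phase = phase,
                          train_loss = ep_loss / n_train,
                          val_pixel_accuracy = val_acc)
    if (config$track_train_accuracy)
      row$train_pixel_accuracy <- ep_acc_num / ep_acc_den
    history[[epoch]] <- row
  }
  history <- dplyr::bind_rows(history)
  class(history) <- c("training_history", class(history))
  structure(list(model = model, history = history, lr_trace = lr_trace,
                 split = list(train_idx = split$train_idx,
                              val_idx = split$val_idx)),
            class = "trained_model")
}
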