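#' Pixel accuracy between two binary masks
#'
#' The fraction of pixels whose predicted class matches the ground truth —
#' the primary segmentation metric.
#'
#' @param pred,truth Binary 0/1 matrices of identical shape.
#' @return Fraction in `[0, 1]`.
#' @export
#' @examples
#' pixel_accuracy(matrix(c(1, 0, 0, 1), 2), matrix(c(1, 1, 0, 0), 2))
pixel_accuracy <- function(pred, truth) {
  pred <- as_mask(pred); truth <- as_mask(truth)
  if (!all(dim(pred) == dim(truth)))
    stop_substacks("mask shapes differ", "substacks_shape_mismatch")
  mean(pred == truth)
}

#' Pixelwise confusion counts
#'
#' @inheritParams pixel_accuracy
#' @return Named integer vector `(TP, FP, FN, TN)`; cell = positive class.
#' @export
confusion_counts <- function(pred, truth) {
  pred <- as_mask(pred); truth <- as_mask(truth)
  if (!all(dim(pred) == dim(truth)))
    stop_substacks("mask shapes differ", "substacks_shape_mismatch")
  c(TP = sum(pred == 1L & truth == 1L),
    FP = sum(pred == 1L & truth == 0L),
    FN = sum(pred == 0L & truth == 1L),
    TN = sum(pred == 0L & truth == 0L))
}

#' Final accuracy over a rolling window
#'
#' The mean validation pixel accuracy over the final `window` training
#' epochs (default 10) — the headline number reported for each model.
#'
#' @param history A `training_history` tibble (or anything with a
#'   `val_pixel_accuracy` column).
#' @param window Number of final epochs to average.
#' @return Mean accuracy.
#' @export
rolling_final_accuracy <- function(history, window = 10) {
  acc <- history$val_pixel_accuracy
  if (length(acc) < window)
    stop_substacks(sprintf("history has %d epochs, fewer than window = %d",
                           length(acc), window), "substacks_invalid_config")
  mean(utils::tail(acc, window))
}

#' Two-sided paired t-test
#'
#' @param a,b Equal-length numeric vectors of per-replicate values (paired
#'   by replicate).
#' @return A list with `t`, `df`, `p_value` and `degenerate`. Zero-variance
#'   differences (including `a == b`) give `degenerate = TRUE` and
#'   `p_value = NA` rather than a spurious p-value.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2)
    stop_substacks("paired t-test needs equal lengths >= 2",
                   "substacks_invalid_config")
  d <- a - b
  if (stats::sd(d) == 0)
    return(list(t = NA_real_, df = length(d) - 1, p_value = NA_real_,
                degenerate = TRUE))
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, degenerate = FALSE)
}

#' Standard validation accuracy of a trained model
#'
#' Mean per-image validation pixel accuracy under the configuration's
#' validation policy (deterministic centre crop + resize, active
#' loading-code randomness with fixed seeds), optionally overriding the
#' channel / merge dropout rates imposed at validation time.
#'
#' @param model A `seg_model`.
#' @param val_set The validation subset (from [split_dataset()]).
#' @param config The [train_config()] the model was trained with.
#' @param channel_dropout,merge_dropout Optional validation-time overrides.
#' @return Mean pixel accuracy.
#' @export
validation_accuracy <- function(model, val_set, config,
                                channel_dropout = NULL, merge_dropout = NULL) {
  code <- validation_code(config)
  if (!is.null(channel_dropout) || !is.null(merge_dropout))
    code <- override_dropout(code, channel_dropout = channel_dropout,
                             merge_dropout = merge_dropout)
  evaluate_model(model, val_set, config, epoch = 0L, code = code)
}

# Shared replicate seed derivation; explicit vectors may override.
replicate_seeds <- function(base_seed, n, split_seeds, init_seeds) {
  if (is.null(split_seeds))
    split_seeds <- vapply(seq_len(n), function(r)
      mix_seed(base_seed, 50, r), integer(1))
  if (is.null(init_seeds))
    init_seeds <- vapply(seq_len(n), function(r)
      mix_seed(base_seed, 60, r), integer(1))
  if (anyDuplicated(split_seeds) || anyDuplicated(init_seeds))
    stop_substacks("replicate seeds collide across replicates",
                   "substacks_invalid_config")
  list(split = split_seeds, init = init_seeds)
}

#' Compare labeling strategies on a shared dataset
#'
#' Trains one model per loading code per replicate. Within each replicate
#' every code shares the same train/validation split and the same weight
#' initialisation seed, so codes are compared on identical data — the
#' paired design. Reports each code's mean rolling final accuracy with its
#' standard error and a two-sided paired t-test against a reference code.
#'
#' @param codes Named list of [loading_code()]s (>= 2).
#' @param dataset A manifest tibble or `stack_dataset`.
#' @param config A [train_config()]; its `code` field is replaced per run.
#' @param n_replicates Number of paired replicates.
#' @param reference Name of the reference code for the t-test (default
#'   `"brightfield"`, or the first code if absent).
#' @param model_cfg A [model_config()] for the trained networks.
#' @param window Rolling-window length for the final accuracy.
#' @param split_seeds,init_seeds Optional explicit per-replicate seeds;
#'   must be distinct across replicates.
#' @return A `comparison_table` tibble: one row per code with
#'   `mean_final_accuracy`, `sem`, `n`, `p_value_vs_reference`. The
#'   per-replicate results are in `attr(, "runs")`; per-run histories in
#'   `attr(, "histories")`.
#' @export
compare_strategies <- function(codes, dataset, config, n_replicates = 3,
                               reference = "brightfield",
                               model_cfg = model_config(width_multiplier = 1),
                               window = 10,
                               split_seeds = NULL, init_seeds = NULL) {
  if (length(codes) < 2)
    stop_substacks("need at least two codes to compare",
                   "substacks_invalid_config")
  if (is.null(names(codes)))
    names(codes) <- vapply(codes, function(cd) cd$name, character(1))
  if (!reference %in% names(codes)) reference <- names(codes)[1]
  seeds <- replicate_seeds(config$run_seed, n_replicates,
                           split_seeds, init_seeds)
  runs <- list(); histories <- list()
  for (r in seq_len(n_replicates)) {
    for (nm in names(codes)) {
      cfg <- config
      cfg$code <- codes[[nm]]
      cfg$split_seed <- seeds$split[r]
      cfg$run_seed <- mix_seed(config$run_seed, 70, r)
      model <- build_model(model_cfg, seed = seeds$init[r])
      fit <- train_model(model, dataset, cfg)
      runs[[length(runs) + 1]] <- tibble::tibble(
        code = nm, replicate = r,
        final_accuracy = rolling_final_accuracy(fit$history,
                                                min(window, nrow(fit$history))))
      histories[[paste(nm, r, sep = "/")]] <- fit$history
    }
  }
  runs <- dplyr::bind_rows(runs)
  ref_acc <- runs$final_accuracy[runs$code == reference]
  summary <- runs |>
    dplyr::group_by(.data$code) |>
    dplyr::summarise(mean_final_accuracy = mean(.data$final_accuracy),
                     sem = stats::sd(.data$final_accuracy) /
                       sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
  summary$p_value_vs_reference <- vapply(summary$code, function(nm) {
    if (nm == reference || n_replicates < 2) return(NA_real_)
    paired_t_test(runs$final_accuracy[runs$code == nm], ref_acc)$p_value
  }, numeric(1))
  summary <- summary[match(names(codes), summary$code), ]
  attr(summary, "runs") <- runs
  attr(summary, "histories") <- histories
  attr(summary, "reference") <- reference
  class(summary) <- c("comparison_table", class(summary))
  summary
}

#' Train-by-validate dropout robustness sweep
#'
#' For each training dropout rate, trains a model with the template code's
#' dropout parameter set to that rate, then evaluates the trained model at
#' every validation rate by overriding the rate during validation loading.
#' The result grid (training rate x validation rate) quantifies robustness
#' to labeling conditions: a robust model holds its accuracy across the
#' whole validation row.
#'
#' @param code_template A [loading_code()]; must contain a merge source when
#'   `param = "merge"`.
#' @param dataset A manifest tibble or `stack_dataset`.
#' @param config A [train_config()].
#' @param train_rates,val_rates Dropout rates in `[0, 1]`, sorted.
#' @param n_replicates Replicates averaged into the grid.
#' @param param Which dropout knob to sweep: `"merge"` (merge dropout),
#'   `"channel"` (channel dropout), or `"auto"` (merge if the template has a
#'   merge source, channel otherwise).
#' @param model_cfg A [model_config()].
#' @param split_seeds,init_seeds Optional explicit per-replicate seeds.
#' @return A `sweep_result`: list with `train_rates`, `val_rates`,
#'   `accuracy_grid` (train x val matrix of mean accuracies),
#'   `standard_accuracy` (per train rate, accuracy at its own rate),
#'   `n_replicates`, `param`, and the long per-replicate tibble `runs`.
#' @export
dropout_sweep <- function(code_template, dataset, config,
                          train_rates = seq(0, 1, 0.1),
                          val_rates = seq(0, 1, 0.1),
                          n_replicates = 1,
                          param = c("auto", "merge", "channel"),
                          model_cfg = model_config(width_multiplier = 1),
                          split_seeds = NULL, init_seeds = NULL) {
  param <- match.arg(param)
  if (param == "auto")
    param <- if (code_has_merge(code_template)) "merge" else "channel"
  if (param == "merge" && !code_has_merge(code_template))
    stop_substacks("code template has no merge source to sweep",
                   "substacks_bad_code")
  if (any(train_rates < 0 | train_rates > 1) ||
      any(val_rates < 0 | val_rates > 1))
    stop_substacks("dropout rates must be in [0, 1]",
                   "substacks_invalid_config")
  if (is.unsorted(train_rates) || is.unsorted(val_rates))
    stop_substacks("dropout rates must be sorted", "substacks_invalid_config")

  rate_code <- function(rate) {
    if (param == "merge")
      override_dropout(code_template, merge_dropout = rate)
    else
      override_dropout(code_template, channel_dropout = rate)
  }
  seeds <- replicate_seeds(config$run_seed, n_replicates,
                           split_seeds, init_seeds)
  grid <- array(0, dim = c(length(train_rates), length(val_rates),
                           n_replicates))
  std <- matrix(0, length(train_rates), n_replicates)
  runs <- list()
  for (r in seq_len(n_replicates)) {
    for (ti in seq_along(train_rates)) {
      cfg <- config
      cfg$code <- rate_code(train_rates[ti])
      cfg$split_seed <- seeds$split[r]
      cfg$run_seed <- mix_seed(config$run_seed, 70, r)
      model <- build_model(model_cfg, seed = seeds$init[r])
      fit <- train_model(model, dataset, cfg)
      split <- split_dataset(dataset, cfg$split_fraction, cfg$split_seed)
      for (vi in seq_along(val_rates)) {
        acc <- if (param == "merge")
          validation_accuracy(model, split$val, cfg,
                              merge_dropout = val_rates[vi])
        else
          validation_accuracy(model, split$val, cfg,
                              channel_dropout = val_rates[vi])
        grid[ti, vi, r] <- acc
        runs[[length(runs) + 1]] <- tibble::tibble(
          replicate = r, train_rate = train_rates[ti],
          val_rate = val_rates[vi], accuracy = acc)
      }
      std[ti, r] <- validation_accuracy(model, split$val, cfg)
    }
  }
  acc_grid <- apply(grid, c(1, 2), mean)
  dimnames(acc_grid) <- list(train = format(train_rates),
                             val = format(val_rates))
  structure(list(train_rates = train_rates, val_rates = val_rates,
                 accuracy_grid = acc_grid,
                 standard_accuracy = rowMeans(std),
                 n_replicates = n_replicates, param = param,
                 runs = dplyr::bind_rows(runs)),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %s dropout, %d x %d grid, %d replicate(s)\n",
              x$param, length(x$train_rates), length(x$val_rates),
              x$n_replicates))
  print(round(x$accuracy_grid, 3))
  invisible(x)
}
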