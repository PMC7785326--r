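test_that("weighted cross-entropy matches the printed formula", {
  w <- class_weights()

  # symmetric logits, cell pixel, weight 1 -> ln 2
  lg <- array(0, dim = c(1, 1, 2))
  expect_equal(weighted_cross_entropy(lg, matrix(1, 1, 1), w), log(2),
               tolerance = 1e-12)

  # background pixel with logits (cell 2, background -1), weight 0.5
  lg2 <- array(c(2, -1), dim = c(1, 1, 2))
  expect_equal(weighted_cross_entropy(lg2, matrix(0, 1, 1), w),
               0.5 * (1 + log(exp(2) + exp(-1))), tolerance = 1e-12)

  # loss -> 0 as the correct-class margin grows
  margins <- c(5, 20, 60)
  losses <- vapply(margins, function(m)
    weighted_cross_entropy(array(c(m, 0), dim = c(1, 1, 2)),
                           matrix(1, 1, 1), w), numeric(1))
  expect_true(all(diff(losses) < 0))
  expect_lt(losses[3], 1e-12)

  # independent per-pixel oracle on random multi-pixel inputs
  set.seed(1)
  for (rep in 1:20) {
    h <- sample(2:5, 1); wd <- sample(2:5, 1)
    lg <- array(rnorm(h * wd * 2, sd = 3), dim = c(h, wd, 2))
    tg <- matrix(rbinom(h * wd, 1, 0.5), h, wd)
    ws <- class_weights(cell = runif(1, 0.5, 2), background = runif(1, 0.5, 2))
    ref <- mean(vapply(seq_len(h * wd), function(k) {
      i <- (k - 1) %% h + 1; j <- (k - 1) %/% h + 1
      cls <- if (tg[i, j] == 1) 1 else 2
      oracle_wce_pixel(c(lg[i, j, 1], lg[i, j, 2]), cls,
                       c(ws[["cell"]], ws[["background"]]))
    }, numeric(1)))
    expect_equal(weighted_cross_entropy(lg, tg, ws), ref, tolerance = 1e-10)
  }

  # loss gradient agrees with finite differences
  lg <- array(rnorm(8), dim = c(2, 2, 2))
  tg <- matrix(c(1, 0, 0, 1), 2, 2)
  gr <- substacks:::wce_loss_grad(lg, tg, w)$grad
  for (k in 1:8) {
    eps <- 1e-6
    lp <- lg; lp[k] <- lp[k] + eps
    lm <- lg; lm[k] <- lm[k] - eps
    num <- (weighted_cross_entropy(lp, tg, w) -
              weighted_cross_entropy(lm, tg, w)) / (2 * eps)
    expect_equal(gr[k], num, tolerance = 1e-6)
  }

  expect_error(weighted_cross_entropy(lg, matrix(c(1, 0.5, 0, 1), 2), w),
               class = "substacks_nonbinary_mask")
  expect_error(class_weights(background = 0),
               class = "substacks_invalid_config")
})

test_that("dataset splitting is exact, seeded and exhaustive", {
  man <- tibble::tibble(image_path = sprintf("i%03d.tiff", 1:275),
                        mask_path = sprintf("m%03d.png", 1:275),
                        is_negative = FALSE)
  sp <- split_dataset(man, 0.8, split_seed = 11)
  expect_equal(nrow(sp$train), 220)      # round(0.8 * 275)
  expect_equal(nrow(sp$val), 55)
  expect_length(intersect(sp$train_idx, sp$val_idx), 0)
  expect_setequal(c(sp$train_idx, sp$val_idx), 1:275)

  # identical seed -> identical partition; different seeds differ
  sp2 <- split_dataset(man, 0.8, split_seed = 11)
  expect_identical(sp$train_idx, sp2$train_idx)
  sp3 <- split_dataset(man, 0.8, split_seed = 12)
  expect_false(identical(sp$train_idx, sp3$train_idx))

  expect_error(split_dataset(man[1:3, ], 0.01),
               class = "substacks_invalid_config")
})

test_that("the 1-cycle schedule peaks exactly and shapes correctly", {
  s <- one_cycle_schedule(2e-4, 500)
  expect_equal(max(s), 2e-4)             # peak is exact
  expect_length(s, 500)
  expect_true(all(s > 0))

  # warmup 0.5: unimodal (rises then falls, one peak)
  s2 <- one_cycle_schedule(1e-3, 100, warmup_frac = 0.5)
  k <- which.max(s2)
  expect_true(all(diff(s2[1:k]) >= 0))
  expect_true(all(diff(s2[k:100]) <= 0))

  # per-group scaling: peaks span [2e-6, 1e-4] exactly, geometric spacing
  m <- one_cycle_schedule(NA, 300, lr_range = c(2e-6, 1e-4), n_groups = 5)
  expect_identical(dim(m), c(300L, 5L))
  peaks <- apply(m, 2, max)
  expect_equal(peaks[1], 2e-6)
  expect_equal(peaks[5], 1e-4)
  ratios <- peaks[-1] / peaks[-5]
  expect_equal(ratios, rep((1e-4 / 2e-6)^(1 / 4), 4), tolerance = 1e-12)

  expect_error(one_cycle_schedule(-1, 10), class = "substacks_invalid_config")
  expect_error(one_cycle_schedule(1e-3, 1), class = "substacks_invalid_config")
})

test_that("the lr finder ramps geometrically and finds the stable band", {
  # endpoint / spacing closed form
  calls <- numeric(0)
  res <- lr_find_core(function(lr) { calls <<- c(calls, lr); 1 - 0.001 * length(calls) },
                      min_lr = 1e-7, max_lr = 1e-1, n_iters = 100)
  expect_equal(calls[1], 1e-7)
  expect_equal(calls[100], 1e-1)
  ratios <- calls[-1] / calls[-100]
  expect_equal(ratios, rep((1e-1 / 1e-7)^(1 / 99), 99), tolerance = 1e-10)

  # convex quadratic proxy: loss 0.5 * lambda * w^2, gradient-descent step
  # w <- w (1 - lr * lambda); stable iff lr < 2 / lambda, fastest near
  # 1 / lambda. The suggestion must land in the stable-and-fast band.
  lambda <- 100
  wgt <- 10
  step_fn <- function(lr) {
    loss <- 0.5 * lambda * wgt^2
    wgt <<- wgt * (1 - lr * lambda)
    loss
  }
  res <- lr_find_core(step_fn, 1e-7, 1e-1, 100)
  expect_gt(res$suggestion, 1e-4)
  expect_lt(res$suggestion, 2 / lambda)

  # flat loss: no suggestion, with a warning
  expect_warning(res0 <- lr_find_core(function(lr) 1, 1e-7, 1e-1, 50),
                 "never decreased")
  expect_true(is.na(res0$suggestion))

  # immediate non-finite loss errors with the lr reported
  expect_error(lr_find_core(function(lr) NaN, 1e-7, 1e-1, 10),
               class = "substacks_divergence")
})

test_that("the default configuration trains 5 + 100 = 105 epochs", {
  tc <- train_config(builtin_codes()$fluorescence)
  expect_equal(tc$frozen_epochs + tc$unfrozen_epochs, 105)
  expect_equal(tc$frozen_epochs, 5)
  expect_equal(tc$max_lr_phase1, 2e-4)
  expect_equal(tc$lr_range_phase2, c(2e-6, 1e-4))
  expect_equal(tc$split_fraction, 0.8)
  expect_equal(tc$augment$target_size, 400L)
  expect_equal(unname(tc$class_weights), c(1, 0.5))
})

tiny_world <- function() fx_once("tiny32", function() {
  cfg <- sim_config(image_size = 32, seed = 3)
  list(config = cfg, dataset = simulate_dataset(cfg, 8, seed = 13))
})

tiny_tc <- function(...) {
  defaults <- list(code = builtin_codes()$fluorescence, frozen_epochs = 1,
                   unfrozen_epochs = 2, max_lr_phase1 = 1e-3,
                   lr_range_phase2 = c(3e-4, 3e-3), batch_size = 2,
                   split_fraction = 0.75, split_seed = 4, run_seed = 6,
                   augment = augment_params(target_size = 32,
                                            rotation = FALSE, skew = FALSE,
                                            warp = FALSE, brightness = FALSE,
                                            contrast = FALSE))
  do.call(train_config, utils::modifyList(defaults, list(...)))
}

tiny_model_cfg <- model_config(width_multiplier = 1 / 16, encoder_depth = 2)

test_that("training is bit-reproducible given identical seeds", {
  tw <- tiny_world()
  f1 <- train_model(build_model(tiny_model_cfg, seed = 8), tw$dataset,
                    tiny_tc())
  f2 <- train_model(build_model(tiny_model_cfg, seed = 8), tw$dataset,
                    tiny_tc())
  expect_identical(as.data.frame(f1$history), as.data.frame(f2$history))
  expect_identical(f1$lr_trace, f2$lr_trace)
  expect_identical(substacks:::param_snapshot(f1$model),
                   substacks:::param_snapshot(f2$model))

  # a different run seed changes the trajectory
  f3 <- train_model(build_model(tiny_model_cfg, seed = 8), tw$dataset,
                    tiny_tc(run_seed = 61))
  expect_false(identical(as.data.frame(f1$history),
                         as.data.frame(f3$history)))

  # history bookkeeping: one row per epoch, lr trace matches iterations
  expect_equal(nrow(f1$history), 3)
  expect_identical(f1$history$phase, c(1L, 2L, 2L))
  expect_true(all(f1$history$train_loss > 0))
  expect_true(all(f1$history$val_pixel_accuracy >= 0 &
                    f1$history$val_pixel_accuracy <= 1))
})

test_that("phase 1 keeps the whole encoder bit-identical", {
  tw <- tiny_world()
  model <- build_model(tiny_model_cfg, seed = 12)
  enc0 <- substacks:::param_snapshot(model, arc = "encoder")
  fit <- train_model(model, tw$dataset,
                     tiny_tc(frozen_epochs = 2, unfrozen_epochs = 0))
  expect_identical(substacks:::param_snapshot(fit$model, arc = "encoder"),
                   enc0)
  expect_false(identical(substacks:::param_snapshot(fit$model,
                                                    arc = "decoder"),
                         substacks:::param_snapshot(
                           build_model(tiny_model_cfg, seed = 12),
                           arc = "decoder")))
})

test_that("the model-level lr finder runs real optimisation steps", {
  tw <- tiny_world()
  model <- build_model(tiny_model_cfg, seed = 15)
  res <- lr_find(model, tw$dataset, tiny_tc(), min_lr = 1e-6,
                 max_lr = 1e-2, n_iters = 12)
  expect_lte(nrow(res$trace), 12)
  expect_equal(res$trace$lr[1], 1e-6)
  expect_true(all(is.finite(res$trace$loss)))
  expect_true(all(diff(res$trace$lr) > 0))
})
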