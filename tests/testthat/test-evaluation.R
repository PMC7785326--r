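test_that("pixel accuracy and confusion counts agree with hand tallies", {
  a <- matrix(c(1, 0, 0, 1), 2)
  b <- matrix(c(1, 1, 0, 0), 2)
  expect_equal(pixel_accuracy(a, a), 1)
  expect_equal(pixel_accuracy(a, 1 - a), 0)
  expect_equal(pixel_accuracy(a, b), 0.5)

  expect_equal(confusion_counts(matrix(1, 10, 10), matrix(0, 10, 10)),
               c(TP = 0L, FP = 100L, FN = 0L, TN = 0L))
  expect_equal(confusion_counts(a, a)[c("FP", "FN")], c(FP = 0L, FN = 0L))

  # brute-force oracle on random 16-px masks, plus the accuracy identity
  set.seed(5)
  for (rep in 1:20) {
    p <- matrix(rbinom(16, 1, 0.5), 4)
    t <- matrix(rbinom(16, 1, 0.5), 4)
    ref <- c(TP = 0L, FP = 0L, FN = 0L, TN = 0L)
    for (k in 1:16) {
      key <- if (p[k] == 1 && t[k] == 1) "TP" else if (p[k] == 1) "FP"
      else if (t[k] == 1) "FN" else "TN"
      ref[key] <- ref[key] + 1L
    }
    cc <- confusion_counts(p, t)
    expect_identical(cc, ref)
    expect_equal(sum(cc), 16L)
    expect_equal(pixel_accuracy(p, t),
                 1 - (cc[["FP"]] + cc[["FN"]]) / 16)
  }
  expect_error(pixel_accuracy(a, matrix(0, 3, 3)),
               class = "substacks_shape_mismatch")
})

test_that("rolling final accuracy averages the last window", {
  h <- tibble::tibble(val_pixel_accuracy = rep(0.9, 20))
  expect_equal(rolling_final_accuracy(h), 0.9)
  h2 <- tibble::tibble(val_pixel_accuracy = c(rep(0.1, 5),
                                              seq(0.90, 0.99, 0.01)))
  expect_equal(rolling_final_accuracy(h2, 10), 0.945)
  expect_equal(rolling_final_accuracy(h2, 1), 0.99)
  expect_error(rolling_final_accuracy(h2[1:4, ], 10),
               class = "substacks_invalid_config")
})

test_that("paired t-test matches the closed form and flags degeneracy", {
  a <- c(0.93, 0.95, 0.91, 0.96, 0.94, 0.92)
  b <- c(0.90, 0.93, 0.90, 0.92, 0.93, 0.90)
  res <- paired_t_test(a, b)
  d <- a - b
  t_ref <- mean(d) * sqrt(length(d)) / sd(d)
  p_ref <- 2 * pt(-abs(t_ref), df = length(d) - 1)
  expect_equal(res$t, t_ref, tolerance = 1e-10)
  expect_equal(res$p_value, p_ref, tolerance = 1e-10)
  expect_false(res$degenerate)

  # identical vectors and constant shifts are degenerate, not p-values
  expect_true(paired_t_test(a, a)$degenerate)
  expect_true(paired_t_test(a, a + 0.05)$degenerate)
  expect_error(paired_t_test(1, 2), class = "substacks_invalid_config")
})

test_that("sweep grids have the right shape and consistency diagonal", {
  tw <- fx_once("tiny32", function() {
    cfg <- sim_config(image_size = 32, seed = 3)
    list(config = cfg, dataset = simulate_dataset(cfg, 8, seed = 13))
  })
  code <- builtin_codes()$`Merge+Br`
  tc <- train_config(code, frozen_epochs = 1, unfrozen_epochs = 1,
                     max_lr_phase1 = 1e-3, lr_range_phase2 = c(3e-4, 3e-3),
                     batch_size = 2, split_fraction = 0.75, split_seed = 4,
                     run_seed = 6,
                     augment = augment_params(target_size = 32,
                                              rotation = FALSE, skew = FALSE,
                                              warp = FALSE, brightness = FALSE,
                                              contrast = FALSE))
  sw <- dropout_sweep(code, tw$dataset, tc, train_rates = c(0, 1),
                      val_rates = c(0, 1), n_replicates = 1,
                      model_cfg = model_config(width_multiplier = 1 / 16,
                                               encoder_depth = 2))
  expect_identical(dim(sw$accuracy_grid), c(2L, 2L))
  expect_true(all(sw$accuracy_grid >= 0 & sw$accuracy_grid <= 1))
  expect_equal(sw$param, "merge")
  # a model evaluated at its own training rate reproduces its standard
  # validation accuracy (consistency identity)
  expect_equal(sw$accuracy_grid[1, 1], sw$standard_accuracy[1])
  expect_equal(sw$accuracy_grid[2, 2], sw$standard_accuracy[2])
  # tidy/autoplot interfaces
  td <- tidy(sw)
  expect_identical(nrow(td), 4L)
  expect_s3_class(autoplot(sw), "ggplot")

  # sweeping merge dropout needs a merge-bearing template
  expect_error(dropout_sweep(builtin_codes()$brightfield, tw$dataset, tc,
                             c(0, 1), c(0, 1), param = "merge"),
               class = "substacks_bad_code")
  expect_error(dropout_sweep(code, tw$dataset, tc, c(0.5, 0.1), c(0, 1)),
               class = "substacks_invalid_config")
})

test_that("strategy comparison enforces the paired design", {
  tw <- fx_once("tiny32", function() {
    cfg <- sim_config(image_size = 32, seed = 3)
    list(config = cfg, dataset = simulate_dataset(cfg, 8, seed = 13))
  })
  codes <- builtin_codes()[c("fluorescence", "all_black")]
  tc <- train_config(codes[[1]], frozen_epochs = 1, unfrozen_epochs = 1,
                     max_lr_phase1 = 1e-3, lr_range_phase2 = c(3e-4, 3e-3),
                     batch_size = 2, split_fraction = 0.75, split_seed = 4,
                     run_seed = 6,
                     augment = augment_params(target_size = 32,
                                              rotation = FALSE, skew = FALSE,
                                              warp = FALSE, brightness = FALSE,
                                              contrast = FALSE))
  cmp <- compare_strategies(codes, tw$dataset, tc, n_replicates = 2,
                            reference = "all_black",
                            model_cfg = model_config(width_multiplier = 1 / 16,
                                                     encoder_depth = 2),
                            window = 2)
  expect_s3_class(cmp, "comparison_table")
  expect_identical(cmp$code, c("fluorescence", "all_black"))
  expect_identical(cmp$n, c(2L, 2L))
  runs <- tidy(cmp)
  expect_identical(nrow(runs), 4L)
  expect_true(is.na(cmp$p_value_vs_reference[cmp$code == "all_black"]))
  expect_s3_class(autoplot(cmp), "ggplot")

  # colliding replicate seeds are rejected
  expect_error(compare_strategies(codes, tw$dataset, tc, n_replicates = 2,
                                  split_seeds = c(3, 3)),
               class = "substacks_invalid_config")

  # comparing a code against itself in deterministic mode: differences are
  # exactly zero, flagged degenerate rather than given a fake p-value
  same <- compare_strategies(list(a = codes[[1]], b = codes[[1]]),
                             tw$dataset, tc, n_replicates = 2,
                             reference = "a",
                             model_cfg = model_config(width_multiplier = 1 / 16,
                                                      encoder_depth = 2),
                             window = 2)
  runs2 <- tidy(same)
  acc_a <- runs2$final_accuracy[runs2$code == "a"]
  acc_b <- runs2$final_accuracy[runs2$code == "b"]
  expect_identical(acc_a, acc_b)
  expect_true(is.na(same$p_value_vs_reference[same$code == "b"]))
})

test_that("training histories tidy, summarise and plot", {
  h <- tibble::tibble(epoch = 1:12, phase = c(1L, rep(2L, 11)),
                      train_loss = seq(1, 0.2, length.out = 12),
                      val_pixel_accuracy = seq(0.5, 0.95, length.out = 12))
  class(h) <- c("training_history", class(h))
  long <- tidy(h)
  expect_setequal(unique(long$metric), c("train_loss", "val_pixel_accuracy"))
  expect_equal(nrow(long), 24)
  fit <- structure(list(history = h), class = "trained_model")
  g <- glance(fit)
  expect_equal(g$epochs, 12)
  expect_equal(g$final_accuracy, mean(tail(h$val_pixel_accuracy, 10)))
  expect_s3_class(autoplot(h), "ggplot")
  # the rolling window pads early epochs with NA
  rm10 <- substacks:::rolling_mean(h$val_pixel_accuracy, 10)
  expect_true(all(is.na(rm10[1:9])))
  expect_equal(rm10[12], mean(h$val_pixel_accuracy[3:12]))
})
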