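#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a training history
#'
#' @param x A `training_history`.
#' @param ... Unused.
#' @return Long tibble with `epoch`, `phase`, `metric`, `value`.
#' @export
tidy.training_history <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(-c("epoch", "phase"),
                        names_to = "metric", values_to = "value")
}

#' @rdname tidy.training_history
#' @param window Rolling-window length for the summary.
#' @export
glance.trained_model <- function(x, window = 10, ...) {
  h <- x$history
  tibble::tibble(
    epochs = nrow(h),
    frozen_epochs = sum(h$phase == 1),
    final_train_loss = utils::tail(h$train_loss, 1),
    final_accuracy = rolling_final_accuracy(h, min(window, nrow(h))))
}

# 10-point moving average with empty (NA) padding for early epochs.
rolling_mean <- function(x, window = 10) {
  n <- length(x)
  out <- rep(NA_real_, n)
  if (n >= window)
    for (i in window:n) out[i] <- mean(x[(i - window + 1):i])
  out
}

#' Plot a training history
#'
#' Validation pixel accuracy per epoch with a 10-point moving average
#' (empty padding for early epochs).
#'
#' @param object A `training_history`.
#' @param window Moving-average window.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.training_history <- function(object, window = 10, ...) {
  df <- tibble::as_tibble(object)
  df$rolling <- rolling_mean(df$val_pixel_accuracy, min(window, nrow(df)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$val_pixel_accuracy),
                       alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$rolling), linewidth = 1,
                       na.rm = TRUE) +
    ggplot2::labs(y = "validation pixel accuracy", x = "epoch") +
    ggplot2::theme_minimal()
}

#' @export
tidy.comparison_table <- function(x, ...) attr(x, "runs")

#' @export
glance.comparison_table <- function(x, ...) {
  out <- x
  attributes(out)[c("runs", "histories", "reference")] <- NULL
  class(out) <- setdiff(class(out), "comparison_table")
  tibble::as_tibble(out)
}

#' Plot a strategy comparison
#'
#' Mean rolling final accuracy per loading code with standard-error bars.
#'
#' @param object A `comparison_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.comparison_table <- function(object, ...) {
  df <- glance(object)
  df$code <- factor(df$code, levels = df$code)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$code,
                                   y = .data$mean_final_accuracy)) +
    ggplot2::geom_col(fill = "grey55") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_final_accuracy - .data$sem,
      ymax = .data$mean_final_accuracy + .data$sem), width = 0.25) +
    ggplot2::labs(x = NULL, y = "final accuracy (rolling mean)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @export
tidy.sweep_result <- function(x, ...) {
  expand.grid(train_rate = x$train_rates, val_rate = x$val_rates) |>
    tibble::as_tibble() |>
    dplyr::mutate(accuracy = as.vector(x$accuracy_grid))
}

#' Plot a dropout sweep as a heatmap
#'
#' @param object A `sweep_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sweep_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$val_rate, y = .data$train_rate,
                                   fill = .data$accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "validation dropout rate", y = "training dropout rate",
                  fill = "accuracy") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
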