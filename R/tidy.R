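#' Tidy the training history of a fitted model
#'
#' @param x A `capstm_model`.
#' @param ... Unused.
#' @return Tibble with one row per epoch: `epoch`, `train_loss`,
#'   `dev_precision`, `dev_recall`, `dev_f`.
#' @method tidy capstm_model
#' @export
tidy.capstm_model <- function(x, ...) {
  x$history
}

#' One-row model summary
#'
#' @param x A `capstm_model`.
#' @param ... Unused.
#' @return One-row tibble: `preset`, `capsule_mode`, `use_attention`,
#'   `epochs_trained`, `best_epoch`, `dev_f`, `n_parameters`.
#' @method glance capstm_model
#' @export
glance.capstm_model <- function(x, ...) {
  count <- function(p) if (is.list(p)) sum(vapply(p, count, 0)) else length(p)
  tibble::tibble(
    preset = x$config$preset,
    capsule_mode = x$config$capsule_mode,
    use_attention = x$config$use_attention,
    epochs_trained = nrow(x$history),
    best_epoch = x$best_epoch,
    dev_f = x$dev_f,
    n_parameters = count(x$params)
  )
}

#' Training curves of a fitted model
#'
#' Plots the training loss and the per-epoch dev precision/recall/F-score,
#' with the selected (best dev F) epoch marked.
#'
#' @param object A `capstm_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot capstm_model
#' @export
autoplot.capstm_model <- function(object, ...) {
  h <- object$history
  long <- tibble::tibble(
    epoch = rep(h$epoch, 4L),
    metric = rep(c("train loss", "dev precision", "dev recall", "dev F"),
                 each = nrow(h)),
    value = c(h$train_loss, h$dev_precision, h$dev_recall, h$dev_f)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed") +
    ggplot2::labs(title = "Training history",
                  subtitle = sprintf("selected epoch %d (dev F %.3f)",
                                     object$best_epoch, object$dev_f)) +
    ggplot2::theme_minimal()
}
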