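#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the per-fold results of a nested cross-validation
#'
#' @param x An `errp_cv` object.
#' @param ... Unused.
#' @return Tibble with one row per outer fold: chosen cost, confusion counts
#'   and metrics.
#' @export
tidy.errp_cv <- function(x, ...) x$per_fold

#' One-row summary of a nested cross-validation
#'
#' @param x An `errp_cv` object.
#' @param ... Unused.
#' @return One-row tibble: pooled confusion counts and metrics, fold counts
#'   and the median selected cost.
#' @export
glance.errp_cv <- function(x, ...) {
  dplyr::bind_cols(
    x$pooled,
    tibble(
      outer_folds = x$plan$outer_folds, inner_folds = x$plan$inner_folds,
      median_cost = median(x$per_fold$cost), concat_first = x$concat_first
    )
  )
}

#' Tidy a fitted linear ErrP classifier
#'
#' @param x An `errp_model`.
#' @param ... Unused.
#' @return Tibble of model terms: one row per feature weight plus the bias.
#' @export
tidy.errp_model <- function(x, ...) {
  tibble(
    term = c(sprintf("feature_%03d", seq_along(x$weights)), "(bias)"),
    estimate = c(x$weights, x$bias)
  )
}

#' @export
glance.errp_model <- function(x, ...) {
  tibble(
    cost = x$cost,
    weight_noerrp = x$class_weights[["NoErrP"]],
    weight_errp = x$class_weights[["ErrP"]],
    n_support_vectors = nrow(x$svm$SV)
  )
}

#' Tidy an averaged ERP into a long waveform table
#'
#' @param x An `errp_erp`.
#' @param ... Unused.
#' @return Tibble with columns `time` (s), `channel`, `condition`,
#'   `amplitude` (microvolts).
#' @export
tidy.errp_erp <- function(x, ...) {
  tibble(
    time = rep(x$time, times = length(x$montage)),
    channel = rep(x$montage, each = length(x$time)),
    condition = x$condition,
    amplitude = as.vector(t(x$waveform))
  )
}

#' Plot an averaged ERP, one panel per channel
#'
#' @param object An `errp_erp`.
#' @param channels Channels to show (default all).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.errp_erp <- function(object, channels = object$montage, ...) {
  df <- dplyr::filter(tidy(object), .data$channel %in% channels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$amplitude)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2, colour = "grey60") +
    ggplot2::geom_line(colour = if (object$condition == "S96") "#c0392b" else "#2c3e50") +
    ggplot2::facet_wrap(~channel) +
    ggplot2::labs(
      x = "time relative to event (s)", y = expression(amplitude ~ (mu * V)),
      title = sprintf("Average ERP, condition %s (n = %d)",
                      object$condition, object$n_epochs)
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-fold cross-validation metrics
#'
#' @param object An `errp_cv`.
#' @param ... Unused.
#' @return A ggplot object with one point per outer fold and metric.
#' @export
autoplot.errp_cv <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_fold, c("bacc", "tpr", "tnr"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$fold), y = .data$value,
                                   colour = .data$metric, group = .data$metric)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "outer fold", y = "metric value") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
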