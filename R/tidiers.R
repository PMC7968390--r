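#' Tidy the per-iteration outcomes of a model comparison
#'
#' @param x An `sg_cv` from [evaluate_models()].
#' @param ... Unused.
#' @return A tibble with one row per family x iteration (`family`,
#'   `iteration`, `r2_train`, `r2_val`).
#' @export
tidy.sg_cv <- function(x, ...) {
  x$outcomes
}

#' One-row-per-family summary of a model comparison
#'
#' @param x An `sg_cv` from [evaluate_models()].
#' @param ... Unused.
#' @return A tibble with mean and SD of training and validation R-squared per
#'   family.
#' @export
glance.sg_cv <- function(x, ...) {
  x$summary
}

#' Plot mean R-squared per model family and evaluation set
#'
#' Bar chart of the mean training and validation R-squared per family, with
#' one-SD error bars, mirroring the standard presentation of repeated-holdout
#' model comparisons.
#'
#' @param object An `sg_cv` from [evaluate_models()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sg_cv <- function(object, ...) {
  d <- object$summary |>
    tidyr::pivot_longer(cols = c("mean_r2_train", "mean_r2_val"),
                        names_to = "set", values_to = "mean_r2") |>
    dplyr::mutate(
      sd = dplyr::if_else(.data$set == "mean_r2_train",
                          .data$sd_r2_train, .data$sd_r2_val),
      set = dplyr::if_else(.data$set == "mean_r2_train",
                           "training", "validation")
    )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$family, y = .data$mean_r2,
                                  fill = .data$set)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_r2 - .data$sd,
                   ymax = .data$mean_r2 + .data$sd),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2
    ) +
    ggplot2::labs(x = NULL, y = expression(mean ~ R^2),
                  fill = NULL,
                  title = paste("Model fits for", object$response)) +
    ggplot2::theme_minimal()
}

#' Plot total-effect feature importances
#'
#' Bar chart of per-feature importances with the importance threshold drawn as
#' a dashed line.
#'
#' @param importance An importance tibble (columns `feature`, `fi`, and
#'   optionally `family`), e.g. from [total_effect_importance()] or the
#'   `importance` element of an `sg_cv`.
#' @param threshold Threshold line position, default 0.1.
#' @return A ggplot object.
#' @export
plot_importance <- function(importance, threshold = 0.1) {
  p <- ggplot2::ggplot(importance,
                       ggplot2::aes(x = stats::reorder(.data$feature, -.data$fi),
                                    y = .data$fi)) +
    ggplot2::geom_col(width = 0.7, fill = "grey35") +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "total-effect importance") +
    ggplot2::theme_minimal()
  if ("family" %in% names(importance) &&
      length(unique(importance$family)) > 1) {
    p <- p + ggplot2::facet_wrap(~family)
  }
  p
}
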