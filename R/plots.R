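#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Traffic-light validation plot
#'
#' Per-patient predictive mean with a ~95% normal band, coloured by the
#' traffic-light verdict (green perfect, blue fulfilled within the
#' prediction's uncertainty, red off-prognosis); black points are the
#' targets. One facet per task.
#'
#' @param object A `balonn_validation`.
#' @param max_patients Show at most this many patients (default 20, the
#'   cohort-excerpt convention for this plot).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.balonn_validation <- function(object, max_patients = 20, ...) {
  d <- object$patients |>
    dplyr::filter(.data$patient <= max_patients)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$patient))) +
    ggplot2::geom_linerange(
      ggplot2::aes(ymin = .data$mean - 1.96 * .data$sd,
                   ymax = .data$mean + 1.96 * .data$sd,
                   colour = .data$light), linewidth = 1.2) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean, colour = .data$light),
                        size = 2) +
    ggplot2::geom_point(ggplot2::aes(y = .data$target), colour = "black",
                        shape = 16, size = 1.6) +
    ggplot2::scale_colour_manual(
      values = c(green = "#2e9e4f", blue = "#3a6fd8", red = "#d64541"),
      drop = FALSE) +
    ggplot2::facet_wrap(~task, scales = "free_y") +
    ggplot2::labs(x = "patient", y = "sampled prediction",
                  colour = "validation") +
    ggplot2::theme_minimal()
}

#' Sensitivity-sweep plot
#'
#' Precision (and error) against the prior scale, with the posterior scale
#' mapped to shape/colour — the standard way to read a prior/posterior
#' sensitivity sweep.
#'
#' @param object A `balonn_sweep`.
#' @param metric `"precision"` or `"error"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.balonn_sweep <- function(object, metric = c("precision", "error"),
                                  ...) {
  metric <- match.arg(metric)
  d <- tidy(object) |>
    dplyr::filter(.data$metric == !!metric, !.data$failed)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sigma_pr, y = .data$value,
                                  shape = factor(.data$sigma_po),
                                  colour = factor(.data$sigma_po))) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::facet_wrap(~task) +
    ggplot2::labs(x = expression(sigma[pr]), y = metric,
                  shape = expression(sigma[po]),
                  colour = expression(sigma[po])) +
    ggplot2::theme_minimal()
}

#' Training-trace plot
#'
#' Data-fit and KL terms of the objective per epoch.
#'
#' @param object A trained `balonn_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.balonn_model <- function(object, ...) {
  if (is.null(object$trace)) {
    stop("Model has no training trace; train it first.", call. = FALSE)
  }
  d <- object$trace |>
    tidyr::pivot_longer(-"epoch", names_to = "term", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(.data$epoch, .data$value,
                                  colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "loss term") +
    ggplot2::theme_minimal()
}

#' Predicted vs target class histogram
#'
#' The distribution comparison emitted by [validate_model()]: counts of
#' predicted-mean classes against target classes per task, plot-ready.
#'
#' @param validation A `balonn_validation`.
#' @return A ggplot object.
#' @export
plot_class_histogram <- function(validation) {
  stopifnot(inherits(validation, "balonn_validation"))
  d <- validation$histogram |>
    tidyr::pivot_longer(c("predicted", "target"),
                        names_to = "source", values_to = "count")
  ggplot2::ggplot(d, ggplot2::aes(factor(.data$class), .data$count,
                                  fill = .data$source)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~task, scales = "free_x") +
    ggplot2::labs(x = "class", y = "patients") +
    ggplot2::theme_minimal()
}
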