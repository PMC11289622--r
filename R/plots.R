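#' Volcano plot of a DE result
#'
#' @param object A `de_result`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.de_result <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$lfc, y = .data$neg_log10_p,
                               colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = expression(log[2] ~ "fold change"),
                  y = expression(-log[10] ~ italic(p)),
                  colour = "significant") +
    ggplot2::theme_minimal()
}

#' Binned MNA expression profile plot
#'
#' @param object An `mna_profile` from [binned_mna_profile()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.mna_profile <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = (.data$bin_start_um + .data$bin_end_um) / 2,
                               y = .data$mna)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "distance from tract (µm)",
                  y = "MNA counts",
                  title = attr(object, "gene")) +
    ggplot2::theme_minimal()
}

#' Radial profile plot (density or intensity)
#'
#' @param object A `radial_profile`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.radial_profile <- function(object, ...) {
  ylab <- if (identical(attr(object, "profile_type"), "density")) {
    expression("neuronal density (mm"^-2 * ")")
  } else "mean intensity (a.u.)"
  ggplot2::ggplot(object,
                  ggplot2::aes(x = (.data$bin_start_um + .data$bin_end_um) / 2,
                               y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "distance from tract (µm)", y = ylab) +
    ggplot2::theme_minimal()
}

#' LFC-versus-R-squared candidate scatter for one metric
#'
#' @param object A `candidate_set` from [select_candidates()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.candidate_set <- function(object, ...) {
  lfc_col <- if ("lfc" %in% names(object)) "lfc" else "mean_abs_lfc"
  label <- if ("gene" %in% names(object)) "gene" else "gene_set"
  ggplot2::ggplot(object,
                  ggplot2::aes(x = abs(.data[[lfc_col]]),
                               y = .data$r_squared,
                               colour = .data$selected)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(
      data = object[object$selected, , drop = FALSE],
      ggplot2::aes(label = .data[[label]]),
      vjust = -0.8, size = 3, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "|LFC|", y = expression(R^2), colour = "selected") +
    ggplot2::theme_minimal()
}

#' Predicted-versus-actual fit plot
#'
#' @param object A `metric_fit` from [predict_metric()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.metric_fit <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$actual, y = .data$fitted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "actual", y = "predicted",
      subtitle = sprintf("R² = %.3f", attr(object, "r_squared"))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
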