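# ggplot2 displays for fitted size histories and accuracy curves.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

size_history_steps <- function(model, label, k_min, k_max) {
  hist <- size_history(model)
  starts <- pmax(hist$generation_start, k_min)
  ends <- pmin(hist$generation_end, k_max)
  keep <- starts < ends
  tibble::tibble(
    k = c(rbind(starts[keep], ends[keep])),
    N = rep(hist$N_diploid[keep], each = 2),
    history = label
  )
}

#' Plot a fitted population size history
#'
#' Step plot of diploid size against generations before present on
#' log-log axes; the true history can be overlaid for simulation studies.
#'
#' @param object A `coalsize_fit`.
#' @param truth Optional true `coal_model` to overlay.
#' @param k_min,k_max Plotted time range in generations.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coalsize_fit <- function(object, truth = NULL, k_min = 10,
                                  k_max = 1e6, ...) {
  df <- size_history_steps(object$model, "estimate", k_min, k_max)
  if (!is.null(truth)) {
    df <- dplyr::bind_rows(df, size_history_steps(truth, "truth", k_min, k_max))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$N,
                                   colour = .data$history)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "generations before present", y = "diploid size N(k)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a coalescent model's size history
#'
#' @param object A `coal_model`.
#' @param k_min,k_max Plotted time range in generations.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coal_model <- function(object, k_min = 10, k_max = 1e6, ...) {
  df <- size_history_steps(object, "model", k_min, k_max)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$N)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "generations before present", y = "diploid size N(k)") +
    ggplot2::theme_minimal()
}

#' Plot an accuracy curve from [mean_signed_error()]
#'
#' @param err Result of [mean_signed_error()].
#' @return A ggplot object with `Delta(k)` against generations (log x).
#' @export
plot_accuracy <- function(err) {
  ggplot2::ggplot(err$delta, ggplot2::aes(x = .data$k, y = .data$delta)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "generations before present",
                  y = expression(Delta(k)),
                  subtitle = sprintf("phi = %.3f", err$phi)) +
    ggplot2::theme_minimal()
}
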