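#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a piecewise theory curve
#'
#' Log-log plot of the predicted translocation time against force or chain
#' length, coloured by force regime, with the regime boundaries marked.
#'
#' @param object a `pore_theory_curve` from [theory_curve()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.pore_theory_curve <- function(object, ...) {
  mode <- attr(object, "mode")
  xlab <- if (identical(mode, "tau_vs_f")) "driving force f" else
    "chain length N"
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$tau,
                                       colour = .data$regime)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = attr(object, "boundaries"),
                        linetype = "dotted", colour = "grey50") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = xlab, y = expression(tau), colour = "regime") +
    ggplot2::theme_minimal()
}

#' Plot the variance of the translocation coordinate
#'
#' Log-log plot of `<dn^2>` against normalized time, with an optional
#' fitted-slope guide from [fit_gamma()].
#'
#' @param variance a tibble from [translocation_variance()].
#' @param gamma_fit optional one-row tibble from [fit_gamma()].
#' @return A ggplot object.
#' @export
plot_variance <- function(variance, gamma_fit = NULL) {
  p <- ggplot2::ggplot(variance[variance$var_n > 0, ],
                       ggplot2::aes(x = .data$t_norm, y = .data$var_n)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(t / bar(tau)),
                  y = expression(group(langle, Delta * n^2, rangle))) +
    ggplot2::theme_minimal()
  if (!is.null(gamma_fit)) {
    w <- variance[variance$t_norm >= gamma_fit$window_lo &
                    variance$t_norm <= gamma_fit$window_hi &
                    variance$var_n > 0, ]
    if (nrow(w) > 1) {
      anchor <- w$var_n[1] / w$t_norm[1]^gamma_fit$value
      p <- p + ggplot2::geom_line(
        data = tibble::tibble(t_norm = w$t_norm,
                              var_n = anchor * w$t_norm^gamma_fit$value),
        colour = "red", linetype = "dashed")
    }
  }
  p
}

#' Plot mean translocation time against field or chain length
#'
#' @param data a tibble with a column `tau` (or `mean_tau`) and the chosen
#'   abscissa.
#' @param x abscissa column name (string), e.g. `"E"` or `"N"`.
#' @return A ggplot object (log-log).
#' @export
plot_tau_scaling <- function(data, x = "E") {
  ycol <- if ("mean_tau" %in% names(data)) "mean_tau" else "tau"
  ggplot2::ggplot(data, ggplot2::aes(x = .data[[x]], y = .data[[ycol]])) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = x, y = expression(group(langle, tau, rangle))) +
    ggplot2::theme_minimal()
}
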