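# Optional figures (ggplot2 in Suggests).

#' Ribbon plot of growing-window coefficient trajectories
#'
#' @param gw a [growing_window()] result.
#' @param terms terms to display.
#' @return a ggplot object.
#' @export
plot_growing_window <- function(gw, terms = c("S", "displacement")) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  d <- gw[gw$term %in% terms, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$window_end, y = .data$estimate,
                                  colour = .data$term, fill = .data$term)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo95, ymax = .data$hi95),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "days since closure (window end)",
                  y = "standardized coefficient on performance deviance") +
    ggplot2::theme_minimal()
}

#' Density plot of a strategy metric before vs during the disturbance
#'
#' @param before,during score vectors.
#' @param metric axis label.
#' @return a ggplot object.
#' @export
plot_metric_shift <- function(before, during, metric = "choice entropy (bits)") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  d <- data.frame(value = c(before, during),
                  period = rep(c("before", "during"),
                               c(length(before), length(during))))
  mu <- stats::aggregate(value ~ period, d, mean)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value, fill = .data$period)) +
    ggplot2::geom_density(alpha = 0.4) +
    ggplot2::geom_vline(data = mu,
                        ggplot2::aes(xintercept = .data$value,
                                     colour = .data$period), linetype = 2) +
    ggplot2::labs(x = metric, y = "density") +
    ggplot2::theme_minimal()
}
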