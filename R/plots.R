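# ggplot2 views of the pipeline outputs.

#' Plot coupling coordination degree trajectories
#'
#' Line plot of `D` over years by region, with horizontal guides at the
#' stage boundaries (0.4 and 0.6) separating low-, medium- and
#' high-level coordination.
#'
#' @param records Coordination records from [run_coordination()].
#' @return A ggplot object.
#' @export
plot_coordination <- function(records) {
  ggplot2::ggplot(
    records,
    ggplot2::aes(.data$year, .data$D, colour = .data$region)
  ) +
    ggplot2::geom_hline(
      yintercept = c(0.4, 0.6),
      linetype = "dashed", colour = "grey60"
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::scale_x_continuous(breaks = unique(records$year)) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = NULL, y = "coupling coordination degree D",
      colour = NULL,
      title = "Coupling coordination of health resources and economy"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the two composite indices over time
#'
#' @param records Coordination records from [run_coordination()].
#' @return A ggplot object faceted by region with one line per
#'   subsystem.
#' @export
plot_indices <- function(records) {
  long <- tidyr::pivot_longer(
    records[c("region", "year", "U_h", "U_e")],
    c("U_h", "U_e"),
    names_to = "subsystem", values_to = "index"
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(.data$year, .data$index, colour = .data$subsystem)
  ) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~region) +
    ggplot2::labs(
      x = NULL, y = "comprehensive evaluation index",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot entropy weights by subsystem
#'
#' @param weights Weight tibble from [entropy_weights()].
#' @return A ggplot bar chart.
#' @export
plot_weights <- function(weights) {
  ggplot2::ggplot(
    weights,
    ggplot2::aes(
      stats::reorder(.data$indicator, .data$weight),
      .data$weight
    )
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~system, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "entropy weight") +
    ggplot2::theme_minimal()
}

#' Coefficient plot for a fixed-effects fit
#'
#' @param object A `fem_fit` object.
#' @param ... Unused.
#' @return A ggplot object showing estimates with 95 percent confidence
#'   intervals.
#' @export
autoplot.fem_fit <- function(object, ...) {
  td <- tidy(object)
  crit <- stats::qt(0.975, object$n_units - 1)
  ggplot2::ggplot(td, ggplot2::aes(.data$estimate, .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$estimate - crit * .data$std.error,
      xmax = .data$estimate + crit * .data$std.error
    )) +
    ggplot2::labs(
      x = "coefficient (95% CI, cluster-robust)", y = NULL
    ) +
    ggplot2::theme_minimal()
}
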