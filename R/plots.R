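#' Plot a Monte-Carlo null distribution
#'
#' Histogram of the simulated coinfected-line counts, with an optional
#' vertical line marking the observed count — the figure that makes the
#' competition result visible: the observed count sits far in the lower tail
#' of the independence null.
#'
#' @param object A `null_dist` from [null_distribution()].
#' @param observed Optional observed coinfected-line count to mark.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.null_dist <- function(object, observed = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$n_coinfected)) +
    ggplot2::geom_bar(fill = "grey40") +
    ggplot2::labs(
      x = "Coinfected lines at final generation",
      y = "Monte-Carlo replicates",
      title = "Null distribution under independent transmission"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(observed)) {
    p <- p +
      ggplot2::geom_vline(xintercept = observed, colour = "firebrick",
                          linetype = "dashed", linewidth = 0.8) +
      ggplot2::annotate("text", x = observed, y = Inf, label = "observed",
                        vjust = 1.5, hjust = -0.1, colour = "firebrick")
  }
  p
}

#' Plot status frequencies of simulated lineages by generation
#'
#' Stacked-area view of how the four infection statuses redistribute across
#' generations as incomplete transmission erodes coinfection.
#'
#' @param object A `lineage_tbl` from [simulate_lineages()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lineage_tbl <- function(object, ...) {
  freq <- object |>
    dplyr::count(.data$generation, .data$status) |>
    dplyr::group_by(.data$generation) |>
    dplyr::mutate(prop = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::mutate(status = factor(.data$status, levels = rev(infection_statuses())))
  ggplot2::ggplot(freq, ggplot2::aes(x = .data$generation, y = .data$prop,
                                     fill = .data$status)) +
    ggplot2::geom_area(position = "stack", alpha = 0.9) +
    ggplot2::scale_fill_brewer(palette = "RdYlBu", direction = -1) +
    ggplot2::labs(x = "Generation", y = "Proportion of lines", fill = "Status") +
    ggplot2::theme_minimal()
}
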