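# ggplot2 displays for the main result types.

#' @rdname fitness_trajectory
#' @param object A `plasfit_fitness` object.
#' @param ... Unused.
#' @exportS3Method
autoplot.plasfit_fitness <- function(object, ...) {
  ggplot2::ggplot(as_tibble(unclass_first(object)),
                  ggplot2::aes(x = .data$time_h, y = .data$mean_w)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_w - .data$sd_w,
                                        ymax = .data$mean_w + .data$sd_w),
                           width = 2) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (h)", y = "Relative fitness W",
                  title = "Competition-assay fitness trajectory")
}

#' @rdname simulate_competition
#' @param object A `plasfit_sim` object.
#' @param ... Unused.
#' @exportS3Method
autoplot.plasfit_sim <- function(object, ...) {
  ggplot2::ggplot(object$densities,
                  ggplot2::aes(x = .data$time_h, y = .data$fraction_bearing)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Time (h)", y = "Plasmid-bearing fraction",
                  title = "Simulated serial-transfer competition")
}

#' @rdname enrich_table
#' @param object A `plasfit_enrichment` object.
#' @param ... Unused.
#' @exportS3Method
autoplot.plasfit_enrichment <- function(object, ...) {
  d <- filter(as_tibble(unclass_first(object)), !is.na(.data$p_value))
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$cog_code, .data$p_value),
                                  y = -log10(.data$p_value),
                                  fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "alpha")),
                        linetype = "dashed") +
    ggplot2::labs(x = "COG category", y = "-log10 p",
                  title = "COG enrichment of the DE set") +
    ggplot2::theme(legend.position = "none")
}

#' Plot a colony-diameter histogram
#'
#' @inheritParams diameter_histogram
#' @param threshold_mm Optional vertical reference line (mm).
#' @return A ggplot object.
#' @export
plot_diameter_histogram <- function(data, bin_width_mm = 0.25,
                                    threshold_mm = NULL) {
  h <- diameter_histogram(data, bin_width_mm)
  p <- ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_start + bin_width_mm / 2,
                                       y = .data$count)) +
    ggplot2::geom_col(width = bin_width_mm, colour = "white") +
    ggplot2::labs(x = "Colony diameter (mm)", y = "Colonies")
  if (!is.null(threshold_mm)) {
    p <- p + ggplot2::geom_vline(xintercept = threshold_mm,
                                 linetype = "dashed", colour = "red")
  }
  p
}
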