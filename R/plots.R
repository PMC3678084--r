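# Visual summaries built on ggplot2.

#' Histogram of the seed-space Tm distribution
#'
#' Shows the distribution of seed-duplex melting temperatures over all
#' 16,384 7-mers with the Tm threshold marked; the shaded part of seed space
#' is what remains available for off-target-conscious design.
#'
#' @param x A tibble as returned by [seed_space()].
#' @param threshold Tm threshold to mark, degC. Default 21.5.
#' @param binwidth Histogram bin width in degC.
#' @return A ggplot object.
#' @export
plot_seed_space <- function(x, threshold = 21.5, binwidth = 2) {
  stopifnot(all(c("seed", "tm_celsius") %in% names(x)))
  ggplot2::ggplot(x, ggplot2::aes(x = .data$tm_celsius,
                                  fill = .data$tm_celsius <= threshold)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2c7fb8",
                                          `FALSE` = "grey70")) +
    ggplot2::labs(
      x = "seed-duplex Tm (°C)",
      y = "number of 7-mer seeds",
      title = "Seed-space melting-temperature distribution",
      subtitle = sprintf("%.1f%% of seeds at or below %.1f °C",
                         100 * mean(x$tm_celsius <= threshold), threshold)
    )
}

#' Plot seed Tm along the target mRNA for a design result
#'
#' One point per reported candidate at its window start; the dashed line is
#' the design Tm threshold and filled points pass all five conditions.
#'
#' @param object A `sirna_design` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sirna_design
#' @export
autoplot.sirna_design <- function(object, ...) {
  cfg <- attr(object, "config")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$window_start,
                                       y = .data$seed_tm_celsius,
                                       colour = .data$all_pass)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = cfg$tm_threshold, linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$target_id)) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2c7fb8",
                                            `FALSE` = "grey65"),
                                 name = "all five\nconditions") +
    ggplot2::labs(
      x = "target window start (nt, 1-based)",
      y = "seed-duplex Tm (°C)",
      title = "Candidate siRNAs along the target mRNA"
    )
}
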