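#' Scatter plot of a PCoA ordination
#'
#' @param p A `"siam_pcoa"` result.
#' @param design Sample design; points are colored by treatment and labeled
#'   by timepoint.
#' @return A ggplot object.
#' @export
plot_ordination <- function(p, design) {
  coords <- tibble::as_tibble(p$coordinates, rownames = "sample_id") |>
    dplyr::left_join(design, by = "sample_id")
  pct <- round(100 * p$prop_var[1:2], 1)
  ggplot2::ggplot(coords, ggplot2::aes(.data$Axis1, .data$Axis2,
                                       color = .data$treatment,
                                       shape = .data$timepoint)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = sprintf("PCo1 (%.1f%%)", pct[1]),
                  y = sprintf("PCo2 (%.1f%%)", pct[2])) +
    ggplot2::theme_minimal()
}

#' Time-series plot of partitioned CO2 fluxes
#'
#' @param per_day Per-day partition table from [partition_series()].
#' @return A ggplot object with litter, peat and priming components over
#'   incubation time.
#' @export
plot_flux_partition <- function(per_day) {
  long <- per_day |>
    tidyr::pivot_longer(c("litter_flux", "peat_flux", "priming_flux"),
                        names_to = "component", values_to = "flux")
  ggplot2::ggplot(long, ggplot2::aes(.data$day, .data$flux,
                                     color = .data$component,
                                     group = interaction(.data$jar_id, .data$component))) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::labs(x = "day", y = "CO2 flux (umol g-1 d-1)") +
    ggplot2::theme_minimal()
}
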