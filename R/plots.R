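#' Map a gridded field
#'
#' Tile map of one month (or the mean over a window of months) of a
#' [flux_grid()].
#'
#' @param object A [flux_grid()].
#' @param year,month Select a single month to draw; by default the field is
#'   averaged over all months.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flux_grid <- function(object, year = NULL, month = NULL, ...) {
  d <- as_tibble(object)
  lab <- fg_variable(object)
  if (!is.null(year)) d <- filter(d, .data$year == .env$year)
  if (!is.null(month)) d <- filter(d, .data$month == .env$month)
  d <- d %>%
    group_by(.data$lat, .data$lon) %>%
    summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(.data$lon, .data$lat, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = paste0(lab, "\n[", fg_units(object), "]")) +
    ggplot2::coord_fixed(ratio = 1) +
    ggplot2::labs(x = "longitude", y = "latitude")
}

#' Map the per-cell compensation/amplification RATIO
#'
#' Tile map of [ratio_map()] output on a log2 color scale centered at
#' RATIO = 1 (compensation and amplification equally strong); degenerate
#' cells (zero amplification sum) are drawn distinctly.
#'
#' @param rmap A tibble from [ratio_map()].
#' @param max_ratio Cap for the color scale (default 8).
#' @return A ggplot object.
#' @export
plot_ratio_map <- function(rmap, max_ratio = 8) {
  d <- mutate(rmap,
    shown = pmin(pmax(.data$ratio, 1 / max_ratio), max_ratio),
    shown = ifelse(.data$degenerate, NA_real_, .data$shown)
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$lon, .data$lat, fill = log2(.data$shown))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      name = "RATIO", low = "#b35806", mid = "white", high = "#542788",
      midpoint = 0,
      labels = function(x) sprintf("%.2g", 2^x),
      na.value = "grey40"
    ) +
    ggplot2::coord_fixed(ratio = 1) +
    ggplot2::labs(
      x = "longitude", y = "latitude",
      subtitle = "purple: compensation dominates; orange: amplification; grey: degenerate"
    )
}

#' Plot the monthly singular vectors of a mode decomposition
#'
#' @param object A `mode_decomposition` from [svd_modes()].
#' @param n_modes Number of leading modes to draw (default 2).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mode_decomposition <- function(object, n_modes = 2, ...) {
  d <- tidy(object) %>%
    filter(.data$mode <= n_modes) %>%
    mutate(panel = sprintf("mode %d: %s (%.0f%%)", .data$mode, .data$label,
                           100 * .data$variance_fraction))
  ggplot2::ggplot(d, ggplot2::aes(.data$month, .data$weight)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::scale_x_continuous(breaks = c(3, 6, 9, 12)) +
    ggplot2::labs(x = "month", y = "monthly weight")
}

#' Map windowed flux-driver correlations with significance stippling
#'
#' @param stats_map A tibble from [windowed_correlation()].
#' @return A ggplot object; cells with p < 0.05 carry a point marker.
#' @export
plot_driver_map <- function(stats_map) {
  ggplot2::ggplot(stats_map, ggplot2::aes(.data$lon, .data$lat)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$r)) +
    ggplot2::geom_point(
      data = filter(stats_map, .data$significant),
      shape = 4, size = 0.8
    ) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#2166ac",
                                  high = "#b2182b", mid = "white") +
    ggplot2::coord_fixed(ratio = 1) +
    ggplot2::facet_grid(~ paste(.data$flux_window, "flux vs",
                                .data$driver_window, "driver")) +
    ggplot2::labs(x = "longitude", y = "latitude")
}
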