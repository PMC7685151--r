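#' Per-year seasonal compensation and amplification components
#'
#' For each year with a complete April-September record, the spring
#' (April-June) and summer (July-September) mean anomalies and the derived
#' components:
#' \deqn{comp_y = summer_y - spring_y, \qquad amp_y = summer_y + spring_y.}
#' Amplification measures a coherent whole-season enhancement or
#' suppression (for NEE, `amp > 0` is enhanced emission to the atmosphere);
#' compensation measures a spring/summer see-saw (`comp < 0` when a positive
#' spring anomaly is offset by a negative summer one). The identities
#' `comp + amp = 2 * summer` and `amp - comp = 2 * spring` hold exactly.
#' Years with an incomplete April-September are skipped.
#'
#' @param anoms An `anomaly_grid`, `region_series`, or data frame with
#'   `year`, `month`, `value` columns (plus optional `lat`/`lon`/`region`).
#' @return A tibble with the grouping columns and `year`, `spring_mean`,
#'   `summer_mean`, `comp`, `amp`; zero-row (with a warning) if no year is
#'   complete.
#' @export
components_per_year <- function(anoms) {
  grp <- intersect(c("region", "lat", "lon"), names(anoms))
  spring <- seasonal_window_mean(anoms, "AMJ")
  summer <- seasonal_window_mean(anoms, "JAS")
  out <- inner_join(
    rename(spring, spring_mean = "mean"),
    rename(summer, summer_mean = "mean"),
    by = c(grp, "year")
  ) %>%
    filter(!is.na(.data$spring_mean), !is.na(.data$summer_mean)) %>%
    mutate(
      comp = .data$summer_mean - .data$spring_mean,
      amp = .data$summer_mean + .data$spring_mean
    )
  if (nrow(out) == 0) {
    warn("no year has a complete April-September record; empty components")
  }
  out
}

#' Multi-year compensation-to-amplification magnitude RATIO
#'
#' The ratio of the summed absolute compensation component to the summed
#' absolute amplification component across years:
#' \deqn{RATIO = \sum_y |comp_y| / \sum_y |amp_y|.}
#' A RATIO of one means the two components have equal magnitude; above one,
#' seasonal compensation dominates interannual variability; below one,
#' amplification dominates. The metric is scale-free but can blow up when
#' the amplification magnitude is very small: a zero denominator is
#' reported as an `Inf` sentinel with `degenerate = TRUE`, both sums
#' retained, never dropped silently.
#'
#' @param components A tibble from [components_per_year()] (at least
#'   columns `year`, `comp`, `amp`; optional grouping columns
#'   `lat`/`lon`/`region` give one result row per group). Needs >= 2 years
#'   per group.
#' @return A tibble with the grouping columns and `ratio`, `sum_abs_comp`,
#'   `sum_abs_amp`, `n_years`, `degenerate`.
#' @export
ratio_metric <- function(components) {
  grp <- intersect(c("region", "lat", "lon"), names(components))
  out <- as_tibble(components) %>%
    group_by(across(dplyr::all_of(grp))) %>%
    summarise(
      sum_abs_comp = sum(abs(.data$comp)),
      sum_abs_amp = sum(abs(.data$amp)),
      n_years = dplyr::n_distinct(.data$year),
      .groups = "drop"
    ) %>%
    mutate(
      degenerate = .data$sum_abs_amp == 0,
      ratio = ifelse(.data$degenerate, Inf,
                     .data$sum_abs_comp / .data$sum_abs_amp)
    )
  if (any(out$n_years < 2)) {
    abort("RATIO needs at least 2 complete years")
  }
  out[c(grp, "ratio", "sum_abs_comp", "sum_abs_amp", "n_years", "degenerate")]
}

#' Per-cell RATIO map
#'
#' Computes the compensation/amplification RATIO for every grid cell of an
#' anomaly field over a chosen year set, optionally attaching each cell's
#' April-September mean temperature and soil moisture (for
#' ratio-versus-climate scatter plots). Degenerate cells (zero
#' amplification sum) are flagged, and cells with fewer than two complete
#' years are dropped.
#'
#' @param anoms An `anomaly_grid`.
#' @param years Integer vector of years entering the sums (the year set is
#'   an explicit argument because period choice changes the metric).
#'   Default: all years in the record.
#' @param temp,moist Optional [flux_grid()]s of raw soil temperature and
#'   soil moisture; when given, columns `mean_T_AprSep` and `mean_M_AprSep`
#'   (multi-year April-September cell means) are attached.
#' @return A tibble with one row per cell: `lat`, `lon`, `ratio`,
#'   `sum_abs_comp`, `sum_abs_amp`, `n_years`, `degenerate` and optional
#'   driver-mean columns.
#' @export
ratio_map <- function(anoms, years = NULL, temp = NULL, moist = NULL) {
  comps <- components_per_year(anoms)
  if (!is.null(years)) comps <- filter(comps, .data$year %in% .env$years)
  enough <- comps %>%
    group_by(.data$lat, .data$lon) %>%
    filter(dplyr::n() >= 2) %>%
    ungroup()
  out <- ratio_metric(enough)
  attach_mean <- function(out, grid, col) {
    m <- as_tibble(grid) %>%
      filter(.data$month %in% 4:9) %>%
      group_by(.data$lat, .data$lon) %>%
      summarise(!!col := mean(.data$value, na.rm = TRUE), .groups = "drop")
    left_join(out, m, by = c("lat", "lon"))
  }
  if (!is.null(temp)) out <- attach_mean(out, temp, "mean_T_AprSep")
  if (!is.null(moist)) out <- attach_mean(out, moist, "mean_M_AprSep")
  out
}
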