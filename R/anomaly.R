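#' Per-cell monthly climatology over a baseline period
#'
#' For each cell and calendar month, the mean over baseline years, ignoring
#' missing entries; a cell-month with fewer than two contributing years is
#' flagged missing.
#'
#' @param grid A [flux_grid()].
#' @param baseline Length-2 integer vector `(start_year, end_year)`,
#'   inclusive, within the record.
#' @return A tibble with columns `lat`, `lon`, `month`, `clim`, `n_years`.
#' @export
monthly_climatology <- function(grid, baseline) {
  check_baseline(grid, baseline)
  as_tibble(grid) %>%
    filter(.data$year >= baseline[1], .data$year <= baseline[2]) %>%
    group_by(.data$lat, .data$lon, .data$month) %>%
    summarise(
      n_years = sum(!is.na(.data$value)),
      clim = ifelse(.data$n_years >= 2, mean(.data$value, na.rm = TRUE), NA_real_),
      .groups = "drop"
    ) %>%
    select("lat", "lon", "month", "clim", "n_years")
}

check_baseline <- function(grid, baseline) {
  if (length(baseline) != 2 || baseline[2] < baseline[1]) {
    abort("`baseline` must be (start_year, end_year) with start <= end")
  }
  yrs <- range(fg_times(grid)$year)
  if (baseline[1] > yrs[2] || baseline[2] < yrs[1]) {
    abort("baseline period does not intersect the record")
  }
  invisible(baseline)
}

#' Convert a raw monthly gridded field to anomalies
#'
#' Removes the per-cell mean seasonal cycle over the baseline period and,
#' optionally, a per-cell linear trend fitted by OLS to the deseasonalized
#' monthly series against fractional time (one line per cell, all calendar
#' months pooled). Missing entries stay missing; anomalies are never
#' interpolated. For every calendar month, the mean anomaly over baseline
#' years is zero (to rounding) wherever data are complete.
#'
#' @inheritParams monthly_climatology
#' @param detrend Remove a linear trend after deseasonalizing?
#' @return An `anomaly_grid` (a [flux_grid()] subclass) with attributes
#'   `baseline`, `detrended` and `climatology` (the table from
#'   [monthly_climatology()]).
#' @details With `detrend = TRUE`, the line removal and the per-month
#'   baseline centering are alternated to convergence (backfitting), so the
#'   result is the joint projection out of both the seasonal-cycle and
#'   linear subspaces: a series that is exactly a repeated cycle plus a
#'   linear ramp detrends to zero, and both anomaly invariants (zero
#'   per-month baseline means, zero OLS slope) hold simultaneously.
#' @export
compute_anomalies <- function(grid, baseline, detrend = FALSE) {
  clim <- monthly_climatology(grid, baseline)
  out <- as_tibble(grid) %>%
    left_join(clim[c("lat", "lon", "month", "clim")], by = c("lat", "lon", "month")) %>%
    mutate(value = .data$value - .data$clim) %>%
    select("year", "month", "lat", "lon", "value")
  if (detrend) {
    out <- out %>%
      mutate(
        t_frac = .data$year + (.data$month - 0.5) / 12,
        in_base = .data$year >= baseline[1] & .data$year <= baseline[2]
      ) %>%
      group_by(.data$lat, .data$lon) %>%
      mutate(value = detrend_backfit(.data$value, .data$t_frac, .data$month,
                                     .data$in_base)) %>%
      ungroup() %>%
      select(-"t_frac", -"in_base")
  }
  g <- new_flux_grid(out, variable = fg_variable(grid), units = fg_units(grid))
  structure(g,
    baseline = as.integer(baseline),
    detrended = isTRUE(detrend),
    climatology = clim,
    class = c("anomaly_grid", class(g))
  )
}

# alternate OLS line removal (all non-missing months) with per-calendar-
# month baseline centering until both are null; NA preserved
detrend_backfit <- function(y, t, month, in_base, max_iter = 50L) {
  ok <- !is.na(y)
  if (sum(ok) < 2) return(y)
  scale <- sd(y[ok]) + 1e-30
  X <- cbind(1, t[ok])
  for (i in seq_len(max_iter)) {
    fit <- stats::lm.fit(X, y[ok])
    y[ok] <- fit$residuals
    mm <- tapply(y[ok & in_base], month[ok & in_base], mean)
    adj <- mm[as.character(month)]
    adj[is.na(adj)] <- 0
    y <- y - adj
    drift <- max(abs(fit$coefficients[2]) * diff(range(t[ok])),
                 max(abs(mm), na.rm = TRUE))
    if (!is.finite(drift) || drift < 1e-13 * scale) break
  }
  y
}

#' Seasonal window means of anomalies
#'
#' Arithmetic mean of the monthly anomalies in a window for each year and
#' cell (or region). Spring is April-June (`"AMJ"`), summer July-September
#' (`"JAS"`), and the growing season April-September (`"AprSep"`). A year
#' missing any month of the window yields a missing mean.
#'
#' @param x An `anomaly_grid`, `region_series`, or any data frame with
#'   columns `year`, `month`, `value` (plus optional `lat`/`lon`/`region`
#'   grouping columns).
#' @param window `"AMJ"`, `"JAS"` or `"AprSep"`.
#' @param years Optional integer vector restricting the years reported.
#' @return A tibble with the grouping columns, `year`, and `mean` (the
#'   window mean), one row per group-year.
#' @export
seasonal_window_mean <- function(x, window, years = NULL) {
  months <- window_months(window)
  grp <- intersect(c("region", "lat", "lon"), names(x))
  out <- as_tibble(x) %>%
    filter(.data$month %in% months) %>%
    group_by(across(dplyr::all_of(c(grp, "year")))) %>%
    summarise(
      mean = ifelse(sum(!is.na(.data$value)) == length(months),
                    mean(.data$value), NA_real_),
      .groups = "drop"
    )
  if (!is.null(years)) out <- filter(out, .data$year %in% .env$years)
  out
}
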