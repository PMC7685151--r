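# Small in-code fixtures shared across test files.

# grid whose values repeat a fixed 12-month pattern every year, plus an
# optional linear ramp (slope per year) and cell offsets
pattern_grid <- function(pattern = 1:12, years = 2001:2004,
                         lats = c(30, 34), lons = c(-100, -95),
                         slope = 0, offset = 0,
                         variable = "GPP", units = "gC m-2 month-1") {
  d <- tidyr::expand_grid(year = years, month = 1:12, lat = lats, lon = lons)
  t_frac <- (d$year - years[1]) + (d$month - 0.5) / 12
  d$value <- pattern[d$month] + slope * t_frac + offset
  flux_grid(d, variable = variable, units = units)
}

# single-series tibble (no lat/lon) of monthly anomalies from per-year
# spring/summer window values
series_from_windows <- function(spring, summer) {
  yrs <- seq_along(spring) + 2000L
  d <- tidyr::expand_grid(year = yrs, month = 1:12)
  d$value <- 0
  d$value[d$month %in% 4:6] <- rep(spring, each = 3)
  d$value[d$month %in% 7:9] <- rep(summer, each = 3)
  d
}

# uniform-weight mask over all cells of a grid
full_mask <- function(grid, name = "all") {
  region_mask(name, tidyr::expand_grid(lat = fg_lats(grid),
                                       lon = fg_lons(grid), weight = 1))
}

# small-domain generator config with all variability off unless overridden
noiseless_config <- function(years = 5, ...) {
  regions <- carboniav:::default_region_params("all")
  regions$sigma_amp <- 0
  regions$sigma_comp <- 0
  regions$sigma_eps <- 0
  regions$beta <- 0
  extra <- list(...)
  for (nm in names(extra)) regions[[nm]] <- extra[[nm]]
  synthetic_config(
    years = years,
    grid = list(lat_range = c(32, 40), lon_range = c(-110, -100)),
    regions = regions, seed = 9
  )
}

# fast series-level anomaly helper for Monte-Carlo tests: remove the
# per-calendar-month mean (full-record baseline, no detrending)
deseasonalize_series <- function(series) {
  out <- tibble::as_tibble(series)
  out |>
    dplyr::group_by(month) |>
    dplyr::mutate(value = value - mean(value, na.rm = TRUE)) |>
    dplyr::ungroup()
}
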