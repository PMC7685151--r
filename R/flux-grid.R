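#' Monthly gridded fields as tidy tibbles
#'
#' A `flux_grid` is the common currency of the package: one monthly,
#' time-indexed gridded field (a carbon flux or an environmental driver),
#' stored long-format with one row per (year, month, latitude, longitude)
#' cell. Missing observations are `NA` in `value`. Units are carried as an
#' attribute and preserved through I/O. Fluxes are intensive
#' (gC m-2 month-1); NEE uses the atmospheric sign convention throughout:
#' positive values are a flux from land to atmosphere.
#'
#' @param data A data frame with columns `year`, `month`, `lat`, `lon`,
#'   `value`. Any (time, cell) combinations absent from `data` are completed
#'   with `NA` values.
#' @param variable Name of the field (e.g. `"GPP"`, `"NEE"`, `"T"`, `"M"`).
#' @param units Unit string, preserved verbatim (e.g. `"gC m-2 month-1"`).
#'
#' @details Invariants enforced at construction: time labels are consecutive
#'   calendar months with no gaps; latitude and longitude centers are
#'   strictly increasing with uniform spacing; longitudes lie in
#'   \[-180, 180); latitudes in \[-90, 90\].
#'
#' @return A tibble of class `flux_grid` with columns
#'   `year`, `month`, `lat`, `lon`, `value`, ordered by time then cell.
#' @export
#' @examples
#' g <- flux_grid(
#'   expand.grid(year = 2001, month = 1:12, lat = c(30, 34), lon = c(-100, -95)) |>
#'     transform(value = 1),
#'   variable = "GPP", units = "gC m-2 month-1"
#' )
flux_grid <- function(data, variable, units = "") {
  data <- as_tibble(data)
  req <- c("year", "month", "lat", "lon", "value")
  if (!all(req %in% names(data))) {
    abort(paste0(
      "`data` must have columns ",
      paste(req, collapse = ", ")
    ))
  }
  data <- data[req]
  data$year <- as.integer(data$year)
  data$month <- as.integer(data$month)
  lats <- sort(unique(data$lat))
  lons <- sort(unique(data$lon))
  check_axis(lats, "lat")
  check_axis(lons, "lon")
  if (any(abs(lats) > 90)) abort("latitudes must lie in [-90, 90]")
  if (any(lons < -180 | lons >= 180)) {
    abort("longitudes must lie in [-180, 180); normalize before construction")
  }
  times <- month_seq(data$year, data$month)
  full <- tidyr::expand_grid(times, lat = lats, lon = lons)
  out <- left_join(full, data, by = c("year", "month", "lat", "lon"))
  if (nrow(out) != nrow(full)) {
    abort("duplicate (year, month, lat, lon) rows in `data`")
  }
  new_flux_grid(out, variable = variable, units = units)
}

new_flux_grid <- function(data, variable, units) {
  structure(
    as_tibble(data),
    variable = as.character(variable),
    units = as.character(units),
    class = c("flux_grid", class(tibble()))
  )
}

# consecutive (year, month) labels spanning the observed range
month_seq <- function(year, month) {
  idx <- year * 12L + (month - 1L)
  rng <- range(idx)
  seq_idx <- seq(rng[1], rng[2])
  tibble(year = seq_idx %/% 12L, month = seq_idx %% 12L + 1L)
}

check_axis <- function(x, name) {
  if (length(x) > 1) {
    d <- diff(x)
    if (any(d <= 0) || diff(range(d)) > 1e-6 * mean(d)) {
      abort(paste0(name, " centers must be strictly monotonic with uniform spacing"))
    }
  }
  invisible(x)
}

#' @export
print.flux_grid <- function(x, ...) {
  cat(sprintf(
    "<flux_grid> %s [%s]  %d months (%d-%02d to %d-%02d), %d x %d cells\n",
    fg_variable(x), fg_units(x),
    nrow(fg_times(x)),
    min(x$year), x$month[which.min(x$year * 12 + x$month)],
    max(x$year), x$month[which.max(x$year * 12 + x$month)],
    length(fg_lats(x)), length(fg_lons(x))
  ))
  NextMethod()
}

#' Accessors for flux_grid metadata
#'
#' @param grid A [flux_grid()].
#' @return `fg_variable()` and `fg_units()` return strings; `fg_lats()` and
#'   `fg_lons()` sorted coordinate centers; `fg_times()` a tibble of
#'   (`year`, `month`) labels in time order.
#' @export
fg_variable <- function(grid) attr(grid, "variable") %||% NA_character_

#' @rdname fg_variable
#' @export
fg_units <- function(grid) attr(grid, "units") %||% ""

#' @rdname fg_variable
#' @export
fg_lats <- function(grid) sort(unique(grid$lat))

#' @rdname fg_variable
#' @export
fg_lons <- function(grid) sort(unique(grid$lon))

#' @rdname fg_variable
#' @export
fg_times <- function(grid) {
  distinct(arrange(as_tibble(grid)[c("year", "month")], .data$year, .data$month))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# dense [time, lat, lon] array view; inverse below
fg_array <- function(grid) {
  lats <- fg_lats(grid)
  lons <- fg_lons(grid)
  times <- fg_times(grid)
  g <- arrange(as_tibble(grid), .data$lon, .data$lat, .data$year, .data$month)
  array(g$value, dim = c(nrow(times), length(lats), length(lons)))
}

fg_from_array <- function(values, times, lats, lons, variable, units) {
  out <- tidyr::expand_grid(lon = lons, lat = lats, times)
  out$value <- as.vector(values)
  out <- arrange(out, .data$year, .data$month, .data$lat, .data$lon)
  new_flux_grid(
    out[c("year", "month", "lat", "lon", "value")],
    variable = variable, units = units
  )
}

# uniform axis spacing; explicit override needed for single-center axes
axis_step <- function(x, default = NULL) {
  if (length(x) > 1) return(diff(x)[1])
  if (!is.null(default)) return(default)
  abort("cannot infer spacing from a single coordinate center; supply it explicitly")
}

# month windows used throughout: spring AMJ, summer JAS, growing season AprSep
window_months <- function(window) {
  switch(window,
    AMJ = 4:6,
    JAS = 7:9,
    AprSep = 4:9,
    abort(sprintf("unknown window '%s' (use AMJ, JAS or AprSep)", window))
  )
}
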