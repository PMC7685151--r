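#' Region masks as fractional cell weights
#'
#' A `region_mask` assigns each grid cell a weight in \[0, 1\]: the fraction
#' of the cell belonging to the region. Complementary masks in a default
#' west/east pair are pointwise disjoint.
#'
#' @param name Region name (e.g. `"west"`, `"east"`).
#' @param weights Data frame with columns `lat`, `lon`, `weight`.
#' @return A tibble of class `region_mask` with columns `lat`, `lon`,
#'   `weight` and a `region` attribute.
#' @export
region_mask <- function(name, weights) {
  weights <- as_tibble(weights)[c("lat", "lon", "weight")]
  if (any(weights$weight < 0 | weights$weight > 1)) {
    abort("mask weights must lie in [0, 1]")
  }
  if (!any(weights$weight > 0)) {
    abort("mask must have at least one strictly positive weight")
  }
  structure(weights,
    region = as.character(name),
    class = c("region_mask", class(tibble()))
  )
}

#' @rdname region_mask
#' @param mask A `region_mask`.
#' @export
mask_region <- function(mask) attr(mask, "region") %||% NA_character_

#' Default west/east region masks for temperate North America
#'
#' Rectangular-in-coordinates masks over a default domain of 24-52 degN,
#' 125-65 degW, split at the 103 degW meridian (west: lon < -103; east:
#' lon >= -103). Cells straddling a boundary receive the area fraction of
#' their overlap with the region box, so the pair tiles the domain exactly
#' and is pointwise disjoint. All bounds are configurable; the default split
#' is an approximation of the arid/mesic divide and should be adjusted for
#' other domains.
#'
#' @param grid A [flux_grid()] supplying the cell layout.
#' @param config List with elements `lat_range` (default `c(24, 52)`),
#'   `lon_range` (default `c(-125, -65)`) and `split_lon` (default `-103`).
#' @return A named list of two [region_mask()]s, `west` and `east`.
#' @export
default_masks <- function(grid, config = list()) {
  cfg <- modifyList(
    list(lat_range = c(24, 52), lon_range = c(-125, -65), split_lon = -103),
    config
  )
  if (cfg$split_lon <= cfg$lon_range[1] || cfg$split_lon >= cfg$lon_range[2]) {
    abort("split_lon must fall strictly inside lon_range")
  }
  lats <- fg_lats(grid); lons <- fg_lons(grid)
  dlat <- axis_step(lats, 4); dlon <- axis_step(lons, 5)
  cells <- tidyr::expand_grid(lat = lats, lon = lons)

  # fraction of each cell's area inside a lat x lon box
  box_frac <- function(lat, lon, lat_rng, lon_rng) {
    ll <- pmax(lat - dlat / 2, -90); lu <- pmin(lat + dlat / 2, 90)
    lat_num <- pmax(0, sinpi(pmin(lu, lat_rng[2]) / 180) -
                      sinpi(pmax(ll, lat_rng[1]) / 180))
    lat_den <- sinpi(lu / 180) - sinpi(ll / 180)
    lon_num <- pmax(0, pmin(lon + dlon / 2, lon_rng[2]) -
                      pmax(lon - dlon / 2, lon_rng[1]))
    (lat_num / lat_den) * (lon_num / dlon)
  }
  west_w <- box_frac(cells$lat, cells$lon, cfg$lat_range,
                     c(cfg$lon_range[1], cfg$split_lon))
  east_w <- box_frac(cells$lat, cells$lon, cfg$lat_range,
                     c(cfg$split_lon, cfg$lon_range[2]))
  list(
    west = region_mask("west", mutate(cells, weight = west_w)),
    east = region_mask("east", mutate(cells, weight = east_w))
  )
}

#' Aggregate a gridded field over a region
#'
#' Mode `"total"` computes the regional flux total per month,
#' `sum(value * area * weight)` converted gC to PgC (x 1e-15), for
#' intensive per-area fluxes. Mode `"mean"` computes the area-and-weight
#' weighted regional mean, appropriate for drivers (temperature, soil
#' moisture). Missing cells are excluded and the per-month coverage
#' fraction (weighted area with data / total weighted area) is recorded;
#' months with no contributing data are flagged missing, never silently
#' zero.
#'
#' @param grid A [flux_grid()].
#' @param mask A [region_mask()] on the same cell layout.
#' @param mode `"total"` or `"mean"`.
#' @return A tibble of class `region_series` with columns `region`, `year`,
#'   `month`, `value`, `coverage`; units attribute `"PgC month-1"` for
#'   totals, the field's own units for means.
#' @export
aggregate_region <- function(grid, mask, mode = c("total", "mean")) {
  mode <- match.arg(mode)
  stopifnot(inherits(grid, "flux_grid"))
  areas <- cell_areas(fg_lats(grid), fg_lons(grid),
                      dlat = axis_step(fg_lats(grid), 4),
                      dlon = axis_step(fg_lons(grid), 5))
  area_tbl <- tidyr::expand_grid(lat = fg_lats(grid), lon = fg_lons(grid))
  area_tbl$area <- as.vector(t(areas)) # expand_grid varies lon fastest
  w <- inner_join(as_tibble(mask), area_tbl, by = c("lat", "lon"))
  w$aw <- w$area * w$weight
  joined <- inner_join(as_tibble(grid), w[c("lat", "lon", "aw")],
                       by = c("lat", "lon"))
  if (nrow(joined) == 0) abort("mask does not match the flux grid cells")
  out <- joined %>%
    group_by(.data$year, .data$month) %>%
    summarise(
      total_aw = sum(.data$aw),
      got_aw = sum(.data$aw[!is.na(.data$value)]),
      value = if (mode == "total") {
        sum(.data$value * .data$aw, na.rm = TRUE) * 1e-15
      } else {
        sum(.data$value * .data$aw, na.rm = TRUE) /
          sum(.data$aw[!is.na(.data$value)])
      },
      .groups = "drop"
    ) %>%
    mutate(
      coverage = .data$got_aw / .data$total_aw,
      value = ifelse(.data$got_aw > 0, .data$value, NA_real_)
    ) %>%
    arrange(.data$year, .data$month)
  out$region <- mask_region(mask)
  structure(
    out[c("region", "year", "month", "value", "coverage")],
    units = if (mode == "total") "PgC month-1" else fg_units(grid),
    mode = mode,
    class = c("region_series", class(tibble()))
  )
}
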