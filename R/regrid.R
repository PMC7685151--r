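EARTH_RADIUS_M <- 6371e3 # spherical Earth, radius 6371 km

#' Spherical cell areas for a regular latitude-longitude grid
#'
#' Cells are spherical quadrilaterals on a sphere of radius 6371 km;
#' the area of a cell is `R^2 * dlon_rad * (sin(lat_u) - sin(lat_l))`,
#' with cell edges clipped at the poles. Coordinates are cell centers on
#' half-open edge intervals.
#'
#' @param lat_centers,lon_centers Cell-center coordinates (degrees),
#'   uniformly spaced.
#' @param dlat,dlon Cell sizes in degrees; inferred from the centers when an
#'   axis has two or more of them.
#' @return A `length(lat_centers)` x `length(lon_centers)` matrix of areas
#'   in m^2. Summed over a global grid this reproduces the sphere surface
#'   area to within 1e-6 relative.
#' @export
cell_areas <- function(lat_centers, lon_centers, dlat = NULL, dlon = NULL) {
  dlat <- axis_step(lat_centers, dlat)
  dlon <- axis_step(lon_centers, dlon)
  lat_u <- pmin(lat_centers + dlat / 2, 90)
  lat_l <- pmax(lat_centers - dlat / 2, -90)
  band <- EARTH_RADIUS_M^2 * (sinpi(lat_u / 180) - sinpi(lat_l / 180))
  outer(band, rep(dlon * pi / 180, length(lon_centers)))
}

# overlap of two sets of 1-D cells given centers and widths, in "measure"
# units: sin-latitude for lat axes (area-true), radians for lon axes.
overlap_matrix <- function(src_centers, src_w, tgt_centers, tgt_w, latitude) {
  sl <- src_centers - src_w / 2; su <- src_centers + src_w / 2
  tl <- tgt_centers - tgt_w / 2; tu <- tgt_centers + tgt_w / 2
  if (latitude) {
    sl <- pmax(sl, -90); su <- pmin(su, 90)
    tl <- pmax(tl, -90); tu <- pmin(tu, 90)
  }
  lo <- outer(sl, tl, pmax)
  hi <- outer(su, tu, pmin)
  if (latitude) {
    out <- sinpi(hi / 180) - sinpi(lo / 180)
  } else {
    out <- (hi - lo) * pi / 180
  }
  out[hi <= lo] <- 0
  out
}

#' Area-weighted regridding of an intensive field
#'
#' Each target cell value is the overlap-area-weighted mean of the source
#' cells it covers, the standard first-order conservative remapping for
#' intensive quantities (per-area fluxes, temperatures, volumetric soil
#' moisture). Missing source cells are excluded from the weight sum; a
#' target cell whose covered (non-missing) fraction falls below
#' `min_coverage` is set missing. A uniform field is preserved exactly at
#' any target resolution, and regridding a complete field onto a grid that
#' tiles the same domain preserves its global area-weighted mean.
#'
#' @param grid A [flux_grid()] on the source grid (resolution finer than or
#'   equal to the target).
#' @param target_lat,target_lon Target cell centers (degrees), uniformly
#'   spaced.
#' @param min_coverage Minimum covered area fraction of a target cell for it
#'   to be reported (default 0.5).
#' @param dlat,dlon Target cell sizes, inferred when possible.
#' @return A [flux_grid()] on the target grid, same variable and units.
#' @export
area_weighted_regrid <- function(grid, target_lat, target_lon,
                                 min_coverage = 0.5,
                                 dlat = NULL, dlon = NULL) {
  stopifnot(inherits(grid, "flux_grid"))
  check_axis(target_lat, "target_lat")
  check_axis(target_lon, "target_lon")
  src_lat <- fg_lats(grid); src_lon <- fg_lons(grid)
  s_dlat <- axis_step(src_lat); s_dlon <- axis_step(src_lon)
  t_dlat <- axis_step(target_lat, dlat); t_dlon <- axis_step(target_lon, dlon)

  w_lat <- overlap_matrix(src_lat, s_dlat, target_lat, t_dlat, latitude = TRUE)
  w_lon <- overlap_matrix(src_lon, s_dlon, target_lon, t_dlon, latitude = FALSE)
  if (sum(w_lat) == 0 || sum(w_lon) == 0) {
    abort("source and target grids do not overlap")
  }

  # full target-cell measure for coverage accounting
  tgt_area <- outer(
    sinpi(pmin(target_lat + t_dlat / 2, 90) / 180) -
      sinpi(pmax(target_lat - t_dlat / 2, -90) / 180),
    rep(t_dlon * pi / 180, length(target_lon))
  )

  arr <- fg_array(grid)
  times <- fg_times(grid)
  n_t <- nrow(times)
  out <- array(NA_real_, dim = c(n_t, length(target_lat), length(target_lon)))
  for (k in seq_len(n_t)) {
    v <- matrix(arr[k, , ], length(src_lat), length(src_lon))
    present <- !is.na(v)
    v0 <- ifelse(present, v, 0)
    numer <- crossprod(w_lat, v0) %*% w_lon
    denom <- crossprod(w_lat, present * 1) %*% w_lon
    val <- numer / denom
    val[denom / tgt_area < min_coverage] <- NA_real_
    out[k, , ] <- val
  }
  if (all(is.na(out))) abort("regrid produced an empty output (no covered target cells)")
  fg_from_array(out, times, target_lat, target_lon,
                variable = fg_variable(grid), units = fg_units(grid))
}
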