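test_that("gridded fields round-trip through the text format losslessly", {
  set.seed(42)
  g <- pattern_grid()
  vals <- runif(nrow(g), -50, 400)
  vals[c(3, 17, 90)] <- NA # missing cells must survive
  g$value <- vals
  path <- withr::local_tempfile(fileext = ".csv")
  write_gridded(g, path)
  g2 <- read_gridded(path, "GPP")
  expect_identical(g2$value, g$value)
  expect_identical(fg_lats(g2), fg_lats(g))
  expect_identical(fg_lons(g2), fg_lons(g))
  expect_identical(fg_units(g2), "gC m-2 month-1")
  expect_identical(fg_variable(g2), "GPP")
})

test_that("reading a file without the requested variable is a format error", {
  g <- pattern_grid()
  path <- withr::local_tempfile(fileext = ".csv")
  write_gridded(g, path)
  expect_error(read_gridded(path, "NEE"), "not present")
  expect_error(read_gridded(tempfile(), "GPP"), "no such file")
})

test_that("longitudes on [0, 360) are remapped into [-180, 180) consistently", {
  # values encode their own original longitude, so after remapping each
  # cell must carry the value of the source longitude it came from
  lons360 <- c(0, 90, 180, 270)
  d <- tidyr::expand_grid(year = 2001, month = 1:12, lat = c(-10, 10),
                          lon = lons360)
  d$value <- d$lon * 1000 + d$lat
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(d, path)
  hdr <- c("# variable: GPP", "# units: x", readLines(path))
  writeLines(hdr, path)
  g <- read_gridded(path, "GPP")
  expect_equal(fg_lons(g), c(-180, -90, 0, 90))
  sub <- g[g$month == 1 & g$lat == 10, ]
  expect_equal(sub$value[sub$lon == -90], 270 * 1000 + 10)
  expect_equal(sub$value[sub$lon == 0], 0 * 1000 + 10)
  expect_equal(sub$value[sub$lon == -180], 180 * 1000 + 10)
})

test_that("flux_grid enforces its invariants", {
  d <- tidyr::expand_grid(year = 2001, month = 1:12, lat = c(0, 4, 12),
                          lon = -100)
  d$value <- 1
  expect_error(flux_grid(d, "x"), "uniform spacing")
  d2 <- tidyr::expand_grid(year = 2001, month = 1:12, lat = 95, lon = -100)
  d2$value <- 1
  expect_error(flux_grid(d2, "x"), "-90, 90")
  # gap-free monthly time axis is completed with NA rows
  d3 <- tidyr::expand_grid(year = 2001, month = c(1, 3), lat = 0, lon = 0)
  d3$value <- 1
  g3 <- flux_grid(d3, "x")
  expect_equal(nrow(g3), 3)
  expect_true(is.na(g3$value[g3$month == 2]))
})

test_that("cell areas reproduce the sphere and match quadrature", {
  R <- 6371e3
  lat4 <- seq(-88, 88, by = 4)
  lon5 <- seq(-177.5, 177.5, by = 5)
  a <- cell_areas(lat4, lon5)
  expect_equal(sum(a), 4 * pi * R^2, tolerance = 1e-6)
  expect_true(all(a > 0))
  # symmetry: equal |lat| implies equal area
  expect_equal(a[lat4 == -60, 1], a[lat4 == 60, 1])
  # one 1x1 degree equatorial cell against direct numerical integration
  a1 <- cell_areas(0.5, 0.5, dlat = 1, dlon = 1)[1, 1]
  oracle <- stats::integrate(function(phi) cos(phi), 0, pi / 180,
                             rel.tol = 1e-12)$value * (pi / 180) * R^2
  expect_equal(a1, oracle, tolerance = 1e-9)
})

test_that("regridding preserves uniform fields exactly and handles missing sources", {
  src <- pattern_grid(pattern = rep(7, 12), years = 2001,
                      lats = seq(30.5, 37.5, by = 1),
                      lons = seq(-99.5, -90.5, by = 1))
  tgt <- area_weighted_regrid(src, target_lat = c(32, 36),
                              target_lon = c(-97.5, -92.5))
  expect_lt(max(abs(tgt$value - 7)), 1e-12)
  # a target cell whose sources are all missing comes out missing
  src2 <- src
  src2$value[src2$lat < 34 & src2$lon < -95] <- NA
  tgt2 <- area_weighted_regrid(src2, c(32, 36), c(-97.5, -92.5))
  expect_true(all(is.na(tgt2$value[tgt2$lat == 32 & tgt2$lon == -97.5])))
  expect_lt(max(abs(tgt2$value[tgt2$lat == 36 & tgt2$lon == -92.5] - 7)), 1e-12)
  expect_error(area_weighted_regrid(src, c(80), c(100), dlat = 4, dlon = 5),
               "not overlap")
})

test_that("regridding a linear-in-latitude field matches the closed-form weights", {
  lats <- seq(30.5, 37.5, by = 1)
  src <- pattern_grid(pattern = rep(1, 12), years = 2001, lats = lats,
                      lons = seq(-99.5, -90.5, by = 1))
  src$value <- 2 * src$lat + 3
  tgt <- area_weighted_regrid(src, c(32, 36), c(-97.5, -92.5))
  # independent arithmetic: sin-latitude band weights over the four source
  # rows under each target row
  band_w <- function(centers) {
    sinpi((centers + 0.5) / 180) - sinpi((centers - 0.5) / 180)
  }
  for (tlat in c(32, 36)) {
    rows <- lats[lats > tlat - 2 & lats < tlat + 2]
    expected <- sum((2 * rows + 3) * band_w(rows)) / sum(band_w(rows))
    got <- tgt$value[tgt$lat == tlat & tgt$month == 1][1]
    expect_equal(got, expected, tolerance = 1e-10)
  }
})

test_that("regridding preserves the global area-weighted mean of complete fields", {
  set.seed(7)
  lats1 <- seq(-89.5, 89.5, by = 1)
  lons1 <- seq(-179, 179, by = 2) # 2-degree cells tiling [-180, 180]
  vals <- array(rnorm(length(lats1) * length(lons1)),
                dim = c(1, length(lats1), length(lons1)))
  src <- carboniav:::fg_from_array(vals, tibble::tibble(year = 2001L, month = 1L),
                                   lats1, lons1, "x", "")
  tgt <- area_weighted_regrid(src, seq(-88, 88, by = 4), seq(-177.5, 177.5, by = 5))
  wm <- function(g) {
    a <- cell_areas(fg_lats(g), fg_lons(g))
    arr <- matrix(g$value[order(g$lon, g$lat)], nrow = length(fg_lats(g)))
    sum(arr * a) / sum(a)
  }
  expect_equal(wm(tgt), wm(src), tolerance = 1e-10)
})

test_that("regional aggregation matches explicit per-cell loops and is linear", {
  set.seed(11)
  g <- pattern_grid(years = 2001:2002)
  g$value <- rnorm(nrow(g))
  w <- tidyr::expand_grid(lat = fg_lats(g), lon = fg_lons(g))
  w$weight <- runif(nrow(w))
  mask <- region_mask("r", w)
  out <- aggregate_region(g, mask, mode = "total")
  areas <- cell_areas(fg_lats(g), fg_lons(g))
  # explicit loop oracle for one month
  oracle_month <- function(yy, mm) {
    s <- 0
    for (i in seq_along(fg_lats(g))) {
      for (j in seq_along(fg_lons(g))) {
        v <- g$value[g$year == yy & g$month == mm &
                       g$lat == fg_lats(g)[i] & g$lon == fg_lons(g)[j]]
        wt <- w$weight[w$lat == fg_lats(g)[i] & w$lon == fg_lons(g)[j]]
        s <- s + v * areas[i, j] * wt
      }
    }
    s * 1e-15
  }
  expect_equal(out$value[out$year == 2001 & out$month == 5], oracle_month(2001, 5))
  expect_equal(out$value[out$year == 2002 & out$month == 11], oracle_month(2002, 11))

  # linearity: aggregate(f + g) = aggregate(f) + aggregate(g)
  g2 <- g
  g2$value <- rnorm(nrow(g2))
  gsum <- g
  gsum$value <- g$value + g2$value
  expect_equal(aggregate_region(gsum, mask)$value,
               aggregate_region(g, mask)$value + aggregate_region(g2, mask)$value)
})

test_that("uniform fields aggregate to f * area and to the uniform mean", {
  g <- pattern_grid(pattern = rep(3, 12), years = 2001)
  mask <- full_mask(g)
  A <- sum(cell_areas(fg_lats(g), fg_lons(g)))
  tot <- aggregate_region(g, mask, mode = "total")
  expect_equal(unique(tot$value), 3 * A * 1e-15)
  mn <- aggregate_region(g, mask, mode = "mean")
  expect_equal(unique(mn$value), 3)
})

test_that("all-missing months are flagged missing with zero coverage", {
  g <- pattern_grid(years = 2001)
  g$value[g$month == 6] <- NA
  out <- aggregate_region(g, full_mask(g))
  expect_true(is.na(out$value[out$month == 6]))
  expect_equal(out$coverage[out$month == 6], 0)
  expect_equal(out$coverage[out$month == 7], 1)
})

test_that("default west/east masks split the domain at the configured meridian", {
  g <- pattern_grid(years = 2001, lats = seq(26, 50, by = 4),
                    lons = seq(-122.5, -67.5, by = 5))
  masks <- default_masks(g)
  w <- masks$west
  e <- masks$east
  at <- function(m, lat, lon) m$weight[m$lat == lat & m$lon == lon]
  expect_equal(at(w, 38, -112.5), 1)
  expect_equal(at(e, 38, -112.5), 0)
  expect_equal(at(e, 38, -77.5), 1)
  expect_equal(at(w, 38, -77.5), 0)
  # the straddling cell (edges -105, -100) splits 2/5 west, 3/5 east
  expect_equal(at(w, 38, -102.5), 2 / 5)
  expect_equal(at(e, 38, -102.5), 3 / 5)
  # disjoint and tiling inside the domain
  expect_true(all(w$weight * e$weight == 0 |
                    abs(w$weight + e$weight - 1) < 1e-12))
  expect_error(default_masks(g, list(split_lon = -200)), "split_lon")
})
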