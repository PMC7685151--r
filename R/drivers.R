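# Pearson correlation + OLS of yearly window means, two-sided t test with
# n - 2 degrees of freedom. Shared by the gridded and regional paths.
year_pair_stats <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3) {
    return(tibble(r = NA_real_, slope = NA_real_, intercept = NA_real_,
                  r_squared = NA_real_, p_value = NA_real_, n_years = n))
  }
  x <- x[ok]; y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble(r = NA_real_, slope = NA_real_, intercept = NA_real_,
                  r_squared = NA_real_, p_value = NA_real_, n_years = n))
  }
  r <- cor(x, y)
  slope <- r * sd(y) / sd(x)
  tstat <- r * sqrt(n - 2) / sqrt(max(1 - r^2, .Machine$double.eps))
  tibble(
    r = r,
    slope = slope,
    intercept = mean(y) - slope * mean(x),
    r_squared = r^2,
    p_value = 2 * pt(-abs(tstat), df = n - 2),
    n_years = n
  )
}

#' Windowed (and lagged) flux-driver correlation maps
#'
#' For every grid cell, the Pearson correlation between yearly flux-window
#' mean anomalies and yearly driver-window mean anomalies over the common
#' years, with a two-sided p-value from the t statistic on n - 2 degrees of
#' freedom and a significance flag at `alpha`. The lagged pairing of
#' interest correlates July-September flux anomalies with April-September
#' driver anomalies, capturing delayed effects of spring climate on summer
#' carbon fluxes; contemporaneous pairings use matching windows. No
#' autocorrelation or multiple-testing correction is applied (per-cell
#' significance only) - a documented limitation.
#'
#' @param flux,driver `anomaly_grid`s on the same grid, or `region_series`
#'   of anomalies on matching region labels.
#' @param flux_window,driver_window `"AMJ"`, `"JAS"` or `"AprSep"`.
#' @param alpha Significance level for the flag (default 0.05).
#' @param years Optional restriction of the years used.
#' @return A tibble with one row per cell (or region): the grouping
#'   columns, `flux_window`, `driver_window`, `r`, `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n_years`, `significant`. Units with fewer
#'   than 3 common years are reported missing.
#' @export
windowed_correlation <- function(flux, driver, flux_window, driver_window,
                                 alpha = 0.05, years = NULL) {
  fx <- seasonal_window_mean(flux, flux_window, years = years)
  dv <- seasonal_window_mean(driver, driver_window, years = years)
  grp <- setdiff(intersect(names(fx), names(dv)), c("year", "mean"))
  joined <- inner_join(
    rename(fx, flux = "mean"), rename(dv, driver = "mean"),
    by = c(grp, "year")
  )
  out <- joined %>%
    group_by(across(dplyr::all_of(grp))) %>%
    summarise(year_pair_stats(.data$flux, .data$driver), .groups = "drop") %>%
    mutate(
      flux_window = .env$flux_window,
      driver_window = .env$driver_window,
      significant = !is.na(.data$p_value) & .data$p_value < alpha
    )
  out[c(grp, "flux_window", "driver_window", "r", "slope",
        "intercept", "r_squared", "p_value", "n_years", "significant")]
}

#' Regional flux-to-driver sensitivity regression
#'
#' OLS regression of yearly April-September regional flux anomaly totals
#' (seasonal totals in PgC: window-mean monthly anomaly x number of window
#' months) on yearly regional driver anomaly means (area-weighted, in the
#' driver's units), giving a sensitivity in PgC K-1 or
#' PgC (m3 m-3)-1. Returns a fitted object carrying the underlying
#' [stats::lm()] fit; [glance()] gives the slope, R-squared and p-value,
#' [tidy()] the per-term coefficients.
#'
#' @param flux_region A `region_series` of flux anomaly totals
#'   (PgC month-1).
#' @param driver_region A `region_series` of driver anomaly means.
#' @param window Window over which yearly values are formed (default
#'   `"AprSep"`).
#' @param years Optional restriction of the years used.
#' @return An object of class `driver_fit`.
#' @export
sensitivity_regression <- function(flux_region, driver_region,
                                   window = "AprSep", years = NULL) {
  n_m <- length(window_months(window))
  fx <- seasonal_window_mean(flux_region, window, years = years) %>%
    mutate(flux = .data$mean * n_m) %>%
    select("year", "flux")
  dv <- seasonal_window_mean(driver_region, window, years = years) %>%
    rename(driver = "mean") %>%
    select("year", "driver")
  d <- inner_join(fx, dv, by = "year") %>%
    filter(!is.na(.data$flux), !is.na(.data$driver))
  if (nrow(d) < 3) abort("need at least 3 common years")
  if (sd(d$driver) == 0) abort("driver series has zero variance")
  fit <- lm(flux ~ driver, data = d)
  structure(
    list(
      fit = fit, data = d, window = window,
      region = if ("region" %in% names(flux_region)) {
        flux_region$region[1]
      } else {
        NA_character_
      }
    ),
    class = "driver_fit"
  )
}

#' @export
print.driver_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<driver_fit> %s window: slope %.4g, R^2 %.3f, p %.3g (n = %d years)\n",
    x$window, g$slope, g$r_squared, g$p_value, g$n_years
  ))
  invisible(x)
}

#' Tidy and glance methods for sensitivity regressions
#'
#' @param x A `driver_fit` from [sensitivity_regression()].
#' @param ... Unused.
#' @return `tidy()`: one row per coefficient with estimate, standard error,
#'   statistic and p-value. `glance()`: a one-row summary with `slope`,
#'   `intercept`, `r`, `r_squared`, `p_value` (two-sided, for the slope),
#'   `slope_se` and `n_years`.
#' @export
tidy.driver_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = rownames(s),
    estimate = unname(s[, "Estimate"]),
    std_error = unname(s[, "Std. Error"]),
    statistic = unname(s[, "t value"]),
    p_value = unname(s[, "Pr(>|t|)"])
  )
}

#' @rdname tidy.driver_fit
#' @export
glance.driver_fit <- function(x, ...) {
  s <- summary(x$fit)
  co <- s$coefficients
  tibble(
    slope = co["driver", "Estimate"],
    intercept = co["(Intercept)", "Estimate"],
    r = sign(co["driver", "Estimate"]) * sqrt(s$r.squared),
    r_squared = s$r.squared,
    p_value = co["driver", "Pr(>|t|)"],
    slope_se = co["driver", "Std. Error"],
    n_years = nrow(x$data)
  )
}

#' Correlations of seasonal components with driver windows
#'
#' Pearson correlations of the per-year compensation and amplification
#' components with yearly driver anomalies over standard windows: spring
#' (AMJ) and growing-season (AprSep) temperature, spring, summer (JAS) and
#' growing-season soil moisture, and growing-season precipitation when
#' supplied. All-zero (zero-variance) components are reported missing.
#'
#' @param components A tibble from [components_per_year()] for one series
#'   (columns `year`, `comp`, `amp`).
#' @param temp,moist `region_series` (or data frames with `year`, `month`,
#'   `value`) of driver anomalies.
#' @param precip Optional precipitation anomaly series.
#' @return A long tibble: `component` (`"comp"`/`"amp"`), `driver`,
#'   `window`, `r`, `p_value`, `n_years`.
#' @export
component_driver_table <- function(components, temp, moist, precip = NULL) {
  if (nrow(components) < 3) abort("need at least 3 years of components")
  pairs <- list(
    list(driver = "T", window = "AMJ", series = temp),
    list(driver = "T", window = "AprSep", series = temp),
    list(driver = "M", window = "AMJ", series = moist),
    list(driver = "M", window = "JAS", series = moist),
    list(driver = "M", window = "AprSep", series = moist)
  )
  if (!is.null(precip)) {
    pairs <- c(pairs, list(list(driver = "P", window = "AprSep", series = precip)))
  }
  purrr::map_dfr(pairs, function(p) {
    dv <- seasonal_window_mean(p$series, p$window)
    dv <- dv[c("year", "mean")]
    d <- inner_join(as_tibble(components), dv, by = "year")
    purrr::map_dfr(c("comp", "amp"), function(cmp) {
      st <- year_pair_stats(d$mean, d[[cmp]])
      tibble(component = cmp, driver = p$driver, window = p$window,
             r = st$r, p_value = st$p_value, n_years = st$n_years)
    })
  })
}
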