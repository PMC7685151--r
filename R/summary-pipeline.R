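#' Regional mean-flux and IAV-magnitude summary
#'
#' The three regional quantities behind the east/west contribution
#' comparison, per variable:
#' (i) the April-September mean flux (mean over years of the seasonal
#' total, PgC per season), (ii) the mean magnitude of April-September
#' anomalies (mean over years of the absolute yearly April-September mean
#' anomaly, scaled to a seasonal total, PgC per season), and (iii) their
#' ratio as a percent (IAV relative to the mean flux).
#'
#' @param flux A raw [flux_grid()] (for the mean flux).
#' @param anoms The matching `anomaly_grid` (for the anomaly magnitudes).
#' @param mask A [region_mask()].
#' @param years Optional restriction of the years used.
#' @return A one-row tibble of class `region_summary`: `region`,
#'   `variable`, `mean_AprSep_flux`, `mean_abs_AprSep_anomaly`,
#'   `iav_to_mean` (percent), `n_years`.
#' @export
region_summary <- function(flux, anoms, mask, years = NULL) {
  flux_series <- aggregate_region(flux, mask, mode = "total")
  anom_series <- aggregate_region(anoms, mask, mode = "total")
  fx <- seasonal_window_mean(flux_series, "AprSep", years = years)
  ax <- seasonal_window_mean(anom_series, "AprSep", years = years)
  common <- inner_join(
    rename(fx, flux = "mean"), rename(ax, anom = "mean"),
    by = c("region", "year")
  ) %>%
    filter(!is.na(.data$flux), !is.na(.data$anom))
  mean_flux <- mean(common$flux) * 6
  mean_abs_anom <- mean(abs(common$anom)) * 6
  out <- tibble(
    region = mask_region(mask),
    variable = fg_variable(flux),
    mean_AprSep_flux = mean_flux,
    mean_abs_AprSep_anomaly = mean_abs_anom,
    iav_to_mean = ifelse(abs(mean_flux) > 0,
                         100 * mean_abs_anom / abs(mean_flux), NA_real_),
    n_years = nrow(common)
  )
  structure(out, class = c("region_summary", class(tibble())))
}

#' West/east contribution contrast
#'
#' Ratios comparing two regional summaries of the same variable: the
#' west-over-east ratio of mean anomaly magnitudes (the IAV contribution
#' contrast, also reported as a percent) and the east-over-west ratio of
#' mean flux magnitudes (the productivity contrast). Both identities are
#' recomputable from the two input rows.
#'
#' @param west,east `region_summary` rows for the same variable and year
#'   set.
#' @return A one-row tibble: `variable`,
#'   `west_over_east_anomaly_ratio`, `west_over_east_anomaly_pct`,
#'   `east_over_west_mean_ratio`, plus `degenerate` flagging zero
#'   denominators.
#' @export
contrast <- function(west, east) {
  if (!identical(west$variable, east$variable)) {
    abort("summaries compare different variables")
  }
  an_ratio <- ifelse(east$mean_abs_AprSep_anomaly > 0,
                     west$mean_abs_AprSep_anomaly / east$mean_abs_AprSep_anomaly,
                     NA_real_)
  mn_ratio <- ifelse(abs(west$mean_AprSep_flux) > 0,
                     abs(east$mean_AprSep_flux) / abs(west$mean_AprSep_flux),
                     NA_real_)
  tibble(
    variable = west$variable,
    west_over_east_anomaly_ratio = an_ratio,
    west_over_east_anomaly_pct = 100 * an_ratio,
    east_over_west_mean_ratio = mn_ratio,
    degenerate = is.na(an_ratio) | is.na(mn_ratio)
  )
}

#' Run the full IAV analysis end to end
#'
#' Orchestrates the whole pipeline on a two-region dataset: anomaly
#' construction for fluxes and drivers, per-cell RATIO map, regional
#' aggregation, per-region seasonal components and RATIO, SVD mode tables,
#' driver correlations (contemporaneous and lagged) and sensitivity
#' regressions, regional summaries and the west/east contrast. Fully
#' deterministic given the config (and its seed, when simulating).
#'
#' @param config Either a `synthetic_config` (or preset name) to simulate
#'   from, a path to a YAML config file, or a list with elements
#'   `preset`/`seed`/`years`, plus optional `baseline`
#'   (default: the full simulated period), `detrend` (default `TRUE` for
#'   multi-decade records, `FALSE` under 8 years), and `regions`
#'   (bounding-box config for [default_masks()]).
#' @param out_dir Optional directory; when given, all tables are written as
#'   CSV together with a `manifest.json` recording the configuration, seed
#'   and package version.
#' @return Invisibly, a named list: `data` (the four grids), `anomalies`,
#'   `ratio_map`, `regional` (per-region components, RATIO, modes),
#'   `drivers` (correlation maps and sensitivity fits),
#'   `summaries`, `contrasts`, and `manifest`.
#' @export
run_pipeline <- function(config = preset("two-region"), out_dir = NULL) {
  if (is.character(config) && length(config) == 1 && file.exists(config)) {
    config <- yaml::read_yaml(config)
  }
  if (is.character(config)) config <- list(preset = config)
  if (is.list(config) && !inherits(config, "synthetic_config")) {
    config <- modifyList(list(preset = "two-region", seed = 1, years = 17,
                              baseline = NULL, detrend = NULL), config)
    cfg <- preset(config$preset, years = config$years, seed = config$seed)
    extra <- config[c("baseline", "detrend")]
  } else {
    cfg <- config
    extra <- list(baseline = NULL, detrend = NULL)
  }
  data <- generate_dataset(cfg)
  yrs <- range(fg_times(data$gpp)$year)
  baseline <- extra$baseline %||% yrs
  detrend <- extra$detrend %||% (diff(yrs) + 1 >= 8)

  anoms <- purrr::map(data, compute_anomalies, baseline = baseline,
                      detrend = detrend)
  masks <- default_masks(data$gpp, cfg$grid)

  rmap <- ratio_map(anoms$gpp, temp = data$temp, moist = data$moist)

  regional <- purrr::map(masks, function(mask) {
    series <- purrr::map2(
      anoms, c(gpp = "total", nee = "total", temp = "mean", moist = "mean"),
      function(a, mode) aggregate_region(a, mask, mode = mode)
    )
    comps <- purrr::map(series[c("gpp", "nee")], components_per_year)
    list(
      series = series,
      components = comps,
      ratio = purrr::imap_dfr(comps, function(x, v) {
        mutate(ratio_metric(x), variable = toupper(v), .before = 1)
      }),
      modes = purrr::map(series[c("gpp", "nee")], function(s) {
        svd_modes(build_month_year_matrix(s))
      }),
      driver_table = component_driver_table(
        comps$gpp, temp = series$temp, moist = series$moist
      ),
      sensitivity = purrr::map(
        list(gpp_T = c("gpp", "temp"), gpp_M = c("gpp", "moist"),
             nee_T = c("nee", "temp"), nee_M = c("nee", "moist")),
        function(p) sensitivity_regression(series[[p[1]]], series[[p[2]]])
      )
    )
  })

  corr_maps <- bind_rows(
    windowed_correlation(anoms$gpp, anoms$temp, "AMJ", "AMJ"),
    windowed_correlation(anoms$gpp, anoms$temp, "JAS", "AprSep"),
    windowed_correlation(anoms$gpp, anoms$moist, "AMJ", "AMJ"),
    windowed_correlation(anoms$gpp, anoms$moist, "JAS", "AprSep")
  )

  summaries <- purrr::map_dfr(masks, function(mask) {
    bind_rows(
      region_summary(data$gpp, anoms$gpp, mask),
      region_summary(data$nee, anoms$nee, mask)
    )
  })
  contrasts <- purrr::map_dfr(c("GPP", "NEE"), function(v) {
    s <- filter(summaries, .data$variable == v)
    contrast(filter(s, .data$region == "west"), filter(s, .data$region == "east"))
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("carboniav")),
    seed = cfg$seed, years = cfg$years, start_year = cfg$start_year,
    baseline = as.integer(baseline), detrend = detrend,
    regions = as.list(cfg$regions$region),
    grid = cfg$grid
  )

  result <- list(
    data = data, anomalies = anoms, masks = masks, ratio_map = rmap,
    regional = regional, driver_maps = corr_maps,
    summaries = summaries, contrasts = contrasts, manifest = manifest
  )
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  invisible(result)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) {
    readr::write_csv(x, file.path(out_dir, paste0(name, ".csv")))
  }
  w(result$ratio_map, "ratio_map")
  w(result$driver_maps, "driver_correlations")
  w(result$summaries, "region_summaries")
  w(result$contrasts, "contrasts")
  for (rg in names(result$regional)) {
    reg <- result$regional[[rg]]
    w(reg$ratio, paste0("ratio_", rg))
    w(reg$driver_table, paste0("component_driver_", rg))
    modes <- purrr::imap_dfr(reg$modes, function(m, v) {
      mutate(tidy(m), variable = toupper(v), .before = 1)
    })
    w(modes, paste0("modes_", rg))
    sens <- purrr::imap_dfr(reg$sensitivity, function(f, nm) {
      mutate(glance(f), pairing = nm, .before = 1)
    })
    w(sens, paste0("sensitivity_", rg))
  }
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Multi-dataset model-versus-observation comparison table
#'
#' Recomputes the regional IAV summaries for a collection of labelled
#' datasets (e.g. several flux products or model runs with different year
#' ranges): per dataset x region x variable, the mean absolute
#' compensation and amplification components, the RATIO, and the
#' region-summary quantities, over (a) each dataset's full period and (b)
#' an optional common sub-period - making period sensitivity explicit.
#'
#' @param datasets Named list; each element a list with `flux` (a raw
#'   [flux_grid()]) and `anoms` (its `anomaly_grid`).
#' @param masks Named list of [region_mask()]s.
#' @param common_years Optional integer vector of years for the shared
#'   sub-period pass.
#' @return A long tibble: `dataset`, `region`, `variable`, `period`,
#'   `years`, `mean_abs_comp`, `mean_abs_amp`, `ratio`,
#'   `mean_AprSep_flux`, `mean_abs_AprSep_anomaly`, `iav_to_mean`.
#' @export
model_vs_obs_table <- function(datasets, masks, common_years = NULL) {
  one <- function(flux, anoms, mask, years, period, dataset) {
    series <- aggregate_region(anoms, mask, mode = "total")
    comps <- components_per_year(series)
    if (!is.null(years)) comps <- filter(comps, .data$year %in% .env$years)
    rm_ <- ratio_metric(comps)
    rs <- region_summary(flux, anoms, mask, years = years)
    tibble(
      dataset = dataset, region = mask_region(mask),
      variable = fg_variable(flux), period = period,
      years = nrow(comps),
      mean_abs_comp = mean(abs(comps$comp)),
      mean_abs_amp = mean(abs(comps$amp)),
      ratio = rm_$ratio,
      mean_AprSep_flux = rs$mean_AprSep_flux,
      mean_abs_AprSep_anomaly = rs$mean_abs_AprSep_anomaly,
      iav_to_mean = rs$iav_to_mean
    )
  }
  purrr::imap_dfr(datasets, function(ds, nm) {
    purrr::map_dfr(masks, function(mask) {
      full <- one(ds$flux, ds$anoms, mask, NULL, "full", nm)
      if (is.null(common_years)) return(full)
      bind_rows(
        full,
        one(ds$flux, ds$anoms, mask, common_years, "common", nm)
      )
    })
  })
}
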