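#' Write / read per-region daily weather CSV
#'
#' Columns: date fields (`year`, `doy`), `cell_id`, `area_weight`,
#' `precip`, `tas`, `tasmax`, `tasmin`.
#'
#' @param weather a `region_weather`.
#' @param path CSV file path.
#' @export
write_weather_csv <- function(weather, path) {
  df <- as.data.frame(weather)[, c("year", "doy", "cell_id", "area_weight",
                                   "precip", "tas", "tasmax", "tasmin")]
  df$region <- attr(weather, "region")
  df$regime <- attr(weather, "regime")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weather_csv
#' @param harvest_years harvest years the series supports (stored as an
#'   attribute; the base year is inferred from the data).
#' @export
read_weather_csv <- function(path, harvest_years = NULL) {
  df <- read.csv(path)
  base_year <- min(df$year)
  df$day <- day_index(df$year, df$doy, base_year)
  region <- df$region[1]
  regime <- df$regime[1]
  df <- df[order(df$cell_id, df$day),
           c("cell_id", "area_weight", "year", "doy", "day",
             "precip", "tas", "tasmax", "tasmin")]
  structure(df, region = region, regime = regime, base_year = base_year,
            years = as.integer(harvest_years %||% ((base_year + 1):max(df$year))),
            class = c("region_weather", "data.frame"))
}

#' Write / read monthly SST anomaly CSV
#'
#' Columns: `index`, `year`, `month`, `anomaly`.
#'
#' @param sst_list named list of `sst_series` objects.
#' @param path CSV file path.
#' @export
write_sst_csv <- function(sst_list, path) {
  df <- do.call(rbind, lapply(sst_list, function(s)
    as.data.frame(s)[, c("index", "year", "month", "anomaly")]))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sst_csv
#' @export
read_sst_csv <- function(path) {
  df <- read.csv(path)
  base_year <- min(df$year)
  out <- lapply(split(df, df$index), function(s) {
    s <- s[order(s$year, s$month), ]
    s$mid_day <- (s$year - base_year) * DAYS_PER_YEAR + MONTH_MIDPOINTS[s$month]
    structure(s[, c("index", "year", "month", "mid_day", "anomaly")],
              base_year = base_year,
              class = c("sst_series", "data.frame"))
  })
  out[order(match(names(out), c("nino34", "wp", "iod")))]
}

#' Write / read annual yields CSV
#'
#' Columns: `region`, `year`, `yield_t_ha`.
#'
#' @param yields a `yield_series` (or several row-bound).
#' @param path CSV file path.
#' @export
write_yields_csv <- function(yields, path) {
  df <- data.frame(region = yields$region, year = yields$year,
                   yield_t_ha = yields$yield)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_yields_csv
#' @export
read_yields_csv <- function(path) {
  df <- read.csv(path)
  structure(data.frame(region = df$region, year = as.integer(df$year),
                       yield = df$yield_t_ha),
            class = c("yield_series", "data.frame"))
}

#' Write / read the regional crop-calendar CSV
#'
#' Columns: `region`, `regime`, `onset_doy`, `split_doy`, `end_doy`,
#' `lead_time_days` (plus the season-relative split and year offset needed
#' to rebuild the calendar object).
#'
#' @param calendars list of `season_calendar` objects.
#' @param path CSV file path.
#' @export
write_calendar_csv <- function(calendars, path) {
  df <- do.call(rbind, lapply(calendars, function(cal)
    data.frame(region = cal$region, regime = cal$regime,
               onset_doy = cal$onset_doy, split_doy = cal$split_doy,
               end_doy = cal$end_doy, lead_time_days = cal$lead_time_days,
               split = cal$split, season_length = cal$season_length,
               onset_year_offset = cal$onset_year_offset)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calendar_csv
#' @export
read_calendar_csv <- function(path) {
  df <- read.csv(path)
  lapply(seq_len(nrow(df)), function(i)
    structure(list(region = df$region[i], regime = df$regime[i],
                   onset_doy = as.integer(df$onset_doy[i]),
                   onset_year_offset = as.integer(df$onset_year_offset[i]),
                   season_length = as.integer(df$season_length[i]),
                   split = as.integer(df$split[i]),
                   split_doy = as.integer(df$split_doy[i]),
                   end_doy = as.integer(df$end_doy[i]),
                   lead_time_days = as.integer(df$lead_time_days[i]),
                   yearly_onsets = NULL),
              class = "season_calendar"))
}

#' Write a feature table as tidy CSV
#'
#' Long format: `region`, `year`, `feature`, `value`, `phase`,
#' `native_units`.
#'
#' @param features a `feature_table`.
#' @param path CSV file path.
#' @export
write_features_csv <- function(features, path) {
  X <- features$X
  df <- data.frame(region = features$region,
                   year = rep(features$years, times = ncol(X)),
                   feature = rep(colnames(X), each = nrow(X)),
                   value = as.numeric(X),
                   phase = rep(unname(features$phase), each = nrow(X)),
                   native_units = rep(unname(features$units), each = nrow(X)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write the ground truth of a synthetic experiment as JSON
#'
#' @param truth a [synthetic_truth()].
#' @param path JSON file path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write trend, fit and validation reports of a pipeline run
#'
#' Emits `calendars.csv`, `summary.csv`, `fit_reports.json`,
#' `validation.csv` (per region/level/year observed and predicted values)
#' and `manifest.json` under `out_dir`.
#'
#' @param run result of [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @export
write_pipeline_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_calendar_csv(lapply(run$results, `[[`, "calendar"),
                     file.path(out_dir, "calendars.csv"))
  if (!is.null(run$summary)) {
    write.csv(run$summary, file.path(out_dir, "summary.csv"),
              row.names = FALSE)
  }
  if (run$mode != "holdout") {
    fits <- lapply(run$results, function(r)
      list(trend_type = r$trend$type,
           trend_coefficients = r$trend$coefficients,
           trend_aic = as.list(r$trend$aic),
           selected = r$selected,
           betas = as.list(r$fit$betas),
           breusch_godfrey_p = r$diagnostics$breusch_godfrey_p,
           breusch_pagan_p = r$diagnostics$breusch_pagan_p,
           vif = as.list(r$diagnostics$vif)))
    jsonlite::write_json(fits, file.path(out_dir, "fit_reports.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    val <- do.call(rbind, lapply(names(run$results), function(rn) {
      r <- run$results[[rn]]
      do.call(rbind, lapply(c("level1", "level2"), function(lv)
        data.frame(region = rn, level = lv, year = r[[lv]]$years,
                   observed = r[[lv]]$obs_yield,
                   predicted_anomaly = r[[lv]]$pred_anomaly,
                   predicted_absolute = r[[lv]]$pred_yield)))
    }))
    write.csv(val, file.path(out_dir, "validation.csv"), row.names = FALSE)
  }
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
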