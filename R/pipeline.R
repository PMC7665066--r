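#' Pipeline configuration
#'
#' Captures every tunable of the end-to-end run: the synthetic-data
#' configuration and ground truth (or paths to input CSVs), the onset
#' criteria, the crop-calendar constants, the feature thresholds, the SST
#' lead times, the selection caps and the master seed. All printed
#' constants of the method live here — there are no hidden constants in
#' the code.
#'
#' @param synthetic a [synthetic_config()] (inline synthetic inputs).
#' @param truth a [synthetic_truth()].
#' @param gdd [gdd_params()].
#' @param onset_windows search windows per regime, see
#'   [onset_search_windows()].
#' @param onset list of onset-criterion constants (25 mm within 6 days,
#'   wet day > 0.1 mm, >= 3 wet days, no >= 10-day dry run within the next
#'   40 days).
#' @param season_length fixed season length, days (110).
#' @param rain_thresholds pA/pB thresholds, mm.
#' @param cdd_lengths dry-spell lengths, days.
#' @param percentiles lower/upper long-term percentiles.
#' @param sst_leads lead time per SST index, days (120/120/30).
#' @param max_vars selection cap for estimation and level-1 (5).
#' @param max_vars_level2 per-fold cap inside level-2 (4).
#' @param r_threshold collinearity threshold (0.7).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            truth = synthetic_truth(seed = synthetic$seed),
                            gdd = gdd_params(),
                            onset_windows = onset_search_windows(),
                            onset = list(amount = 25, amount_window = 6L,
                                         wet_threshold = 0.1,
                                         min_wet_days = 3L,
                                         dry_spell_len = 10L,
                                         dry_check_window = 40L),
                            season_length = 110L,
                            rain_thresholds = c(5, 10, 15),
                            cdd_lengths = c(5, 10, 15, 20),
                            percentiles = c(lo = 1, hi = 99),
                            sst_leads = c(nino34 = 120L, wp = 120L, iod = 30L),
                            max_vars = 5L,
                            max_vars_level2 = 4L,
                            r_threshold = 0.7) {
  stopifnot(max_vars >= 1L, max_vars_level2 >= 1L, season_length >= 2L,
            all(rain_thresholds > 0), all(cdd_lengths > 0))
  structure(list(synthetic = synthetic, truth = truth, gdd = gdd,
                 onset_windows = onset_windows, onset = onset,
                 season_length = as.integer(season_length),
                 rain_thresholds = rain_thresholds,
                 cdd_lengths = cdd_lengths,
                 percentiles = percentiles,
                 sst_leads = sst_leads,
                 max_vars = as.integer(max_vars),
                 max_vars_level2 = as.integer(max_vars_level2),
                 r_threshold = r_threshold,
                 seed = synthetic$seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Only keys present in the file override the defaults of
#' [pipeline_config()], [synthetic_config()] and [synthetic_truth()].
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  syn <- do.call(synthetic_config, y$synthetic %||% list())
  tru_args <- y$truth %||% list()
  if (is.null(tru_args$seed)) tru_args$seed <- syn$seed
  tru <- do.call(synthetic_truth, tru_args)
  extra <- y[setdiff(names(y), c("synthetic", "truth"))]
  do.call(pipeline_config, c(list(synthetic = syn, truth = tru), extra))
}

# Small stable checksum of a configuration for the run manifest.
config_hash <- function(config) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else unname(x)
  s <- jsonlite::toJSON(strip(config), auto_unbox = TRUE, digits = NA)
  sprintf("%08x", derive_seed(0L, as.character(s)))
}

# Run the per-region analysis for one region of a generated dataset.
run_region <- function(reg, config, mode) {
  scope <- if (mode == "estimate") "estimation" else "forecast"
  yields <- reg$yields
  years <- yields$year
  if (mode == "holdout") {
    train_years <- years[-length(years)]
    test_year <- years[length(years)]
    rep <- holdout_forecast(reg$features_native, yields, train_years,
                            test_year, feature_scope = scope,
                            max_vars = config$max_vars,
                            r_threshold = config$r_threshold)
    return(list(calendar = reg$calendar, holdout = rep))
  }
  det <- detrend_yields(yields)
  fstd <- standardize_features(scope_features(reg$features_native, scope))
  sel <- select_variables(fstd, det$anomalies[as.character(years)],
                          max_vars = config$max_vars,
                          r_threshold = config$r_threshold)
  fit <- fit_region_model(sel$features, sel$selected,
                          det$anomalies[as.character(years)])
  diag <- model_diagnostics(fit, sel$features)
  est_pred <- predict_anomalies(fit, sel$features, years)
  l1 <- loocv_level1(reg$features_native, yields, feature_scope = scope,
                     max_vars = config$max_vars,
                     r_threshold = config$r_threshold)
  l2 <- loocv_level2(reg$features_native, yields, feature_scope = scope,
                     max_vars = config$max_vars_level2,
                     r_threshold = config$r_threshold)
  base <- constant_baseline(yields)
  list(calendar = reg$calendar, trend = det$trend,
       selected = sel$selected, fit = fit, diagnostics = diag,
       nse_estimation = nse(det$anomalies[as.character(years)], est_pred),
       level1 = l1, level2 = l2, baseline = base)
}

#' Run the pipeline end-to-end
#'
#' Generates the synthetic inputs from the configuration, builds the crop
#' calendar and feature table per region, and runs the mode-dependent
#' analysis: `"estimate"` (both phases; full fit + diagnostics + level-1 +
#' level-2), `"forecast"` (vegetative + SST features only, same
#' validations), or `"holdout"` (train on all but the last year, forecast
#' the last year, pooled NSE by rainfall regime). Per-region failures are
#' collected in the manifest without aborting other regions. Reruns with
#' the same configuration and seed are bit-identical; if `out_dir` is
#' given, calendars, features, yields, fit and validation reports and a
#' run manifest are also written there.
#'
#' @param config a `pipeline_config`.
#' @param mode `"estimate"`, `"forecast"` or `"holdout"`.
#' @param out_dir optional output directory.
#' @return list with `mode`, `dataset`, per-region `results`, `summary`
#'   (data frame of per-region scores), `pooled` (holdout mode only) and
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         mode = c("estimate", "forecast", "holdout"),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  mode <- match.arg(mode)
  dataset <- gen_dataset(config$synthetic, config$truth)
  results <- list()
  failures <- character(0)
  for (rn in names(dataset$regions)) {
    res <- tryCatch(run_region(dataset$regions[[rn]], config, mode),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, setNames(conditionMessage(res), rn))
    } else {
      results[[rn]] <- res
    }
  }
  summary <- if (mode == "holdout") {
    do.call(rbind, lapply(names(results), function(rn) {
      r <- results[[rn]]
      data.frame(region = rn, regime = r$calendar$regime,
                 test_year = r$holdout$years,
                 obs_yield = r$holdout$obs_yield,
                 pred_yield = r$holdout$pred_yield,
                 stringsAsFactors = FALSE)
    }))
  } else {
    do.call(rbind, lapply(names(results), function(rn) {
      r <- results[[rn]]
      data.frame(region = rn, regime = r$calendar$regime,
                 trend_type = r$trend$type,
                 n_selected = length(r$selected),
                 nse_estimation = r$nse_estimation,
                 nse_level1 = r$level1$nse_anomaly,
                 nse_level2 = r$level2$nse_anomaly,
                 nse_level1_absolute = r$level1$nse_absolute,
                 rmse_level1_absolute = r$level1$rmse_absolute,
                 rmse_level2_absolute = r$level2$rmse_absolute,
                 baseline_rmse = r$baseline$rmse,
                 stringsAsFactors = FALSE)
    }))
  }
  pooled <- NULL
  if (mode == "holdout" && !is.null(summary) && nrow(summary) > 1L) {
    pooled <- pooled_nse(summary$obs_yield, summary$pred_yield,
                         summary$regime)
  }
  manifest <- list(mode = mode, seed = config$seed,
                   config_hash = config_hash(config),
                   n_regions = config$synthetic$n_regions,
                   years = config$synthetic$years,
                   failures = as.list(failures),
                   package_version = as.character(utils::packageVersion("maizecast")))
  out <- list(mode = mode, dataset = dataset, results = results,
              summary = summary, pooled = pooled, manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}
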