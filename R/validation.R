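#' Nash-Sutcliffe efficiency
#'
#' `1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)`. 1 means perfect
#' agreement, 0 means no better than the observation mean, and the value is
#' unbounded below.
#'
#' @param obs observed values (>= 2, not all equal).
#' @param pred predicted values, same length.
#' @return dimensionless efficiency, <= 1.
#' @export
nse <- function(obs, pred) {
  if (length(obs) != length(pred)) stop("obs and pred must be aligned")
  if (length(obs) < 2L) stop("need at least 2 observations")
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) stop("NSE undefined: zero observed variance")
  1 - sum((obs - pred)^2) / ss_tot
}

#' Root mean squared error
#'
#' @param obs observed values (>= 1).
#' @param pred predicted values, same length.
#' @return RMSE in the native units of the inputs.
#' @export
rmse <- function(obs, pred) {
  if (length(obs) != length(pred)) stop("obs and pred must be aligned")
  if (length(obs) == 0L) stop("empty input")
  sqrt(mean((obs - pred)^2))
}

#' Pooled NSE by group
#'
#' NSE computed within each group (e.g. rainfall regime), pooling all
#' observations of the group and using the group mean as the reference.
#'
#' @param obs,pred aligned observation/prediction vectors.
#' @param group grouping factor.
#' @return named numeric vector of per-group NSE values.
#' @export
pooled_nse <- function(obs, pred, group) {
  groups <- unique(as.character(group))
  setNames(vapply(groups, function(g) {
    sel <- group == g
    tryCatch(nse(obs[sel], pred[sel]), error = function(e) NA_real_)
  }, numeric(1)), groups)
}

# One cross-validation fold: refit trend + standardization (+ optionally the
# whole selection chain) on the training years only, then predict the
# held-out years. Shared by both LOOCV levels and the holdout forecast.
fit_fold <- function(features_native, yields, train_years, test_years,
                     scope, selected = NULL, max_vars = 5L,
                     r_threshold = 0.7) {
  det <- detrend_yields(yields, fit_years = train_years)
  fstd <- standardize_features(scope_features(features_native, scope),
                               fit_years = train_years)
  anom_train <- det$anomalies[as.character(train_years)]
  if (is.null(selected)) {
    sel <- select_variables(fstd, anom_train, fit_years = train_years,
                            max_vars = max_vars, r_threshold = r_threshold)
    fstd_sel <- sel$features
    selected <- sel$selected
  } else {
    # a pre-selected feature can be constant on this fold's training years
    # (e.g. a sparse count); it carries no information here and is dropped
    # from this fold's fit, as are columns that become exactly collinear on
    # the reduced training design
    selected <- setdiff(selected, fstd$zero_variance)
    if (length(selected) > 1L) {
      Xtr <- fstd$X[match(train_years, fstd$years), selected, drop = FALSE]
      qrX <- qr(Xtr)
      if (qrX$rank < length(selected)) {
        keep <- sort(qrX$pivot[seq_len(qrX$rank)])
        selected <- selected[keep]
      }
    }
    fstd_sel <- fstd
  }
  fit <- fit_region_model(fstd_sel, selected, anom_train,
                          fit_years = train_years)
  pred_anom <- predict_anomalies(fit, fstd_sel, test_years)
  trend_log <- trend_predict(det$trend, test_years)
  list(selected = selected,
       trend = det$trend,
       center = fstd$center, scale = fstd$scale,
       betas = fit$betas,
       obs_anomaly = det$anomalies[as.character(test_years)],
       pred_anomaly = pred_anom,
       pred_yield = exp(pred_anom + trend_log),
       trend_yield = exp(trend_log))
}

# Assemble a validation report from per-year fold outputs.
make_report <- function(region, level, years, obs_yield, folds,
                        selected_global = NULL) {
  obs_anom <- unlist(lapply(folds, `[[`, "obs_anomaly"))
  pred_anom <- unlist(lapply(folds, `[[`, "pred_anomaly"))
  pred_yield <- unlist(lapply(folds, `[[`, "pred_yield"))
  trend_yield <- unlist(lapply(folds, `[[`, "trend_yield"))
  structure(list(
    region = region, level = level, years = as.integer(years),
    obs_anomaly = unname(obs_anom), pred_anomaly = unname(pred_anom),
    obs_yield = unname(obs_yield),
    pred_yield = unname(pred_yield), trend_yield = unname(trend_yield),
    nse_anomaly = tryCatch(nse(obs_anom, pred_anom), error = function(e) NA_real_),
    rmse_anomaly = rmse(obs_anom, pred_anom),
    nse_absolute = tryCatch(nse(obs_yield, pred_yield), error = function(e) NA_real_),
    rmse_absolute = rmse(obs_yield, pred_yield),
    selected = selected_global,
    selected_per_fold = lapply(folds, `[[`, "selected"),
    folds = folds
  ), class = "validation_report")
}

#' Level-1 leave-one-year-out cross-validation
#'
#' Variable selection is done once on all years (cap `max_vars` = 5); then,
#' per fold, one year is held out and the trend, the standardization and
#' the regression coefficients are refit on the remaining years only before
#' predicting the held-out year. Scores are computed over the out-of-sample
#' predictions, on the anomaly (log) scale and on the absolute (t/ha) scale
#' after retrending.
#'
#' @param features_native a `feature_table` in native units.
#' @param yields a `yield_series` covering the validation years (>= 5).
#' @param feature_scope `"estimation"` (both phases) or `"forecast"`
#'   (vegetative + SST only).
#' @param max_vars selection cap.
#' @param r_threshold collinearity threshold.
#' @return a `validation_report` (level `"level1"`).
#' @export
loocv_level1 <- function(features_native, yields,
                         feature_scope = c("estimation", "forecast"),
                         max_vars = 5L, r_threshold = 0.7) {
  feature_scope <- match.arg(feature_scope)
  years <- yields$year
  if (length(years) < 5L) stop("need at least 5 years")
  det_all <- detrend_yields(yields)
  fstd_all <- standardize_features(scope_features(features_native, feature_scope),
                                   fit_years = years)
  sel <- select_variables(fstd_all, det_all$anomalies[as.character(years)],
                          fit_years = years,
                          max_vars = max_vars, r_threshold = r_threshold)
  folds <- lapply(years, function(t)
    fit_fold(features_native, yields,
             train_years = setdiff(years, t), test_years = t,
             scope = feature_scope, selected = sel$selected))
  names(folds) <- years
  make_report(features_native$region, "level1", years, yields$yield, folds,
              selected_global = sel$selected)
}

#' Level-2 leave-one-year-out cross-validation
#'
#' Per fold, the entire chain — detrending, standardization, zero-variance
#' filter, collinearity filter, LASSO selection (cap `max_vars` = 4) and
#' the regression fit — is run on the training years only, so no
#' information from the held-out year enters any step. The per-fold
#' selections are reported.
#'
#' @inheritParams loocv_level1
#' @param max_vars per-fold selection cap (4: one less than half the 10
#'   training observations).
#' @return a `validation_report` (level `"level2"`).
#' @export
loocv_level2 <- function(features_native, yields,
                         feature_scope = c("estimation", "forecast"),
                         max_vars = 4L, r_threshold = 0.7) {
  feature_scope <- match.arg(feature_scope)
  years <- yields$year
  if (length(years) < 5L) stop("need at least 5 years")
  folds <- lapply(years, function(t)
    fit_fold(features_native, yields,
             train_years = setdiff(years, t), test_years = t,
             scope = feature_scope, selected = NULL,
             max_vars = max_vars, r_threshold = r_threshold))
  names(folds) <- years
  make_report(features_native$region, "level2", years, yields$yield, folds)
}

#' Independent forecast of a final held-out year
#'
#' The full chain (detrend, standardize, select with cap `max_vars`, fit)
#' is developed on the training years only, then the held-out year —
#' typically the year following the training series, so the trend is
#' extrapolated — is forecast as anomaly and absolute yield.
#'
#' @param features_native a `feature_table` covering training and test
#'   years.
#' @param yields a `yield_series`; must contain the training years (the
#'   test-year yield, if present, is used only for scoring afterwards).
#' @param train_years training years.
#' @param test_year single held-out year, not in `train_years`.
#' @param feature_scope `"forecast"` (default) or `"estimation"`.
#' @param max_vars selection cap (5).
#' @param r_threshold collinearity threshold.
#' @return a `validation_report` (level `"holdout"`) with one prediction.
#' @export
holdout_forecast <- function(features_native, yields, train_years, test_year,
                             feature_scope = c("forecast", "estimation"),
                             max_vars = 5L, r_threshold = 0.7) {
  feature_scope <- match.arg(feature_scope)
  if (test_year %in% train_years) stop("test year inside training years")
  train_yields <- yields[yields$year %in% train_years, , drop = FALSE]
  fold <- fit_fold(features_native, train_yields, train_years, test_year,
                   scope = feature_scope, selected = NULL,
                   max_vars = max_vars, r_threshold = r_threshold)
  obs_yield <- yields$yield[yields$year == test_year]
  if (length(obs_yield) == 0L) obs_yield <- NA_real_
  fold$obs_anomaly <- if (is.na(obs_yield)) NA_real_ else
    log(obs_yield) - trend_predict(fold$trend, test_year)
  rep <- make_report(features_native$region, "holdout", test_year, obs_yield,
                     setNames(list(fold), test_year))
  # single-year scores are undefined (no variance); keep RMSE only
  rep$nse_anomaly <- NA_real_
  rep$nse_absolute <- NA_real_
  rep
}

#' Decompose out-of-sample forecasts into trend-only and combined series
#'
#' Given an anomaly-level validation report with fold-wise trends, emits
#' the three absolute-scale series: the trend-only forecast
#' `exp(trend(year))`, the anomaly forecast, and the combined forecast
#' `exp(anomaly + trend(year))`, with NSE/RMSE for the trend-only and
#' combined series.
#'
#' @param report a `validation_report` from one of the LOOCV runs.
#' @return list with `years`, `obs_yield`, `trend_only`, `combined`,
#'   `pred_anomaly`, and scores `nse_trend`, `nse_combined`, `rmse_trend`,
#'   `rmse_combined`.
#' @export
forecast_absolute <- function(report) {
  if (is.null(report$folds)) stop("report carries no fold trends")
  list(years = report$years,
       obs_yield = report$obs_yield,
       trend_only = report$trend_yield,
       combined = report$pred_yield,
       pred_anomaly = report$pred_anomaly,
       nse_trend = tryCatch(nse(report$obs_yield, report$trend_yield),
                            error = function(e) NA_real_),
       nse_combined = report$nse_absolute,
       rmse_trend = rmse(report$obs_yield, report$trend_yield),
       rmse_combined = report$rmse_absolute)
}

#' Constant-model baseline
#'
#' Predicts each year's absolute yield by the mean of all other years'
#' observed yields (leave-one-out mean), the reference any forecast must
#' beat.
#'
#' @param yields a `yield_series` (>= 2 years).
#' @return list with `years`, `pred` and `rmse` (t/ha).
#' @export
constant_baseline <- function(yields) {
  y <- yields$yield
  n <- length(y)
  if (n < 2L) stop("need at least 2 years")
  pred <- (sum(y) - y) / (n - 1)
  list(years = yields$year, pred = pred, rmse = rmse(y, pred))
}

#' Median summary of per-region validation scores
#'
#' @param reports list of `validation_report` objects.
#' @param what score field to summarize.
#' @return the median of the per-region values.
#' @export
summarize_regions <- function(reports, what = "nse_anomaly") {
  median(vapply(reports, function(r) r[[what]], numeric(1)))
}
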