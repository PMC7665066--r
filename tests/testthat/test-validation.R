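test_that("scoring metrics satisfy their defining identities", {
  obs <- c(1, 2, 3)
  expect_equal(nse(obs, obs), 1)
  expect_equal(nse(obs, rep(mean(obs), 3)), 0)
  expect_equal(nse(obs, c(1, 2, 4)), 0.5)
  expect_error(nse(rep(2, 4), rep(2, 4)), "undefined")
  expect_error(nse(1, 1), "at least 2")

  expect_equal(rmse(obs, obs), 0)
  expect_equal(rmse(c(1, 2), c(2, 3)), 1)
  set.seed(31)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(rmse(a, b), sqrt(mean((a - b)^2)))
  expect_error(rmse(numeric(0), numeric(0)), "empty")
})

test_that("NSE is invariant under a common positive affine rescaling", {
  set.seed(32)
  for (i in 1:20) {
    obs <- rnorm(8); pred <- rnorm(8)
    a <- runif(1, -5, 5); b <- runif(1, 0.1, 10)
    expect_equal(nse(a + b * obs, a + b * pred), nse(obs, pred), tolerance = 1e-10)
  }
})

test_that("pooled NSE by group matches the per-group formula", {
  set.seed(33)
  obs <- rnorm(12); pred <- rnorm(12)
  grp <- rep(c("unimodal", "bimodal"), each = 6)
  p <- pooled_nse(obs, pred, grp)
  for (g in c("unimodal", "bimodal")) {
    o <- obs[grp == g]; q <- pred[grp == g]
    expect_equal(unname(p[g]), 1 - sum((o - q)^2) / sum((o - mean(o))^2))
  }
})

test_that("median-over-regions summary equals the sort oracle", {
  reps <- lapply(c(0.4, 0.9, -0.2, 0.7, 0.55), function(v) list(nse_anomaly = v))
  vals <- sort(vapply(reps, `[[`, numeric(1), "nse_anomaly"))
  expect_equal(summarize_regions(reps), vals[3])
})

test_that("level-1 validation has one fold per year and near-perfect skill on noise-free truth", {
  ds <- small_dataset(3, truth = synthetic_truth(
    c("nino34_120.median", "iod_30.median"), c(0.8, -0.8),
    trend_type = "mean", trend_coefficients = c(log(1.6), 0, 0),
    noise_sd = 0, seed = 3))
  reg <- ds$regions$region1
  rep1 <- loocv_level1(reg$features_native, reg$yields)
  expect_equal(rep1$years, 2009:2018)
  expect_length(rep1$folds, 10)
  for (f in rep1$folds) expect_length(f$trend$fit_years, 9)
  expect_gt(rep1$nse_anomaly, 1 - 1e-6)
  expect_gt(rep1$nse_absolute, 1 - 1e-6)
})

test_that("level-2 validation caps every fold at four variables and reports per-fold selections", {
  ds <- small_dataset(6)
  reg <- ds$regions$region1
  rep2 <- loocv_level2(reg$features_native, reg$yields)
  expect_length(rep2$selected_per_fold, 10)
  for (sel in rep2$selected_per_fold) expect_lte(length(sel), 4)
  expect_error(loocv_level2(reg$features_native, reg$yields[1:4, ]), "at least 5")
})

test_that("no information from the held-out year leaks into a level-2 fold", {
  ds <- small_dataset(8)
  reg <- ds$regions$region1
  rep_a <- loocv_level2(reg$features_native, reg$yields)
  # perturb the 2014 yield only
  yields_b <- reg$yields
  yields_b$yield[yields_b$year == 2014] <- yields_b$yield[yields_b$year == 2014] * 3
  rep_b <- loocv_level2(reg$features_native, yields_b)
  fa <- rep_a$folds[["2014"]]; fb <- rep_b$folds[["2014"]]
  expect_identical(fa$selected, fb$selected)
  expect_identical(fa$center, fb$center)
  expect_identical(fa$scale, fb$scale)
  expect_identical(fa$trend$coefficients, fb$trend$coefficients)
  expect_identical(fa$betas, fb$betas)
  expect_identical(fa$pred_anomaly, fb$pred_anomaly)
  # only the observation itself changes
  expect_false(identical(fa$obs_anomaly, fb$obs_anomaly))
})

test_that("holdout forecasting extrapolates the trained chain to an unseen year", {
  ds <- small_dataset(4, years = 2009:2019, truth = synthetic_truth(
    c("nino34_120.median", "iod_30.median"), c(0.8, -0.8),
    trend_type = "mean", trend_coefficients = c(log(1.6), 0, 0),
    noise_sd = 0, seed = 4))
  reg <- ds$regions$region1
  rep <- holdout_forecast(reg$features_native, reg$yields, 2009:2018, 2019)
  expect_equal(rep$level, "holdout")
  expect_equal(rep$years, 2019)
  # noise-free truth in the forecast scope: the prediction matches generation
  expect_equal(rep$pred_yield, reg$yields$yield[reg$yields$year == 2019],
               tolerance = 1e-6)
  expect_error(holdout_forecast(reg$features_native, reg$yields, 2009:2018, 2015),
               "inside training")

  # zero-effect truth: the forecast equals the extrapolated trend
  ds0 <- small_dataset(5, years = 2009:2019, truth = noise_truth(5, noise_sd = 0))
  reg0 <- ds0$regions$region1
  rep0 <- holdout_forecast(reg0$features_native, reg0$yields, 2009:2018, 2019)
  expect_equal(rep0$pred_yield, exp(trend_predict(rep0$folds[[1]]$trend, 2019)),
               tolerance = 1e-8)
})

test_that("absolute-scale decomposition separates trend-only and combined forecasts", {
  ds <- small_dataset(9, truth = noise_truth(9, noise_sd = 0.05))
  reg <- ds$regions$region1
  rep1 <- loocv_level1(reg$features_native, reg$yields)
  dec <- forecast_absolute(rep1)
  expect_equal(dec$combined, exp(dec$pred_anomaly) * dec$trend_only,
               tolerance = 1e-10)
  # with an empty selection the anomaly prediction is zero for every fold,
  # so the combined forecast equals the trend-only forecast
  if (length(rep1$selected) == 0) expect_equal(dec$combined, dec$trend_only)
  # scoring a perfect report returns NSE 1
  perfect <- rep1
  perfect$pred_yield <- perfect$obs_yield
  perfect$trend_yield <- perfect$obs_yield
  perfect$nse_absolute <- nse(perfect$obs_yield, perfect$pred_yield)
  dec_p <- forecast_absolute(perfect)
  expect_equal(dec_p$nse_combined, 1)
  expect_equal(dec_p$nse_trend, 1)
})

test_that("the constant baseline predicts the leave-one-out mean", {
  y_const <- yields_from_log(rep(log(2), 5), 2010:2014)
  b <- constant_baseline(y_const)
  expect_equal(b$rmse, 0)

  y2 <- structure(data.frame(region = 1L, year = 2010:2011, yield = c(1, 3)),
                  class = c("yield_series", "data.frame"))
  b2 <- constant_baseline(y2)
  expect_equal(b2$pred, c(3, 1))
  expect_equal(b2$rmse, 2)
  expect_error(constant_baseline(y2[1, ]), "at least 2")
})
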