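#' Configuration for the synthetic agro-climate generator
#'
#' Bundles every tunable of the synthetic inputs: daily Bernoulli-gamma
#' rainfall with a unimodal (Musumi-like, Dec--Apr) or bimodal (Vuli short
#' rains + Masika long rains) seasonal cycle, sinusoidal daily temperature
#' with AR(1) noise, AR(1) monthly SST anomaly series for three ocean
#' indices, and per-region grid cells with area weights.
#'
#' @param n_regions number of regions (>= 1).
#' @param n_grid_cells_per_region grid cells per region; daily weather is
#'   generated per cell and aggregated by area-weighted mean.
#' @param years strictly increasing, contiguous harvest years (length >= 6
#'   recommended; the generated daily span additionally covers the year
#'   preceding the first harvest year, so seasons may start in it).
#' @param regime_per_region character vector, `"unimodal"` or `"bimodal"`,
#'   recycled over regions. Defaults to alternating regimes.
#' @param wet_season_peak_doy named list with elements `unimodal` (single
#'   peak day-of-year), `bimodal_masika` and `bimodal_vuli` (two peaks).
#' @param mean_annual_rain expected annual precipitation total, mm.
#' @param temp_mean,temp_amplitude seasonal temperature cycle, deg C; the
#'   warm peak sits in mid-January (southern-hemisphere summer).
#' @param temp_ar1,temp_noise_sd AR(1) coefficient and innovation scale of
#'   the daily mean-temperature noise.
#' @param diurnal_half_range half the mean diurnal range, deg C; tasmax/tasmin
#'   are `tas +/- (diurnal_half_range + |noise|)` so the ordering
#'   tasmin <= tas <= tasmax holds by construction.
#' @param sst_ar1_coefficient AR(1) coefficient of monthly SST anomalies,
#'   |phi| < 1.
#' @param sst_marginal_sd stationary standard deviation of the SST
#'   anomalies, deg C.
#' @param seed master integer seed; every stream is derived from it by
#'   stable hashing of (region, cell, variable) labels.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_regions = 4L,
                             n_grid_cells_per_region = 1L,
                             years = 2009:2018,
                             regime_per_region = NULL,
                             wet_season_peak_doy = list(unimodal = 46L,
                                                        bimodal_masika = 100L,
                                                        bimodal_vuli = 320L),
                             mean_annual_rain = 800,
                             temp_mean = 24,
                             temp_amplitude = 3,
                             temp_ar1 = 0.7,
                             temp_noise_sd = 1,
                             diurnal_half_range = 5,
                             sst_ar1_coefficient = 0.8,
                             sst_marginal_sd = 0.8,
                             seed = 1L) {
  years <- as.integer(years)
  if (n_regions < 1L) stop("n_regions must be >= 1")
  if (length(years) < 2L || any(diff(years) != 1L)) {
    stop("years must be strictly increasing and contiguous")
  }
  if (abs(sst_ar1_coefficient) >= 1) stop("sst AR(1) coefficient must satisfy |phi| < 1")
  if (mean_annual_rain < 0) stop("mean_annual_rain must be >= 0")
  if (is.null(regime_per_region)) {
    regime_per_region <- rep_len(c("unimodal", "bimodal"), n_regions)
  } else {
    regime_per_region <- rep_len(match.arg(regime_per_region,
                                           c("unimodal", "bimodal"),
                                           several.ok = TRUE),
                                 n_regions)
  }
  structure(list(
    n_regions = as.integer(n_regions),
    n_grid_cells_per_region = as.integer(n_grid_cells_per_region),
    years = years,
    base_year = min(years) - 1L,
    regime_per_region = regime_per_region,
    wet_season_peak_doy = wet_season_peak_doy,
    mean_annual_rain = mean_annual_rain,
    temp_mean = temp_mean,
    temp_amplitude = temp_amplitude,
    temp_ar1 = temp_ar1,
    temp_noise_sd = temp_noise_sd,
    diurnal_half_range = diurnal_half_range,
    sst_ar1_coefficient = sst_ar1_coefficient,
    sst_marginal_sd = sst_marginal_sd,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Ground truth of a synthetic yield experiment
#'
#' Records the known data-generating process of the log yields so that
#' parameter-recovery experiments can compare the selected features and
#' fitted coefficients against truth. Log yield is
#' `trend(year) + sum(beta_k * x_k) + N(0, noise_sd)` with `x_k`
#' standardized features from the predictor catalogue.
#'
#' @param true_feature_names names of at most 5 catalogue features carrying
#'   real effects.
#' @param true_betas effects per standard deviation of the feature, log-yield
#'   units; same length as `true_feature_names`.
#' @param trend_type `"mean"`, `"linear"` or `"quadratic"`.
#' @param trend_coefficients log-scale polynomial coefficients
#'   (intercept, slope, curvature) in powers of `year - first_year`; only the
#'   first 1/2/3 are used depending on `trend_type`. The default level
#'   `log(1.6)` matches a typical regional maize yield of 1.6 t/ha.
#' @param noise_sd standard deviation of the log-yield noise (>= 0).
#' @param seed integer seed for the noise stream.
#' @return an object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(true_feature_names = c("cdd5_v",
                                                   "nino34_120.median",
                                                   "wp_120.median",
                                                   "iod_30.median"),
                            true_betas = c(-0.25, 0.25, -0.25, 0.25),
                            trend_type = c("linear", "mean", "quadratic"),
                            trend_coefficients = c(log(1.6), 0.02, 0),
                            noise_sd = 0.05,
                            seed = 1L) {
  trend_type <- match.arg(trend_type)
  if (length(true_feature_names) != length(true_betas)) {
    stop("true_feature_names and true_betas must have the same length")
  }
  if (length(true_feature_names) > 5L) stop("at most 5 true features")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(
    true_feature_names = as.character(true_feature_names),
    true_betas = as.numeric(true_betas),
    trend_type = trend_type,
    trend_coefficients = as.numeric(trend_coefficients),
    noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "synthetic_truth")
}
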