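# Fixture builders shared across the test files. Everything is generated in
# code; no stored data.

# Random Bernoulli-gamma rainfall series (not via the package generator, so
# oracle comparisons stay independent of it).
random_rain_series <- function(n, p_wet = 0.45, mean_wet = 8) {
  wet <- stats::rbinom(n, 1, p_wet)
  wet * stats::rgamma(n, shape = 0.9, scale = mean_wet / 0.9)
}

# A 2-year designed weather series whose onsets are placed at known
# days-of-year of the harvest year: a 3-day 30 mm burst followed by 5 mm
# every 4th day for 48 days, dry elsewhere.
designed_onset_weather <- function(onset_doys, years, base_year = min(years) - 1L,
                                   tas = 25) {
  n_years <- max(years) - base_year + 1L
  precip <- numeric(n_years * 365L)
  for (i in seq_along(years)) {
    d0 <- (years[i] - base_year) * 365L + onset_doys[i]
    precip[d0 + 0:2] <- 10
    precip[d0 + seq(6, 48, by = 4)] <- 5
  }
  region_weather(precip, tas = rep(tas, length(precip)),
                 base_year = base_year, years = years, regime = "bimodal")
}

# Minimal standardized feature table from an iid Gaussian design.
gaussian_feature_table <- function(n_years = 10L, p = 12L,
                                   years = seq(2009L, length.out = n_years),
                                   standardize = TRUE) {
  X <- matrix(stats::rnorm(n_years * p), n_years, p)
  if (standardize) X <- scale(X)[, , drop = FALSE]
  colnames(X) <- sprintf("f%02d", seq_len(p))
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  feature_table(X, years, standardized = standardize)
}

# Yield series from given log values.
yields_from_log <- function(log_yield, years, region = 1L) {
  structure(data.frame(region = region, year = as.integer(years),
                       yield = exp(log_yield)),
            class = c("yield_series", "data.frame"))
}

# Small single-region synthetic dataset under a configurable truth.
small_dataset <- function(seed, n_regions = 1L, years = 2009:2018,
                          truth = recovery_truth(seed)) {
  cfg <- synthetic_config(n_regions = n_regions, years = years, seed = seed)
  gen_dataset(cfg, truth)
}

# The identifiable truth used in the recovery experiments: two strong,
# near-orthogonal SST effects, a constant trend at the typical yield level,
# and near-noiseless log yields.
recovery_truth <- function(seed) {
  synthetic_truth(true_feature_names = c("nino34_120.median", "iod_30.median"),
                  true_betas = c(0.8, -0.8),
                  trend_type = "mean",
                  trend_coefficients = c(log(1.6), 0, 0),
                  noise_sd = 0.02, seed = seed)
}

# Pure-noise truth: no climatic effects, only level + noise.
noise_truth <- function(seed, noise_sd = 0.1) {
  synthetic_truth(true_feature_names = character(0),
                  true_betas = numeric(0),
                  trend_type = "mean",
                  trend_coefficients = c(log(1.6), 0, 0),
                  noise_sd = noise_sd, seed = seed)
}
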