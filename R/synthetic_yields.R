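# Evaluate the truth trend polynomial at (year - first_year).
truth_trend <- function(truth, years, first_year) {
  t <- years - first_year
  k <- switch(truth$trend_type, mean = 1L, linear = 2L, quadratic = 3L)
  co <- c(truth$trend_coefficients, 0, 0)[1:3]
  co[seq_len(3) > k] <- 0
  co[1] + co[2] * t + co[3] * t^2
}

#' Generate yields from a known linear model on standardized features
#'
#' Log yield for each year is `trend(year) + sum(beta_k x_k) + N(0,
#' noise_sd)` with `x_k` the truth features read from a standardized
#' feature table; the result is returned on the absolute scale (t/ha) via
#' exponentiation, so all yields are strictly positive.
#'
#' @param features a standardized `feature_table` containing all
#'   `truth$true_feature_names`.
#' @param truth a [synthetic_truth()].
#' @param region region id recorded on the output (defaults to the feature
#'   table's region); the noise stream is derived from `truth$seed` and
#'   this id.
#' @return a `yield_series` data frame with columns `region`, `year`,
#'   `yield` (t/ha).
#' @export
gen_yields <- function(features, truth, region = features$region) {
  stopifnot(inherits(features, "feature_table"), inherits(truth, "synthetic_truth"))
  if (!isTRUE(features$standardized)) stop("features must be standardized")
  missing <- setdiff(truth$true_feature_names, colnames(features$X))
  if (length(missing)) {
    stop("true features missing from feature table: ",
         paste(missing, collapse = ", "))
  }
  degenerate <- intersect(truth$true_feature_names, features$zero_variance)
  if (length(degenerate)) {
    stop("true features without variance (cannot carry a standardized effect): ",
         paste(degenerate, collapse = ", "))
  }
  years <- features$years
  Xt <- features$X[, truth$true_feature_names, drop = FALSE]
  signal <- as.numeric(Xt %*% truth$true_betas)
  trend <- truth_trend(truth, years, min(years))
  noise <- if (truth$noise_sd > 0) {
    with_seed(derive_seed(truth$seed, "yield-noise", region),
              rnorm(length(years), sd = truth$noise_sd))
  } else {
    numeric(length(years))
  }
  structure(data.frame(region = region, year = years,
                       yield = exp(trend + signal + noise)),
            class = c("yield_series", "data.frame"))
}

#' Generate a complete multi-region synthetic dataset
#'
#' Convenience wrapper running the full generator for every region: daily
#' weather, the three SST anomaly series, the static crop calendar, the
#' native and standardized feature tables, and yields from the ground-truth
#' model. Standardization here uses all years — it defines the
#' data-generating process; the analysis pipeline refits its own
#' standardization on its own fit years.
#'
#' @param config a [synthetic_config()].
#' @param truth a [synthetic_truth()].
#' @return list with elements `config`, `truth`, `sst` (named list),
#'   `regions` (per region: `weather`, `calendar`, `features_native`,
#'   `features`, `yields`).
#' @export
gen_dataset <- function(config, truth = synthetic_truth(seed = config$seed)) {
  sst <- list(nino34 = gen_sst_series(config, "nino34"),
              wp = gen_sst_series(config, "wp"),
              iod = gen_sst_series(config, "iod"))
  regions <- lapply(seq_len(config$n_regions), function(r) {
    weather <- gen_region_weather(config, r)
    calendar <- build_calendar(weather)
    ftab <- build_feature_table(weather, sst, calendar, config$years)
    fstd <- standardize_features(ftab)
    yields <- gen_yields(fstd, truth, region = r)
    list(weather = weather, calendar = calendar,
         features_native = ftab, features = fstd, yields = yields)
  })
  names(regions) <- paste0("region", seq_len(config$n_regions))
  list(config = config, truth = truth, sst = sst, regions = regions)
}
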