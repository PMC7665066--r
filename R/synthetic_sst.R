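#' Generate a monthly SST anomaly series
#'
#' Zero-mean AR(1) monthly anomalies with coefficient `phi =
#' sst_ar1_coefficient` and stationary standard deviation `sst_marginal_sd`,
#' spanning January of the base year (the year before the first harvest
#' year) through December of the last harvest year. Each index gets its own
#' RNG stream derived from the master seed, so the three indices are
#' mutually independent and stable under reordering.
#'
#' @param config a [synthetic_config()].
#' @param index_name one of `"nino34"` (El Nino 3.4), `"wp"` (West Pacific
#'   box), `"iod"` (Indian Ocean Dipole, west-minus-east anomaly
#'   difference).
#' @return an `sst_series` data frame with columns `index`, `year`, `month`,
#'   `mid_day` (continuous day index of the month midpoint) and `anomaly`
#'   (deg C); attribute `base_year`.
#' @export
gen_sst_series <- function(config, index_name) {
  stopifnot(inherits(config, "synthetic_config"))
  index_name <- match.arg(index_name, c("nino34", "wp", "iod"))
  base_year <- config$base_year
  cal_years <- base_year:max(config$years)
  n <- length(cal_years) * 12L
  phi <- config$sst_ar1_coefficient
  innov_sd <- config$sst_marginal_sd * sqrt(1 - phi^2)
  anomaly <- with_seed(derive_seed(config$seed, "sst", index_name), {
    eps <- rnorm(n, sd = innov_sd)
    # start the recursion from the stationary distribution
    eps[1] <- rnorm(1, sd = config$sst_marginal_sd)
    as.numeric(stats::filter(eps, phi, method = "recursive"))
  })
  year <- rep(cal_years, each = 12L)
  month <- rep(1:12, times = length(cal_years))
  mid_day <- (year - base_year) * DAYS_PER_YEAR + MONTH_MIDPOINTS[month]
  structure(data.frame(index = index_name, year = year, month = month,
                       mid_day = mid_day, anomaly = anomaly),
            base_year = base_year,
            class = c("sst_series", "data.frame"))
}
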