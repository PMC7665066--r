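# Seasonal wet-day probability on the day-of-year circle: a von Mises style
# bump exp(kappa * (cos(angle) - 1)) centred on each wet-season peak.
seasonal_bump <- function(doy, peak_doy, kappa = 6) {
  exp(kappa * (cos(2 * pi * (doy - peak_doy) / DAYS_PER_YEAR) - 1))
}

wet_day_probability <- function(doy, regime, peaks,
                                p_base = 0.05, p_amp = 0.55) {
  bump <- switch(regime,
    unimodal = seasonal_bump(doy, peaks$unimodal),
    bimodal  = 0.6 * seasonal_bump(doy, peaks$bimodal_masika) +
               0.4 * seasonal_bump(doy, peaks$bimodal_vuli),
    stop("unknown rainfall regime: ", regime)
  )
  pmin(p_base + p_amp * bump, 0.95)
}

#' Generate daily weather for one synthetic region
#'
#' Daily precipitation follows a Bernoulli-gamma model: wet-day probability
#' varies seasonally (one peak for the unimodal regime, two for the bimodal
#' regime, the Masika peak being the larger) and wet-day amounts are gamma
#' distributed with a constant mean chosen so the expected annual total
#' equals `mean_annual_rain`. Daily mean temperature is a seasonal sinusoid
#' plus AR(1) noise; tasmax/tasmin are offset from tas by the diurnal
#' half-range plus independent positive noise, so
#' `tasmin <= tas <= tasmax` holds on every day. The daily span covers the
#' calendar year before the first harvest year (growing seasons may start
#' in it) through the last harvest year, on a leap-free 365-day calendar.
#'
#' @param config a [synthetic_config()].
#' @param region region index in `1:config$n_regions`.
#' @return a `region_weather` data frame with columns `cell_id`,
#'   `area_weight`, `year`, `doy`, `day` (continuous index, 1 = Jan 1 of the
#'   base year), `precip` (mm), `tas`, `tasmax`, `tasmin` (deg C); attributes
#'   `region`, `regime`, `base_year`, `years`.
#' @export
gen_region_weather <- function(config, region) {
  stopifnot(inherits(config, "synthetic_config"))
  region <- as.integer(region)
  if (region < 1L || region > config$n_regions) stop("unknown region: ", region)
  base_year <- config$base_year
  cal_years <- base_year:max(config$years)
  if (min(cal_years) > config$years[1] - 1L) stop("insufficient span")
  n_years <- length(cal_years)
  n_days <- n_years * DAYS_PER_YEAR
  doy <- rep(seq_len(DAYS_PER_YEAR), times = n_years)
  year <- rep(cal_years, each = DAYS_PER_YEAR)
  regime <- config$regime_per_region[region]

  p_wet <- wet_day_probability(doy, regime, config$wet_season_peak_doy)
  # gamma mean per wet day such that the expected annual total matches
  rain_per_year <- sum(wet_day_probability(seq_len(DAYS_PER_YEAR), regime,
                                           config$wet_season_peak_doy))
  mu_wet <- if (config$mean_annual_rain > 0) config$mean_annual_rain / rain_per_year else 0
  gamma_shape <- 0.9

  cells <- lapply(seq_len(config$n_grid_cells_per_region), function(cell) {
    precip <- if (mu_wet > 0) {
      with_seed(derive_seed(config$seed, "precip", region, cell), {
        wet <- rbinom(n_days, 1L, p_wet)
        amt <- rgamma(n_days, shape = gamma_shape, scale = mu_wet / gamma_shape)
        wet * amt
      })
    } else {
      numeric(n_days)
    }
    with_seed(derive_seed(config$seed, "temp", region, cell), {
      seasonal <- config$temp_mean +
        config$temp_amplitude * cos(2 * pi * (doy - 15) / DAYS_PER_YEAR)
      eps <- rnorm(n_days, sd = config$temp_noise_sd)
      noise <- as.numeric(stats::filter(eps, config$temp_ar1, method = "recursive"))
      tas <- seasonal + noise
      tasmax <- tas + config$diurnal_half_range + abs(rnorm(n_days, sd = 1.5))
      tasmin <- tas - config$diurnal_half_range - abs(rnorm(n_days, sd = 1.5))
      data.frame(cell_id = cell,
                 area_weight = 1 / config$n_grid_cells_per_region,
                 year = year, doy = doy, day = seq_len(n_days),
                 precip = precip, tas = tas, tasmax = tasmax, tasmin = tasmin)
    })
  })
  out <- do.call(rbind, cells)
  structure(out,
            region = region, regime = regime,
            base_year = base_year, years = config$years,
            class = c("region_weather", "data.frame"))
}

#' Construct a regional weather series from daily vectors
#'
#' Wraps continuous daily series (365-day years, starting Jan 1 of
#' `base_year`) in the container used by the calendar and feature modules;
#' useful for custom data and for tests.
#'
#' @param precip,tas,tasmax,tasmin daily vectors of equal length, a
#'   multiple of 365.
#' @param base_year calendar year of the first day.
#' @param years harvest years the series supports.
#' @param region region id.
#' @param regime `"unimodal"` or `"bimodal"`.
#' @return a `region_weather` data frame with one cell.
#' @export
region_weather <- function(precip, tas = rep(25, length(precip)),
                           tasmax = tas + 5, tasmin = tas - 5,
                           base_year, years, region = 1L,
                           regime = "unimodal") {
  n <- length(precip)
  stopifnot(n %% DAYS_PER_YEAR == 0, length(tas) == n,
            length(tasmax) == n, length(tasmin) == n)
  n_years <- n %/% DAYS_PER_YEAR
  structure(data.frame(cell_id = 1L, area_weight = 1,
                       year = rep(base_year + seq_len(n_years) - 1L,
                                  each = DAYS_PER_YEAR),
                       doy = rep(seq_len(DAYS_PER_YEAR), times = n_years),
                       day = seq_len(n),
                       precip = precip, tas = tas,
                       tasmax = tasmax, tasmin = tasmin),
            region = region, regime = regime, base_year = base_year,
            years = as.integer(years),
            class = c("region_weather", "data.frame"))
}

#' Aggregate grid-cell weather to a single regional series
#'
#' Area-weighted daily mean over cells, applied before any feature
#' computation so every downstream quantity is cell-order invariant.
#'
#' @param weather a `region_weather` data frame.
#' @return a `region_weather` data frame with one (aggregate) cell.
#' @export
aggregate_region_weather <- function(weather) {
  cells <- unique(weather$cell_id)
  if (length(cells) == 1L) return(weather)
  w <- tapply(weather$area_weight, weather$cell_id, function(x) x[1])
  w <- w / sum(w)
  first <- weather[weather$cell_id == cells[1],
                   c("year", "doy", "day")]
  agg <- first
  for (v in c("precip", "tas", "tasmax", "tasmin")) {
    m <- matrix(0, nrow(first), 1)
    for (cell in cells) {
      sub <- weather[weather$cell_id == cell, ]
      sub <- sub[order(sub$day), ]
      m <- m + w[as.character(cell)] * sub[[v]]
    }
    agg[[v]] <- as.numeric(m)
  }
  agg$cell_id <- 1L
  agg$area_weight <- 1
  agg <- agg[, c("cell_id", "area_weight", "year", "doy", "day",
                 "precip", "tas", "tasmax", "tasmin")]
  attributes(agg)[c("region", "regime", "base_year", "years")] <-
    attributes(weather)[c("region", "regime", "base_year", "years")]
  class(agg) <- c("region_weather", "data.frame")
  agg
}

# Daily vector (ordered by continuous day) of one variable for one cell.
cell_series <- function(weather, var, cell = NULL) {
  if (!is.null(cell)) weather <- weather[weather$cell_id == cell, ]
  weather <- weather[order(weather$day), ]
  weather[[var]]
}
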