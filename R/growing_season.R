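#' Growing-degree-day parameters
#'
#' Base and cap temperatures for thermal accumulation. Defaults are the
#' standard maize values (base 10 deg C, cap 30 deg C).
#'
#' @param t_base base temperature, deg C.
#' @param t_cap cap temperature, deg C; must exceed `t_base`.
#' @return an object of class `gdd_params`.
#' @export
gdd_params <- function(t_base = 10, t_cap = 30) {
  if (t_cap <= t_base) stop("t_cap must exceed t_base")
  structure(list(t_base = t_base, t_cap = t_cap), class = "gdd_params")
}

#' Daily growing degree days
#'
#' `max(0, min(tas, t_cap) - t_base)`: thermal accumulation above the base
#' temperature, capped at the cap temperature.
#'
#' @param tas daily mean temperature(s), deg C.
#' @param params a [gdd_params()].
#' @return GDD in deg C day, same length as `tas`.
#' @export
daily_gdd <- function(tas, params = gdd_params()) {
  if (any(!is.finite(tas))) stop("non-finite temperature")
  pmax(0, pmin(tas, params$t_cap) - params$t_base)
}

#' Default onset search windows per rainfall regime
#'
#' Unimodal (Musumi) regions: Nov 1 of the year preceding harvest through
#' Feb 28 (rains run Dec--Apr). Bimodal regions: Feb 1 through Apr 30 of the
#' harvest year, restricting the search to the long rains (Masika) so the
#' main-season onset is taken rather than the short rains (Vuli).
#'
#' @return named list of `c(start_doy, end_doy)` per regime; a window whose
#'   start exceeds its end wraps into the following calendar year.
#' @export
onset_search_windows <- function() {
  list(unimodal = c(start_doy = 305L, end_doy = 59L),
       bimodal  = c(start_doy = 32L,  end_doy = 120L))
}

#' Detect the rainfall onset of the growing season
#'
#' Scans candidate days `d` in `[search_start, search_end]` (indices into
#' `precip`) and returns the first day satisfying the three onset criteria
#' of Dodd and Jolliffe:
#' (i) at least `amount` mm (25 mm) total rainfall within the `amount_window`
#' (6) days `d..d+5`;
#' (ii) day `d` is wet (> `wet_threshold` = 0.1 mm) and at least two other
#' days in `d..d+5` are wet;
#' (iii) the following `dry_check_window` (40) days `d+1..d+40` contain no
#' run of `dry_spell_len` (10) or more consecutive dry days
#' (<= `wet_threshold` mm).
#'
#' @param precip continuous daily precipitation vector, mm.
#' @param search_start,search_end first and last candidate index; the series
#'   must extend at least `dry_check_window` days past `search_end`.
#' @param wet_threshold wet-day threshold, mm.
#' @param amount rainfall sum required in the amount window, mm.
#' @param amount_window length of the rainfall-sum window, days.
#' @param min_wet_days wet days required within the amount window
#'   (including the starting day).
#' @param dry_spell_len dry-run length that disqualifies a candidate, days.
#' @param dry_check_window number of days after the candidate to scan for
#'   dry spells.
#' @return the index of the first qualifying day, or `NA_integer_` if none.
#' @export
detect_onset <- function(precip, search_start, search_end,
                         wet_threshold = 0.1, amount = 25,
                         amount_window = 6L, min_wet_days = 3L,
                         dry_spell_len = 10L, dry_check_window = 40L) {
  n <- length(precip)
  search_start <- as.integer(search_start)
  search_end <- as.integer(search_end)
  if (search_start < 1L || search_end < search_start) stop("invalid search window")
  if (n < search_end + dry_check_window) stop("window not covered")

  wet <- precip > wet_threshold
  # dry-run length ending at each day
  rl <- integer(n)
  run <- 0L
  for (j in seq_len(n)) {
    run <- if (wet[j]) 0L else run + 1L
    rl[j] <- run
  }
  csum <- c(0, cumsum(precip))
  cwet <- c(0L, cumsum(wet))
  for (d in search_start:search_end) {
    sum6 <- csum[d + amount_window] - csum[d]
    if (sum6 < amount) next
    nwet6 <- cwet[d + amount_window] - cwet[d]
    if (!(wet[d] && nwet6 >= min_wet_days)) next
    jlo <- d + dry_spell_len
    jhi <- d + dry_check_window
    if (any(rl[jlo:jhi] >= dry_spell_len)) next
    return(d)
  }
  NA_integer_
}

#' Build the static regional crop calendar
#'
#' Runs onset detection per grid cell and harvest year inside the
#' regime-specific search window, takes the median over cells within each
#' year and then the median over years (lower-median rule for even counts),
#' fixes the season end at `onset + season_length` days, and places the
#' vegetative/reproductive split at the median over years of the per-year
#' 50%-GDD split days. Cells or years with no detected onset are skipped;
#' if no onset is found anywhere, an error is raised.
#'
#' @param weather a `region_weather` data frame (possibly multi-cell).
#' @param regime `"unimodal"` or `"bimodal"`.
#' @param years harvest years to scan.
#' @param windows onset search windows, see [onset_search_windows()].
#' @param season_length fixed season length, days (110: mean time from
#'   sowing to maturity of typical Tanzanian maize cultivars).
#' @param params [gdd_params()] for the phase split.
#' @param ... further arguments passed to [detect_onset()].
#' @return a `season_calendar` list with fields `region`, `regime`,
#'   `onset_doy`, `split` (vegetative length, season-relative days),
#'   `split_doy` (first reproductive day), `end_doy`, `season_length`,
#'   `lead_time_days` (= season_length - split), `onset_year_offset`
#'   (0 or -1 relative to the harvest year) and the per-year onset table.
#' @export
build_calendar <- function(weather, regime = attr(weather, "regime"),
                           years = attr(weather, "years"),
                           windows = onset_search_windows(),
                           season_length = 110L,
                           params = gdd_params(), ...) {
  regime <- match.arg(regime, c("unimodal", "bimodal"))
  base_year <- attr(weather, "base_year")
  win <- windows[[regime]]
  wraps <- win["start_doy"] > win["end_doy"]
  cells <- unique(weather$cell_id)

  onsets <- data.frame()
  for (year in years) {
    start_year <- if (wraps) year - 1L else year
    s_idx <- day_index(start_year, win["start_doy"], base_year)
    e_idx <- day_index(year, win["end_doy"], base_year)
    per_cell <- c()
    for (cell in cells) {
      precip <- cell_series(weather, "precip", cell)
      d <- detect_onset(precip, s_idx, e_idx, ...)
      if (!is.na(d)) per_cell <- c(per_cell, d - s_idx) # offset from window start
    }
    if (length(per_cell)) {
      onsets <- rbind(onsets, data.frame(year = year,
                                         onset_offset = med_day(per_cell)))
    }
  }
  if (nrow(onsets) == 0L) stop("no growing season detected")

  onset_offset <- med_day(onsets$onset_offset)
  onset_doy <- wrap_doy(win["start_doy"] + onset_offset)
  onset_year_offset <- if (wraps && win["start_doy"] + onset_offset <= DAYS_PER_YEAR) -1L else 0L

  cal <- structure(list(region = attr(weather, "region") %||% NA_integer_,
                        regime = regime,
                        onset_doy = as.integer(onset_doy),
                        onset_year_offset = onset_year_offset,
                        season_length = as.integer(season_length),
                        split = NA_integer_, split_doy = NA_integer_,
                        end_doy = wrap_doy(onset_doy + season_length),
                        lead_time_days = NA_integer_,
                        yearly_onsets = onsets),
                   class = "season_calendar")

  agg <- aggregate_region_weather(weather)
  splits <- c()
  for (year in years) {
    sp <- try(split_phases(agg, cal, params, year), silent = TRUE)
    if (!inherits(sp, "try-error")) splits <- c(splits, sp)
  }
  if (length(splits) == 0L) stop("no thermal accumulation")
  cal$split <- as.integer(med_day(splits))
  cal$split_doy <- wrap_doy(cal$onset_doy + cal$split)
  cal$lead_time_days <- cal$season_length - cal$split
  cal
}

# Continuous day index of the season start for one harvest year.
season_start_day <- function(calendar, year, base_year) {
  day_index(year + calendar$onset_year_offset, calendar$onset_doy, base_year)
}

#' Split one season into vegetative and reproductive phases by GDD
#'
#' Returns the first season-relative day `s` at which the cumulative GDD
#' reaches 50% of the full-season GDD sum; days `1..s` form the vegetative
#' phase, `s+1..season_length` the reproductive phase.
#'
#' @param weather aggregated (single-cell) `region_weather`.
#' @param calendar a `season_calendar` (its `onset_doy` defines the season).
#' @param params [gdd_params()].
#' @param year harvest year.
#' @return integer split day in `[1, season_length]`.
#' @export
split_phases <- function(weather, calendar, params, year) {
  base_year <- attr(weather, "base_year")
  start <- season_start_day(calendar, year, base_year)
  idx <- start:(start + calendar$season_length - 1L)
  tas <- cell_series(weather, "tas")
  if (start < 1L || max(idx) > length(tas)) stop("season not covered by weather")
  g <- daily_gdd(tas[idx], params)
  total <- sum(g)
  if (total <= 0) stop("no thermal accumulation")
  cg <- cumsum(g)
  as.integer(which(cg >= 0.5 * total)[1])
}

# Season-relative day indices (continuous) of one phase for one year.
phase_day_indices <- function(calendar, year, base_year,
                              phase = c("v", "r")) {
  phase <- match.arg(phase)
  start <- season_start_day(calendar, year, base_year)
  if (phase == "v") start:(start + calendar$split - 1L)
  else (start + calendar$split):(start + calendar$season_length - 1L)
}
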