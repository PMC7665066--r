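#' Long-term empirical percentile threshold
#'
#' Empirical `q`% percentile (linear interpolation, type 7) over a reference
#' sample — here all in-season days of all available years for one region.
#'
#' @param series numeric reference values (>= 100 required).
#' @param q percentile in (0, 100).
#' @return threshold in the native units of `series`.
#' @export
long_term_percentile <- function(series, q) {
  if (length(series) < 100L) stop("need at least 100 reference values")
  if (q <= 0 || q >= 100) stop("q must be in (0, 100)")
  unname(quantile(series, probs = q / 100, type = 7, names = FALSE))
}

#' Count days beyond a percentile threshold
#'
#' Strict-inequality count of days in a phase above or below a threshold.
#'
#' @param series in-phase daily values.
#' @param threshold finite threshold in native units.
#' @param direction `"above"` or `"below"`.
#' @return integer count of qualifying days.
#' @export
count_percentile_events <- function(series, threshold,
                                    direction = c("above", "below")) {
  direction <- match.arg(direction)
  if (!is.finite(threshold)) stop("threshold must be finite")
  if (direction == "above") sum(series > threshold) else sum(series < threshold)
}

#' Count days with precipitation beyond a fixed threshold
#'
#' Same strict-inequality counting as [count_percentile_events()]; used with
#' the 5/10/15 mm thresholds (pA5..pA15 above, pB5..pB15 below). Days below
#' the threshold include zero-rain days.
#'
#' @inheritParams count_percentile_events
#' @export
count_threshold_days <- function(series, threshold,
                                 direction = c("above", "below")) {
  count_percentile_events(series, threshold, direction)
}

#' Count dry spells longer than a minimum length
#'
#' Number of maximal runs of dry days (precip <= `wet_threshold` = 0.1 mm)
#' with length strictly greater than `min_len`, runs truncated at the phase
#' boundaries.
#'
#' @param precip in-phase daily precipitation, mm.
#' @param min_len minimum run length in days (cdd5/10/15/20 use 5, 10, 15,
#'   20).
#' @param wet_threshold wet-day threshold, mm.
#' @return integer count of spells.
#' @export
count_dry_spells <- function(precip, min_len, wet_threshold = 0.1) {
  if (length(precip) == 0L) return(0L)
  r <- rle(precip <= wet_threshold)
  sum(r$values & r$lengths > min_len)
}

# the weather feature names emitted per phase (before the _v/_r suffix)
weather_feature_names <- function() {
  c("tas.median", "tas.max", "tas.min", "Psum",
    "pA5", "pA10", "pA15", "pB5", "pB10", "pB15",
    "cdd5", "cdd10", "cdd15", "cdd20",
    "tas.max99", "tas.min01", "precip.p99")
}

# Region-specific long-term percentile thresholds over all in-season days of
# all years (vegetative + reproductive), used by tas.max99 / tas.min01 /
# precip.p99.
season_percentile_thresholds <- function(weather, calendar, years,
                                         q_hi = 99, q_lo = 1) {
  base_year <- attr(weather, "base_year")
  idx <- unlist(lapply(years, function(y) {
    start <- season_start_day(calendar, y, base_year)
    start:(start + calendar$season_length - 1L)
  }))
  list(tasmax_hi = long_term_percentile(cell_series(weather, "tasmax")[idx], q_hi),
       tasmin_lo = long_term_percentile(cell_series(weather, "tasmin")[idx], q_lo),
       precip_hi = long_term_percentile(cell_series(weather, "precip")[idx], q_hi))
}

#' Weather features for one phase of one season
#'
#' Emits the full per-phase catalogue: phase medians of daily mean, maximum
#' and minimum temperature (tas.median, tas.max, tas.min), precipitation sum
#' (Psum), counts of days with precipitation above/below 5, 10, 15 mm
#' (pA5..pA15, pB5..pB15), counts of dry spells longer than 5, 10, 15, 20
#' days (cdd5..cdd20), and counts of days beyond the region-specific
#' long-term percentiles (tas.max99, tas.min01, precip.p99). Names are
#' suffixed `_v` or `_r` by phase.
#'
#' @param weather aggregated (single-cell) `region_weather`.
#' @param calendar a `season_calendar`.
#' @param year harvest year.
#' @param phase `"v"` (vegetative) or `"r"` (reproductive).
#' @param percentile_thresholds list with elements `tasmax_hi`, `tasmin_lo`,
#'   `precip_hi`; computed with [long_term_percentile()] over all in-season
#'   days if omitted (requires `years` attribute on `weather`).
#' @param rain_thresholds fixed precipitation thresholds, mm.
#' @param cdd_lengths dry-spell minimum lengths, days.
#' @param wet_threshold wet-day threshold, mm.
#' @return named numeric vector of features.
#' @export
phase_weather_features <- function(weather, calendar, year, phase,
                                   percentile_thresholds = NULL,
                                   rain_thresholds = c(5, 10, 15),
                                   cdd_lengths = c(5, 10, 15, 20),
                                   wet_threshold = 0.1) {
  base_year <- attr(weather, "base_year")
  if (is.null(percentile_thresholds)) {
    percentile_thresholds <-
      season_percentile_thresholds(weather, calendar, attr(weather, "years"))
  }
  idx <- phase_day_indices(calendar, year, base_year, phase)
  n_days <- length(cell_series(weather, "precip"))
  if (min(idx) < 1L || max(idx) > n_days) stop("season not covered by weather")
  pr <- cell_series(weather, "precip")[idx]
  tas <- cell_series(weather, "tas")[idx]
  tmx <- cell_series(weather, "tasmax")[idx]
  tmn <- cell_series(weather, "tasmin")[idx]

  vals <- c(
    tas.median = median(tas),
    tas.max = median(tmx),
    tas.min = median(tmn),
    Psum = sum(pr),
    setNames(vapply(rain_thresholds, function(th)
      count_threshold_days(pr, th, "above"), numeric(1)),
      paste0("pA", rain_thresholds)),
    setNames(vapply(rain_thresholds, function(th)
      count_threshold_days(pr, th, "below"), numeric(1)),
      paste0("pB", rain_thresholds)),
    setNames(vapply(cdd_lengths, function(len)
      count_dry_spells(pr, len, wet_threshold), numeric(1)),
      paste0("cdd", cdd_lengths)),
    tas.max99 = count_percentile_events(tmx, percentile_thresholds$tasmax_hi, "above"),
    tas.min01 = count_percentile_events(tmn, percentile_thresholds$tasmin_lo, "below"),
    precip.p99 = count_percentile_events(pr, percentile_thresholds$precip_hi, "above")
  )
  setNames(as.numeric(vals), paste0(names(vals), "_", phase))
}

#' SST features for the lead-shifted vegetative window of one season
#'
#' The SST window is the vegetative phase shifted back by the lead time:
#' `[onset - lead_days, onset + split - 1 - lead_days]` in continuous days.
#' Features are computed over the monthly anomalies whose month midpoint
#' falls inside the window: the median, and strict-inequality counts of
#' months above the 99% / below the 1% percentile of the whole multi-year
#' series. Names are `<index>_<lead>.median`, `<index>_<lead>.p99`,
#' `<index>_<lead>.p01`.
#'
#' @param sst an `sst_series`.
#' @param calendar a `season_calendar`.
#' @param year harvest year.
#' @param lead_days lead time in days (defaults: 120 for nino34/wp, 30 for
#'   iod).
#' @param base_year base year of the continuous day axis.
#' @return named numeric vector of three features.
#' @export
sst_features <- function(sst, calendar, year, lead_days,
                         base_year = attr(sst, "base_year")) {
  start <- season_start_day(calendar, year, base_year)
  lo <- start - lead_days
  hi <- start + calendar$split - 1L - lead_days
  in_win <- sst$mid_day >= lo & sst$mid_day <= hi
  if (!any(in_win)) stop("SST window outside series")
  vals <- sst$anomaly[in_win]
  hi_thr <- quantile(sst$anomaly, 0.99, type = 7, names = FALSE)
  lo_thr <- quantile(sst$anomaly, 0.01, type = 7, names = FALSE)
  prefix <- paste0(sst$index[1], "_", lead_days)
  setNames(c(median(vals),
             count_percentile_events(vals, hi_thr, "above"),
             count_percentile_events(vals, lo_thr, "below")),
           paste0(prefix, c(".median", ".p99", ".p01")))
}

#' Select the SST lead time most correlated with yield anomalies
#'
#' For each candidate lead, the median-SST feature is computed per year and
#' correlated (Pearson) with the yield anomalies; the candidate with the
#' highest absolute correlation wins, ties going to the shorter lead.
#'
#' @param sst an `sst_series`.
#' @param calendar a `season_calendar`.
#' @param anomalies yield anomalies aligned with `years`.
#' @param years harvest years.
#' @param candidate_leads candidate lead times, days.
#' @return the selected lead time in days.
#' @export
select_lead_time <- function(sst, calendar, anomalies, years,
                             candidate_leads) {
  if (length(candidate_leads) == 1L) return(candidate_leads)
  if (length(years) < 3L) stop("need at least 3 years")
  scores <- vapply(candidate_leads, function(lead) {
    feat <- vapply(years, function(y)
      sst_features(sst, calendar, y, lead)[1], numeric(1))
    if (sd(feat) == 0) NA_real_ else abs(cor(feat, anomalies))
  }, numeric(1))
  if (all(is.na(scores))) stop("degenerate SST feature for all candidate leads")
  best <- max(scores, na.rm = TRUE)
  cands <- candidate_leads[!is.na(scores) & scores >= best - 1e-12]
  min(cands)
}

#' Assemble the per-region feature table
#'
#' Computes all weather features for both phases and all SST features for
#' every harvest year, in native units (unstandardized). Percentile
#' thresholds are taken over all in-season days of `years`.
#'
#' @param weather `region_weather` (aggregated internally if multi-cell).
#' @param sst_list named list of `sst_series` objects (names are index
#'   names).
#' @param calendar a `season_calendar`.
#' @param years harvest years (table rows).
#' @param sst_leads named lead times in days per index.
#' @return a `feature_table`: list with `region`, `years`, matrix `X`
#'   (years x features), per-column `phase` tags (`"v"`, `"r"`, `"sst"`),
#'   `units`, and standardization state.
#' @export
build_feature_table <- function(weather, sst_list, calendar, years,
                                sst_leads = c(nino34 = 120L, wp = 120L,
                                              iod = 30L)) {
  weather <- aggregate_region_weather(weather)
  thr <- season_percentile_thresholds(weather, calendar, years)
  rows <- lapply(years, function(y) {
    w <- c(phase_weather_features(weather, calendar, y, "v", thr),
           phase_weather_features(weather, calendar, y, "r", thr))
    s <- unlist(lapply(names(sst_list), function(ix)
      sst_features(sst_list[[ix]], calendar, y, sst_leads[[ix]])))
    c(w, s)
  })
  X <- do.call(rbind, rows)
  rownames(X) <- years
  nw <- length(weather_feature_names())
  phase <- c(rep("v", nw), rep("r", nw),
             rep("sst", ncol(X) - 2L * nw))
  units <- rep("", ncol(X))
  units[grepl("^tas\\.m", colnames(X))] <- "degC"
  units[grepl("^Psum", colnames(X))] <- "mm"
  units[grepl("^(pA|pB|cdd|tas\\.max99|tas\\.min01|precip\\.p99)", colnames(X))] <- "days"
  units[phase == "sst"] <- "degC or months"
  structure(list(region = attr(weather, "region") %||% NA_integer_,
                 years = as.integer(years), X = X,
                 phase = setNames(phase, colnames(X)),
                 units = setNames(units, colnames(X)),
                 standardized = FALSE,
                 center = NULL, scale = NULL,
                 zero_variance = character(0)),
            class = "feature_table")
}

#' Construct a feature table from a matrix
#'
#' Wraps a years-by-predictors matrix in the container used throughout the
#' pipeline; useful for custom predictor sets and for tests.
#'
#' @param X numeric matrix, rows = years, named columns.
#' @param years harvest years (row labels).
#' @param phase per-column phase tags (`"v"`, `"r"`, `"sst"`); recycled.
#' @param region region id.
#' @param standardized whether `X` is already standardized (then unit
#'   center/scale parameters are recorded).
#' @return a `feature_table`.
#' @export
feature_table <- function(X, years, phase = "v", region = NA_integer_,
                          standardized = FALSE) {
  stopifnot(is.matrix(X), nrow(X) == length(years),
            !is.null(colnames(X)), !anyDuplicated(colnames(X)))
  structure(list(region = region, years = as.integer(years), X = X,
                 phase = setNames(rep_len(phase, ncol(X)), colnames(X)),
                 units = setNames(rep("", ncol(X)), colnames(X)),
                 standardized = standardized,
                 center = if (standardized) setNames(rep(0, ncol(X)), colnames(X)),
                 scale = if (standardized) setNames(rep(1, ncol(X)), colnames(X)),
                 zero_variance = character(0)),
            class = "feature_table")
}

#' Standardize a feature table on a fit-year subset
#'
#' Columns are centred and scaled by the mean and sample standard deviation
#' computed over `fit_years` only; the transform is applied to all rows, so
#' held-out years are expressed in fit-year units (no leakage).
#' Zero-variance columns are flagged and left untouched (they are removed
#' later by the zero-variance filter).
#'
#' @param features a `feature_table` in native units.
#' @param fit_years years whose statistics define the transform (default:
#'   all rows).
#' @return a standardized `feature_table` with `center`/`scale` recorded.
#' @export
standardize_features <- function(features, fit_years = features$years) {
  stopifnot(inherits(features, "feature_table"))
  if (isTRUE(features$standardized)) stop("feature table already standardized")
  fit_rows <- match(fit_years, features$years)
  if (anyNA(fit_rows)) stop("fit_years not all present in feature table")
  Xf <- features$X[fit_rows, , drop = FALSE]
  ctr <- colMeans(Xf)
  scl <- apply(Xf, 2, sd)
  zero <- colnames(features$X)[scl < 1e-12 | !is.finite(scl)]
  ctr[colnames(features$X) %in% zero] <- 0
  scl[colnames(features$X) %in% zero] <- 1
  out <- features
  out$X <- sweep(sweep(features$X, 2, ctr, "-"), 2, scl, "/")
  out$standardized <- TRUE
  out$center <- ctr
  out$scale <- scl
  out$zero_variance <- zero
  out$fit_years <- as.integer(fit_years)
  out
}

#' Restrict a feature table to a feature scope
#'
#' The estimation scope keeps everything; the forecast scope keeps only the
#' vegetative-phase weather features and the SST features, the information
#' available at the within-season forecast date (about 55 days before
#' harvest).
#'
#' @param features a `feature_table`.
#' @param scope `"estimation"` or `"forecast"`.
#' @return the restricted `feature_table`.
#' @export
scope_features <- function(features, scope = c("estimation", "forecast")) {
  scope <- match.arg(scope)
  if (scope == "estimation") return(features)
  keep <- features$phase %in% c("v", "sst")
  subset_feature_columns(features, colnames(features$X)[keep])
}

# Keep only the named columns of a feature table (order preserved).
subset_feature_columns <- function(features, cols) {
  out <- features
  out$X <- features$X[, cols, drop = FALSE]
  out$phase <- features$phase[cols]
  out$units <- features$units[cols]
  if (!is.null(out$center)) {
    out$center <- out$center[cols]
    out$scale <- out$scale[cols]
  }
  out$zero_variance <- intersect(features$zero_variance, cols)
  out
}
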