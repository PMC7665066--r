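# Trend design matrix in powers of (year - origin_year).
trend_design <- function(years, origin_year, type) {
  t <- years - origin_year
  one <- rep(1, length(years))
  switch(type,
         mean = cbind(one),
         linear = cbind(one, t),
         quadratic = cbind(one, t, t^2),
         stop("unknown trend type"))
}

#' Predict the log-scale trend for given years
#'
#' @param trend a `trend_model` from [detrend_yields()].
#' @param years harvest years (may extrapolate beyond the fit years).
#' @return log-scale trend values.
#' @export
trend_predict <- function(trend, years) {
  X <- trend_design(years, trend$origin_year, trend$type)
  as.numeric(X %*% trend$coefficients)
}

#' Detrend log yields with the AIC-selected trend model
#'
#' Fits the three candidate trends — mean, linear, quadratic in
#' `year - first_fit_year` — to log yields over the fit years by OLS,
#' scores them with the Gaussian AIC `n * ln(SSE/n) + 2p` (p = number of
#' trend coefficients), and keeps the candidate with the lowest AIC, ties
#' broken toward fewer parameters. Anomalies (log yield minus trend) are
#' returned for every year in the series, including years outside the fit
#' set (trend extrapolated), and have mean ~0 over the fit years.
#'
#' @param yields a `yield_series` (positive t/ha).
#' @param fit_years years used to fit the trend (>= 4; default all).
#' @return list with `anomalies` (named by year, log scale) and `trend`
#'   (a `trend_model`: `type`, `coefficients`, `aic` per candidate,
#'   `fit_years`, `origin_year`).
#' @export
detrend_yields <- function(yields, fit_years = yields$year) {
  if (any(yields$yield <= 0)) stop("yields must be strictly positive")
  fit_years <- as.integer(fit_years)
  if (length(fit_years) < 4L) stop("need at least 4 fit years")
  if (!all(fit_years %in% yields$year)) stop("fit_years not all present")
  origin <- min(fit_years)
  ly <- log(yields$yield)
  names(ly) <- yields$year
  yfit <- ly[as.character(fit_years)]
  n <- length(yfit)
  cand <- c("mean", "linear", "quadratic")
  # SSEs at rounding level are clamped to a common scale-aware floor so that
  # exact fits tie (and the tie then resolves toward fewer parameters)
  sse_floor <- 1e-10 * (mean(yfit^2) + 1)
  fits <- lapply(cand, function(type) {
    X <- trend_design(fit_years, origin, type)
    fit <- lm.fit(X, yfit)
    sse <- max(sum(fit$residuals^2), sse_floor)
    p <- ncol(X)
    list(type = type, coef = fit$coefficients,
         aic = n * log(sse / n) + 2 * p, p = p)
  })
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  # candidates ordered by parameter count, so which.min breaks ties toward
  # the simpler model
  best <- fits[[which.min(aic)]]
  trend <- structure(list(type = best$type,
                          coefficients = as.numeric(best$coef),
                          aic = setNames(aic, cand),
                          fit_years = fit_years,
                          origin_year = origin),
                     class = "trend_model")
  anomalies <- ly - trend_predict(trend, yields$year)
  list(anomalies = anomalies, trend = trend)
}

#' Reconstruct absolute yields from anomalies and a trend model
#'
#' Inverse of [detrend_yields()]: `yield = exp(anomaly + trend(year))`.
#' The round trip detrend -> retrend reproduces the observed yields to
#' numerical tolerance; output is strictly positive by construction.
#'
#' @param anomalies log-scale anomalies (predicted or observed).
#' @param trend a `trend_model`.
#' @param years harvest years aligned with `anomalies`.
#' @return absolute yields, t/ha.
#' @export
retrend_yields <- function(anomalies, trend, years) {
  exp(as.numeric(anomalies) + trend_predict(trend, years))
}
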