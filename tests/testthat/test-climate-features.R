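test_that("long-term percentile interpolates like a sorted-array oracle", {
  expect_equal(long_term_percentile(1:100, 50), 50.5)
  expect_equal(long_term_percentile(rep(7, 150), 99), 7)
  set.seed(8)
  x <- stats::rnorm(500)
  for (q in c(1, 50, 99)) {
    expect_equal(long_term_percentile(x, q), oracle_percentile(x, q))
  }
  expect_error(long_term_percentile(1:10, 50), "100")
  expect_error(long_term_percentile(1:200, 0), "q must")
})

test_that("threshold-event counts use strict inequalities and match loops", {
  expect_equal(count_percentile_events(c(1, 2, 3), 5, "above"), 0)
  expect_equal(count_percentile_events(c(1, 2, 3), 2, "above"), 1)
  expect_equal(count_threshold_days(c(0, 4, 6, 20), 5, "above"), 2)
  expect_equal(count_threshold_days(c(0, 4, 6, 20), 5, "below"), 2)
  expect_error(count_percentile_events(1:3, Inf, "above"), "finite")
  set.seed(9)
  for (i in 1:30) {
    x <- random_rain_series(60)
    thr <- stats::runif(1, 0, 15)
    expect_equal(count_threshold_days(x, thr, "above"), oracle_count_above(x, thr))
    expect_equal(count_threshold_days(x, thr, "below"), oracle_count_below(x, thr))
  }
})

test_that("dry-spell counting matches a run-length oracle and the boundary rules", {
  expect_equal(count_dry_spells(numeric(55), 5), 1)   # one maximal 55-day run
  expect_equal(count_dry_spells(rep(c(0, 1), 28), 5), 0)
  expect_equal(count_dry_spells(numeric(5), 5), 0)    # run not longer than 5
  expect_equal(count_dry_spells(numeric(6), 5), 1)
  set.seed(10)
  for (i in 1:30) {
    x <- random_rain_series(55, p_wet = stats::runif(1, 0.1, 0.8))
    for (len in c(5, 10, 15, 20)) {
      expect_equal(count_dry_spells(x, len), oracle_dry_spells(x, len))
    }
  }
})

test_that("phase features reproduce their stand-alone oracle computations", {
  w <- designed_onset_weather(onset_doys = c(60, 60), years = 2010:2011, tas = 25)
  cal <- build_calendar(w, regime = "bimodal", years = 2010:2011)

  f <- phase_weather_features(w, cal, 2010, "v")
  expect_equal(unname(f["tas.median_v"]), 25)

  # 2 mm/day: Psum = 2 * phase length, no dry spells
  w2 <- region_weather(rep(2, length(w$precip)), tas = rep(25, length(w$precip)),
                       base_year = 2009, years = 2010:2011, regime = "bimodal")
  f2 <- phase_weather_features(w2, cal, 2010, "v",
                               percentile_thresholds = list(tasmax_hi = 40,
                                                            tasmin_lo = 0,
                                                            precip_hi = 50))
  expect_equal(unname(f2["Psum_v"]), 2 * cal$split)
  expect_equal(unname(f2["cdd5_v"]), 0)
  expect_equal(unname(f2["pA5_v"]), 0)
  expect_equal(unname(f2["pB5_v"]), cal$split)

  # random season: every feature equals its oracle
  set.seed(12)
  n <- length(w$precip)
  wr <- region_weather(random_rain_series(n), tas = stats::rnorm(n, 24, 3),
                       base_year = 2009, years = 2010:2011, regime = "bimodal")
  thr <- maizecast:::season_percentile_thresholds(wr, cal, 2010:2011)
  for (phase in c("v", "r")) {
    idx <- maizecast:::phase_day_indices(cal, 2010, 2009, phase)
    pr <- wr$precip[idx]; tmx <- wr$tasmax[idx]; tmn <- wr$tasmin[idx]
    f <- phase_weather_features(wr, cal, 2010, phase, thr)
    suf <- paste0("_", phase)
    expect_equal(unname(f[paste0("tas.median", suf)]), median(wr$tas[idx]))
    expect_equal(unname(f[paste0("tas.max", suf)]), median(tmx))
    expect_equal(unname(f[paste0("tas.min", suf)]), median(tmn))
    expect_equal(unname(f[paste0("Psum", suf)]), sum(pr))
    for (t in c(5, 10, 15)) {
      expect_equal(unname(f[paste0("pA", t, suf)]), oracle_count_above(pr, t))
      expect_equal(unname(f[paste0("pB", t, suf)]), oracle_count_below(pr, t))
    }
    for (len in c(5, 10, 15, 20)) {
      expect_equal(unname(f[paste0("cdd", len, suf)]), oracle_dry_spells(pr, len))
    }
    expect_equal(unname(f[paste0("tas.max99", suf)]),
                 oracle_count_above(tmx, thr$tasmax_hi))
    expect_equal(unname(f[paste0("tas.min01", suf)]),
                 oracle_count_below(tmn, thr$tasmin_lo))
    expect_equal(unname(f[paste0("precip.p99", suf)]),
                 oracle_count_above(pr, thr$precip_hi))
  }
})

test_that("SST features cover the lead-shifted vegetative window with whole-series thresholds", {
  cfg <- synthetic_config(n_regions = 1, years = 2010:2015, seed = 4)
  s <- gen_sst_series(cfg, "nino34")
  w <- designed_onset_weather(onset_doys = rep(60, 6), years = 2010:2015)
  cal <- build_calendar(w, regime = "bimodal", years = 2010:2015)

  # constant series: median is the constant, counts zero
  sc <- s
  sc$anomaly <- rep(0.4, nrow(s))
  fc <- sst_features(sc, cal, 2012, 30, base_year = 2009)
  expect_equal(unname(fc), c(0.4, 0, 0))
  expect_equal(names(fc), c("nino34_30.median", "nino34_30.p99", "nino34_30.p01"))

  # brute-force month selection and counts
  for (lead in c(30, 120)) {
    f <- sst_features(s, cal, 2012, lead, base_year = 2009)
    start <- maizecast:::season_start_day(cal, 2012, 2009)
    lo <- start - lead; hi <- start + cal$split - 1 - lead
    vals <- s$anomaly[s$mid_day >= lo & s$mid_day <= hi]
    hi_thr <- oracle_percentile(s$anomaly, 99)
    lo_thr <- oracle_percentile(s$anomaly, 1)
    expect_equal(unname(f[1]), median(vals))
    expect_equal(unname(f[2]), oracle_count_above(vals, hi_thr))
    expect_equal(unname(f[3]), oracle_count_below(vals, lo_thr))
  }

  expect_error(sst_features(s, cal, 2010, 5000, base_year = 2009), "window")
})

test_that("lead-time selection picks the lead most correlated with anomalies", {
  cfg <- synthetic_config(n_regions = 1, years = 2010:2015, seed = 14)
  s <- gen_sst_series(cfg, "wp")
  w <- designed_onset_weather(onset_doys = rep(60, 6), years = 2010:2015)
  cal <- build_calendar(w, regime = "bimodal", years = 2010:2015)
  feat120 <- vapply(2010:2015, function(y)
    sst_features(s, cal, y, 120, base_year = 2009)[1], numeric(1))
  anomalies <- 2 * feat120 # constructed to be linear in the 120-day feature
  expect_equal(select_lead_time(s, cal, anomalies, 2010:2015,
                                candidate_leads = c(30, 60, 120)), 120)
  expect_equal(select_lead_time(s, cal, anomalies, 2010:2015,
                                candidate_leads = 45), 45)
  # identical features for all candidates: the shorter lead wins
  sc <- s; sc$anomaly <- sin(seq_len(nrow(s)) %% 2) + seq_len(nrow(s)) * 0
  expect_equal(select_lead_time(s, cal, anomalies, 2010:2015,
                                candidate_leads = c(120, 120)), 120)
})

test_that("standardization uses fit-year statistics and flags degenerate columns", {
  X <- cbind(a = c(1, 2, 3, 4), b = c(5, 5, 5, 5), c = c(2, 4, 8, 10))
  ft <- feature_table(X, 2011:2014)
  fs <- standardize_features(ft)
  expect_equal(unname(fs$X[, "a"]), unname(scale(X[, "a"])[, 1]))
  expect_equal(fs$zero_variance, "b")
  expect_equal(unname(fs$X[, "b"]), X[, "b"], ignore_attr = TRUE)

  # column {1,2,3}: sample sd 1, so standardized values are {-1, 0, 1}
  ft3 <- feature_table(cbind(x = c(1, 2, 3)), 2011:2013)
  expect_equal(unname(standardize_features(ft3)$X[, "x"]), c(-1, 0, 1))

  # fit on the first years, transform a held-out year by the same parameters
  fs2 <- standardize_features(ft, fit_years = 2011:2013)
  m <- mean(X[1:3, "c"]); s <- sd(X[1:3, "c"])
  expect_equal(unname(fs2$X[4, "c"]), unname((X[4, "c"] - m) / s))
  expect_error(standardize_features(fs2), "already")
})

test_that("features ignore weather outside the season and lead window", {
  cfg <- synthetic_config(n_regions = 1, years = 2010:2013, seed = 31)
  w <- gen_region_weather(cfg, 1)
  sst <- list(nino34 = gen_sst_series(cfg, "nino34"),
              wp = gen_sst_series(cfg, "wp"),
              iod = gen_sst_series(cfg, "iod"))
  cal <- build_calendar(w)
  ft <- build_feature_table(w, sst, cal, 2010:2013)

  # perturb days more than 200 days after every season end
  w2 <- w
  season_days <- unlist(lapply(2010:2013, function(y) {
    st <- maizecast:::season_start_day(cal, y, 2009)
    st:(st + 109)
  }))
  far <- setdiff(seq_len(nrow(w2)), unique(c(outer(season_days, -200:200, "+"))))
  w2$tas[far] <- w2$tas[far] + 5
  w2$precip[far] <- 0
  ft2 <- build_feature_table(w2, sst, cal, 2010:2013)
  weather_cols <- names(ft$phase)[ft$phase %in% c("v", "r")]
  # percentile thresholds use in-season days only, so weather features match
  expect_equal(ft2$X[, weather_cols], ft$X[, weather_cols])
})
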