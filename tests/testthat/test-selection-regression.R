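test_that("zero-variance filter removes exactly the constant columns", {
  X <- cbind(a = rnorm(8), b = rep(2, 8), c = rnorm(8))
  ft <- feature_table(X, 2011:2018)
  out <- drop_zero_variance(ft)
  expect_equal(colnames(out$X), c("a", "c"))

  ft2 <- feature_table(X[, c("a", "c")], 2011:2018)
  expect_equal(colnames(drop_zero_variance(ft2)$X), c("a", "c"))
  expect_error(drop_zero_variance(feature_table(cbind(z = rep(1, 8)), 2011:2018)),
               "no informative")

  # survivors equal a brute-force sd check on random mixed tables
  set.seed(21)
  for (i in 1:10) {
    M <- matrix(rnorm(40), 8, 5)
    M[, sample(5, 2)] <- rep(1, 8)
    colnames(M) <- letters[1:5]
    want <- colnames(M)[apply(M, 2, sd) > 0]
    expect_equal(colnames(drop_zero_variance(feature_table(M, 2011:2018))$X), want)
  }
})

test_that("collinearity filter keeps the member more correlated with anomalies", {
  set.seed(22)
  x <- rnorm(10)
  y <- x + rnorm(10, sd = 0.3)
  X <- cbind(good = x, dup = x, other = rnorm(10))
  ft <- feature_table(X, 2009:2018)
  out <- collinearity_filter(ft, y)
  # exactly one of the duplicated pair survives: the one more correlated with y
  expect_true(xor("good" %in% colnames(out$X), "dup" %in% colnames(out$X)))
  kept <- intersect(colnames(out$X), c("good", "dup"))
  other <- setdiff(c("good", "dup"), kept)
  expect_gte(abs(cor(X[, kept], y)), abs(cor(X[, other], y)))
  expect_true("other" %in% colnames(out$X))

  # mutually near-orthogonal columns pass unchanged
  Xo <- qr.Q(qr(matrix(rnorm(100), 10)))[, 1:5]
  colnames(Xo) <- letters[1:5]
  expect_equal(colnames(collinearity_filter(feature_table(Xo, 2009:2018), y)$X),
               letters[1:5])
})

test_that("collinearity filter matches the greedy oracle and bounds pairwise correlation", {
  set.seed(23)
  for (i in 1:25) {
    n <- 10
    Z <- matrix(rnorm(n * 4), n, 4)
    # build 8 columns as noisy mixtures so some pairs exceed the threshold
    X <- Z[, c(1, 1, 2, 2, 3, 3, 4, 4)] + matrix(rnorm(n * 8, sd = 0.4), n, 8)
    colnames(X) <- sprintf("c%d", 1:8)
    y <- rnorm(n)
    out <- collinearity_filter(feature_table(X, 2009:2018), y)
    expect_setequal(colnames(out$X), oracle_collinearity(X, y))
    C <- abs(cor(out$X))
    diag(C) <- 0
    expect_lte(max(C), 0.7)
  }
})

test_that("LASSO selection finds a strong single predictor and caps cardinality", {
  set.seed(24)
  ft <- gaussian_feature_table(n_years = 10, p = 12)
  y <- 2 * ft$X[, "f03"] + rnorm(10, sd = 0.05)
  y <- y - mean(y)
  names(y) <- ft$years
  sel <- lasso_select(ft, y)
  expect_true("f03" %in% sel)
  expect_lte(length(sel), 5)

  # ten informative columns still yield at most five selections
  beta <- rep(0.5, 10)
  y10 <- as.numeric(ft$X[, 1:10] %*% beta) + rnorm(10, sd = 0.05)
  y10 <- y10 - mean(y10)
  expect_lte(length(lasso_select(ft, y10)), 5)

  # zero anomalies shrink everything away
  expect_length(lasso_select(ft, rep(0, 10)), 0)
})

test_that("region model fits OLS without intercept and reports exact cases", {
  ft <- gaussian_feature_table(n_years = 10, p = 4)
  y <- 0.7 * ft$X[, "f02"]
  fit <- fit_region_model(ft, "f02", y)
  expect_equal(unname(fit$betas), 0.7, tolerance = 1e-12)
  expect_equal(fit$residuals, rep(0, 10), tolerance = 1e-12)
  expect_equal(fit$K, 1)

  # zero features: the model predicts the mean (zero on anomaly scale)
  fit0 <- fit_region_model(ft, character(0), y)
  expect_equal(fit0$fitted, rep(0, 10))
  expect_equal(predict_anomalies(fit0, ft, 2009:2011), rep(0, 3))

  # duplicated regressor: rank error naming the column
  X <- cbind(a = ft$X[, 1], b = ft$X[, 1])
  ftd <- feature_table(X, ft$years, standardized = TRUE)
  expect_error(fit_region_model(ftd, c("a", "b"), y), "collinear columns: b")
})

test_that("betas are recovered on a well-conditioned design with small noise", {
  set.seed(26)
  ok <- 0
  for (i in 1:20) {
    ft <- gaussian_feature_table(n_years = 10, p = 8)
    truth <- c(f01 = 0.6, f04 = -0.5, f07 = 0.5)
    y <- as.numeric(ft$X[, names(truth)] %*% truth) + rnorm(10, sd = 0.01)
    y <- y - mean(y)
    fit <- fit_region_model(ft, names(truth), y)
    ok <- ok + (max(abs(fit$betas - truth)) <= 0.05)
  }
  expect_gte(ok, 18)
})

test_that("diagnostics report VIF, serial-correlation and heteroscedasticity tests", {
  # orthonormal mean-zero design: all VIF equal 1
  set.seed(25)
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(30), 10, 3))))[, 2:4]
  colnames(Q) <- c("a", "b", "c")
  ftq <- feature_table(Q, 2009:2018, standardized = TRUE)
  y <- as.numeric(Q %*% c(1, -1, 0.5)) + rnorm(10, sd = 0.3)
  fit <- fit_region_model(ftq, c("a", "b", "c"), y)
  d <- model_diagnostics(fit, ftq)
  expect_true(d$applicable)
  expect_equal(unname(d$vif), rep(1, 3), tolerance = 1e-8)
  expect_true(d$breusch_godfrey_p >= 0 && d$breusch_godfrey_p <= 1)
  expect_true(d$breusch_pagan_p >= 0 && d$breusch_pagan_p <= 1)

  # zero selected features: explicit not-applicable report
  fit0 <- fit_region_model(ftq, character(0), y)
  d0 <- model_diagnostics(fit0, ftq)
  expect_false(d0$applicable)
  expect_true(is.na(d0$breusch_godfrey_p))
})

test_that("the serial-correlation test holds its nominal size on iid residuals", {
  set.seed(27)
  n <- 80
  rejections <- 0
  nsim <- 300
  for (i in seq_len(nsim)) {
    X <- matrix(rnorm(n * 2), n, 2)
    colnames(X) <- c("a", "b")
    ft <- feature_table(X, seq_len(n) + 2000, standardized = TRUE)
    y <- as.numeric(X %*% c(0.5, -0.5)) + rnorm(n)
    fit <- fit_region_model(ft, c("a", "b"), y)
    d <- model_diagnostics(fit, ft)
    rejections <- rejections + (d$breusch_godfrey_p < 0.05)
  }
  expect_gt(rejections / nsim, 0.02)
  expect_lt(rejections / nsim, 0.09)
})

test_that("the full selection chain is deterministic and satisfies its contract", {
  set.seed(28)
  ds <- small_dataset(3)
  reg <- ds$regions$region1
  det <- detrend_yields(reg$yields)
  fstd <- standardize_features(reg$features_native)
  s1 <- select_variables(fstd, det$anomalies)
  s2 <- select_variables(fstd, det$anomalies)
  expect_identical(s1$selected, s2$selected)
  expect_lte(length(s1$selected), 5)
  sds <- apply(s1$features$X, 2, sd)
  expect_true(all(sds > 0))
  if (ncol(s1$features$X) > 1) {
    C <- abs(cor(s1$features$X))
    diag(C) <- 0
    expect_lte(max(C), 0.7)
  }
})
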