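#' Drop predictors without year-to-year variation
#'
#' Removes columns whose sample standard deviation over the fit years is
#' zero; survivor order is preserved.
#'
#' @param features a `feature_table`.
#' @param fit_years years over which variance is assessed (default all).
#' @return the filtered `feature_table`.
#' @export
drop_zero_variance <- function(features, fit_years = features$years) {
  rows <- match(fit_years, features$years)
  sds <- apply(features$X[rows, , drop = FALSE], 2, sd)
  keep <- colnames(features$X)[sds > 1e-12 & is.finite(sds)]
  if (length(keep) == 0L) stop("no informative predictors")
  subset_feature_columns(features, keep)
}

#' Greedy collinearity filter
#'
#' Repeatedly finds the remaining pair of predictors with the largest
#' absolute Pearson correlation exceeding `r_threshold` (pairs processed in
#' descending |r|; equal |r| broken by lexicographic pair names) and drops
#' the member with the lower absolute correlation with the yield anomalies
#' (tie: the lexicographically later name is dropped). Stops when all
#' pairwise |r| <= `r_threshold`.
#'
#' @param features a `feature_table` (no zero-variance columns).
#' @param anomalies yield anomalies aligned with `fit_years`.
#' @param fit_years years over which correlations are computed.
#' @param r_threshold collinearity threshold (0.7).
#' @return the filtered `feature_table`.
#' @export
collinearity_filter <- function(features, anomalies,
                                fit_years = features$years,
                                r_threshold = 0.7) {
  rows <- match(fit_years, features$years)
  X <- features$X[rows, , drop = FALSE]
  y <- as.numeric(anomalies)
  keep <- colnames(X)
  if (length(keep) >= 2L) {
    C <- abs(cor(X))
    ry <- if (sd(y) > 0) abs(apply(X, 2, cor, y = y))
          else setNames(rep(0, ncol(X)), colnames(X)) # all duels tie
    repeat {
      Ck <- C[keep, keep, drop = FALSE]
      diag(Ck) <- 0
      m <- max(Ck)
      if (m <= r_threshold) break
      hits <- which(Ck >= m - 1e-12, arr.ind = TRUE)
      pairs <- t(apply(hits, 1, function(ij)
        sort(c(rownames(Ck)[ij[1]], colnames(Ck)[ij[2]]))))
      pairs <- unique(pairs)
      ord <- order(pairs[, 1], pairs[, 2])
      a <- pairs[ord[1], 1]; b <- pairs[ord[1], 2]
      drop <- if (ry[a] > ry[b]) b
              else if (ry[b] > ry[a]) a
              else max(a, b) # tie: drop the lexicographically later name
      keep <- setdiff(keep, drop)
      if (length(keep) < 2L) break
    }
  }
  subset_feature_columns(features, keep)
}

# Soft-threshold operator.
soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

# LASSO coefficient path without intercept for a single predictor; closed
# form beta(lambda) = S(x'y/n, lambda) / (x'x/n). glmnet needs >= 2 columns,
# so the one-column case is computed analytically.
lasso_path_1d <- function(x, y, lambda) {
  n <- length(y)
  rho <- sum(x * y) / n
  xx <- sum(x * x) / n
  matrix(soft(rho, lambda) / xx, nrow = 1,
         dimnames = list(NULL, NULL))
}

lasso_coefs <- function(X, y, lambda) {
  if (ncol(X) == 1L) {
    b <- lasso_path_1d(X[, 1], y, lambda)
    rownames(b) <- colnames(X)
    b
  } else {
    fit <- suppressWarnings(
      glmnet::glmnet(X, y, family = "gaussian", alpha = 1,
                     lambda = lambda, intercept = FALSE,
                     standardize = FALSE, thresh = 1e-9, maxit = 5e5))
    B <- as.matrix(coef(fit))[-1, , drop = FALSE]
    if (ncol(B) < length(lambda)) {
      # tiny penalties may not converge in the p > n interpolation regime;
      # glmnet then returns solutions for the larger penalties only — carry
      # the last converged solution forward
      B <- cbind(B, B[, rep(ncol(B), length(lambda) - ncol(B)), drop = FALSE])
    }
    B
  }
}

#' LASSO variable selection with leave-one-year-out cross-validation
#'
#' The penalty is chosen on a fixed grid of 100 log-spaced values from
#' `lambda_max` (the smallest penalty that zeroes every coefficient) down to
#' `lambda_max * 1e-4` by leave-one-year-out cross-validated MSE, ties
#' going to the larger penalty (sparser fit). Features with nonzero
#' coefficients at the chosen penalty are candidates; if more than
#' `max_vars` remain, the `max_vars` with the highest absolute Pearson
#' correlation with the anomalies are kept. The model is fitted without
#' intercept (the response is demeaned/detrended). An empty selection is a
#' valid outcome (the downstream model then predicts the mean).
#'
#' @param features a standardized `feature_table`.
#' @param anomalies yield anomalies aligned with `fit_years`.
#' @param fit_years years used for selection (>= 4).
#' @param max_vars selection cap (5 for estimation/level-1, 4 inside
#'   level-2 folds).
#' @param nlambda,lambda_min_ratio grid size and range.
#' @return character vector of selected feature names (possibly empty).
#' @export
lasso_select <- function(features, anomalies, fit_years = features$years,
                         max_vars = 5L, nlambda = 100L,
                         lambda_min_ratio = 1e-4) {
  if (length(fit_years) < 4L) stop("need at least 4 fit years")
  rows <- match(fit_years, features$years)
  X <- features$X[rows, , drop = FALSE]
  y <- as.numeric(anomalies)
  n <- length(y)
  if (ncol(X) == 0L) return(character(0))
  lambda_max <- max(abs(crossprod(X, y))) / n
  if (lambda_max < 1e-12) return(character(0)) # anomalies orthogonal to all X
  lambda <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                    length.out = nlambda))
  sqerr <- matrix(NA_real_, n, nlambda)
  for (k in seq_len(n)) {
    B <- lasso_coefs(X[-k, , drop = FALSE], y[-k], lambda)
    pred <- as.numeric(X[k, , drop = FALSE] %*% B)
    sqerr[k, ] <- (y[k] - pred)^2
  }
  cvm <- colMeans(sqerr)
  # grid is descending, so which.min ties resolve to the larger penalty
  lambda_star <- lambda[which.min(cvm)]
  beta <- lasso_coefs(X, y, lambda_star)[, 1]
  selected <- colnames(X)[abs(beta) > 1e-10]
  if (length(selected) > max_vars) {
    ry <- abs(apply(X[, selected, drop = FALSE], 2, cor, y = y))
    selected <- selected[order(-ry, selected)][seq_len(max_vars)]
    selected <- selected[order(match(selected, colnames(X)))]
  }
  selected
}

#' Fit the per-region regression on selected features
#'
#' Ordinary least squares of the demeaned/detrended log-yield anomalies on
#' the selected standardized features, without intercept. With zero
#' selected features the model predicts 0 (the mean). Coefficients are
#' effects per standard deviation of the predictor on log yield.
#'
#' @param features a standardized `feature_table`.
#' @param selected names of selected features (possibly empty).
#' @param anomalies yield anomalies aligned with `fit_years`.
#' @param fit_years years entering the fit; must exceed the number of
#'   selected features.
#' @return a `fit_result`: `region`, `features`, `betas`, `residuals`,
#'   `fitted`, `K`, `T`, `years`.
#' @export
fit_region_model <- function(features, selected, anomalies,
                             fit_years = features$years) {
  rows <- match(fit_years, features$years)
  y <- as.numeric(anomalies)
  K <- length(selected)
  if (K >= length(fit_years)) stop("more selected features than fit years allow")
  if (K == 0L) {
    fitted <- numeric(length(y))
    betas <- setNames(numeric(0), character(0))
    residuals <- y
  } else {
    X <- features$X[rows, selected, drop = FALSE]
    qrX <- qr(X)
    if (qrX$rank < K) {
      bad <- selected[-seq_len(qrX$rank)]
      stop("rank-deficient design; collinear columns: ",
           paste(bad, collapse = ", "))
    }
    fit <- lm.fit(X, y)
    betas <- setNames(as.numeric(fit$coefficients), selected)
    fitted <- as.numeric(fit$fitted.values)
    residuals <- as.numeric(fit$residuals)
  }
  structure(list(region = features$region, features = selected,
                 betas = betas, residuals = residuals, fitted = fitted,
                 K = K, T = length(fit_years),
                 years = as.integer(fit_years)),
            class = "fit_result")
}

#' Predict anomalies from a fitted region model
#'
#' @param fit a `fit_result`.
#' @param features a standardized `feature_table` containing the fit's
#'   features.
#' @param years years to predict.
#' @return predicted log-scale anomalies.
#' @export
predict_anomalies <- function(fit, features, years) {
  rows <- match(years, features$years)
  if (anyNA(rows)) stop("years not in feature table")
  if (fit$K == 0L) return(numeric(length(years)))
  as.numeric(features$X[rows, fit$features, drop = FALSE] %*% fit$betas)
}

#' Residual and collinearity diagnostics for a region fit
#'
#' Breusch-Godfrey test (lag 1, residuals in year order) for serial
#' correlation, studentized Breusch-Pagan test for heteroscedasticity, and
#' variance inflation factors from auxiliary regressions
#' (`VIF = 1 / (1 - R^2_aux)`; 1 for a single predictor). With zero
#' selected features the report is marked not applicable.
#'
#' @param fit a `fit_result`.
#' @param features the standardized `feature_table` used in the fit.
#' @return a `diagnostics_report`: `applicable`, `breusch_godfrey_p`,
#'   `breusch_pagan_p`, `vif` (named, >= 1).
#' @export
model_diagnostics <- function(fit, features) {
  if (fit$K == 0L) {
    return(structure(list(applicable = FALSE,
                          breusch_godfrey_p = NA_real_,
                          breusch_pagan_p = NA_real_,
                          vif = setNames(numeric(0), character(0))),
                     class = "diagnostics_report"))
  }
  if (length(fit$residuals) < fit$K + 2L) stop("too few residuals for diagnostics")
  rows <- match(fit$years, features$years)
  X <- features$X[rows, fit$features, drop = FALSE]
  df <- data.frame(.y = fit$fitted + fit$residuals, X, check.names = FALSE)
  fml <- stats::as.formula(paste0("`.y` ~ 0 + ",
                                  paste0("`", fit$features, "`", collapse = " + ")))
  m <- lm(fml, data = df)
  bg <- lmtest::bgtest(m, order = 1)
  bp <- lmtest::bptest(m) # studentized (Koenker) variant by default
  vif <- if (fit$K == 1L) setNames(1, fit$features) else {
    vapply(seq_len(fit$K), function(j) {
      aux <- lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
      r2 <- 1 - sum(aux$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
      1 / (1 - min(r2, 1 - 1e-12))
    }, numeric(1)) |> setNames(fit$features)
  }
  structure(list(applicable = TRUE,
                 breusch_godfrey_p = unname(bg$p.value),
                 breusch_pagan_p = unname(bp$p.value),
                 vif = vif),
            class = "diagnostics_report")
}

#' Run the full variable-selection chain
#'
#' Zero-variance filter, collinearity filter (|r| > 0.7), then LASSO with
#' leave-one-year-out penalty choice and the correlation cap.
#'
#' @inheritParams lasso_select
#' @param r_threshold collinearity threshold.
#' @return list with `features` (the filtered `feature_table`) and
#'   `selected` (character vector).
#' @export
select_variables <- function(features, anomalies,
                             fit_years = features$years,
                             max_vars = 5L, r_threshold = 0.7) {
  f1 <- drop_zero_variance(features, fit_years)
  f2 <- collinearity_filter(f1, anomalies, fit_years, r_threshold)
  sel <- lasso_select(f2, anomalies, fit_years, max_vars)
  list(features = f2, selected = sel)
}
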