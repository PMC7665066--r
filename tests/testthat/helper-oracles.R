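# Independent brute-force oracles, written as literal transcriptions of the
# definitions and kept free of any package internals.

# Literal day-by-day check of the three rainfall-onset criteria.
oracle_onset <- function(precip, search_start, search_end,
                         wet_threshold = 0.1, amount = 25) {
  for (d in search_start:search_end) {
    window6 <- precip[d:(d + 5)]
    crit1 <- sum(window6) >= amount
    crit2 <- precip[d] > wet_threshold && sum(window6 > wet_threshold) >= 3
    crit3 <- TRUE
    run <- 0
    for (j in (d + 1):(d + 40)) {
      run <- if (precip[j] <= wet_threshold) run + 1 else 0
      if (run >= 10) { crit3 <- FALSE; break }
    }
    if (crit1 && crit2 && crit3) return(d)
  }
  NA_integer_
}

# Cumulative-sum scan for the 50%-GDD split day.
oracle_split <- function(gdd) {
  total <- sum(gdd)
  acc <- 0
  for (s in seq_along(gdd)) {
    acc <- acc + gdd[s]
    if (acc >= 0.5 * total) return(s)
  }
  length(gdd)
}

# Literal loop-based feature computations.
oracle_count_above <- function(x, thr) {
  n <- 0
  for (v in x) if (v > thr) n <- n + 1
  n
}
oracle_count_below <- function(x, thr) {
  n <- 0
  for (v in x) if (v < thr) n <- n + 1
  n
}
oracle_dry_spells <- function(precip, min_len, wet_threshold = 0.1) {
  spells <- 0
  run <- 0
  for (v in c(precip, Inf)) { # sentinel wet day flushes the last run
    if (v <= wet_threshold) run <- run + 1
    else {
      if (run > min_len) spells <- spells + 1
      run <- 0
    }
  }
  spells
}
oracle_percentile <- function(x, q) {
  x <- sort(x)
  h <- (length(x) - 1) * q / 100 + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
}

# Greedy collinearity pruning with the same deterministic ordering rules,
# recomputed from scratch each round.
oracle_collinearity <- function(X, y, r_threshold = 0.7) {
  keep <- colnames(X)
  repeat {
    if (length(keep) < 2L) break
    C <- abs(stats::cor(X[, keep, drop = FALSE]))
    diag(C) <- 0
    if (max(C) <= r_threshold) break
    best <- NULL
    for (a in keep) for (b in keep) {
      if (a < b && C[a, b] >= max(C) - 1e-12) {
        if (is.null(best) || a < best[1] || (a == best[1] && b < best[2])) {
          best <- c(a, b)
        }
      }
    }
    ra <- abs(stats::cor(X[, best[1]], y))
    rb <- abs(stats::cor(X[, best[2]], y))
    drop <- if (ra > rb) best[2] else if (rb > ra) best[1] else max(best)
    keep <- setdiff(keep, drop)
  }
  keep
}

# Sample lag-1 autocorrelation.
lag1_autocor <- function(x) {
  stats::cor(x[-length(x)], x[-1])
}
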