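#' @keywords internal
"_PACKAGE"

#' @importFrom stats median quantile cor sd lm lm.fit coef predict rnorm
#'   rbinom rgamma var setNames
#' @importFrom utils write.csv read.csv head
NULL

# Days per (leap-free) year used throughout the synthetic calendar.
DAYS_PER_YEAR <- 365L

# Month lengths of a 365-day year; used to place monthly SST values on the
# continuous day axis.
MONTH_LENGTHS <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
MONTH_STARTS <- c(0L, cumsum(MONTH_LENGTHS)[-12]) + 1L
MONTH_MIDPOINTS <- MONTH_STARTS + MONTH_LENGTHS / 2 - 0.5

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Median of integer days with a deterministic even-count rule
#'
#' For an even number of values the lower of the two central values is taken,
#' so the result is always one of the observed (integer) days.
#'
#' @param x numeric vector of day indices.
#' @return a single day value.
#' @keywords internal
med_day <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n == 0L) stop("med_day: empty input")
  if (n %% 2L == 1L) x[(n + 1L) %/% 2L] else x[n %/% 2L]
}

#' Derive a reproducible sub-seed from a master seed and labels
#'
#' Stable string hashing so each (region, variable) pair gets its own RNG
#' stream: adding regions or variables never perturbs existing streams.
#'
#' @param seed master integer seed.
#' @param ... labels (coerced to character) identifying the stream.
#' @return an integer in `[1, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (tok in as.character(unlist(list(...)))) {
    for (code in utf8ToInt(tok)) {
      h <- (h * 31 + code) %% m
    }
  }
  as.integer(h %% (m - 2)) + 1L
}

# Evaluate `expr` under a private RNG state seeded with `seed`; the caller's
# global RNG state is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Wrap a 1-based day-of-year onto 1..365.
wrap_doy <- function(doy) ((as.integer(doy) - 1L) %% DAYS_PER_YEAR) + 1L

# Continuous day index (1 = Jan 1 of base_year) for a calendar year + doy.
day_index <- function(year, doy, base_year) {
  (as.integer(year) - as.integer(base_year)) * DAYS_PER_YEAR + as.integer(doy)
}
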