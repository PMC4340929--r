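`%||%` <- function(a, b) if (is.null(a)) b else a

## standard error of the mean
.se <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

.is_binary <- function(m) all(m %in% c(0, 1))

.assert_binary <- function(m, what = "matrix") {
  if (!is.matrix(m) || !is.numeric(m))
    stop(what, " must be a numeric matrix", call. = FALSE)
  if (anyNA(m) || !.is_binary(m))
    stop(what, " must be binary (entries 0/1, no NA)", call. = FALSE)
  invisible(m)
}

## Nearest-rank empirical quantile: the ceiling(p * n)-th order statistic,
## so with n = 100 the 2.5% / 97.5% bounds are the 3rd and 98th values.
.nearest_rank <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  idx <- pmin(pmax(ceiling(p * n), 1L), n)
  x[idx]
}

## Envelope of a permutation-by-statistic matrix, column-wise.
## Returns nearest-rank quantile band and the min-max band.
.envelope <- function(mat, probs = c(0.025, 0.975)) {
  lo <- apply(mat, 2, function(v) .nearest_rank(v[!is.na(v)], probs[1]))
  hi <- apply(mat, 2, function(v) .nearest_rank(v[!is.na(v)], probs[2]))
  mn <- apply(mat, 2, min, na.rm = TRUE)
  mx <- apply(mat, 2, max, na.rm = TRUE)
  list(lo = lo, hi = hi, min = mn, max = mx)
}

## Two-sided empirical rank p-value of an observed value among n null values:
## p = 2 * min(#null <= obs, #null >= obs, each + 1) / (n + 1), capped at 1.
.rank_p <- function(observed, null_values) {
  null_values <- null_values[!is.na(null_values)]
  n <- length(null_values)
  lo <- sum(null_values <= observed) + 1L
  hi <- sum(null_values >= observed) + 1L
  min(1, 2 * min(lo, hi) / (n + 1))
}

## Sample n values from a log-series distribution (parameter 0 < x < 1)
## truncated to 1..kmax, by inversion on the renormalised pmf.
.rlogseries <- function(n, x, kmax) {
  stopifnot(x > 0, x < 1, kmax >= 1)
  k <- seq_len(kmax)
  pmf <- x^k / k
  sample.int(kmax, n, replace = TRUE, prob = pmf)
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)
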