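# Shared fixtures, all built in code.

# three collinear points: exact fit y = 1 + 2x
line_fixture <- function() {
  x <- c(0, 1, 2)
  list(X = cbind(1, x), y = 1 + 2 * x)
}

# a reproducible random regression sample with homoskedastic normal errors
random_fixture <- function(n, p_pred = 1, beta = c(0.5, 1), sigma = 1,
                           seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p_pred), n, p_pred)
  X <- cbind(1, x)
  list(X = X, y = drop(X %*% beta[seq_len(p_pred + 1)]) + sigma * rnorm(n))
}

# closed-form type-6 quantile (weighted average at (B+1)q) for a sorted
# sample; independent oracle for the percentile dialect
quantile6_oracle <- function(x, q) {
  x <- sort(x)
  n <- length(x)
  h <- (n + 1) * q
  lo <- pmax(1, pmin(n, floor(h)))
  hi <- pmax(1, pmin(n, lo + 1))
  frac <- pmax(0, pmin(1, h - lo))
  x[lo] + frac * (x[hi] - x[lo])
}

# run a quick scenario and return the summary
quick_summary <- function(scn, methods) {
  run_scenario(scn, methods)$summary
}
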