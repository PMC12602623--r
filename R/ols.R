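#' Ordinary least squares fit with leverages
#'
#' Fits \eqn{\hat\beta = (X^T X)^{-1} X^T y} through a QR decomposition (the
#' normal-equations inverse \eqn{(X^T X)^{-1}} is still materialized from the
#' R factor because the classical and sandwich covariance estimators need it
#' explicitly). Leverages are the diagonal of the hat matrix
#' \eqn{X (X^T X)^{-1} X^T}.
#'
#' @param X Design matrix, `n x p`, including the intercept column.
#' @param y Outcome vector of length `n`.
#' @return An object of class `ols_fit`: list with `beta_hat`, `residuals`,
#'   `fitted`, `leverage`, `rss`, `sigma2_hat` (= RSS / (n - p)), `xtx_inv`,
#'   `X`, `y`, `n`, `p`.
#' @export
fit_ols <- function(X, y) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, n > p)
  qr_x <- qr(X)
  if (qr_x$rank < p) {
    stop("singular design: X'X is not invertible (rank ", qr_x$rank,
         " < ", p, ")", call. = FALSE)
  }
  beta_hat <- qr.coef(qr_x, y)
  fitted <- drop(X %*% beta_hat)
  residuals <- y - fitted
  xtx_inv <- chol2inv(qr.R(qr_x))
  leverage <- rowSums((X %*% xtx_inv) * X)
  rss <- sum(residuals^2)
  structure(list(beta_hat = beta_hat, residuals = residuals, fitted = fitted,
                 leverage = leverage, rss = rss,
                 sigma2_hat = rss / (n - p), xtx_inv = xtx_inv,
                 X = X, y = y, n = n, p = p),
            class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat("OLS fit:", x$n, "cases,", x$p, "coefficients\n")
  print(x$beta_hat)
  invisible(x)
}

inference_result <- function(method, coef_index, estimate, beta_true,
                             se = NA_real_, t_stat = NA_real_,
                             p_value = NA_real_, ci_low = NA_real_,
                             ci_high = NA_real_, alpha = 0.05,
                             flagged = FALSE) {
  reject <- if (!is.na(p_value)) {
    p_value < alpha
  } else {
    !(ci_low <= 0 && 0 <= ci_high)
  }
  covers <- if (!is.na(ci_low)) {
    ci_low <= beta_true && beta_true <= ci_high
  } else {
    NA
  }
  data.frame(method = method, coef_index = coef_index, estimate = estimate,
             se = se, t_stat = t_stat, p_value = p_value,
             ci_low = ci_low, ci_high = ci_high,
             reject = reject, covers = covers, flagged = flagged,
             stringsAsFactors = FALSE)
}

#' Classical t-based inference for one OLS coefficient
#'
#' The textbook test: \eqn{SE_k = \sqrt{\hat\sigma^2 [(X^T X)^{-1}]_{kk}}},
#' \eqn{t = \hat\beta_k / SE_k}, with two-sided p-value and confidence
#' interval from the t-distribution on \eqn{n - p} degrees of freedom.
#'
#' @param fit An `ols_fit`.
#' @param k Coefficient index of interest (1 = first predictor's slope, i.e.
#'   the second column of `X`). Default 1.
#' @param alpha Two-sided significance level. Default 0.05.
#' @param beta_true True coefficient value, used to set the `covers` flag.
#' @return A one-row data frame (an inference-result record) with columns
#'   `method`, `coef_index`, `estimate`, `se`, `t_stat`, `p_value`, `ci_low`,
#'   `ci_high`, `reject`, `covers`, `flagged`.
#' @export
classical_inference <- function(fit, k = 1L, alpha = 0.05, beta_true = 0) {
  stopifnot(inherits(fit, "ols_fit"))
  idx <- k + 1L  # column k+1 holds the k-th predictor (column 1 = intercept)
  if (fit$rss <= .Machine$double.eps * sum(fit$y^2)) {
    stop("degenerate fit: zero residual variance", call. = FALSE)
  }
  se <- sqrt(fit$sigma2_hat * fit$xtx_inv[idx, idx])
  df <- fit$n - fit$p
  est <- fit$beta_hat[[idx]]
  t_stat <- est / se
  p <- 2 * stats::pt(-abs(t_stat), df)
  half <- stats::qt(1 - alpha / 2, df) * se
  inference_result("classical", k, est, beta_true, se = se, t_stat = t_stat,
                   p_value = p, ci_low = est - half, ci_high = est + half,
                   alpha = alpha)
}
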