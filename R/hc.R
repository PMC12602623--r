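#' Heteroskedasticity-consistent sandwich covariance (HC3 / HC4)
#'
#' Computes \eqn{(X^T X)^{-1} X^T \mathrm{diag}(w_i) X (X^T X)^{-1}} with
#' weights \eqn{w_i = r_i^2 / (1 - h_{ii})^2} for HC3 and
#' \eqn{w_i = r_i^2 / (1 - h_{ii})^{\delta_i}},
#' \eqn{\delta_i = \min\{4, n h_{ii} / p\}}, for HC4. HC4 inflates the
#' deleted-residual weighting adaptively where leverage is high; when all
#' \eqn{\delta_i = 2} the two estimators coincide.
#'
#' Leverages numerically equal to 1 make the weight undefined; such fits are
#' rejected (threshold `1 - 1e-12`).
#'
#' @param fit An `ols_fit`.
#' @param estimator `"HC3"` or `"HC4"`.
#' @return An object of class `sandwich_cov`: list with `estimator`, `cov`
#'   (p x p), and `delta` (the per-case exponents; all 2 for HC3).
#' @export
hc_covariance <- function(fit, estimator = c("HC3", "HC4")) {
  stopifnot(inherits(fit, "ols_fit"))
  estimator <- match.arg(estimator)
  h <- fit$leverage
  if (any(h > 1 - 1e-12)) {
    stop("leverage numerically equal to 1: HC weight undefined", call. = FALSE)
  }
  delta <- if (estimator == "HC3") {
    rep(2, fit$n)
  } else {
    pmin(4, fit$n * h / fit$p)
  }
  w <- fit$residuals^2 / (1 - h)^delta
  meat <- crossprod(fit$X * w, fit$X)
  cov <- fit$xtx_inv %*% meat %*% fit$xtx_inv
  structure(list(estimator = estimator, cov = cov, delta = delta),
            class = "sandwich_cov")
}

#' t-based inference from a sandwich covariance
#'
#' Uses \eqn{SE_k = \sqrt{[\widehat{Cov}]_{kk}}} and refers
#' \eqn{t = \hat\beta_k / SE_k} to the t-distribution with \eqn{n - p}
#' degrees of freedom (the reference distribution the test statistics are
#' compared against throughout; see the methods vignette).
#'
#' @param fit An `ols_fit`.
#' @param cov A `sandwich_cov` from [hc_covariance()].
#' @param k Coefficient index of interest (1 = first predictor's slope).
#' @param alpha Two-sided significance level.
#' @param beta_true True coefficient value for the `covers` flag.
#' @return A one-row inference-result data frame (see
#'   [classical_inference()]).
#' @export
hc_inference <- function(fit, cov, k = 1L, alpha = 0.05, beta_true = 0) {
  stopifnot(inherits(fit, "ols_fit"), inherits(cov, "sandwich_cov"))
  idx <- k + 1L
  v <- cov$cov[idx, idx]
  if (!is.finite(v) || v <= 0) {
    stop("non-positive sandwich variance for coefficient ", k, call. = FALSE)
  }
  se <- sqrt(v)
  df <- fit$n - fit$p
  est <- fit$beta_hat[[idx]]
  t_stat <- est / se
  p <- 2 * stats::pt(-abs(t_stat), df)
  half <- stats::qt(1 - alpha / 2, df) * se
  inference_result(cov$estimator, k, est, beta_true, se = se,
                   t_stat = t_stat, p_value = p,
                   ci_low = est - half, ci_high = est + half, alpha = alpha)
}
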