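#' Bootstrap distribution container
#'
#' Holds the `B` bootstrap coefficient estimates for one coefficient of
#' interest together with the original-sample estimate and classical test
#' statistic. Construct via [pairs_resample()] / [wild_resample()], or
#' directly for hand-built fixtures.
#'
#' @param scheme `"pairs"` or `"wild"`.
#' @param beta_star Numeric vector of length `B`: bootstrap estimates
#'   \eqn{\hat\beta^*_{bk}}.
#' @param estimate Original-sample \eqn{\hat\beta_k}.
#' @param t_stat Original-sample classical t statistic for coefficient `k`.
#' @param k Coefficient index the distribution refers to.
#' @param redraws Count of resamples that had to be redrawn (pairs scheme).
#' @param t_star_sq Optional vector of pre-computed squared studentized
#'   bootstrap statistics (p-value mode); when absent they are derived from
#'   `beta_star` by [bootstrap_p_value()].
#' @return An object of class `bootstrap_dist`.
#' @export
new_bootstrap_distribution <- function(scheme, beta_star, estimate, t_stat,
                                       k = 1L, redraws = 0L,
                                       t_star_sq = NULL) {
  structure(list(scheme = scheme, B = length(beta_star),
                 beta_star = as.numeric(beta_star),
                 estimate = estimate, t_stat = t_stat, k = k,
                 redraws = redraws, t_star_sq = t_star_sq),
            class = "bootstrap_dist")
}

#' @export
print.bootstrap_dist <- function(x, ...) {
  cat(sprintf("%s bootstrap distribution: B = %d, original estimate %.4f\n",
              x$scheme, x$B, x$estimate))
  invisible(x)
}

#' Pairs (case-resampling) bootstrap of an OLS coefficient
#'
#' Draws `B` resamples of the `n` cases with replacement and refits OLS on
#' each. Resampling is realized through multinomial case weights
#' (`rmultinom(B, n, 1/n)`) entering the normal equations as
#' \eqn{\hat\beta^* = (X^T W X)^{-1} X^T W y} with \eqn{W} the diagonal
#' matrix of resample counts - distributionally identical to refitting on the
#' index-resampled rows, and vectorizable: all cross-products are accumulated
#' with a single matrix multiplication. Singular resamples (possible at small
#' `n`) are redrawn, up to `redraw_cap` times each.
#'
#' @param X Design matrix including the intercept column.
#' @param y Outcome vector.
#' @param B Number of bootstrap draws.
#' @param k Coefficient index of interest (1 = first predictor's slope).
#' @param redraw_cap Maximum redraws per singular resample.
#' @return A `bootstrap_dist` (scheme `"pairs"`).
#' @export
pairs_resample <- function(X, y, B, k = 1L, redraw_cap = 100L) {
  fit <- fit_ols(X, y)
  n <- fit$n; p <- fit$p
  idx <- k + 1L
  Z <- cbind(fit$X, fit$y)
  q <- p + 1L
  ut <- which(upper.tri(diag(q), diag = TRUE))
  rows <- ((ut - 1L) %% q) + 1L
  cols <- ((ut - 1L) %/% q) + 1L
  P <- Z[, rows, drop = FALSE] * Z[, cols, drop = FALSE]  # n x q(q+1)/2
  counts <- stats::rmultinom(B, n, rep.int(1 / n, n))
  S <- crossprod(P, counts)                               # sums per resample
  beta_star <- numeric(B)
  redraws <- 0L
  M <- matrix(0, q, q)
  for (b in seq_len(B)) {
    s <- S[, b]
    tries <- 0L
    repeat {
      M[ut] <- s
      M[lower.tri(M)] <- t(M)[lower.tri(M)]
      bs <- tryCatch(
        solve(M[1:p, 1:p, drop = FALSE], M[1:p, q])[idx],
        error = function(e) NULL)
      if (!is.null(bs) && is.finite(bs)) break
      tries <- tries + 1L
      redraws <- redraws + 1L
      if (tries > redraw_cap) {
        stop("pairs bootstrap: singular resamples persisted beyond ",
             redraw_cap, " redraws", call. = FALSE)
      }
      s <- drop(crossprod(P, stats::rmultinom(1, n, rep.int(1 / n, n))))
    }
    beta_star[b] <- bs
  }
  t_orig <- fit$beta_hat[[idx]] /
    sqrt(fit$sigma2_hat * fit$xtx_inv[idx, idx])
  new_bootstrap_distribution("pairs", beta_star, fit$beta_hat[[idx]],
                             t_orig, k, redraws)
}

#' Wild bootstrap of an OLS coefficient (Rademacher weights)
#'
#' Keeps the design matrix fixed and regenerates outcomes as
#' \deqn{y_i^* = X_i \hat\beta + \frac{r_i}{1 - h_{ii}} v_i^*,}
#' with \eqn{v_i^*} drawn independently from the Rademacher distribution
#' (+1 or -1 with probability 0.5 each, refreshed per case and per draw).
#' The residual transform \eqn{r_i/(1-h_{ii})} is the deleted-residual
#' (HC3-style) weighting. Each draw's coefficients are
#' \eqn{(X^T X)^{-1} X^T y^*} with the *original* `X`; all `B` draws are
#' computed in one matrix product.
#'
#' @param fit An `ols_fit`.
#' @param B Number of bootstrap draws.
#' @param k Coefficient index of interest.
#' @param v Optional `n x B` matrix of +1/-1 weights to inject (tests).
#' @return A `bootstrap_dist` (scheme `"wild"`).
#' @export
wild_resample <- function(fit, B, k = 1L, v = NULL) {
  stopifnot(inherits(fit, "ols_fit"))
  if (any(fit$leverage > 1 - 1e-12)) {
    stop("leverage numerically equal to 1: wild transform undefined",
         call. = FALSE)
  }
  n <- fit$n
  idx <- k + 1L
  if (is.null(v)) {
    v <- matrix(sample(c(-1, 1), n * B, replace = TRUE), n, B)
  }
  stopifnot(nrow(v) == n, ncol(v) == B)
  rt <- fit$residuals / (1 - fit$leverage)
  y_star <- fit$fitted + rt * v            # column-wise recycling over draws
  beta_star <- drop(
    (fit$xtx_inv %*% crossprod(fit$X, y_star))[idx, ])
  t_orig <- fit$beta_hat[[idx]] /
    sqrt(fit$sigma2_hat * fit$xtx_inv[idx, idx])
  new_bootstrap_distribution("wild", beta_star, fit$beta_hat[[idx]],
                             t_orig, k)
}

#' Bootstrap p-value from squared studentized bootstrap statistics
#'
#' Computes \eqn{t^*_b = (\hat\beta^*_{bk} - \hat\beta_k) / SE^*_k} where
#' \eqn{SE^*_k} is the sample standard deviation of the `B` bootstrap
#' coefficients (one common denominator for all draws), then
#' \deqn{p = \frac{\#\{t^{*2}_b \ge t_k^2\} + 1}{B + 1},}
#' comparing against the original sample's squared classical t statistic.
#' The "+1" convention bounds the p-value in \eqn{[1/(B+1), 1]}.
#'
#' @param dist A `bootstrap_dist`.
#' @return The bootstrap p-value.
#' @export
bootstrap_p_value <- function(dist) {
  stopifnot(inherits(dist, "bootstrap_dist"))
  t_star_sq <- dist$t_star_sq
  if (is.null(t_star_sq)) {
    se_star <- stats::sd(dist$beta_star)
    # numerically-zero spread (e.g. a perfect original fit) cannot be
    # studentized; compare against the coefficient scale
    if (se_star <= 1e-12 * (abs(dist$estimate) + 1)) {
      stop("degenerate bootstrap distribution: all coefficients identical",
           call. = FALSE)
    }
    t_star_sq <- ((dist$beta_star - dist$estimate) / se_star)^2
  }
  (sum(t_star_sq >= dist$t_stat^2) + 1) / (length(t_star_sq) + 1)
}

#' Percentile bootstrap confidence interval
#'
#' Reads the interval bounds directly from the empirical quantiles of the
#' bootstrap coefficient distribution. The quantile dialect defaults to the
#' "weighted average at \eqn{(B+1)q}" plotting position
#' (`stats::quantile` type 6, the rule used by SPSS's EXAMINE procedure);
#' the dialect shifts bounds by O(1/B) and is swappable via `type`.
#'
#' @param dist A `bootstrap_dist`.
#' @param level Confidence level. Default 0.95.
#' @param type Quantile type passed to [stats::quantile()]. Default 6.
#' @return Numeric vector `c(low, high)`.
#' @export
percentile_ci <- function(dist, level = 0.95, type = 6) {
  stopifnot(inherits(dist, "bootstrap_dist"))
  a <- (1 - level) / 2
  stats::quantile(dist$beta_star, c(a, 1 - a), type = type, names = FALSE)
}

#' Bias-corrected and accelerated (BCa) bootstrap confidence interval
#'
#' Standard Efron BCa: the bias-correction term is
#' \eqn{z_0 = \Phi^{-1}(\#\{\hat\beta^*_b < \hat\beta_k\}/B)} and the
#' acceleration is estimated from jackknife leave-one-out coefficients
#' \eqn{\hat\beta_{k(-i)}} via the skewness formula
#' \deqn{a = \frac{\sum_i (\bar\theta - \theta_i)^3}
#'                {6 [\sum_i (\bar\theta - \theta_i)^2]^{3/2}}.}
#' The nominal levels are then mapped through
#' \eqn{\tilde\alpha = \Phi(z_0 + (z_0 + z_\alpha)/(1 - a (z_0 + z_\alpha)))}
#' and the bounds read from the bootstrap distribution at those adjusted
#' levels (same quantile dialect as [percentile_ci()]).
#'
#' Leave-one-out OLS coefficients use the exact downdating identity
#' \eqn{\hat\beta_{(-i)} = \hat\beta - (X^TX)^{-1} x_i r_i/(1-h_{ii})}, so
#' the jackknife costs O(np) rather than n refits.
#'
#' Degeneracies: if all bootstrap coefficients fall on one side of the
#' estimate, the count is clamped half a step from the edge and the interval
#' is flagged (`attr(., "z0_clamped")`); a zero jackknife variance makes the
#' acceleration undefined, in which case the percentile interval is returned
#' with a warning and `attr(., "fallback") = "percentile"`.
#'
#' @param dist A `bootstrap_dist`.
#' @param X,y The original design matrix and outcome (for the jackknife).
#' @param level Confidence level. Default 0.95.
#' @param type Quantile type passed to [stats::quantile()]. Default 6.
#' @return Numeric vector `c(low, high)`, possibly carrying the attributes
#'   described above.
#' @export
bca_ci <- function(dist, X, y, level = 0.95, type = 6) {
  stopifnot(inherits(dist, "bootstrap_dist"))
  fit <- fit_ols(X, y)
  idx <- dist$k + 1L
  B <- dist$B
  n_below <- sum(dist$beta_star < dist$estimate)
  clamped <- FALSE
  if (n_below == 0L || n_below == B) {
    n_below <- if (n_below == 0L) 0.5 else B - 0.5
    clamped <- TRUE
  }
  z0 <- stats::qnorm(n_below / B)
  # jackknife leave-one-out slopes by exact downdating
  infl <- drop((fit$X %*% fit$xtx_inv)[, idx]) *
    fit$residuals / (1 - fit$leverage)
  theta <- fit$beta_hat[[idx]] - infl
  dev <- mean(theta) - theta
  denom <- sum(dev^2)
  if (denom == 0) {
    warning("degenerate jackknife variance; falling back to the percentile ",
            "interval")
    out <- percentile_ci(dist, level, type)
    attr(out, "fallback") <- "percentile"
    return(out)
  }
  a <- sum(dev^3) / (6 * denom^1.5)
  alpha <- (1 - level) / 2
  z_alpha <- stats::qnorm(c(alpha, 1 - alpha))
  adj <- stats::pnorm(z0 + (z0 + z_alpha) / (1 - a * (z0 + z_alpha)))
  out <- stats::quantile(dist$beta_star, adj, type = type, names = FALSE)
  if (clamped) attr(out, "z0_clamped") <- TRUE
  out
}
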