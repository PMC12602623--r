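#' Error-distribution specification
#'
#' The three error shapes used in the factorial design, each with target
#' population skewness/excess kurtosis for the Fleishman transform and the
#' closed acceptance bounds applied to the *empirical* moments of each drawn
#' error vector under constrained sampling:
#'
#' * `normal`: skew 0, excess kurtosis 0, both bounds \[-1, 1\]
#' * `moderate`: skew 2, excess kurtosis 7, bounds \[1, 3\] and \[6, 8\]
#' * `severe`: skew 3, excess kurtosis 21, bounds \[2, 4\] and \[19, 23\]
#'
#' @param label One of `"normal"`, `"moderate"`, `"severe"`.
#' @return An object of class `distribution_spec` with fields `label`,
#'   `target_skew`, `target_kurtosis`, `skew_bounds`, `kurtosis_bounds` and
#'   the solved Fleishman `coef`.
#' @export
distribution_spec <- function(label = c("normal", "moderate", "severe")) {
  label <- match.arg(label)
  par <- switch(label,
    normal   = list(skew = 0, kurt = 0,  sb = c(-1, 1), kb = c(-1, 1)),
    moderate = list(skew = 2, kurt = 7,  sb = c(1, 3),  kb = c(6, 8)),
    severe   = list(skew = 3, kurt = 21, sb = c(2, 4),  kb = c(19, 23)))
  structure(list(label = label,
                 target_skew = par$skew,
                 target_kurtosis = par$kurt,
                 skew_bounds = par$sb,
                 kurtosis_bounds = par$kb,
                 coef = fleishman_coefficients(par$skew, par$kurt)),
            class = "distribution_spec")
}

#' Define one cell of the simulation grid
#'
#' A scenario fixes the data-generating model, sample size, error
#' distribution, heteroskedasticity exponent and simulation budgets. The four
#' models are
#' \deqn{y_i = 0\cdot x_{i1} + \varepsilon_i \quad (1)}
#' \deqn{y_i = 0.8\, x_{i1} + \varepsilon_i \quad (2)}
#' \deqn{y_i = 0\cdot x_{i1} + 0.3\, x_{i2} + \varepsilon_i \quad (3)}
#' \deqn{y_i = 0.8\, x_{i1} + 0.3\, x_{i2} + \varepsilon_i \quad (4)}
#' with \eqn{\varepsilon_i = u_i \sigma_i} and \eqn{\sigma_i^2 =
#' \exp(g\, x_{ih})}, where the heteroskedasticity source \eqn{h} is predictor
#' 1 for models 1-2 and predictor 2 for models 3-4. Predictors are standard
#' normal; in the two-predictor models they have population correlation `r`.
#'
#' The severely non-normal error shape cannot be paired with `n = 25`:
#' constrained draws matching its empirical-moment bounds are practically
#' unobtainable at that size, so the combination is rejected.
#'
#' @param model_id Integer 1-4.
#' @param n Sample size (25, 50, 100, 200 or 500 in the default grid; any
#'   `n > 3` is accepted).
#' @param dist A `distribution_spec` or a label accepted by
#'   [distribution_spec()].
#' @param g Heteroskedasticity exponent, one of 0, 0.5, 1, 2 in the default
#'   grid (any non-negative value is accepted).
#' @param n_reps Monte-Carlo replications.
#' @param B Bootstrap draws per replication.
#' @param seed Scenario root seed.
#' @param constrained_sampling Apply empirical-moment acceptance bounds when
#'   drawing the standardized errors (`TRUE`, the study condition) or accept
#'   the first draw (`FALSE`, robustness-check mode).
#' @param r Population correlation between the two predictors (two-predictor
#'   models only). Default 0.10.
#' @param max_attempts Cap on constrained-resampling rounds per replication.
#' @return An object of class `scenario`.
#' @export
scenario <- function(model_id, n, dist, g, n_reps = 10000L, B = 1000L,
                     seed = 1L, constrained_sampling = TRUE, r = 0.10,
                     max_attempts = 10000L) {
  stopifnot(model_id %in% 1:4, n > 3, g >= 0, abs(r) < 1)
  if (is.character(dist)) dist <- distribution_spec(dist)
  stopifnot(inherits(dist, "distribution_spec"))
  if (n == 25 && dist$label == "severe") {
    stop("n = 25 cannot be paired with the severely non-normal distribution",
         call. = FALSE)
  }
  beta <- switch(model_id,
                 c(0, 0), c(0, 0.8), c(0, 0, 0.3), c(0, 0.8, 0.3))
  het_source <- if (model_id <= 2) 1L else 2L
  structure(list(model_id = as.integer(model_id), n = as.integer(n),
                 dist = dist, g = g, beta = beta, het_source = het_source,
                 n_reps = as.integer(n_reps), B = as.integer(B),
                 seed = as.integer(seed),
                 constrained_sampling = isTRUE(constrained_sampling),
                 r = r, max_attempts = as.integer(max_attempts)),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf(
    "Scenario: model %d, n = %d, errors %s, g = %g, reps = %d, B = %d\n",
    x$model_id, x$n, x$dist$label, x$g, x$n_reps, x$B))
  invisible(x)
}

#' Draw predictor columns
#'
#' Columns are standard normal; for `K = 2` the pair is multivariate normal
#' with population correlation `r` (via the Cholesky factor of the 2x2
#' correlation matrix). The correlation holds in the population, not exactly
#' in each sample.
#'
#' @param n Number of cases.
#' @param K Number of predictors, 1 or 2.
#' @param r Pairwise population correlation (used only when `K = 2`).
#' @return An `n x K` numeric matrix.
#' @export
generate_predictors <- function(n, K, r = 0.10) {
  stopifnot(K %in% c(1L, 2L), abs(r) < 1)
  if (K == 1L) return(matrix(stats::rnorm(n), n, 1))
  z <- matrix(stats::rnorm(2 * n), n, 2)
  cbind(z[, 1], r * z[, 1] + sqrt(1 - r^2) * z[, 2])
}

#' Draw a standardized error vector under constrained resampling
#'
#' Draws `n` standard normals, applies the distribution's Fleishman
#' transform, and (when `constrained`) repeats until the empirical skewness
#' and excess kurtosis of the vector both lie inside the distribution's
#' closed acceptance bounds. The moment estimators of [sample_skewness()] and
#' [sample_kurtosis()] are used. Unconstrained mode returns the first draw.
#'
#' @param n Number of cases (>= 3).
#' @param dist A `distribution_spec`.
#' @param constrained Apply the acceptance bounds? Default `TRUE`.
#' @param max_attempts Error out after this many rejected draws; guards
#'   against practically infeasible cells such as `n = 25` with the severe
#'   shape.
#' @return Numeric vector of length `n` with attributes `attempts` (rounds
#'   used), `skewness` and `kurtosis` (empirical moments of the returned
#'   draw).
#' @export
draw_constrained_u <- function(n, dist, constrained = TRUE,
                               max_attempts = 10000L) {
  stopifnot(n >= 3, inherits(dist, "distribution_spec"))
  sb <- dist$skew_bounds; kb <- dist$kurtosis_bounds
  for (attempt in seq_len(max_attempts)) {
    u <- fleishman_transform(stats::rnorm(n), dist$coef)
    sk <- sample_skewness(u); ku <- sample_kurtosis(u)
    if (!constrained ||
        (sk >= sb[1] && sk <= sb[2] && ku >= kb[1] && ku <= kb[2])) {
      attr(u, "attempts") <- attempt
      attr(u, "skewness") <- sk
      attr(u, "kurtosis") <- ku
      return(u)
    }
  }
  stop(sprintf(paste0(
    "constrained error sampling exceeded %d attempts for n = %d, '%s' ",
    "(skew bounds [%g, %g], kurtosis bounds [%g, %g])"),
    max_attempts, n, dist$label, sb[1], sb[2], kb[1], kb[2]), call. = FALSE)
}

#' Generate one simulated sample for a scenario
#'
#' Builds the design matrix (intercept column plus freshly drawn predictors),
#' the standardized errors `u`, the per-case error scale
#' \eqn{\sigma_i = \exp(g\, x_{ih} / 2)} (so that \eqn{\sigma_i^2 =
#' \exp(g\, x_{ih})}) and the outcome \eqn{y = X\beta + u \sigma}.
#'
#' `u` and `x` can be injected for exact, hand-checkable construction in
#' tests; by default both are drawn from the scenario's generative model.
#'
#' @param scn A `scenario`.
#' @param u Optional standardized error vector to inject (length `n`).
#' @param x Optional predictor matrix to inject (`n x K`).
#' @return An object of class `simulated_sample`: list with `X` (including
#'   the intercept column), `y`, `u`, `sigma`, `beta`, `empirical_skew`,
#'   `empirical_kurtosis` and `attempts`.
#' @export
generate_sample <- function(scn, u = NULL, x = NULL) {
  stopifnot(inherits(scn, "scenario"))
  K <- length(scn$beta) - 1L
  if (is.null(x)) x <- generate_predictors(scn$n, K, scn$r)
  x <- as.matrix(x)
  stopifnot(nrow(x) == scn$n, ncol(x) == K)
  if (is.null(u)) {
    u <- draw_constrained_u(scn$n, scn$dist, scn$constrained_sampling,
                            scn$max_attempts)
  }
  sigma <- exp(scn$g * x[, scn$het_source] / 2)
  X <- cbind(1, x)
  colnames(X) <- c("(intercept)", paste0("x", seq_len(K)))
  y <- drop(X %*% scn$beta) + as.numeric(u) * sigma
  structure(list(X = X, y = y, u = as.numeric(u), sigma = sigma,
                 beta = scn$beta,
                 empirical_skew = attr(u, "skewness"),
                 empirical_kurtosis = attr(u, "kurtosis"),
                 attempts = attr(u, "attempts")),
            class = "simulated_sample")
}

#' Export a simulated sample as a plain data frame
#'
#' @param sample A `simulated_sample`.
#' @return A data frame with columns `case`, the predictors and `y`,
#'   suitable for `write.csv`.
#' @export
as.data.frame.simulated_sample <- function(x, ...) {
  K <- ncol(x$X) - 1L
  out <- data.frame(case = seq_along(x$y))
  for (k in seq_len(K)) out[[paste0("x", k)]] <- x$X[, k + 1L]
  out$y <- x$y
  out
}
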