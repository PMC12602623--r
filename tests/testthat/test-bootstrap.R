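test_that("resampling a perfect fit returns the original coefficient", {
  set.seed(41)
  x <- seq(-2, 2, length.out = 10)
  X <- cbind(1, x); y <- 1 + 2 * x
  dist <- pairs_resample(X, y, B = 50)
  expect_lt(max(abs(dist$beta_star - 2)), 1e-10)
  fit <- fit_ols(X, y)
  wdist <- wild_resample(fit, B = 50)
  expect_lt(max(abs(wdist$beta_star - 2)), 1e-12)
})

test_that("pairs bootstrap SD tracks the classical SE on clean data", {
  set.seed(42)
  fx <- random_fixture(50, 1, seed = 42)
  dist <- pairs_resample(fx$X, fx$y, B = 1000)
  se_cl <- classical_inference(fit_ols(fx$X, fx$y), 1)$se
  expect_lt(abs(sd(dist$beta_star) / se_cl - 1), 0.15)
})

test_that("bootstrap draws are reproducible under a fixed seed", {
  fx <- random_fixture(20, 1, seed = 43)
  set.seed(7); d1 <- pairs_resample(fx$X, fx$y, B = 100)
  set.seed(7); d2 <- pairs_resample(fx$X, fx$y, B = 100)
  expect_identical(d1$beta_star, d2$beta_star)
  fit <- fit_ols(fx$X, fx$y)
  set.seed(8); w1 <- wild_resample(fit, 100)
  set.seed(8); w2 <- wild_resample(fit, 100)
  expect_identical(w1$beta_star, w2$beta_star)
})

test_that("pairs resampling matches brute-force refits on the same weights", {
  # equivalence of the weighted normal equations to literal row resampling
  set.seed(44)
  fx <- random_fixture(15, 2, beta = c(0, 1, 0.5), seed = 44)
  counts <- drop(rmultinom(1, 15, rep(1 / 15, 15)))
  idx <- rep(seq_len(15), counts)
  brute <- qr.coef(qr(fx$X[idx, ]), fx$y[idx])[2]
  M <- crossprod(fx$X * counts, fx$X)
  weighted <- solve(M, crossprod(fx$X * counts, fx$y))[2]
  expect_lt(abs(brute - weighted), 1e-10)
})

test_that("wild bootstrap rebuilds outcomes exactly per the transform", {
  # one draw with all weights +1, hand-computed on a 3-point fixture
  x <- c(0, 1, 3)
  X <- cbind(1, x); y <- c(0.5, 2.1, 5.9)
  fit <- fit_ols(X, y)
  v <- matrix(1, 3, 1)
  dist <- wild_resample(fit, 1, v = v)
  y_star <- fit$fitted + fit$residuals / (1 - fit$leverage)
  expect_equal(dist$beta_star,
               unname(drop(solve(crossprod(X), crossprod(X, y_star)))[2]))
})

test_that("wild bootstrap coefficients are centered on the estimate", {
  set.seed(45)
  fx <- random_fixture(30, 1, seed = 45)
  fit <- fit_ols(fx$X, fx$y)
  dist <- wild_resample(fit, 1e4)
  se <- sd(dist$beta_star)
  expect_lt(abs(mean(dist$beta_star) - fit$beta_hat[[2]]),
            4 * se / sqrt(1e4))
})

test_that("bootstrap p-values respect the +1 counting convention", {
  mk <- function(t_star_sq, t_stat) {
    new_bootstrap_distribution("pairs", seq_along(t_star_sq), 0, t_stat,
                               t_star_sq = t_star_sq)
  }
  expect_equal(bootstrap_p_value(mk(c(1, 5, 3, 9), 2)), 0.6)  # (2+1)/5
  expect_equal(bootstrap_p_value(mk(rep(5, 10), 1)), 1)       # upper edge
  expect_equal(bootstrap_p_value(mk(rep(0.1, 10), 1)), 1 / 11)  # lower edge
})

test_that("studentization uses one common bootstrap SE", {
  set.seed(46)
  beta_star <- rnorm(200, 1, 0.3)
  dist <- new_bootstrap_distribution("pairs", beta_star, 1.1, 2.5)
  p <- bootstrap_p_value(dist)
  t2 <- ((beta_star - 1.1) / sd(beta_star))^2
  expect_equal(p, (sum(t2 >= 2.5^2) + 1) / 201)
})

test_that("a degenerate bootstrap distribution cannot be studentized", {
  dist <- new_bootstrap_distribution("wild", rep(2, 50), 2, 1.5)
  expect_error(bootstrap_p_value(dist), "degenerate")
})

test_that("percentile bounds follow the declared quantile dialect", {
  set.seed(47)
  dist <- new_bootstrap_distribution("pairs", sample(1:1000), 500, 1)
  ci <- percentile_ci(dist)
  expect_equal(ci, quantile6_oracle(1:1000, c(0.025, 0.975)))
  expect_equal(ci, c(25.025, 975.975))  # (B+1)q interpolation on 1..1000
  const <- new_bootstrap_distribution("pairs", rep(3.2, 100), 3.2, 1)
  expect_equal(percentile_ci(const), c(3.2, 3.2))
  sym <- new_bootstrap_distribution("pairs", c(-(1:500), 1:500), 0, 1)
  ci <- percentile_ci(sym)
  expect_equal(ci[1], -ci[2])
})

test_that("BCa reduces to percentile when z0 = 0 and a = 0", {
  # antisymmetric fixture: jackknife slope deviations cancel in cubes
  x <- c(-1.5, -0.5, 0.5, 1.5)
  y <- c(-1, -1, 1, 1)
  fit <- fit_ols(cbind(1, x), y)
  infl <- drop((fit$X %*% fit$xtx_inv)[, 2]) * fit$residuals /
    (1 - fit$leverage)
  theta <- fit$beta_hat[[2]] - infl
  expect_lt(abs(sum((mean(theta) - theta)^3)), 1e-12)  # a = 0 by symmetry
  b <- fit$beta_hat[[2]]
  beta_star <- b + c(-(1:100), 1:100) / 100  # symmetric about the estimate
  dist <- new_bootstrap_distribution("pairs", beta_star, b, 1)
  expect_equal(bca_ci(dist, cbind(1, x), y),
               unname(percentile_ci(dist)))
})

test_that("one-sided bootstrap distributions clamp z0 and flag the interval", {
  x <- c(-1.5, -0.5, 0.5, 1.5, 2, -2)
  y <- c(-1, -1, 1, 1, 2.2, -1.7)
  b <- fit_ols(cbind(1, x), y)$beta_hat[[2]]
  dist <- new_bootstrap_distribution("pairs", b + (1:100) / 50, b, 1)
  ci <- bca_ci(dist, cbind(1, x), y)
  expect_true(isTRUE(attr(ci, "z0_clamped")))
})

test_that("BCa matches the reference implementation on shared replicates", {
  skip_if_not_installed("boot")
  set.seed(48)
  fx <- random_fixture(30, 1, beta = c(0.3, 0.9), seed = 48)
  df <- data.frame(x = fx$X[, 2], y = fx$y)
  bt <- boot::boot(df, function(d, i) coef(lm(y ~ x, data = d[i, ]))[2],
                   R = 2000)
  ref <- boot::boot.ci(bt, type = "bca")$bca[4:5]
  fit <- fit_ols(fx$X, fx$y)
  t0 <- fit$beta_hat[[2]] / sqrt(fit$sigma2_hat * fit$xtx_inv[2, 2])
  dist <- new_bootstrap_distribution("pairs", bt$t[, 1], bt$t0, t0)
  ours <- bca_ci(dist, fx$X, fx$y)
  # same replicates, so differences come only from quantile interpolation:
  # agree to the local order-statistic spacing around each bound
  sorted <- sort(bt$t[, 1])
  spacing <- max(diff(sorted[c(20:80, 1920:1980)]))
  expect_lt(abs(ours[1] - ref[1]), 3 * spacing)
  expect_lt(abs(ours[2] - ref[2]), 3 * spacing)
})

test_that("pairs-BCa over-rejects where wild-percentile stays controlled
           under severe violations at large n", {
  s <- quick_summary(scenario(1, 500, "severe", 2, n_reps = 300, B = 1000,
                              seed = 49), c("wild_percentile", "pairs_BCa"))
  bca <- s$rejection_rate[s$method == "pairs_BCa"]
  wp <- s$rejection_rate[s$method == "wild_percentile"]
  expect_gt(bca, 0.075)
  expect_gt(bca, wp)
  expect_lt(wp, 0.075 + 3 * sqrt(0.075 * 0.925 / 300))
})
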