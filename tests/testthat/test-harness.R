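test_that("per-replication reject equals not-covers for null CI methods", {
  scn <- scenario(1, 30, "normal", 1, seed = 51)
  set.seed(51)
  ci_methods <- c("classical", "HC3", "HC4", "pairs_percentile",
                  "pairs_BCa", "wild_percentile", "wild_BCa")
  for (i in 1:15) {
    smp <- generate_sample(scn)
    res <- infer_sample(smp, ci_methods, B = 199)
    expect_identical(res$reject, !res$covers)  # beta_true = 0 here
  }
})

test_that("scenario runs are deterministic given the seed", {
  scn <- scenario(2, 25, "normal", 0.5, n_reps = 40, B = 99, seed = 52)
  r1 <- run_scenario(scn)$summary
  r2 <- run_scenario(scn)$summary
  expect_identical(r1, r2)
})

test_that("classical inference is nominal when assumptions hold", {
  s <- quick_summary(scenario(1, 100, "normal", 0, n_reps = 2000, seed = 53),
                     "classical")
  tol <- 3 * sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(s$rejection_rate - 0.05), tol)
  expect_lt(abs(s$coverage_rate - 0.95), tol)
  expect_lt(abs(s$mean_beta), 4 * s$sd_beta / sqrt(2000))  # unbiasedness
})

test_that("classical SEs underestimate the simulated SE under strong
           heteroskedasticity from the predictor of interest", {
  s <- quick_summary(scenario(2, 50, "normal", 2, n_reps = 1500, seed = 54),
                     c("classical", "HC3", "HC4"))
  cl <- s[s$method == "classical", ]
  expect_lt(cl$mean_se, cl$sd_beta)
  bias <- se_bias_table(s)
  expect_true(all(bias$method %in% c("classical", "HC3", "HC4")))
  expect_equal(bias$bias, bias$mean_se - bias$sd_beta)
})

test_that("all SE ratios are near one when assumptions are met", {
  s <- quick_summary(scenario(2, 500, "normal", 0, n_reps = 1200, seed = 55),
                     c("classical", "HC3", "HC4"))
  bias <- se_bias_table(s)
  expect_true(all(abs(bias$ratio - 1) < 0.05))
})

test_that("the simulated SE grows with the heteroskedasticity level", {
  sds <- vapply(c(0, 0.5, 1, 2), function(g) {
    quick_summary(scenario(1, 50, "normal", g, n_reps = 1200,
                           seed = 56), "classical")$sd_beta
  }, 0)
  expect_true(all(diff(sds) > 0))
})

test_that("the default grid enumerates the full factorial minus the
           infeasible cell", {
  scns <- scenario_grid(default_grid_config())
  expect_length(scns, 224)
  expect_false(any(vapply(scns, function(s) {
    s$n == 25 && s$dist$label == "severe"
  }, TRUE)))
  # restricted grid: a single scenario
  cfg <- default_grid_config()
  cfg$models <- 1L; cfg$ns <- 25L; cfg$distributions <- "normal"
  cfg$g_levels <- 0
  expect_length(scenario_grid(cfg), 1)
})

test_that("grid runs are reproducible and resumable", {
  cfg <- default_grid_config(n_reps = 30L, B = 99L, seed = 57)
  cfg$models <- 1:2; cfg$ns <- 25L; cfg$distributions <- "normal"
  cfg$g_levels <- c(0, 1)
  g1 <- run_grid(cfg, methods = c("classical", "wild_percentile"))
  g2 <- run_grid(cfg, methods = c("classical", "wild_percentile"))
  expect_identical(g1, g2)
  expect_identical(nrow(g1), 4L * 2L)
  dir <- tempfile("grid")
  g3 <- run_grid(cfg, methods = c("classical", "wild_percentile"),
                 out_dir = dir)
  expect_identical(length(list.files(dir, pattern = "csv$")), 4L)
  g4 <- run_grid(cfg, methods = c("classical", "wild_percentile"),
                 out_dir = dir)  # resumed entirely from checkpoints
  expect_equal(g3$rejection_rate, g4$rejection_rate)
})

test_that("yaml configs round-trip and unknown keys are named", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("models: [1, 3]", "ns: [50]", "distributions: [normal]",
               "g_levels: [0, 2]", "n_reps: 10", "seed: 99"), path)
  cfg <- read_grid_config(path)
  expect_identical(cfg$models, c(1L, 3L))
  expect_identical(cfg$B, 1000L)  # default preserved
  expect_length(scenario_grid(cfg), 4)
  writeLines("bogus_key: 1", path)
  expect_error(read_grid_config(path), "bogus_key")
})

test_that("degenerate replications abort the scenario past the threshold", {
  # n barely above p with a tiny bootstrap: singular resamples are common
  scn <- scenario(1, 25, "normal", 0, n_reps = 20, B = 20, seed = 58)
  expect_error(
    {
      # forcing failure: inject an impossible method budget via abort_frac 0
      run_scenario(scn, "classical", abort_frac = -1)
    },
    "aborted")
})
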