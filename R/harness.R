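#' The nine inference methods evaluated by the harness
#'
#' @return Character vector of method labels.
#' @export
hetsim_methods <- function() {
  c("classical", "HC3", "HC4",
    "pairs_p", "pairs_percentile", "pairs_BCa",
    "wild_p", "wild_percentile", "wild_BCa")
}

ci_row <- function(method, est, ci, beta_true, alpha, flagged = FALSE) {
  inference_result(method, 1L, est, beta_true,
                   ci_low = ci[1], ci_high = ci[2], alpha = alpha,
                   flagged = flagged)
}

#' Apply the requested inference methods to one simulated sample
#'
#' Runs OLS once, then each method's inference for the first predictor's
#' slope. Bootstrap engines are shared: one pairs and/or one wild resampling
#' pass feeds all requested p-value / percentile / BCa variants.
#'
#' @param smp A `simulated_sample` (or any list with `X`, `y`, `beta`).
#' @param methods Subset of [hetsim_methods()].
#' @param B Bootstrap draws.
#' @param alpha Significance level.
#' @param percentile_type Quantile dialect for the bootstrap intervals.
#' @return A data frame with one inference-result row per method.
#' @export
infer_sample <- function(smp, methods = hetsim_methods(), B = 1000L,
                         alpha = 0.05, percentile_type = 6) {
  stopifnot(length(methods) > 0, all(methods %in% hetsim_methods()))
  beta_true <- smp$beta[2]
  fit <- fit_ols(smp$X, smp$y)
  rows <- list()
  if ("classical" %in% methods) {
    rows$classical <- classical_inference(fit, 1L, alpha, beta_true)
  }
  for (est in c("HC3", "HC4")) {
    if (est %in% methods) {
      rows[[est]] <- hc_inference(fit, hc_covariance(fit, est), 1L, alpha,
                                  beta_true)
    }
  }
  for (scheme in c("pairs", "wild")) {
    wanted <- intersect(paste0(scheme, c("_p", "_percentile", "_BCa")),
                        methods)
    if (length(wanted) == 0) next
    dist <- if (scheme == "pairs") {
      pairs_resample(smp$X, smp$y, B, k = 1L)
    } else {
      wild_resample(fit, B, k = 1L)
    }
    if (paste0(scheme, "_p") %in% wanted) {
      p <- bootstrap_p_value(dist)
      rows[[paste0(scheme, "_p")]] <-
        inference_result(paste0(scheme, "_p"), 1L, dist$estimate, beta_true,
                         p_value = p, alpha = alpha)
    }
    if (paste0(scheme, "_percentile") %in% wanted) {
      ci <- percentile_ci(dist, 1 - alpha, percentile_type)
      rows[[paste0(scheme, "_percentile")]] <-
        ci_row(paste0(scheme, "_percentile"), dist$estimate, ci, beta_true,
               alpha)
    }
    if (paste0(scheme, "_BCa") %in% wanted) {
      ci <- bca_ci(dist, smp$X, smp$y, 1 - alpha, percentile_type)
      rows[[paste0(scheme, "_BCa")]] <-
        ci_row(paste0(scheme, "_BCa"), dist$estimate, ci, beta_true, alpha,
               flagged = isTRUE(attr(ci, "z0_clamped")) ||
                 identical(attr(ci, "fallback"), "percentile"))
    }
  }
  do.call(rbind, rows[methods[methods %in% names(rows)]])
}

#' Run all replications of one scenario
#'
#' For each replication: generate a sample from the scenario's generative
#' model, fit OLS, and apply every requested inference method to the first
#' predictor's slope. Aggregates rejection rate, coverage rate, the mean and
#' SD of the coefficient estimates (the SD across replications is the
#' "simulated standard error"), the mean estimated SE (classical/HC only)
#' and degenerate-replication flags.
#'
#' Reproducibility: the scenario seed generates one sub-seed per replication
#' (`sample.int(2^31 - 2)`), and each replication reseeds from its sub-seed,
#' so any single replication can be regenerated in isolation and results do
#' not depend on execution order.
#'
#' Degenerate replications (e.g. persistent singular resamples) are flagged
#' and skipped for the affected method, never silently substituted; if more
#' than `abort_frac` of replications flag, the scenario aborts.
#'
#' @param scn A `scenario`.
#' @param methods Subset of [hetsim_methods()].
#' @param keep_t_stats Archive per-replication t statistics
#'   (classical/HC3/HC4 only)?
#' @param percentile_type Quantile dialect for bootstrap intervals.
#' @param alpha Significance level.
#' @param abort_frac Abort threshold for the flagged fraction. Default 0.01.
#' @return An object of class `scenario_result`: list with `summary` (one
#'   row per method: `model_id`, `n`, `dist`, `g`, `method`, `n_reps_done`,
#'   `rejection_rate`, `coverage_rate`, `mean_beta`, `sd_beta`, `mean_se`,
#'   `flagged_reps`) and, if requested, `t_stats`.
#' @export
run_scenario <- function(scn, methods = hetsim_methods(),
                         keep_t_stats = FALSE, percentile_type = 6,
                         alpha = 0.05, abort_frac = 0.01) {
  stopifnot(inherits(scn, "scenario"), length(methods) > 0)
  set.seed(scn$seed)
  rep_seeds <- sample.int(2^31 - 2, scn$n_reps)
  m <- length(methods)
  reject <- cover <- se_sum <- se_n <- flagged <- cover_n <- done <-
    stats::setNames(numeric(m), methods)
  est_all <- numeric(scn$n_reps)
  t_arch <- if (keep_t_stats) {
    lapply(stats::setNames(nm = intersect(methods,
                                          c("classical", "HC3", "HC4"))),
           function(m) numeric(scn$n_reps))
  }
  for (j in seq_len(scn$n_reps)) {
    set.seed(rep_seeds[j])
    smp <- generate_sample(scn)
    res <- tryCatch(
      infer_sample(smp, methods, scn$B, alpha, percentile_type),
      error = function(e) NULL)
    if (is.null(res)) {        # whole-replication failure: flag all methods
      flagged <- flagged + 1
      est_all[j] <- NA_real_
      next
    }
    est_all[j] <- res$estimate[1]
    for (i in seq_len(nrow(res))) {
      mth <- res$method[i]
      if (isTRUE(res$flagged[i])) {
        flagged[mth] <- flagged[mth] + 1
        next
      }
      done[mth] <- done[mth] + 1
      reject[mth] <- reject[mth] + res$reject[i]
      if (!is.na(res$covers[i])) {
        cover[mth] <- cover[mth] + res$covers[i]
        cover_n[mth] <- cover_n[mth] + 1
      }
      if (!is.na(res$se[i])) {
        se_sum[mth] <- se_sum[mth] + res$se[i]
        se_n[mth] <- se_n[mth] + 1
      }
      if (keep_t_stats && mth %in% names(t_arch)) {
        t_arch[[mth]][j] <- res$t_stat[i]
      }
    }
  }
  if (any(flagged / scn$n_reps > abort_frac)) {
    stop("scenario aborted: flagged replication fraction exceeded ",
         abort_frac, " for method(s) ",
         paste(names(flagged)[flagged / scn$n_reps > abort_frac],
               collapse = ", "), call. = FALSE)
  }
  est_ok <- est_all[!is.na(est_all)]
  summary <- data.frame(
    model_id = scn$model_id, n = scn$n, dist = scn$dist$label, g = scn$g,
    method = methods,
    n_reps_done = as.integer(done[methods]),
    rejection_rate = reject[methods] / done[methods],
    coverage_rate = ifelse(cover_n[methods] > 0,
                           cover[methods] / cover_n[methods], NA_real_),
    mean_beta = mean(est_ok), sd_beta = stats::sd(est_ok),
    mean_se = ifelse(se_n[methods] > 0,
                     se_sum[methods] / se_n[methods], NA_real_),
    flagged_reps = as.integer(flagged[methods]),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(summary = summary,
                 t_stats = if (keep_t_stats) t_arch),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' Standard-error bias table
#'
#' Compares each SE-based method's mean estimated standard error against the
#' simulated standard error (the SD of the coefficient estimates across
#' replications) per scenario.
#'
#' @param summaries A summary data frame from [run_scenario()] /
#'   [run_grid()] containing classical/HC3/HC4 rows.
#' @return Data frame with `bias = mean_se - sd_beta` and
#'   `ratio = mean_se / sd_beta` per scenario and method.
#' @export
se_bias_table <- function(summaries) {
  s <- summaries[summaries$method %in% c("classical", "HC3", "HC4") &
                   !is.na(summaries$mean_se), ]
  if (nrow(s) == 0) stop("no SE-based method rows in input", call. = FALSE)
  s$bias <- s$mean_se - s$sd_beta
  s$ratio <- s$mean_se / s$sd_beta
  s[, c("model_id", "n", "dist", "g", "method", "mean_se", "sd_beta",
        "bias", "ratio")]
}
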