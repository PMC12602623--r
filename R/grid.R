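#' Default factorial grid configuration
#'
#' The full study design: 4 models x 5 sample sizes x 3 error distributions
#' x 4 heteroskedasticity levels, minus the infeasible pairing of `n = 25`
#' with the severe distribution, i.e. 14 (distribution x size) x 4 (models)
#' x 4 (g) = 224 scenarios.
#'
#' @param n_reps Replications per scenario.
#' @param B Bootstrap draws per replication.
#' @param seed Root seed for the whole grid.
#' @param constrained_sampling Constrained error resampling switch.
#' @return A named list understood by [scenario_grid()].
#' @export
default_grid_config <- function(n_reps = 10000L, B = 1000L, seed = 1L,
                                constrained_sampling = TRUE) {
  list(models = 1:4,
       ns = c(25L, 50L, 100L, 200L, 500L),
       distributions = c("normal", "moderate", "severe"),
       g_levels = c(0, 0.5, 1, 2),
       n_reps = n_reps, B = B, seed = seed,
       constrained_sampling = constrained_sampling)
}

#' Read a scenario-grid configuration from a YAML file
#'
#' Recognized keys: `models`, `ns`, `distributions`, `g_levels`, `n_reps`,
#' `B`, `seed`, `constrained_sampling`. Missing keys fall back to the
#' defaults of [default_grid_config()]; unknown keys raise an error naming
#' the key.
#'
#' @param path Path to a YAML file.
#' @return A configuration list.
#' @export
read_grid_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config did not parse to a mapping", call. = FALSE)
  known <- names(default_grid_config())
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- utils::modifyList(default_grid_config(), cfg)
  stopifnot(all(out$models %in% 1:4),
            all(out$distributions %in% c("normal", "moderate", "severe")),
            all(out$g_levels >= 0), all(out$ns > 3))
  out
}

#' Enumerate the scenarios of a grid configuration
#'
#' Expands the factorial design, drops `n = 25` x severe cells, and assigns
#' each scenario a reproducible sub-seed derived from the grid seed.
#'
#' @param config A configuration list (see [default_grid_config()]).
#' @return A list of `scenario` objects.
#' @export
scenario_grid <- function(config = default_grid_config()) {
  cells <- expand.grid(model_id = config$models, n = config$ns,
                       dist = config$distributions, g = config$g_levels,
                       stringsAsFactors = FALSE)
  cells <- cells[!(cells$n == 25 & cells$dist == "severe"), ]
  set.seed(config$seed)
  seeds <- sample.int(2^31 - 2, nrow(cells))
  specs <- lapply(stats::setNames(nm = unique(cells$dist)),
                  distribution_spec)
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    out[[i]] <- scenario(cells$model_id[i], cells$n[i],
                         specs[[cells$dist[i]]], cells$g[i],
                         n_reps = config$n_reps, B = config$B,
                         seed = seeds[i],
                         constrained_sampling = config$constrained_sampling)
  }
  out
}

scenario_tag <- function(scn) {
  sprintf("m%d_n%d_%s_g%s_R%d_B%d_s%d%s", scn$model_id, scn$n,
          scn$dist$label, format(scn$g), scn$n_reps, scn$B, scn$seed,
          if (scn$constrained_sampling) "" else "_unc")
}

#' Run every scenario of a grid and collect performance summaries
#'
#' Executes [run_scenario()] for each scenario in the configuration. When
#' `out_dir` is given, each completed scenario's summary is written as a CSV
#' named by its parameter tag and already-present scenarios are skipped, so
#' interrupted grids resume where they left off.
#'
#' @param config A configuration list, or a path to a YAML config file.
#' @param methods Subset of [hetsim_methods()].
#' @param out_dir Optional directory for per-scenario CSV checkpoints.
#' @param verbose Print progress lines?
#' @return A data frame of performance summaries, one row per scenario x
#'   method.
#' @export
run_grid <- function(config = default_grid_config(),
                     methods = hetsim_methods(), out_dir = NULL,
                     verbose = FALSE) {
  if (is.character(config)) config <- read_grid_config(config)
  scns <- scenario_grid(config)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  res <- vector("list", length(scns))
  for (i in seq_along(scns)) {
    scn <- scns[[i]]
    f <- if (!is.null(out_dir)) {
      file.path(out_dir, paste0(scenario_tag(scn), ".csv"))
    }
    if (!is.null(f) && file.exists(f)) {
      res[[i]] <- utils::read.csv(f, stringsAsFactors = FALSE)
      next
    }
    if (verbose) message(scenario_tag(scn))
    res[[i]] <- run_scenario(scn, methods)$summary
    if (!is.null(f)) utils::write.csv(res[[i]], f, row.names = FALSE)
  }
  do.call(rbind, res)
}
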