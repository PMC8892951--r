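#' Read a run configuration
#'
#' A YAML (or JSON) file drives the whole workflow: where the data come
#' from (a long-format CSV or a `simulate:` block), the reference
#' treatment, the LBP category and outcome kind to analyse, priors, MCMC
#' settings and an optional column mapping for alternative CSV headers.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return Configuration list with defaults filled in.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg$reference <- cfg$reference %||% "PLA"
  cfg$category <- cfg$category %||% NULL
  cfg$outcome <- cfg$outcome %||% "pain"
  cfg$priors <- do.call(nma_priors, as.list(cfg$priors %||% list()))
  cfg$mcmc <- do.call(nma_mcmc, as.list(cfg$mcmc %||% list()))
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.load_run_data <- function(cfg, config_dir = ".") {
  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    if (!is.null(sim$designs)) sim$designs <- purrr::map(sim$designs, unlist)
    data <- simulate_network(do.call(sim_config, sim))
  } else if (!is.null(cfg$data)) {
    path <- cfg$data
    if (!file.exists(path)) path <- file.path(config_dir, cfg$data)
    data <- read_trials(path, mapping = unlist(cfg$column_mapping))
  } else {
    stop("config needs either a 'data' path or a 'simulate' block",
         call. = FALSE)
  }
  data
}

.prepare_dataset <- function(cfg, data) {
  if (!is.null(cfg$category)) {
    keep <- classify_lbp(data$duration_weeks, data$radicular) == cfg$category
    data <- data[keep, , drop = FALSE]
    if (nrow(data) == 0) {
      stop("no studies in category '", cfg$category, "'", call. = FALSE)
    }
  }
  select_study_outcomes(data, kind = cfg$outcome %||% "pain")
}

.write_manifest <- function(out_dir, cfg, stages, artifacts, extra = list()) {
  manifest <- c(list(
    package_version = as.character(utils::packageVersion("lbpnma")),
    timestamp = format(Sys.time(), tz = "UTC"),
    reference = cfg$reference,
    category = cfg$category,
    outcome = cfg$outcome,
    seed = cfg$mcmc$seed,
    priors = unclass(cfg$priors),
    mcmc = unclass(cfg$mcmc),
    stages = stages,
    artifacts = artifacts
  ), extra)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  path
}

#' Run the estimation workflow
#'
#' Classify/filter the dataset, run the pairwise meta-analysis, fit the
#' Bayesian NMA, rank treatments by SUCRA, and write the artifacts
#' (`pairwise.csv`, `league.csv`, `ranking.csv`, `draws.csv`,
#' `manifest.json`) to `out_dir`. A convergence failure is reported
#' prominently in the manifest and as a warning, never silently.
#'
#' @param config Path to a configuration file (see [read_run_config()])
#'   or a configuration list.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional override of the MCMC master seed.
#' @return Invisibly, a list with the fitted objects and artifact paths.
#' @export
run_fit <- function(config, out_dir = "nma-run", seed = NULL) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  cfg$priors <- cfg$priors %||% nma_priors()
  cfg$mcmc <- cfg$mcmc %||% nma_mcmc()
  if (!is.null(seed)) cfg$mcmc$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  config_dir <- if (is.character(config)) dirname(config) else "."

  data <- .load_run_data(cfg, config_dir)
  dataset <- .prepare_dataset(cfg, data)
  contrasts <- as_contrasts(dataset, placebo = cfg$reference)
  pw <- pairwise_all(contrasts, cfg$reference)
  fit <- fit_nma(contrasts, cfg$reference, cfg$priors, cfg$mcmc)
  league <- league_table(fit)
  ranking <- nma_ranking(fit)

  paths <- list(
    pairwise = file.path(out_dir, "pairwise.csv"),
    league = file.path(out_dir, "league.csv"),
    ranking = file.path(out_dir, "ranking.csv"),
    draws = file.path(out_dir, "draws.csv")
  )
  utils::write.csv(as.data.frame(pw), paths$pairwise, row.names = FALSE)
  utils::write.csv(as.data.frame(league), paths$league, row.names = FALSE)
  utils::write.csv(as.data.frame(ranking), paths$ranking, row.names = FALSE)
  utils::write.csv(as.data.frame(posterior_draws(fit)), paths$draws,
                   row.names = FALSE)
  manifest <- .write_manifest(
    out_dir, cfg,
    stages = list(pairwise = "ok", nma = "ok", ranking = "ok"),
    artifacts = paths,
    extra = list(converged = fit$converged,
                 max_rhat = max(fit$rhat$rhat, na.rm = TRUE),
                 n_studies = dplyr::n_distinct(contrasts$study_id))
  )
  invisible(list(data = dataset, contrasts = contrasts, pairwise = pw,
                 fit = fit, league = league, ranking = ranking,
                 artifacts = c(paths, manifest = manifest)))
}

#' Run the inconsistency and bias diagnostics
#'
#' Global design-by-treatment test, loop inconsistency factors,
#' node-splitting, comparison-adjusted funnel regression and the
#' contribution matrix, written as flat CSV/JSON artifacts.
#'
#' @inheritParams run_fit
#' @param node_splits Run the MCMC node-splitting stage (slowest part)?
#' @return Invisibly, a list with the diagnostic objects and artifact
#'   paths.
#' @export
run_check <- function(config, out_dir = "nma-check", seed = NULL,
                      node_splits = TRUE) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  cfg$priors <- cfg$priors %||% nma_priors()
  cfg$mcmc <- cfg$mcmc %||% nma_mcmc()
  if (!is.null(seed)) cfg$mcmc$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  config_dir <- if (is.character(config)) dirname(config) else "."

  data <- .load_run_data(cfg, config_dir)
  dataset <- .prepare_dataset(cfg, data)
  contrasts <- as_contrasts(dataset, placebo = cfg$reference)
  report <- inconsistency_report(contrasts, cfg$reference, cfg$priors,
                                 cfg$mcmc, node_splits = node_splits)
  funnel <- comparison_adjusted_funnel(contrasts, cfg$reference)
  contrib <- contribution_matrix(contrasts, cfg$reference)

  paths <- list(
    global = file.path(out_dir, "inconsistency_global.json"),
    loops = file.path(out_dir, "inconsistency_loops.csv"),
    node_splits = file.path(out_dir, "node_splits.csv"),
    funnel = file.path(out_dir, "funnel_points.csv"),
    egger = file.path(out_dir, "egger.json"),
    contribution = file.path(out_dir, "contribution_matrix.csv")
  )
  jsonlite::write_json(as.list(report$global), paths$global,
                       auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.csv(as.data.frame(report$loops), paths$loops,
                   row.names = FALSE)
  if (!is.null(report$node_splits)) {
    utils::write.csv(as.data.frame(report$node_splits), paths$node_splits,
                     row.names = FALSE)
  } else {
    paths$node_splits <- NULL
  }
  utils::write.csv(as.data.frame(funnel$points), paths$funnel,
                   row.names = FALSE)
  jsonlite::write_json(as.list(funnel$egger), paths$egger,
                       auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.csv(round(unclass(contrib), 1), paths$contribution)
  manifest <- .write_manifest(
    out_dir, cfg,
    stages = list(inconsistency = "ok", funnel = "ok", contribution = "ok"),
    artifacts = paths
  )
  invisible(list(report = report, funnel = funnel, contribution = contrib,
                 artifacts = c(paths, manifest = manifest)))
}

#' Simulate a dataset from a configuration and write it to CSV
#'
#' @inheritParams run_fit
#' @return Invisibly, the simulated arm-level tibble; written to
#'   `trials.csv` in `out_dir` together with a manifest.
#' @export
run_simulate <- function(config, out_dir = "nma-sim", seed = NULL) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  if (is.null(cfg$simulate)) stop("config has no 'simulate' block",
                                  call. = FALSE)
  if (!is.null(seed)) cfg$simulate$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- cfg$simulate
  if (!is.null(sim$designs)) sim$designs <- purrr::map(sim$designs, unlist)
  data <- simulate_network(do.call(sim_config, sim))
  path <- file.path(out_dir, "trials.csv")
  write_trials(data, path)
  cfg$priors <- cfg$priors %||% nma_priors()
  cfg$mcmc <- cfg$mcmc %||% nma_mcmc(seed = cfg$simulate$seed %||% 1)
  .write_manifest(out_dir, cfg, stages = list(simulate = "ok"),
                  artifacts = list(trials = path))
  invisible(data)
}

#' Run the sensitivity workflow
#'
#' Refit after excluding high risk-of-bias studies and write the
#' per-comparison shift table.
#'
#' @inheritParams run_fit
#' @return Invisibly, the [sensitivity_refit()] result with artifact
#'   paths attached.
#' @export
run_sensitivity <- function(config, out_dir = "nma-sensitivity",
                            seed = NULL) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  cfg$priors <- cfg$priors %||% nma_priors()
  cfg$mcmc <- cfg$mcmc %||% nma_mcmc()
  if (!is.null(seed)) cfg$mcmc$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  config_dir <- if (is.character(config)) dirname(config) else "."

  data <- .load_run_data(cfg, config_dir)
  dataset <- .prepare_dataset(cfg, data)
  sens <- sensitivity_refit(dataset, reference = cfg$reference,
                            priors = cfg$priors, mcmc = cfg$mcmc,
                            placebo = cfg$reference)
  path <- file.path(out_dir, "sensitivity.csv")
  utils::write.csv(as.data.frame(sens$comparison), path, row.names = FALSE)
  manifest <- .write_manifest(
    out_dir, cfg, stages = list(sensitivity = "ok"),
    artifacts = list(sensitivity = path),
    extra = list(excluded = sens$excluded,
                 max_abs_shift = sens$max_abs_shift)
  )
  sens$artifacts <- list(sensitivity = path, manifest = manifest)
  invisible(sens)
}
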