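#' Configuration for the synthetic trial-network generator
#'
#' Defines a trial network with known truth: treatment set (reference
#' first, default codes in the field's abbreviation style), true basic
#' parameters on the SMD scale, between-study SD tau, trial designs and
#' counts, arm sizes and the raw-scale SD. Optional perturbations inject
#' loop inconsistency (a fixed SMD offset on one contrast of one design)
#' or small-study bias (effects inflated proportionally to the trial's
#' SE), giving the diagnostics something to detect.
#'
#' @param n_treatments Number of treatments K (>= 2).
#' @param treatments Treatment codes; default `"PLA"` plus active codes.
#' @param true_d True basic parameters, length K with `true_d[1] = 0`
#'   (reference). Default: evenly spaced 0, 0.3, 0.6, ...
#' @param tau Between-study SD of the random effects (>= 0), default 0.1.
#' @param designs List of treatment subsets (character vectors); default
#'   every pairwise comparison (a fully connected network).
#' @param n_trials_per_design Trials per design (scalar or per-design
#'   vector), default 15.
#' @param n_per_arm Participants per arm (scalar or per-design vector),
#'   default 50.
#' @param n_range Optional length-2 integer range; when given, each
#'   trial's per-arm size is drawn uniformly from it (needed for funnel
#'   analyses, which require SE variation across trials).
#' @param arm_sd Raw-scale outcome SD, default 1.
#' @param mu_sd SD of the study baseline level (in `arm_sd` units),
#'   default 0.5; baselines cancel out of all contrasts.
#' @param inconsistency_offset `NULL` or
#'   `list(design = <treatment subset>, pair = c(t1, t2), offset = <SMD>)`:
#'   the offset is added to the `t1` vs `t2` contrast in trials of that
#'   design.
#' @param small_study_bias `NULL` or a coefficient b: every non-baseline
#'   arm's standardized effect is inflated by `b * sqrt(1/n_b + 1/n_t)`.
#' @param exact_sd Use exact arm summaries (mean, sd without sampling
#'   noise) instead of simulating participant-level draws; for analytic
#'   checks.
#' @param category LBP category emulated (`"chronic"`, `"acute"`,
#'   `"radicular"`); fills duration/radicular metadata.
#' @param rob_high_frac Fraction of trials marked high risk of bias
#'   (default 0).
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_treatments = 2, treatments = NULL, true_d = NULL,
                       tau = 0.1, designs = NULL,
                       n_trials_per_design = 15, n_per_arm = 50,
                       n_range = NULL, arm_sd = 1, mu_sd = 0.5,
                       inconsistency_offset = NULL, small_study_bias = NULL,
                       exact_sd = FALSE,
                       category = c("chronic", "acute", "radicular"),
                       rob_high_frac = 0, seed = 1) {
  category <- match.arg(category)
  if (is.null(treatments)) {
    pool <- c("PLA", "SMR", "NSA", "OPI", "GMA", "C-NSA", "TRA", "DUL",
              "ACE", "TCA", "SSI", "COR")
    if (n_treatments > length(pool)) {
      pool <- c(pool, paste0("T", seq_len(n_treatments - length(pool))))
    }
    treatments <- pool[seq_len(n_treatments)]
  }
  n_treatments <- length(treatments)
  stopifnot(n_treatments >= 2)
  if (is.null(true_d)) true_d <- 0.3 * (seq_len(n_treatments) - 1)
  stopifnot(length(true_d) == n_treatments, true_d[1] == 0, tau >= 0,
            arm_sd > 0, all(n_trials_per_design >= 1), all(n_per_arm >= 1))
  if (is.null(designs)) {
    designs <- utils::combn(treatments, 2, simplify = FALSE)
  }
  stopifnot(all(unlist(designs) %in% treatments))
  if (!is.null(n_range)) stopifnot(length(n_range) == 2, n_range[1] >= 2)
  structure(
    list(treatments = treatments, true_d = stats::setNames(true_d, treatments),
         tau = tau, designs = designs,
         n_trials_per_design = rep_len(n_trials_per_design, length(designs)),
         n_per_arm = rep_len(n_per_arm, length(designs)),
         n_range = n_range, arm_sd = arm_sd, mu_sd = mu_sd,
         inconsistency_offset = inconsistency_offset,
         small_study_bias = small_study_bias, exact_sd = exact_sd,
         category = category, rob_high_frac = rob_high_frac,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# standardized arm deviations for one trial: baseline 0; others get the
# true contrast plus correlated random effects (var tau^2, cov tau^2/2)
# and any injected perturbation
.trial_deltas <- function(config, design, baseline, n_arm) {
  others <- setdiff(design, baseline)
  d <- config$true_d
  delta <- d[others] - d[baseline]
  if (config$tau > 0) {
    shared <- stats::rnorm(1, 0, config$tau / sqrt(2))
    delta <- delta + shared + stats::rnorm(length(others), 0, config$tau / sqrt(2))
  }
  off <- config$inconsistency_offset
  if (!is.null(off) && setequal(design, off$design)) {
    if (off$pair[1] %in% others && off$pair[2] == baseline) {
      delta[off$pair[1]] <- delta[off$pair[1]] + off$offset
    } else if (off$pair[1] %in% others && off$pair[2] %in% others) {
      delta[off$pair[1]] <- delta[off$pair[1]] + off$offset
    }
  }
  if (!is.null(config$small_study_bias)) {
    delta <- delta + config$small_study_bias * sqrt(1 / n_arm + 1 / n_arm)
  }
  delta
}

#' Simulate an arm-level trial network with known truth
#'
#' For every trial a study baseline is drawn, each non-baseline arm's true
#' standardized mean is the basic-parameter contrast plus a correlated
#' between-study random effect (variance tau^2, pairwise covariance
#' tau^2/2, the same structure the NMA likelihood assumes), and arm
#' summaries are computed from simulated participant-level normal draws
#' (or exactly, with `exact_sd = TRUE`). The same seed always produces an
#' identical dataset.
#'
#' @param config A [sim_config()] object.
#' @return Arm-level tibble in the canonical format (see [trial-data]),
#'   ready for [as_contrasts()] and every downstream stage.
#' @export
#' @examples
#' trials <- simulate_network(sim_config(n_treatments = 3, seed = 42))
simulate_network <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  g <- igraph::graph_from_data_frame(
    do.call(rbind, purrr::map(config$designs, function(d) {
      t(utils::combn(d, 2))
    })), directed = FALSE, vertices = config$treatments)
  if (igraph::components(g)$no > 1) {
    stop("design list does not connect the network", call. = FALSE)
  }
  set.seed(config$seed)
  meta <- switch(config$category,
                 acute = list(duration = 6, radicular = FALSE),
                 chronic = list(duration = 26, radicular = FALSE),
                 radicular = list(duration = 8, radicular = TRUE))
  rows <- list()
  sid <- 0
  for (j in seq_along(config$designs)) {
    design <- sort(config$designs[[j]])
    baseline <- if ("PLA" %in% design) "PLA" else design[1]
    for (tr in seq_len(config$n_trials_per_design[j])) {
      sid <- sid + 1
      n_arm <- if (!is.null(config$n_range)) {
        sample(seq(config$n_range[1], config$n_range[2]), 1)
      } else {
        config$n_per_arm[j]
      }
      mu <- stats::rnorm(1, 0, config$mu_sd) * config$arm_sd
      delta <- .trial_deltas(config, design, baseline, n_arm)
      std_mean <- c(stats::setNames(0, baseline), delta)
      rob <- if (stats::runif(1) < config$rob_high_frac) "high" else "low"
      for (trt in design) {
        true_mean <- mu + std_mean[[trt]] * config$arm_sd
        if (config$exact_sd) {
          m <- true_mean; s <- config$arm_sd
        } else {
          x <- stats::rnorm(n_arm, true_mean, config$arm_sd)
          m <- mean(x); s <- stats::sd(x)
        }
        rows[[length(rows) + 1]] <- tibble::tibble(
          study_id = sprintf("S%04d", sid), treatment = trt,
          n = n_arm, mean = m, sd = s, outcome = "average-pain",
          direction = "higher-is-better",
          duration_weeks = meta$duration, radicular = meta$radicular,
          rob = rob)
      }
    }
  }
  purrr::list_rbind(rows)
}

#' Simulate study-level contrasts directly
#'
#' A fast generator for calibration loops: skips arm-level data and draws
#' each trial's contrasts straight from the model
#' `y ~ N(d_t1 - d_t2 + u, v)` with `v = 2/n` per contrast and the same
#' correlated random-effect structure as [simulate_network()]. The
#' effect-size module is bypassed, so use [simulate_network()] when the
#' pipeline should be exercised end-to-end.
#'
#' @param config A [sim_config()] object.
#' @return Contrast tibble (`study_id`, `treat1`, `treat2`, `y`, `v`,
#'   `baseline`).
#' @export
simulate_contrasts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  rows <- list()
  sid <- 0
  for (j in seq_along(config$designs)) {
    design <- sort(config$designs[[j]])
    baseline <- if ("PLA" %in% design) "PLA" else design[1]
    others <- setdiff(design, baseline)
    for (tr in seq_len(config$n_trials_per_design[j])) {
      sid <- sid + 1
      n_arm <- if (!is.null(config$n_range)) {
        sample(seq(config$n_range[1], config$n_range[2]), 1)
      } else {
        config$n_per_arm[j]
      }
      delta <- .trial_deltas(config, design, baseline, n_arm)
      v <- 2 / n_arm
      rows[[length(rows) + 1]] <- tibble::tibble(
        study_id = sprintf("S%04d", sid),
        treat1 = others, treat2 = baseline,
        y = delta + stats::rnorm(length(others), 0, sqrt(v)),
        v = v, baseline = baseline)
    }
  }
  purrr::list_rbind(rows)
}

#' Replicated simulate-and-analyze runs
#'
#' Runs `analyze` on `n_reps` independently simulated datasets, with
#' replicate r using the derived seed `seed + r * 1e6`. Callback failures
#' are recorded per replicate and the run continues.
#'
#' @param config A [sim_config()] object.
#' @param n_reps Number of replicates (>= 1).
#' @param analyze Callback `function(data, config)` returning a one-row
#'   data frame of per-replicate results.
#' @param generator [simulate_network] (default) or [simulate_contrasts].
#' @return Tibble with columns `replicate`, `seed`, `error` plus the
#'   callback's columns.
#' @export
replicate_study <- function(config, n_reps, analyze,
                            generator = simulate_network) {
  stopifnot(n_reps >= 1)
  purrr::map(seq_len(n_reps), function(r) {
    cfg <- config
    cfg$seed <- config$seed + r * 1000000L
    base <- tibble::tibble(replicate = r, seed = cfg$seed,
                           error = NA_character_)
    res <- tryCatch(
      tibble::as_tibble(analyze(generator(cfg), cfg)),
      error = function(e) conditionMessage(e)
    )
    if (is.character(res)) {
      base$error <- res
      base
    } else {
      dplyr::bind_cols(base, res)
    }
  }) |> purrr::list_rbind()
}
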