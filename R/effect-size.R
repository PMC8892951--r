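#' Hedges' g standardized mean difference
#'
#' Computes the bias-corrected standardized mean difference between a
#' treatment arm and a control arm, with its large-sample variance:
#' \deqn{d = (m_t - m_c) / s_p, \quad J = 1 - \frac{3}{4(n_t+n_c-2)-1},
#' \quad g = J d,}
#' \deqn{v = \frac{n_t+n_c}{n_t n_c} + \frac{g^2}{2(n_t+n_c)},}
#' where \eqn{s_p} is the pooled standard deviation. For lower-is-better
#' scales (pain, disability scores) the mean difference is sign-flipped
#' before standardization, so a positive g always means benefit of the
#' treatment arm.
#'
#' @param mean_t,sd_t,n_t Treatment-arm mean, SD (> 0) and size.
#' @param mean_c,sd_c,n_c Control-arm mean, SD (> 0) and size.
#' @param direction `"higher-is-better"` or `"lower-is-better"` for the raw
#'   scale; vectorized.
#' @return A tibble with columns `g` and `v`.
#' @export
#' @examples
#' smd_hedges(1, 1, 10, 0, 1, 10)
smd_hedges <- function(mean_t, sd_t, n_t, mean_c, sd_c, n_c,
                       direction = "higher-is-better") {
  if (any(sd_t <= 0) || any(sd_c <= 0)) {
    stop("arm standard deviations must be > 0", call. = FALSE)
  }
  if (any(n_t + n_c < 3)) {
    stop("total sample size must be >= 3 to standardize", call. = FALSE)
  }
  if (!all(direction %in% .lbp_directions)) {
    stop("direction must be one of: ", paste(.lbp_directions, collapse = ", "),
         call. = FALSE)
  }
  sign <- ifelse(direction == "lower-is-better", -1, 1)
  n <- n_t + n_c
  s_pooled <- sqrt(((n_t - 1) * sd_t^2 + (n_c - 1) * sd_c^2) / (n - 2))
  if (any(s_pooled <= 0 | !is.finite(s_pooled))) {
    stop("degenerate pooled standard deviation", call. = FALSE)
  }
  d <- sign * (mean_t - mean_c) / s_pooled
  j <- 1 - 3 / (4 * (n - 2) - 1)
  g <- j * d
  v <- n / (n_t * n_c) + g^2 / (2 * n)
  tibble::tibble(g = g, v = v)
}

#' Contrasts for one study
#'
#' Converts the arms of a single study into k-1 standardized-mean-difference
#' contrasts against one baseline arm. The baseline is the placebo arm when
#' present, otherwise the first treatment in `treatment_order` (default:
#' lexicographic). Contrasts keep the shared `study_id` so the NMA
#' likelihood can apply within-study correlation.
#'
#' @param study Arm-level tibble for one study (>= 2 rows).
#' @param placebo Treatment code regarded as placebo (`"PLA"`).
#' @param treatment_order Optional character vector giving the baseline
#'   preference order used when no placebo arm exists.
#' @return Tibble with columns `study_id`, `treat1`, `treat2`, `y`, `v`,
#'   `baseline` (`treat2` is always the baseline arm).
#' @export
contrasts_from_study <- function(study, placebo = "PLA",
                                 treatment_order = NULL) {
  if (nrow(study) < 2) stop("a study needs >= 2 arms", call. = FALSE)
  trts <- study$treatment
  if (anyDuplicated(trts)) {
    stop("duplicate treatments within study ", study$study_id[1],
         call. = FALSE)
  }
  baseline <- if (placebo %in% trts) {
    placebo
  } else if (!is.null(treatment_order) && any(treatment_order %in% trts)) {
    treatment_order[treatment_order %in% trts][1]
  } else {
    sort(trts)[1]
  }
  base <- study[study$treatment == baseline, ]
  rest <- study[study$treatment != baseline, ]
  es <- smd_hedges(rest$mean, rest$sd, rest$n,
                   base$mean, base$sd, base$n,
                   direction = rest$direction)
  tibble::tibble(
    study_id = rest$study_id,
    treat1 = rest$treatment,
    treat2 = baseline,
    y = es$g,
    v = es$v,
    baseline = baseline
  )
}

#' Convert an arm-level table to study-level contrasts
#'
#' Applies [contrasts_from_study()] to every study of an arm-level table.
#' The table must already contain one outcome per study (see
#' [select_study_outcomes()]).
#'
#' @inheritParams contrasts_from_study
#' @param data Arm-level tibble.
#' @return Contrast tibble (one row per non-baseline arm).
#' @export
#' @examples
#' trials <- simulate_network(sim_config(n_treatments = 3, seed = 1))
#' as_contrasts(trials)
as_contrasts <- function(data, placebo = "PLA", treatment_order = NULL) {
  validate_trials(data)
  data |>
    dplyr::group_by(.data$study_id) |>
    dplyr::group_split() |>
    purrr::map(contrasts_from_study, placebo = placebo,
               treatment_order = treatment_order) |>
    purrr::list_rbind() |>
    dplyr::arrange(.data$study_id, .data$treat1)
}

#' Read contrast-format data
#'
#' Some evidence is only available as study-level contrasts (SMD and
#' standard error). These rows bypass effect-size construction; the
#' variance is `se^2`.
#'
#' @param path Delimited file with columns `study_id`, `treat1`, `treat2`,
#'   `smd`, `se`.
#' @param delim Field delimiter.
#' @return Contrast tibble compatible with [as_contrasts()] output.
#' @export
read_contrasts <- function(path, delim = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, sep = delim, stringsAsFactors = FALSE)
  need <- c("study_id", "treat1", "treat2", "smd", "se")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop("input file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(raw$se <= 0 | is.na(raw$se))) {
    stop("se must be > 0", call. = FALSE)
  }
  tibble::tibble(
    study_id = as.character(raw$study_id),
    treat1 = raw$treat1,
    treat2 = raw$treat2,
    y = raw$smd,
    v = raw$se^2,
    baseline = raw$treat2
  )
}
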