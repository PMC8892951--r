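#' Arm-level trial data
#'
#' The whole pipeline works on a long-format table with one row per study
#' arm. The canonical columns are:
#'
#' * `study_id` — study identifier (character).
#' * `treatment` — treatment code, e.g. `"PLA"`, `"SMR"`, `"NSA+GMA"`;
#'   `"+"` is reserved as the combination separator.
#' * `n` — number of participants contributing to the arm summary (>= 1).
#' * `mean`, `sd` — arm outcome mean and standard deviation (`sd > 0`).
#' * `outcome` — outcome label, one of [lbp_outcomes()].
#' * `direction` — `"higher-is-better"` or `"lower-is-better"` for the raw
#'   scale (pain and disability scores are usually lower-is-better).
#' * `duration_weeks` — pain duration at baseline (weeks), may be `NA`.
#' * `radicular` — logical, neuropathic/nerve-root involvement.
#' * `rob` — risk-of-bias rating: `"low"`, `"some-concerns"`, `"high"`.
#'
#' @name trial-data
#' @keywords internal
NULL

.lbp_required_cols <- c(
  "study_id", "treatment", "n", "mean", "sd", "outcome", "direction",
  "duration_weeks", "radicular", "rob"
)

.lbp_rob_levels <- c("low", "some-concerns", "high")
.lbp_directions <- c("higher-is-better", "lower-is-better")

#' Controlled outcome vocabulary
#'
#' Pain outcomes are listed in the priority order used by
#' [select_pain_outcome()]: average pain intensity, then pain on rest,
#' walking and sleep. Function outcomes are the Roland Morris disability
#' questionnaire (RMDQ) and the Oswestry disability index (ODI).
#'
#' @param kind `"pain"`, `"function"` or `"all"`.
#' @return Character vector of outcome labels.
#' @export
#' @examples
#' lbp_outcomes("pain")
lbp_outcomes <- function(kind = c("all", "pain", "function")) {
  kind <- match.arg(kind)
  pain <- c("average-pain", "rest-pain", "walking-pain", "sleep-pain")
  fn <- c("RMDQ", "ODI")
  switch(kind, pain = pain, "function" = fn, all = c(pain, fn))
}

#' Validate an arm-level trial table
#'
#' Checks the structural invariants every downstream stage relies on:
#' required columns present, `n >= 1`, `sd > 0`, non-empty treatment codes,
#' every study has at least two arms with distinct treatments.
#'
#' @param data A data frame of trial arms (see [trial-data]).
#' @return The input as a tibble, invisibly for side-effect style use.
#' @export
validate_trials <- function(data) {
  data <- tibble::as_tibble(data)
  missing_cols <- setdiff(.lbp_required_cols, names(data))
  if (length(missing_cols) > 0) {
    stop("trial data is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(data) == 0) stop("trial data has no rows", call. = FALSE)
  if (any(is.na(data$study_id)) || any(!nzchar(as.character(data$study_id)))) {
    stop("study_id must be non-missing and non-empty", call. = FALSE)
  }
  if (any(is.na(data$treatment)) || any(!nzchar(data$treatment))) {
    bad <- unique(data$study_id[is.na(data$treatment) | !nzchar(data$treatment)])
    stop("empty treatment code in study: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  bad_n <- is.na(data$n) | data$n < 1 | data$n != round(data$n)
  if (any(bad_n)) {
    stop("n must be a positive integer; offending study: ",
         paste(unique(data$study_id[bad_n]), collapse = ", "), call. = FALSE)
  }
  bad_sd <- is.na(data$sd) | data$sd <= 0
  if (any(bad_sd)) {
    stop("sd must be > 0; offending study: ",
         paste(unique(data$study_id[bad_sd]), collapse = ", "), call. = FALSE)
  }
  if (!all(data$direction %in% .lbp_directions)) {
    stop("direction must be one of: ", paste(.lbp_directions, collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.na(data$rob) | data$rob %in% .lbp_rob_levels)) {
    stop("rob must be one of: ", paste(.lbp_rob_levels, collapse = ", "),
         call. = FALSE)
  }
  dup <- data |>
    dplyr::count(.data$study_id, .data$outcome, .data$treatment,
                 name = "n_rows") |>
    dplyr::filter(.data$n_rows > 1)
  if (nrow(dup) > 0) {
    stop("duplicate treatment within a study/outcome: ",
         paste(unique(dup$study_id), collapse = ", "), call. = FALSE)
  }
  n_arms <- data |>
    dplyr::distinct(.data$study_id, .data$outcome, .data$treatment) |>
    dplyr::count(.data$study_id, .data$outcome, name = "n_arms")
  if (any(n_arms$n_arms < 2)) {
    bad <- unique(n_arms$study_id[n_arms$n_arms < 2])
    stop("every study needs >= 2 arms; offending study: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(data)
}

#' Read arm-level trial data from delimited text
#'
#' Reads a long-format delimited file (comma by default) into a validated
#' arm-level tibble. Alternative headers are handled through `mapping`, a
#' named character vector `c(canonical = "file_column")`.
#'
#' @param path Path to the delimited file.
#' @param mapping Optional named character vector mapping canonical column
#'   names (see [trial-data]) to the file's column names.
#' @param delim Field delimiter, `","` by default.
#' @return A validated tibble of trial arms.
#' @export
read_trials <- function(path, mapping = NULL, delim = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, sep = delim, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (!is.null(mapping)) {
    for (canon in names(mapping)) {
      src <- mapping[[canon]]
      if (!src %in% names(raw)) {
        stop("mapped column '", src, "' (for '", canon, "') not in file",
             call. = FALSE)
      }
      names(raw)[names(raw) == src] <- canon
    }
  }
  missing_cols <- setdiff(.lbp_required_cols, names(raw))
  if (length(missing_cols) > 0) {
    stop("input file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- tibble::as_tibble(raw[.lbp_required_cols])
  data$study_id <- as.character(data$study_id)
  data$treatment <- as.character(data$treatment)
  data$radicular <- as.logical(data$radicular)
  # report malformed numeric rows with their (1-based, post-header) line numbers
  num_ok <- !is.na(suppressWarnings(as.numeric(data$n))) &
    !is.na(suppressWarnings(as.numeric(data$sd)))
  if (any(!num_ok)) {
    stop("malformed numeric fields at data line(s): ",
         paste(which(!num_ok), collapse = ", "), call. = FALSE)
  }
  validate_trials(data)
  data
}

#' Write arm-level trial data to delimited text
#'
#' @param data A validated arm-level tibble.
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_trials <- function(data, path, delim = ",") {
  validate_trials(data)
  utils::write.table(as.data.frame(data)[.lbp_required_cols], path,
                     sep = delim, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Classify low back pain by duration and radicular status
#'
#' Neuropathic (radicular) involvement takes precedence regardless of
#' duration; otherwise pain lasting at most 12 weeks is acute (including
#' subacute) and anything longer is chronic. A non-radicular record with
#' missing duration cannot be classified and raises an error.
#'
#' @param duration_weeks Numeric vector of pain durations (weeks); `NA`
#'   allowed only where `radicular` is `TRUE`.
#' @param radicular Logical vector.
#' @return Character vector with values `"acute"`, `"chronic"`,
#'   `"radicular"`.
#' @export
#' @examples
#' classify_lbp(c(8, 52, 8), c(FALSE, FALSE, TRUE))
classify_lbp <- function(duration_weeks, radicular) {
  if (length(duration_weeks) != length(radicular)) {
    stop("duration_weeks and radicular must have equal length", call. = FALSE)
  }
  if (any(is.na(radicular))) stop("radicular must be TRUE/FALSE", call. = FALSE)
  if (any(!is.na(duration_weeks) & duration_weeks < 0)) {
    stop("duration_weeks must be nonnegative", call. = FALSE)
  }
  unclass_ok <- radicular | !is.na(duration_weeks)
  if (any(!unclass_ok)) {
    stop("unclassifiable record(s): missing duration with radicular = FALSE ",
         "at position(s) ", paste(which(!unclass_ok), collapse = ", "),
         call. = FALSE)
  }
  dplyr::case_when(
    radicular ~ "radicular",
    duration_weeks <= 12 ~ "acute",
    TRUE ~ "chronic"
  )
}

#' Pick the highest-priority pain outcome
#'
#' When a trial reports several pain conditions, one is selected by the
#' fixed hierarchy: average pain intensity, then pain on rest, walking and
#' sleep.
#'
#' @param available Character vector of outcome labels present in a study.
#' @return The selected label.
#' @export
#' @examples
#' select_pain_outcome(c("rest-pain", "walking-pain"))
select_pain_outcome <- function(available) {
  if (length(available) == 0) stop("no outcomes supplied", call. = FALSE)
  hier <- lbp_outcomes("pain")
  hit <- hier[hier %in% available]
  if (length(hit) == 0) {
    stop("no pain outcome among: ", paste(available, collapse = ", "),
         call. = FALSE)
  }
  hit[[1]]
}

#' Reduce a trial table to one outcome per study
#'
#' For `kind = "pain"` each study keeps only its highest-priority pain
#' outcome per [select_pain_outcome()]; for `kind = "function"` RMDQ is
#' preferred over ODI. Studies without any outcome of the requested kind
#' are dropped.
#'
#' @param data Arm-level tibble.
#' @param kind `"pain"` or `"function"`.
#' @return Filtered arm-level tibble.
#' @export
select_study_outcomes <- function(data, kind = c("pain", "function")) {
  kind <- match.arg(kind)
  validate_trials(data)
  hier <- lbp_outcomes(kind)
  data |>
    dplyr::filter(.data$outcome %in% hier) |>
    dplyr::group_by(.data$study_id) |>
    dplyr::filter(.data$outcome == hier[min(match(.data$outcome, hier))]) |>
    dplyr::ungroup()
}

#' Per-study metadata
#'
#' Collapses an arm-level table to one row per study with its LBP category
#' and risk-of-bias rating.
#'
#' @param data Arm-level tibble.
#' @return Tibble with columns `study_id`, `n_arms`, `duration_weeks`,
#'   `radicular`, `category`, `rob`.
#' @export
study_info <- function(data) {
  validate_trials(data)
  data |>
    dplyr::group_by(.data$study_id) |>
    dplyr::summarise(
      n_arms = dplyr::n_distinct(.data$treatment),
      duration_weeks = .data$duration_weeks[1],
      radicular = .data$radicular[1],
      rob = .data$rob[1],
      .groups = "drop"
    ) |>
    dplyr::mutate(category = classify_lbp(.data$duration_weeks, .data$radicular))
}
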