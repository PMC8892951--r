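#' Build the evidence-network geometry
#'
#' Derives treatments, edges (direct comparisons with study counts),
#' designs (distinct treatment sets with multiplicities), closed loops and
#' connectivity from an arm-level trial table. A k-arm study contributes
#' all k(k-1)/2 unordered treatment pairs to edge counting.
#'
#' @param data Arm-level tibble (see [trial-data]) or a contrast tibble as
#'   produced by [as_contrasts()] (columns `study_id`, `treat1`, `treat2`).
#' @param reference Reference treatment code (e.g. `"PLA"`); must occur in
#'   the data.
#' @return An object of class `nma_network`: a list with `treatments`
#'   (reference first), `reference`, `edges`, `designs`, `loops`,
#'   `connected` and `stranded` (treatments outside the reference
#'   component). A disconnected network is returned with a warning, not an
#'   error, so the stranded set can be inspected.
#' @export
#' @examples
#' trials <- simulate_network(sim_config(n_treatments = 3, seed = 1))
#' build_network(trials, reference = "PLA")
build_network <- function(data, reference) {
  pairs <- if (all(c("treat1", "treat2") %in% names(data))) {
    tibble::tibble(study_id = as.character(data$study_id),
                   treat1 = data$treat1, treat2 = data$treat2)
  } else {
    validate_trials(data)
    data |>
      dplyr::distinct(.data$study_id, .data$treatment) |>
      dplyr::group_by(.data$study_id) |>
      dplyr::reframe(as.data.frame(t(utils::combn(sort(.data$treatment), 2)))) |>
      dplyr::rename(treat1 = "V1", treat2 = "V2")
  }
  treatments <- sort(unique(c(pairs$treat1, pairs$treat2)))
  if (!reference %in% treatments) {
    stop("reference treatment '", reference, "' not present in the data",
         call. = FALSE)
  }
  treatments <- c(reference, setdiff(treatments, reference))

  edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  edges <- pairs |>
    dplyr::mutate(lo = pmin(.data$treat1, .data$treat2),
                  hi = pmax(.data$treat1, .data$treat2),
                  treat1 = .data$lo, treat2 = .data$hi) |>
    dplyr::distinct(.data$study_id, .data$treat1, .data$treat2) |>
    dplyr::count(.data$treat1, .data$treat2, name = "n_studies") |>
    dplyr::arrange(.data$treat1, .data$treat2)

  designs <- pairs |>
    dplyr::group_by(.data$study_id) |>
    dplyr::summarise(
      design = paste(sort(unique(c(.data$treat1, .data$treat2))),
                     collapse = ";"),
      .groups = "drop"
    ) |>
    dplyr::count(.data$design, name = "n_studies") |>
    dplyr::arrange(.data$design)

  g <- igraph::graph_from_data_frame(edges[, c("treat1", "treat2")],
                                     directed = FALSE,
                                     vertices = treatments)
  tri <- matrix(igraph::triangles(g), nrow = 3)
  loops <- if (ncol(tri) > 0) {
    nm <- apply(tri, 2, function(ix) sort(igraph::V(g)$name[ix]))
    tibble::tibble(t1 = nm[1, ], t2 = nm[2, ], t3 = nm[3, ]) |>
      dplyr::arrange(.data$t1, .data$t2, .data$t3)
  } else {
    tibble::tibble(t1 = character(), t2 = character(), t3 = character())
  }

  comp <- igraph::components(g)
  ref_comp <- comp$membership[[reference]]
  stranded <- names(comp$membership)[comp$membership != ref_comp]
  connected <- length(stranded) == 0
  if (!connected) {
    warning("network is disconnected; stranded treatment(s): ",
            paste(stranded, collapse = ", "), call. = FALSE)
  }

  structure(
    list(treatments = treatments, reference = reference, edges = edges,
         designs = designs, loops = loops, connected = connected,
         stranded = stranded),
    class = "nma_network"
  )
}

#' @export
print.nma_network <- function(x, ...) {
  cat("<nma_network> ", length(x$treatments), " treatments (reference ",
      x$reference, "), ", nrow(x$edges), " edges, ",
      sum(x$edges$n_studies), " study-contrast pairs, ",
      nrow(x$loops), " triangle(s); ",
      if (x$connected) "connected" else
        paste0("DISCONNECTED (stranded: ",
               paste(x$stranded, collapse = ", "), ")"),
      "\n", sep = "")
  invisible(x)
}
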