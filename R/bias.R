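#' Comparison-adjusted funnel analysis
#'
#' Centers every study effect on the random-effects pooled estimate of its
#' own comparison, so studies from different comparisons can share one
#' funnel. Small-study effects are then tested with an Egger-type
#' regression of the standardized centered effect `x/se` on precision
#' `1/se`: under no bias the intercept is 0. With fewer than 3 points the
#' points are still returned but the regression is suppressed.
#'
#' @param contrasts Contrast tibble.
#' @param reference Reference treatment code (orientation only).
#' @return List of class `nma_funnel`: `points` (tibble `study_id`,
#'   `treat1`, `treat2`, `x`, `se`) and `egger` (one-row tibble
#'   `intercept`, `se`, `statistic`, `p_value`, `suppressed`).
#' @export
comparison_adjusted_funnel <- function(contrasts, reference = "PLA") {
  oriented <- orient_contrasts(contrasts, reference)
  pooled <- pairwise_all(oriented, reference)
  points <- oriented |>
    dplyr::left_join(pooled[, c("treat1", "treat2", "pooled")],
                     by = c("treat1", "treat2")) |>
    dplyr::transmute(.data$study_id, .data$treat1, .data$treat2,
                     x = .data$y - .data$pooled, se = sqrt(.data$v))
  if (nrow(points) < 3) {
    egger <- tibble::tibble(intercept = NA_real_, se = NA_real_,
                            statistic = NA_real_, p_value = NA_real_,
                            suppressed = TRUE)
  } else {
    fit <- stats::lm(I(x / se) ~ I(1 / se), data = points)
    co <- summary(fit)$coefficients
    egger <- tibble::tibble(intercept = co[1, 1], se = co[1, 2],
                            statistic = co[1, 3], p_value = co[1, 4],
                            suppressed = FALSE)
  }
  structure(list(points = points, egger = egger), class = "nma_funnel")
}

#' @export
print.nma_funnel <- function(x, ...) {
  cat("<nma_funnel> ", nrow(x$points), " points\n", sep = "")
  if (x$egger$suppressed) {
    cat("  Egger regression suppressed (< 3 points)\n")
  } else {
    cat(sprintf("  Egger intercept %.3f (p = %.3f)\n", x$egger$intercept,
                x$egger$p_value))
  }
  invisible(x)
}

# decompose one hat-matrix row into paths (streams): the row coefficients
# form a unit flow from `from` to `to` over the direct comparisons; the
# flow is peeled off along shortest paths, and each path's contribution is
# shared equally among its edges.
.flow_contributions <- function(h, edges, from, to, tol = 1e-9) {
  flow <- abs(h)
  tail <- ifelse(h >= 0, edges$treat1, edges$treat2)
  head <- ifelse(h >= 0, edges$treat2, edges$treat1)
  contrib <- numeric(nrow(edges))
  verts <- unique(c(tail, head, from, to))
  for (iter in seq_len(1000)) {
    live <- flow > tol
    if (!any(live)) break
    g <- igraph::graph_from_data_frame(
      data.frame(from = tail[live], to = head[live]),
      directed = TRUE, vertices = verts)
    path <- suppressWarnings(
      igraph::shortest_paths(g, from, to, mode = "out", output = "vpath"))
    vp <- path$vpath[[1]]
    if (length(vp) < 2) break
    vnames <- igraph::V(g)$name[as.integer(vp)]
    steps <- cbind(vnames[-length(vnames)], vnames[-1])
    idx <- apply(steps, 1, function(s) {
      which(live & tail == s[1] & head == s[2])[1]
    })
    phi <- min(flow[idx])
    contrib[idx] <- contrib[idx] + phi / length(idx)
    flow[idx] <- flow[idx] - phi
  }
  contrib
}

#' Contribution matrix of the network estimator
#'
#' Quantifies how much each direct comparison contributes to each network
#' estimate. The aggregate-level weighted least-squares hat matrix of the
#' network estimator is computed from per-edge pooled direct estimates;
#' each row is a unit evidence flow from one treatment to the other, which
#' is decomposed into paths (shortest first), sharing every path's flow
#' equally among its edges. Contributions are reported as percentages;
#' every column (one network estimate) sums to 100.
#'
#' @param contrasts Contrast tibble.
#' @param reference Reference treatment code.
#' @param estimates `"all"` for every treatment pair (mixed and indirect
#'   comparisons) or `"edges"` for pairs with direct evidence only.
#' @return A matrix (class `nma_contribution`): rows are direct
#'   comparisons, columns network estimates, entries percentage
#'   contributions. Attribute `network_percent` holds each direct
#'   comparison's average contribution across all estimates (sums to
#'   100): the whole-network normalization variant.
#' @export
contribution_matrix <- function(contrasts, reference = "PLA",
                                estimates = c("all", "edges")) {
  estimates <- match.arg(estimates)
  net <- build_network(contrasts, reference)  # errors noisily if missing ref
  if (!net$connected) {
    stop("contribution matrix needs a connected network; stranded: ",
         paste(net$stranded, collapse = ", "), call. = FALSE)
  }
  oriented <- orient_contrasts(contrasts, reference)
  pooled <- pairwise_all(oriented, reference)
  edges <- pooled[, c("treat1", "treat2", "se")]
  w <- 1 / edges$se^2
  treatments <- net$treatments
  x_agg <- .design_matrix(edges, treatments)
  xtwx <- crossprod(x_agg, w * x_agg)
  xtw <- t(x_agg * w)

  pair_grid <- if (estimates == "edges") {
    edges[, c("treat1", "treat2")]
  } else {
    all_pairs <- t(utils::combn(treatments, 2))
    # orient like pairwise_all: reference second, else lexicographic
    tibble::tibble(
      treat1 = ifelse(all_pairs[, 1] == reference, all_pairs[, 2],
                      pmin(all_pairs[, 1], all_pairs[, 2])),
      treat2 = ifelse(all_pairs[, 1] == reference, reference,
                      pmax(all_pairs[, 1], all_pairs[, 2]))
    )
  }
  basic <- treatments[-1]
  out <- matrix(0, nrow(edges), nrow(pair_grid))
  for (j in seq_len(nrow(pair_grid))) {
    xt <- numeric(length(basic))
    a <- pair_grid$treat1[j]; b <- pair_grid$treat2[j]
    if (a != reference) xt[match(a, basic)] <- 1
    if (b != reference) xt[match(b, basic)] <- xt[match(b, basic)] - 1
    h <- as.vector(xt %*% solve(xtwx, xtw))
    out[, j] <- 100 * .flow_contributions(h, edges, a, b)
  }
  dimnames(out) <- list(paste(edges$treat1, "vs", edges$treat2),
                        paste(pair_grid$treat1, "vs", pair_grid$treat2))
  netp <- rowMeans(out)
  attr(out, "network_percent") <- 100 * netp / sum(netp)
  class(out) <- c("nma_contribution", class(out))
  out
}

#' Sensitivity refit after excluding flagged studies
#'
#' Refits the Bayesian NMA without the flagged studies (by default those
#' rated at high risk of bias) using the same priors, MCMC settings and
#' seed, and reports the per-comparison shift in the posterior median and
#' whether any credible-interval conclusion (excludes 0 versus not)
#' changes.
#'
#' @param data Arm-level tibble.
#' @param exclude Either a character vector of study ids, or a predicate
#'   taking the [study_info()] tibble and returning a logical vector.
#'   Default: studies with `rob == "high"`.
#' @param reference Reference treatment code.
#' @param priors,mcmc Passed to [fit_nma()].
#' @param ... Passed to [as_contrasts()].
#' @return List of class `nma_sensitivity`: `fit_full`, `fit_reduced`,
#'   `comparison` (per-pair medians, shift, conclusion flags),
#'   `max_abs_shift`, `excluded`.
#' @export
sensitivity_refit <- function(data, exclude = NULL, reference = "PLA",
                              priors = nma_priors(), mcmc = nma_mcmc(),
                              ...) {
  info <- study_info(data)
  excluded <- if (is.null(exclude)) {
    info$study_id[!is.na(info$rob) & info$rob == "high"]
  } else if (is.function(exclude)) {
    info$study_id[exclude(info)]
  } else {
    as.character(exclude)
  }
  reduced_data <- data[!data$study_id %in% excluded, , drop = FALSE]
  if (nrow(reduced_data) == 0) {
    stop("exclusion removes every study", call. = FALSE)
  }
  contrasts_full <- as_contrasts(data, ...)
  contrasts_red <- as_contrasts(reduced_data, ...)
  if (!reference %in% c(contrasts_red$treat1, contrasts_red$treat2)) {
    stop("exclusion removes the reference treatment '", reference, "'",
         call. = FALSE)
  }
  net_red <- suppressWarnings(build_network(contrasts_red, reference))
  lost <- setdiff(unique(c(contrasts_full$treat1, contrasts_full$treat2)),
                  net_red$treatments)
  if (!net_red$connected || length(lost) > 0) {
    stop("exclusion disconnects the network; lost/stranded treatment(s): ",
         paste(union(lost, net_red$stranded), collapse = ", "),
         call. = FALSE)
  }
  fit_full <- fit_nma(contrasts_full, reference, priors, mcmc)
  fit_red <- fit_nma(contrasts_red, reference, priors, mcmc)
  lt_full <- league_table(fit_full) |>
    dplyr::filter(.data$treat1 != reference, .data$treat1 != .data$treat2,
                  .data$treat2 == reference |
                    (.data$treat2 != reference & .data$treat1 < .data$treat2))
  lt_red <- league_table(fit_red)
  comparison <- lt_full |>
    dplyr::inner_join(lt_red, by = c("treat1", "treat2"),
                      suffix = c("_full", "_reduced")) |>
    dplyr::mutate(
      shift = .data$median_reduced - .data$median_full,
      sig_full = .data$ci_low_full > 0 | .data$ci_high_full < 0,
      sig_reduced = .data$ci_low_reduced > 0 | .data$ci_high_reduced < 0,
      conclusion_change = .data$sig_full != .data$sig_reduced
    ) |>
    dplyr::select("treat1", "treat2", "median_full", "median_reduced",
                  "shift", "sig_full", "sig_reduced", "conclusion_change")
  structure(
    list(fit_full = fit_full, fit_reduced = fit_red,
         comparison = comparison,
         max_abs_shift = max(abs(comparison$shift)),
         excluded = excluded),
    class = "nma_sensitivity"
  )
}

#' @export
print.nma_sensitivity <- function(x, ...) {
  cat("<nma_sensitivity> excluded ", length(x$excluded), " study(ies); ",
      "max |shift| in posterior median = ",
      sprintf("%.3f", x$max_abs_shift), "; conclusion changes: ",
      sum(x$comparison$conclusion_change), "\n", sep = "")
  invisible(x)
}

.grade_levels <- c("very-low", "low", "moderate", "high")

#' Combine direct and indirect GRADE ratings
#'
#' The evidence rating of an NMA estimate is the *higher* of the direct
#' and indirect ratings on the ordered scale very-low < low < moderate <
#' high. A missing rating passes the other one through; both missing is an
#' error. Vectorized, commutative and idempotent.
#'
#' @param direct,indirect Character vectors of ratings (or `NA`).
#' @return Character vector of combined ratings.
#' @export
#' @examples
#' grade_combine("moderate", "low")
grade_combine <- function(direct, indirect) {
  n <- max(length(direct), length(indirect))
  direct <- rep_len(direct, n)
  indirect <- rep_len(indirect, n)
  ok <- function(x) is.na(x) | x %in% .grade_levels
  if (!all(ok(direct) & ok(indirect))) {
    stop("ratings must be one of: ", paste(.grade_levels, collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(direct) & is.na(indirect))) {
    stop("both ratings missing for some comparison", call. = FALSE)
  }
  di <- match(direct, .grade_levels)
  ii <- match(indirect, .grade_levels)
  .grade_levels[pmax(di, ii, na.rm = TRUE)]
}
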