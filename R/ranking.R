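#' Posterior rank probabilities
#'
#' For each MCMC draw the treatments (including the reference) are ranked
#' by their sampled effect; rank 1 is best. Under the package's direction
#' convention a larger SMD means more improvement, so the default ranks
#' larger effects first; `direction = "lower-is-better"` reverses this for
#' effects left on a harm scale. Exact ties within a draw (probability ~0
#' for continuous draws) are broken at random with an internal fixed-seed
#' generator so results are reproducible.
#'
#' @param fit An [fit_nma()] result.
#' @param direction `"higher-is-better"` (default) or `"lower-is-better"`.
#' @param tie_seed Seed of the internal tie-breaking generator.
#' @return A treatments x ranks matrix of probabilities; every row and
#'   every column sums to 1.
#' @export
rank_probabilities <- function(fit, direction = c("higher-is-better",
                                                  "lower-is-better"),
                               tie_seed = 20260101) {
  stopifnot(inherits(fit, "nma_fit"))
  direction <- match.arg(direction)
  k <- length(fit$treatments)
  draws <- vapply(fit$treatments, function(tr) as.vector(fit$d[, , tr]),
                  numeric(dim(fit$d)[1] * dim(fit$d)[2]))
  if (direction == "higher-is-better") draws <- -draws  # rank() is ascending
  # seeded tie-break jitter, leaving the caller's RNG stream untouched
  has_ties <- any(apply(draws, 1, anyDuplicated) > 0)
  if (has_ties) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(tie_seed)
    draws <- draws + matrix(stats::runif(length(draws), -1e-9, 1e-9),
                            nrow(draws))
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }
  ranks <- t(apply(draws, 1, rank, ties.method = "first"))
  probs <- vapply(seq_len(k), function(r) colMeans(ranks == r),
                  numeric(k))
  dimnames(probs) <- list(fit$treatments, paste0("rank", seq_len(k)))
  probs
}

#' SUCRA scores from a rank-probability matrix
#'
#' The surface under the cumulative ranking curve:
#' \deqn{SUCRA_k = \frac{1}{K-1} \sum_{r=1}^{K-1} P(\text{rank of } k \le r).}
#' 1 means certainly best, 0 certainly worst, and the scores always
#' average to 0.5 across treatments.
#'
#' @param rank_probs Treatments x ranks probability matrix (rows sum
#'   to 1), e.g. from [rank_probabilities()].
#' @return Named numeric vector of SUCRA scores in \[0, 1\].
#' @export
#' @examples
#' m <- rbind(A = c(.7, .2, .1), B = c(.2, .6, .2), C = c(.1, .2, .7))
#' sucra(m)
sucra <- function(rank_probs) {
  rank_probs <- as.matrix(rank_probs)
  k <- ncol(rank_probs)
  if (k < 2) stop("SUCRA needs >= 2 treatments", call. = FALSE)
  if (any(abs(rowSums(rank_probs) - 1) > 1e-6)) {
    stop("every row of rank_probs must sum to 1", call. = FALSE)
  }
  cum <- t(apply(rank_probs, 1, cumsum))
  out <- rowSums(cum[, seq_len(k - 1), drop = FALSE]) / (k - 1)
  stats::setNames(as.numeric(out), rownames(rank_probs))
}

#' Treatment ranking summary
#'
#' @inheritParams rank_probabilities
#' @return Tibble with one row per treatment: `p_best` (probability of
#'   rank 1), `sucra`, `mean_rank`, sorted by decreasing SUCRA.
#' @export
nma_ranking <- function(fit, direction = c("higher-is-better",
                                           "lower-is-better")) {
  direction <- match.arg(direction)
  probs <- rank_probabilities(fit, direction)
  k <- ncol(probs)
  tibble::tibble(
    treatment = rownames(probs),
    p_best = probs[, 1],
    sucra = sucra(probs),
    mean_rank = as.vector(probs %*% seq_len(k))
  ) |> dplyr::arrange(dplyr::desc(.data$sucra))
}
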