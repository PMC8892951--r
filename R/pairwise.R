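#' Random-effects pooling for one comparison
#'
#' DerSimonian–Laird random-effects meta-analysis of the contrasts of a
#' single treatment pair. With fixed-effect weights \eqn{w_i = 1/v_i}:
#' \deqn{Q = \sum w_i (y_i - \hat y_{FE})^2, \quad
#'   \tau^2 = \max\!\left(0, \frac{Q - (k-1)}{C}\right), \quad
#'   C = \sum w_i - \frac{\sum w_i^2}{\sum w_i},}
#' then random-effects weights \eqn{1/(v_i + \tau^2)} give the pooled
#' estimate, its normal 95% CI, and
#' \eqn{I^2 = \max(0, (Q - (k-1))/Q)}. With a single study (or Q = 0)
#' heterogeneity is reported as 0 and flagged via `het_defined = FALSE`.
#'
#' @param contrasts Contrast tibble (columns `y`, `v`, optionally
#'   `treat1`/`treat2`, which must then be constant).
#' @return One-row tibble: `treat1`, `treat2`, `k`, `pooled`, `se`,
#'   `ci_low`, `ci_high`, `tau2`, `i2`, `q`, `q_df`, `q_pvalue`,
#'   `het_defined`.
#' @export
#' @examples
#' pool_random_effects(tibble::tibble(y = c(0.2, 0.8), v = c(0.04, 0.04)))
pool_random_effects <- function(contrasts) {
  if (nrow(contrasts) == 0) stop("no contrasts supplied", call. = FALSE)
  if (all(c("treat1", "treat2") %in% names(contrasts))) {
    pair <- unique(paste(contrasts$treat1, contrasts$treat2, sep = " vs "))
    if (length(pair) > 1) {
      stop("contrasts mix several comparisons: ",
           paste(pair, collapse = "; "), call. = FALSE)
    }
    t1 <- contrasts$treat1[1]; t2 <- contrasts$treat2[1]
  } else {
    t1 <- NA_character_; t2 <- NA_character_
  }
  y <- contrasts$y; v <- contrasts$v
  if (any(v <= 0)) stop("contrast variances must be > 0", call. = FALSE)
  k <- length(y)
  w <- 1 / v
  y_fe <- sum(w * y) / sum(w)
  q <- sum(w * (y - y_fe)^2)
  if (k > 1) {
    cc <- sum(w) - sum(w^2) / sum(w)
    tau2 <- max(0, (q - (k - 1)) / cc)
    i2 <- if (q > 0) max(0, (q - (k - 1)) / q) else 0
    q_p <- stats::pchisq(q, df = k - 1, lower.tail = FALSE)
  } else {
    tau2 <- 0; i2 <- 0; q_p <- NA_real_
  }
  w_re <- 1 / (v + tau2)
  pooled <- sum(w_re * y) / sum(w_re)
  se <- sqrt(1 / sum(w_re))
  z <- stats::qnorm(0.975)
  tibble::tibble(
    treat1 = t1, treat2 = t2, k = k,
    pooled = pooled, se = se,
    ci_low = pooled - z * se, ci_high = pooled + z * se,
    tau2 = tau2, i2 = i2, q = q, q_df = k - 1, q_pvalue = q_p,
    het_defined = k > 1 && q > 0
  )
}

#' Pairwise meta-analysis of every direct comparison
#'
#' Runs [pool_random_effects()] on each edge of the evidence network that
#' has at least one study. Contrasts are first oriented canonically:
#' comparisons involving the reference put the reference second (so the
#' pooled SMD reads "active vs reference"); other pairs are oriented
#' lexicographically.
#'
#' @param data Arm-level tibble or a contrast tibble from
#'   [as_contrasts()].
#' @param reference Reference treatment code.
#' @param ... Passed to [as_contrasts()] when `data` is arm-level.
#' @return Tibble with one [pool_random_effects()] row per comparison,
#'   reference comparisons first, then lexicographic.
#' @export
pairwise_all <- function(data, reference = "PLA", ...) {
  contrasts <- if (all(c("y", "v", "treat1", "treat2") %in% names(data))) {
    data
  } else {
    as_contrasts(data, ...)
  }
  oriented <- orient_contrasts(contrasts, reference)
  res <- oriented |>
    dplyr::group_by(.data$treat1, .data$treat2) |>
    dplyr::group_split() |>
    purrr::map(pool_random_effects) |>
    purrr::list_rbind()
  res |>
    dplyr::arrange(.data$treat2 != reference, .data$treat1, .data$treat2)
}

# canonical orientation: reference second where present, else lexicographic
orient_contrasts <- function(contrasts, reference) {
  flip <- (contrasts$treat2 != reference) &
    (contrasts$treat1 == reference | contrasts$treat1 > contrasts$treat2)
  out <- contrasts
  out$treat1 <- ifelse(flip, contrasts$treat2, contrasts$treat1)
  out$treat2 <- ifelse(flip, contrasts$treat1, contrasts$treat2)
  out$y <- ifelse(flip, -contrasts$y, contrasts$y)
  out
}
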