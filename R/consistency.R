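#' @keywords internal
# consistency design matrix over basic parameters (reference first)
.design_matrix <- function(contrasts, treatments) {
  basic <- treatments[-1]
  X <- matrix(0, nrow(contrasts), length(basic),
              dimnames = list(NULL, paste0("d_", basic)))
  i1 <- match(contrasts$treat1, basic)
  i2 <- match(contrasts$treat2, basic)
  ok1 <- !is.na(i1); ok2 <- !is.na(i2)
  X[cbind(which(ok1), i1[ok1])] <- 1
  X[cbind(which(ok2), i2[ok2])] <- X[cbind(which(ok2), i2[ok2])] - 1
  X
}

# per-study design string (sorted treatment set)
.design_of <- function(contrasts) {
  contrasts |>
    dplyr::group_by(.data$study_id) |>
    dplyr::mutate(design = paste(sort(unique(c(.data$treat1, .data$treat2))),
                                 collapse = ";")) |>
    dplyr::ungroup()
}

# weighted least squares: returns rank and weighted RSS given full weight
# matrix W (symmetric positive definite)
.wls_rss <- function(y, X, W) {
  u <- chol(W)
  yt <- as.vector(u %*% y)
  if (is.null(X) || ncol(X) == 0) {
    return(list(rank = 0L, rss = sum(yt^2)))
  }
  qx <- qr(u %*% X)
  list(rank = qx$rank, rss = sum(qr.resid(qx, yt)^2))
}

# within-study random-effects structure: unit diagonal, 1/2 off-diagonal
.sigma0 <- function(study) {
  n <- length(study)
  s <- 0.5 * outer(study, study, "==")
  diag(s) <- 1
  s
}

#' Global design-by-treatment interaction test
#'
#' Compares the consistency model against the design-by-treatment
#' interaction model (a separate mean effect for every design-comparison
#' combination) by weighted least squares, giving a Wald-type chi-squared
#' statistic for global inconsistency. A common between-study variance is
#' estimated by the method of moments under the consistency model and
#' shared by both fits; multi-arm studies enter with the usual tau^2/2
#' within-study covariance and contribute a single design, so they are
#' never counted as evidence of inconsistency against themselves. Networks
#' without loops or repeated designs give 0 degrees of freedom and are
#' flagged (`estimable = FALSE`) rather than raising an error.
#'
#' @param contrasts Contrast tibble (`study_id`, `treat1`, `treat2`, `y`,
#'   `v`).
#' @param reference Reference treatment code.
#' @return One-row tibble: `chi2`, `df`, `p_value`, `tau2`, `estimable`,
#'   `note`.
#' @export
design_by_treatment_test <- function(contrasts, reference = "PLA") {
  net <- suppressWarnings(build_network(contrasts, reference))
  cc <- .design_of(contrasts)
  x_cons <- .design_matrix(cc, net$treatments)
  # one free mean per (design, comparison): disjoint-support indicator
  group <- paste(cc$design, pmin(cc$treat1, cc$treat2),
                 pmax(cc$treat1, cc$treat2), sep = "|")
  glev <- unique(group)
  x_full <- matrix(0, nrow(cc), length(glev))
  sign <- ifelse(cc$treat1 <= cc$treat2, 1, -1)
  x_full[cbind(seq_len(nrow(cc)), match(group, glev))] <- sign

  v <- cc$v
  study <- as.character(cc$study_id)
  sig0 <- .sigma0(study)
  # shared method-of-moments tau^2, estimated under the consistency model:
  # its larger residual df gives a less noisy plug-in than the interaction
  # model's, which keeps the Wald test close to nominal size
  w0 <- diag(1 / v, length(v))
  fe <- .wls_rss(cc$y, x_cons, w0)
  df_res <- length(v) - fe$rank
  xtwx <- crossprod(x_cons, w0 %*% x_cons)
  h <- w0 %*% x_cons %*% solve(xtwx, crossprod(x_cons, w0))
  p_mat <- w0 - h
  denom <- sum(diag(p_mat %*% sig0))
  tau2 <- if (df_res > 0 && denom > 0) max(0, (fe$rss - df_res) / denom) else 0

  w1 <- solve(diag(v, length(v)) + tau2 * sig0)
  fit_cons <- .wls_rss(cc$y, x_cons, w1)
  fit_full <- .wls_rss(cc$y, x_full, w1)
  df <- fit_full$rank - fit_cons$rank
  if (df <= 0) {
    return(tibble::tibble(chi2 = 0, df = 0L, p_value = NA_real_, tau2 = tau2,
                          estimable = FALSE,
                          note = "no inconsistency estimable (no loop or repeated design)"))
  }
  chi2 <- max(0, fit_cons$rss - fit_full$rss)
  tibble::tibble(chi2 = chi2, df = as.integer(df),
                 p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
                 tau2 = tau2, estimable = TRUE, note = NA_character_)
}

#' Loop-specific inconsistency factor
#'
#' For a treatment triangle A-B-C (labels sorted), each edge's direct
#' contrasts are pooled by random effects with a loop-common
#' method-of-moments tau^2, and the absolute inconsistency factor
#' \eqn{IF = |\hat d_{AB} - \hat d_{AC} + \hat d_{BC}|} is tested against
#' 0 with a two-sided z-test. The 95% CI is truncated below at 0.
#'
#' @param contrasts Contrast tibble.
#' @param loop Character vector of three treatment codes.
#' @return One-row tibble: the loop, `if_est`, `se_if`, `ci_low`,
#'   `ci_high`, `z`, `p_value`, `tau2_loop`, `note` (non-`NA` when the
#'   loop was skipped for missing direct evidence).
#' @export
loop_inconsistency <- function(contrasts, loop) {
  stopifnot(length(loop) == 3)
  loop <- sort(loop)
  skel <- tibble::tibble(t1 = loop[1], t2 = loop[2], t3 = loop[3],
                         if_est = NA_real_, se_if = NA_real_,
                         ci_low = NA_real_, ci_high = NA_real_,
                         z = NA_real_, p_value = NA_real_,
                         tau2_loop = NA_real_, note = NA_character_)
  pairs <- list(c(loop[1], loop[2]), c(loop[1], loop[3]),
                c(loop[2], loop[3]))
  key <- paste(pmin(contrasts$treat1, contrasts$treat2),
               pmax(contrasts$treat1, contrasts$treat2))
  edge_rows <- purrr::map(pairs, function(pr) {
    rows <- contrasts[key == paste(pr[1], pr[2]), , drop = FALSE]
    if (nrow(rows) == 0) return(NULL)
    flip <- rows$treat1 != pr[1]
    tibble::tibble(y = ifelse(flip, -rows$y, rows$y), v = rows$v)
  })
  if (any(vapply(edge_rows, is.null, logical(1)))) {
    skel$note <- "skipped: loop edge without direct evidence"
    return(skel)
  }
  # loop-common method-of-moments tau^2 pooled over the three edges
  mom <- purrr::map(edge_rows, function(e) {
    w <- 1 / e$v
    yfe <- sum(w * e$y) / sum(w)
    list(q = sum(w * (e$y - yfe)^2), df = nrow(e) - 1,
         c = sum(w) - sum(w^2) / sum(w))
  })
  q_sum <- sum(purrr::map_dbl(mom, "q"))
  df_sum <- sum(purrr::map_dbl(mom, "df"))
  c_sum <- sum(purrr::map_dbl(mom, "c"))
  tau2 <- if (df_sum > 0 && c_sum > 0) max(0, (q_sum - df_sum) / c_sum) else 0
  est <- purrr::map(edge_rows, function(e) {
    w <- 1 / (e$v + tau2)
    list(d = sum(w * e$y) / sum(w), var = 1 / sum(w))
  })
  if_raw <- est[[1]]$d - est[[2]]$d + est[[3]]$d
  se_if <- sqrt(est[[1]]$var + est[[2]]$var + est[[3]]$var)
  z <- abs(if_raw) / se_if
  zq <- stats::qnorm(0.975)
  skel$if_est <- abs(if_raw)
  skel$se_if <- se_if
  skel$ci_low <- max(0, abs(if_raw) - zq * se_if)
  skel$ci_high <- abs(if_raw) + zq * se_if
  skel$z <- z
  skel$p_value <- 2 * stats::pnorm(z, lower.tail = FALSE)
  skel$tau2_loop <- tau2
  skel
}

#' Inconsistency factors for every triangle in the network
#'
#' @param contrasts Contrast tibble.
#' @param reference Reference treatment code (used to enumerate loops).
#' @return Tibble with one [loop_inconsistency()] row per triangle.
#' @export
loop_inconsistency_all <- function(contrasts, reference = "PLA") {
  net <- suppressWarnings(build_network(contrasts, reference))
  if (nrow(net$loops) == 0) {
    return(loop_inconsistency(contrasts, c("..a", "..b", "..c"))[0, ])
  }
  purrr::pmap(net$loops, function(t1, t2, t3) {
    loop_inconsistency(contrasts, c(t1, t2, t3))
  }) |> purrr::list_rbind()
}

#' Bayesian node-splitting for one comparison
#'
#' Refits the NMA with a separate parameter for the direct evidence on the
#' split comparison: contrasts whose treatment pair equals `edge` inform a
#' free direct-effect parameter, while the rest of the network informs the
#' indirect estimate through the consistency structure (same priors as the
#' main fit). The inconsistency is the posterior of
#' \eqn{\omega = d_{direct} - d_{indirect}}, with the two-sided Bayesian
#' p-value \eqn{2 \min(P(\omega > 0), P(\omega < 0))}. A comparison with
#' no independent indirect path is reported as not splittable rather than
#' being an error.
#'
#' @param contrasts Contrast tibble.
#' @param edge Character vector of two treatment codes; the direct effect
#'   is reported as `edge[1]` versus `edge[2]`.
#' @param reference Reference treatment code.
#' @param priors An [nma_priors()] object.
#' @param mcmc An [nma_mcmc()] object.
#' @return One-row tibble: `treat1`, `treat2`, `splittable`, posterior
#'   median and 95% CrI of the direct, indirect and difference
#'   distributions, `bayes_p`, `note`.
#' @export
node_split <- function(contrasts, edge, reference = "PLA",
                       priors = nma_priors(), mcmc = nma_mcmc()) {
  stopifnot(length(edge) == 2)
  skel <- tibble::tibble(
    treat1 = edge[1], treat2 = edge[2], splittable = FALSE,
    direct = NA_real_, direct_low = NA_real_, direct_high = NA_real_,
    indirect = NA_real_, indirect_low = NA_real_, indirect_high = NA_real_,
    diff = NA_real_, diff_low = NA_real_, diff_high = NA_real_,
    bayes_p = NA_real_, note = NA_character_
  )
  key <- paste(pmin(contrasts$treat1, contrasts$treat2),
               pmax(contrasts$treat1, contrasts$treat2))
  is_direct <- key == paste(min(edge), max(edge))
  if (!any(is_direct)) {
    skel$note <- "no direct evidence on this comparison"
    return(skel)
  }
  rest <- contrasts[!is_direct, , drop = FALSE]
  has_indirect <- nrow(rest) > 0 && all(edge %in% c(rest$treat1, rest$treat2))
  if (has_indirect) {
    g <- igraph::graph_from_data_frame(rest[, c("treat1", "treat2")],
                                       directed = FALSE)
    has_indirect <-
      suppressWarnings(igraph::distances(g, edge[1], edge[2])[1, 1] < Inf)
  }
  if (!has_indirect) {
    skel$note <- "not splittable: no independent indirect path"
    return(skel)
  }

  net <- suppressWarnings(build_network(contrasts, reference))
  treatments <- net$treatments
  x_cons <- .design_matrix(contrasts, treatments)
  x_cons[is_direct, ] <- 0
  dir_sign <- ifelse(contrasts$treat1[is_direct] == edge[1], 1, -1)
  x_dir <- numeric(nrow(contrasts))
  x_dir[is_direct] <- dir_sign
  X <- cbind(x_cons, d_direct = x_dir)

  run <- .run_mcmc(contrasts$y, contrasts$v, as.character(contrasts$study_id),
                   X, rep(priors$d_sd, ncol(X)), priors$tau_upper, mcmc)
  basic <- treatments[-1]
  col_of <- function(tr) if (tr == reference) 0 else match(tr, basic)
  draw_of <- function(tr) {
    j <- col_of(tr)
    if (j == 0) 0 else as.vector(run$beta[, , j])
  }
  direct_d <- as.vector(run$beta[, , ncol(X)])
  indirect_d <- draw_of(edge[1]) - draw_of(edge[2])
  diff_d <- direct_d - indirect_d
  qs <- function(x) stats::quantile(x, c(0.025, 0.5, 0.975), names = FALSE)
  qd <- qs(direct_d); qi <- qs(indirect_d); qw <- qs(diff_d)
  skel$splittable <- TRUE
  skel$direct <- qd[2]; skel$direct_low <- qd[1]; skel$direct_high <- qd[3]
  skel$indirect <- qi[2]; skel$indirect_low <- qi[1]
  skel$indirect_high <- qi[3]
  skel$diff <- qw[2]; skel$diff_low <- qw[1]; skel$diff_high <- qw[3]
  skel$bayes_p <- 2 * min(mean(diff_d > 0), mean(diff_d < 0))
  skel
}

#' Node-splitting across all splittable comparisons
#'
#' @inheritParams node_split
#' @return Tibble with one [node_split()] row per direct comparison
#'   (non-splittable comparisons keep their `note`).
#' @export
node_split_all <- function(contrasts, reference = "PLA",
                           priors = nma_priors(), mcmc = nma_mcmc()) {
  net <- suppressWarnings(build_network(contrasts, reference))
  purrr::pmap(net$edges[, c("treat1", "treat2")], function(treat1, treat2) {
    node_split(contrasts, c(treat1, treat2), reference, priors, mcmc)
  }) |> purrr::list_rbind()
}

#' Full inconsistency report
#'
#' Bundles the global design-by-treatment test, the loop-specific
#' inconsistency factors and (optionally) node-splitting into one list.
#'
#' @inheritParams node_split
#' @param node_splits Run the (MCMC-based) node-splitting stage?
#' @return List of class `nma_inconsistency` with elements `global`,
#'   `loops`, `node_splits`.
#' @export
inconsistency_report <- function(contrasts, reference = "PLA",
                                 priors = nma_priors(), mcmc = nma_mcmc(),
                                 node_splits = TRUE) {
  structure(
    list(
      global = design_by_treatment_test(contrasts, reference),
      loops = loop_inconsistency_all(contrasts, reference),
      node_splits = if (node_splits) {
        node_split_all(contrasts, reference, priors, mcmc)
      } else {
        NULL
      }
    ),
    class = "nma_inconsistency"
  )
}

#' @export
print.nma_inconsistency <- function(x, ...) {
  cat("<nma_inconsistency>\n  global design-by-treatment: ")
  if (!x$global$estimable) {
    cat(x$global$note, "\n")
  } else {
    cat(sprintf("chi2 = %.3f, df = %d, p = %.3f\n", x$global$chi2,
                x$global$df, x$global$p_value))
  }
  cat("  loops assessed: ", nrow(x$loops), "\n", sep = "")
  if (!is.null(x$node_splits)) {
    cat("  node-splits: ", sum(x$node_splits$splittable), " splittable of ",
        nrow(x$node_splits), " comparisons\n", sep = "")
  }
  invisible(x)
}
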