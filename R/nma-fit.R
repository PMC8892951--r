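#' Prior specification for the Bayesian NMA
#'
#' Vague priors in the style of the NICE technical support documents:
#' independent Normal(0, `d_sd`^2) priors on the basic parameters (effects
#' of each treatment versus the reference) and a Uniform(0, `tau_upper`)
#' prior on the between-study SD tau.
#'
#' @param d_sd Prior SD of the basic parameters (default 100, effectively
#'   flat on the SMD scale).
#' @param tau_upper Upper bound of the uniform prior on tau (default 5,
#'   far above any plausible between-study SD for standardized effects).
#' @return A list of class `nma_priors`.
#' @export
nma_priors <- function(d_sd = 100, tau_upper = 5) {
  stopifnot(d_sd > 0, tau_upper > 0)
  structure(list(d_sd = d_sd, tau_upper = tau_upper), class = "nma_priors")
}

#' MCMC settings
#'
#' @param n_chains Number of independent chains (>= 2; default 3).
#' @param n_iter Post-burn-in iterations per chain (>= 1000).
#' @param n_burnin Discarded iterations per chain.
#' @param thin Thinning stride (>= 1).
#' @param seed Master seed; per-chain seeds are `seed + chain`.
#' @param rhat_threshold Convergence bound on the split Gelman-Rubin
#'   statistic (default 1.05).
#' @return A list of class `nma_mcmc`.
#' @export
nma_mcmc <- function(n_chains = 3, n_iter = 20000, n_burnin = 10000,
                     thin = 1, seed = 1, rhat_threshold = 1.05) {
  stopifnot(n_chains >= 2, n_iter >= 1000, n_burnin >= 0, thin >= 1)
  structure(list(n_chains = n_chains, n_iter = n_iter, n_burnin = n_burnin,
                 thin = thin, seed = seed, rhat_threshold = rhat_threshold),
            class = "nma_mcmc")
}

# Block structure of the within-study random-effects covariance:
# Sigma_s = tau^2/2 (I + J) over the contrasts of one study (diagonal
# tau^2, off-diagonal tau^2/2), so Sigma_s^{-1} = Omega0_s / tau^2 with
# Omega0_s = 2 (I - J/(p_s + 1)), and det Sigma_s = (tau^2/2)^p (p+1).
.omega0_block <- function(p) {
  2 * (diag(p) - matrix(1 / (p + 1), p, p))
}

# Metropolis-within-Gibbs sampler for the contrast-level random-effects
# model  y_i ~ N(delta_i, v_i),  delta_s ~ MVN(X_s beta, Sigma_s(tau)),
# beta_j ~ N(0, prior_sd_j^2),  tau ~ U(0, tau_upper).
# The study effects delta are linear-Gaussian and are integrated out
# analytically: y_s | beta, tau ~ MVN(X_s beta, V_s + Sigma_s(tau)), so
# the chain alternates an exact Gibbs draw of beta from its marginal
# conditional with a reflected random-walk Metropolis step on tau against
# the marginal likelihood (a partially collapsed scheme; the coupling
# between delta and tau that slows the uncollapsed sampler disappears).
# Returns draws of beta (n_save x n_chains x p) and tau.
.run_mcmc <- function(y, v, study, X, prior_sd, tau_upper, mcmc) {
  n <- length(y)
  p <- ncol(X)
  groups <- split(seq_len(n), study)
  sizes <- lengths(groups)
  single <- unlist(groups[sizes == 1], use.names = FALSE)
  multi <- unname(groups[sizes > 1])
  # within-study correlation structure of multi-arm random effects
  sig0_multi <- lapply(multi, function(ix) {
    s <- matrix(0.5, length(ix), length(ix)); diag(s) <- 1; s
  })
  prior_prec <- diag(1 / prior_sd^2, p)

  # log marginal likelihood of tau given residuals r = y - X beta
  loglik_tau <- function(tau, r) {
    tau2 <- tau^2
    ll <- 0
    if (length(single) > 0) {
      s <- v[single] + tau2
      ll <- -0.5 * sum(log(s) + r[single]^2 / s)
    }
    for (j in seq_along(multi)) {
      ix <- multi[[j]]
      u <- chol(diag(v[ix], length(ix)) + tau2 * sig0_multi[[j]])
      z <- forwardsolve(t(u), r[ix])
      ll <- ll - sum(log(diag(u))) - 0.5 * sum(z^2)
    }
    ll
  }

  n_save <- floor(mcmc$n_iter / mcmc$thin)
  beta_draws <- array(NA_real_, c(n_save, mcmc$n_chains, p))
  tau_draws <- matrix(NA_real_, n_save, mcmc$n_chains)
  accept <- numeric(mcmc$n_chains)

  for (chain in seq_len(mcmc$n_chains)) {
    set.seed(mcmc$seed + chain)
    # over-dispersed starts: spread tau across the prior range, diffuse beta
    beta <- stats::rnorm(p, 0, 1) * chain
    tau <- max(min(tau_upper * chain / (mcmc$n_chains + 1), tau_upper * 0.99),
               tau_upper * 1e-4)
    step <- max(0.02, tau_upper / 100)
    acc_win <- 0
    total <- mcmc$n_burnin + mcmc$n_iter
    isave <- 0

    for (it in seq_len(total)) {
      tau2 <- tau^2
      # beta | y, tau  (delta integrated out; conjugate multivariate normal)
      wx <- matrix(0, n, p)
      wy <- numeric(n)
      if (length(single) > 0) {
        w <- 1 / (v[single] + tau2)
        wx[single, ] <- X[single, , drop = FALSE] * w
        wy[single] <- y[single] * w
      }
      for (j in seq_along(multi)) {
        ix <- multi[[j]]
        s <- diag(v[ix], length(ix)) + tau2 * sig0_multi[[j]]
        sol <- solve(s, cbind(X[ix, , drop = FALSE], y[ix]))
        wx[ix, ] <- sol[, seq_len(p), drop = FALSE]
        wy[ix] <- sol[, p + 1]
      }
      post_prec <- crossprod(X, wx) + prior_prec
      bvec <- crossprod(X, wy)
      u <- chol(post_prec)
      mu <- backsolve(u, forwardsolve(t(u), bvec))
      beta <- as.vector(mu + backsolve(u, stats::rnorm(p)))
      # tau | y, beta  (random-walk Metropolis, reflected at 0)
      r <- y - as.vector(X %*% beta)
      ll_cur <- loglik_tau(tau, r)
      tau_prop <- abs(tau + stats::rnorm(1, 0, step))
      if (tau_prop > 0 && tau_prop < tau_upper &&
          log(stats::runif(1)) < loglik_tau(tau_prop, r) - ll_cur) {
        tau <- tau_prop
        acc_win <- acc_win + 1
        if (it > mcmc$n_burnin) accept[chain] <- accept[chain] + 1
      }
      # adapt the Metropolis step during burn-in only
      if (it <= mcmc$n_burnin && it %% 50 == 0) {
        step <- step * exp(0.5 * (acc_win / 50 - 0.44))
        acc_win <- 0
      }
      if (it > mcmc$n_burnin && (it - mcmc$n_burnin) %% mcmc$thin == 0) {
        isave <- isave + 1
        beta_draws[isave, chain, ] <- beta
        tau_draws[isave, chain] <- tau
      }
    }
  }
  list(beta = beta_draws, tau = tau_draws,
       accept_rate = accept / mcmc$n_iter)
}

#' Fit the Bayesian random-effects consistency NMA
#'
#' Fits the contrast-level consistency model
#' \deqn{y_i \sim N(\delta_i, v_i), \quad
#'   \delta_i \sim N(d_{t1(i)} - d_{t2(i)}, \tau^2),}
#' where contrasts from the same multi-arm study share a joint normal
#' random effect with off-diagonal covariance \eqn{\tau^2/2} (the usual
#' homogeneous-variance multi-arm treatment). The reference effect is
#' fixed at 0; the remaining basic parameters get vague normal priors and
#' tau a Uniform(0, upper) prior. Sampling is Metropolis-within-Gibbs on
#' the marginal model with the (linear-Gaussian) study effects integrated
#' out analytically: an exact conjugate Gibbs draw of the basic parameters
#' alternates with a reflected random-walk Metropolis step for tau,
#' adapted during burn-in only. Chains start over-dispersed and
#' convergence is assessed with the split Gelman-Rubin statistic.
#'
#' @param contrasts Contrast tibble (`study_id`, `treat1`, `treat2`, `y`,
#'   `v`).
#' @param reference Reference treatment code.
#' @param priors An [nma_priors()] object.
#' @param mcmc An [nma_mcmc()] object.
#' @return An object of class `nma_fit` with elements `treatments`
#'   (reference first), `d` (draws array: iteration x chain x treatment,
#'   reference column identically 0), `tau` (iteration x chain), `rhat`
#'   (per-parameter tibble), `converged`, plus the inputs. Non-convergence
#'   produces a warning, never a silent result.
#' @export
#' @examples
#' trials <- simulate_network(sim_config(n_treatments = 3,
#'                                       n_trials_per_design = 4, seed = 1))
#' fit <- fit_nma(as_contrasts(trials),
#'                mcmc = nma_mcmc(n_iter = 1000, n_burnin = 500, seed = 1))
fit_nma <- function(contrasts, reference = "PLA", priors = nma_priors(),
                    mcmc = nma_mcmc()) {
  net <- suppressWarnings(build_network(contrasts, reference))
  if (!net$connected) {
    stop("network is disconnected; treatments out of the reference ",
         "component: ", paste(net$stranded, collapse = ", "), call. = FALSE)
  }
  treatments <- net$treatments
  k <- length(treatments)
  basic <- treatments[-1]
  X <- matrix(0, nrow(contrasts), k - 1,
              dimnames = list(NULL, paste0("d_", basic)))
  i1 <- match(contrasts$treat1, basic)
  i2 <- match(contrasts$treat2, basic)
  ok1 <- !is.na(i1); ok2 <- !is.na(i2)
  X[cbind(which(ok1), i1[ok1])] <- 1
  X[cbind(which(ok2), i2[ok2])] <- X[cbind(which(ok2), i2[ok2])] - 1

  run <- .run_mcmc(contrasts$y, contrasts$v, as.character(contrasts$study_id),
                   X, rep(priors$d_sd, k - 1), priors$tau_upper, mcmc)

  d <- array(0, c(dim(run$beta)[1], mcmc$n_chains, k),
             dimnames = list(NULL, NULL, treatments))
  d[, , -1] <- run$beta
  rhat <- tibble::tibble(
    parameter = c(paste0("d_", basic), "tau"),
    rhat = c(vapply(seq_len(k - 1),
                    function(j) gelman_rubin(run$beta[, , j, drop = TRUE]),
                    numeric(1)),
             gelman_rubin(run$tau))
  )
  converged <- all(is.na(rhat$rhat) | rhat$rhat < mcmc$rhat_threshold)
  if (!converged) {
    warning("MCMC did not reach the R-hat threshold ", mcmc$rhat_threshold,
            " (max R-hat = ", round(max(rhat$rhat, na.rm = TRUE), 3),
            "); inspect the draws before using this fit", call. = FALSE)
  }
  structure(
    list(treatments = treatments, reference = reference,
         d = d, tau = run$tau, rhat = rhat, converged = converged,
         accept_rate = run$accept_rate, contrasts = contrasts,
         network = net, priors = priors, mcmc = mcmc),
    class = "nma_fit"
  )
}

#' Split Gelman-Rubin convergence statistic
#'
#' Each chain is split in half and the usual between/within variance ratio
#' is computed over the resulting sequences. Values near 1 indicate that
#' the chains have mixed.
#'
#' @param draws Matrix of draws, iterations x chains (>= 2 chains, >= 10
#'   iterations).
#' @return The R-hat value; `NA` (with attribute `degenerate = TRUE`) when
#'   all sequences have zero variance.
#' @export
gelman_rubin <- function(draws) {
  draws <- as.matrix(draws)
  if (ncol(draws) < 2) stop("R-hat needs >= 2 chains", call. = FALSE)
  if (nrow(draws) < 10) stop("R-hat needs >= 10 draws per chain", call. = FALSE)
  half <- floor(nrow(draws) / 2)
  seqs <- cbind(draws[seq_len(half), , drop = FALSE],
                draws[half + seq_len(half), , drop = FALSE])
  w <- mean(apply(seqs, 2, stats::var))
  if (w == 0) return(structure(NA_real_, degenerate = TRUE))
  b <- half * stats::var(colMeans(seqs))
  var_plus <- (half - 1) / half * w + b / half
  sqrt(var_plus / w)
}

# draws of the contrast A - B, pooled over chains
.pair_draws <- function(fit, a, b) {
  as.vector(fit$d[, , a]) - as.vector(fit$d[, , b])
}

#' League table of all pairwise treatment comparisons
#'
#' Summarizes the posterior of every ordered treatment contrast
#' `d[treat1] - d[treat2]`: median, 95% credible interval and the
#' posterior probability that the contrast is positive. The table is
#' antisymmetric in the point estimate, with a zero diagonal.
#'
#' @param fit An [fit_nma()] result.
#' @return A tibble of class `nma_league` with columns `treat1`, `treat2`,
#'   `median`, `mean`, `ci_low`, `ci_high`, `p_gt0`.
#' @export
league_table <- function(fit) {
  stopifnot(inherits(fit, "nma_fit"))
  grid <- tidyr::expand_grid(treat1 = fit$treatments,
                             treat2 = fit$treatments)
  out <- purrr::pmap(grid, function(treat1, treat2) {
    dd <- .pair_draws(fit, treat1, treat2)
    qq <- stats::quantile(dd, c(0.025, 0.5, 0.975), names = FALSE)
    tibble::tibble(treat1 = treat1, treat2 = treat2,
                   median = qq[2], mean = mean(dd),
                   ci_low = qq[1], ci_high = qq[3],
                   p_gt0 = mean(dd > 0))
  }) |> purrr::list_rbind()
  class(out) <- c("nma_league", class(out))
  out
}

#' @export
print.nma_fit <- function(x, ...) {
  cat("<nma_fit> ", length(x$treatments), " treatments (reference ",
      x$reference, "), ", nrow(x$contrasts), " contrasts, ",
      x$mcmc$n_chains, " chains x ", x$mcmc$n_iter, " iterations\n",
      sep = "")
  cat("  converged: ", x$converged, " (max R-hat ",
      round(max(x$rhat$rhat, na.rm = TRUE), 4), ")\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy posterior summaries of the basic parameters
#'
#' One row per treatment (versus the reference) plus the between-study SD
#' tau, with posterior median, mean, SD, 95% credible interval and R-hat.
#'
#' @param x An `nma_fit` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy nma_fit
#' @export
tidy.nma_fit <- function(x, ...) {
  basic <- x$treatments[-1]
  rows <- purrr::map(basic, function(tr) {
    dd <- as.vector(x$d[, , tr])
    qq <- stats::quantile(dd, c(0.025, 0.5, 0.975), names = FALSE)
    tibble::tibble(term = paste0("d_", tr), treatment = tr,
                   estimate = qq[2], mean = mean(dd), sd = stats::sd(dd),
                   ci_low = qq[1], ci_high = qq[3])
  }) |> purrr::list_rbind()
  tau_d <- as.vector(x$tau)
  qq <- stats::quantile(tau_d, c(0.025, 0.5, 0.975), names = FALSE)
  rows <- dplyr::bind_rows(rows, tibble::tibble(
    term = "tau", treatment = NA_character_, estimate = qq[2],
    mean = mean(tau_d), sd = stats::sd(tau_d), ci_low = qq[1],
    ci_high = qq[3]))
  dplyr::left_join(rows, x$rhat, by = dplyr::join_by("term" == "parameter"))
}

#' One-row fit summary
#'
#' @param x An `nma_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: treatments, studies, contrasts, chains,
#'   iterations, posterior median tau, max R-hat, convergence flag.
#' @method glance nma_fit
#' @export
glance.nma_fit <- function(x, ...) {
  tibble::tibble(
    n_treatments = length(x$treatments),
    n_studies = dplyr::n_distinct(x$contrasts$study_id),
    n_contrasts = nrow(x$contrasts),
    n_chains = x$mcmc$n_chains,
    n_iter = x$mcmc$n_iter,
    tau_median = stats::median(as.vector(x$tau)),
    max_rhat = max(x$rhat$rhat, na.rm = TRUE),
    converged = x$converged
  )
}

#' Export posterior draws in long format
#'
#' One row per (chain, iteration, parameter) triple, consumable by
#' standard MCMC-diagnostic tooling.
#'
#' @param fit An `nma_fit` object.
#' @return A tibble with columns `chain`, `iteration`, `parameter`,
#'   `value`.
#' @export
posterior_draws <- function(fit) {
  stopifnot(inherits(fit, "nma_fit"))
  basic <- fit$treatments[-1]
  n_save <- dim(fit$d)[1]
  per_par <- function(name, mat) {
    tibble::tibble(
      chain = rep(seq_len(ncol(mat)), each = n_save),
      iteration = rep(seq_len(n_save), times = ncol(mat)),
      parameter = name,
      value = as.vector(mat)
    )
  }
  dplyr::bind_rows(
    purrr::map(basic, function(tr) {
      per_par(paste0("d_", tr), fit$d[, , tr, drop = TRUE])
    }) |> purrr::list_rbind(),
    per_par("tau", fit$tau)
  )
}

# batch-means Monte Carlo standard error of a posterior mean,
# computed per chain and combined
mcse_mean <- function(draws) {
  draws <- as.matrix(draws)
  per_chain <- apply(draws, 2, function(x) {
    nb <- max(2, floor(sqrt(length(x))))
    bs <- floor(length(x) / nb)
    bm <- colMeans(matrix(x[seq_len(nb * bs)], bs, nb))
    bs * stats::var(bm) / (nb * bs)
  })
  sqrt(mean(per_chain) / ncol(draws))
}
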