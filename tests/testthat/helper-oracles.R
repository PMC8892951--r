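# Independent brute-force oracles, written directly from the defining
# formulas; deliberately kept separate from the package implementation.

oracle_hedges <- function(m1, s1, n1, m2, s2, n2) {
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  d <- (m1 - m2) / sp
  j <- 1 - 3 / (4 * (n1 + n2 - 2) - 1)
  g <- j * d
  v <- (n1 + n2) / (n1 * n2) + g^2 / (2 * (n1 + n2))
  c(g = g, v = v)
}

oracle_dl <- function(y, v) {
  k <- length(y)
  w <- 1 / v
  yfe <- sum(w * y) / sum(w)
  q <- sum(w * (y - yfe)^2)
  cc <- sum(w) - sum(w^2) / sum(w)
  tau2 <- if (k > 1) max(0, (q - (k - 1)) / cc) else 0
  i2 <- if (k > 1 && q > 0) max(0, (q - (k - 1)) / q) else 0
  wr <- 1 / (v + tau2)
  pooled <- sum(wr * y) / sum(wr)
  c(pooled = pooled, se = sqrt(1 / sum(wr)), tau2 = tau2, i2 = i2, q = q)
}

# a minimal hand-built arm-level table
make_arm <- function(study, trt, n, mean, sd, outcome = "average-pain",
                     direction = "higher-is-better", duration = 26,
                     radicular = FALSE, rob = "low") {
  tibble::tibble(study_id = study, treatment = trt, n = n, mean = mean,
                 sd = sd, outcome = outcome, direction = direction,
                 duration_weeks = duration, radicular = radicular, rob = rob)
}

two_study_trials <- function() {
  dplyr::bind_rows(
    make_arm("s1", "PLA", 30, 0.0, 1.0),
    make_arm("s1", "SMR", 30, 0.5, 1.1),
    make_arm("s2", "PLA", 40, 0.1, 0.9),
    make_arm("s2", "SMR", 40, 0.4, 1.0)
  )
}

# an nma_fit-shaped object with prescribed posterior draws (one chain per
# column set), for exercising ranking/league code without MCMC
fake_fit <- function(draws, reference = colnames(draws)[1]) {
  treatments <- colnames(draws)
  stopifnot(all(draws[, reference] == 0))
  n <- nrow(draws)
  d <- array(0, c(n, 1, length(treatments)),
             dimnames = list(NULL, NULL, treatments))
  for (tr in treatments) d[, 1, tr] <- draws[, tr]
  structure(list(treatments = c(reference,
                                setdiff(treatments, reference)),
                 reference = reference, d = d,
                 tau = matrix(0.1, n, 1),
                 rhat = tibble::tibble(parameter = "tau", rhat = 1),
                 converged = TRUE),
            class = "nma_fit")
}
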