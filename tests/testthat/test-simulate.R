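test_that("the generator is deterministic for a fixed seed", {
  cfg <- sim_config(n_treatments = 3, n_trials_per_design = 4, seed = 99)
  expect_identical(simulate_network(cfg), simulate_network(cfg))
  expect_identical(simulate_contrasts(cfg), simulate_contrasts(cfg))
  cfg2 <- sim_config(n_treatments = 3, n_trials_per_design = 4, seed = 100)
  expect_false(identical(simulate_network(cfg), simulate_network(cfg2)))
})

test_that("with tau = 0 and huge arms the SMDs converge to the truth", {
  cfg <- sim_config(n_treatments = 3, true_d = c(0, 0.3, 0.6), tau = 0,
                    n_trials_per_design = 1, n_per_arm = 1e6, seed = 471)
  ctr <- as_contrasts(simulate_network(cfg))
  truth <- c(SMR = 0.3, NSA = 0.6)
  for (i in seq_len(nrow(ctr))) {
    expected <- if (ctr$treat2[i] == "PLA") truth[[ctr$treat1[i]]] else
      truth[[ctr$treat1[i]]] - truth[[ctr$treat2[i]]]
    expect_lt(abs(ctr$y[i] - expected), 0.01)
  }
})

test_that("exact-SD mode reproduces the analytic arm summaries", {
  cfg <- sim_config(n_treatments = 2, true_d = c(0, 0.5), tau = 0,
                    n_trials_per_design = 1, n_per_arm = 50, mu_sd = 0,
                    exact_sd = TRUE, seed = 472)
  data <- simulate_network(cfg)
  expect_equal(data$sd, rep(1, 2))
  expect_equal(data$mean[data$treatment == "SMR"], 0.5)
  expect_equal(data$mean[data$treatment == "PLA"], 0)
})

test_that("a null two-treatment network pools to zero", {
  cfg <- sim_config(n_treatments = 2, true_d = c(0, 0), tau = 0,
                    n_trials_per_design = 20, n_per_arm = 50, seed = 473)
  res <- pairwise_all(simulate_network(cfg), "PLA")
  expect_lt(abs(res$pooled), 3 * res$se)
})

test_that("between-study spread of effects approaches tau^2", {
  cfg <- sim_config(n_treatments = 2, true_d = c(0, 0.4), tau = 0.2,
                    n_trials_per_design = 300, n_per_arm = 1e6, seed = 474)
  ctr <- simulate_contrasts(cfg)
  # sampling error of a variance over 300 trials is ~ sqrt(2/299) ~ 8%
  expect_equal(stats::var(ctr$y), 0.04, tolerance = 0.25)
})

test_that("the inconsistency offset shifts only the named design", {
  base <- sim_config(treatments = c("PLA", "SMR", "NSA"),
                     true_d = c(0, 0.3, 0.6), tau = 0,
                     n_trials_per_design = 200, n_per_arm = 1e5, seed = 475)
  off <- base
  off$inconsistency_offset <- list(design = c("PLA", "SMR"),
                                   pair = c("SMR", "PLA"), offset = 0.8)
  ctr <- simulate_contrasts(off)
  smr_pla <- ctr[ctr$treat1 == "SMR" & ctr$treat2 == "PLA", ]
  nsa_pla <- ctr[ctr$treat1 == "NSA" & ctr$treat2 == "PLA", ]
  expect_equal(mean(smr_pla$y), 1.1, tolerance = 0.02)
  expect_equal(mean(nsa_pla$y), 0.6, tolerance = 0.02)
})

test_that("small-study bias inflates effects in proportion to the SE", {
  cfg <- sim_config(n_treatments = 2, true_d = c(0, 0), tau = 0,
                    n_trials_per_design = 400, n_per_arm = 25, seed = 476)
  cfg$small_study_bias <- 2
  ctr <- simulate_contrasts(cfg)
  mc_se <- stats::sd(ctr$y) / sqrt(nrow(ctr))
  expect_lt(abs(mean(ctr$y) - 2 * sqrt(2 / 25)), 3 * mc_se)
})

test_that("n_range varies trial sizes for funnel identifiability", {
  cfg <- sim_config(n_treatments = 2, n_trials_per_design = 30,
                    n_range = c(10, 200), seed = 477)
  data <- simulate_network(cfg)
  expect_gt(dplyr::n_distinct(data$n), 5)
  expect_true(all(data$n >= 10 & data$n <= 200))
})

test_that("disconnected design lists are refused", {
  expect_error(simulate_network(
    sim_config(treatments = c("PLA", "SMR", "NSA", "OPI"),
               designs = list(c("PLA", "SMR"), c("NSA", "OPI")),
               seed = 1)),
    "connect")
})

test_that("replicate_study derives seeds and records failures", {
  cfg <- sim_config(n_treatments = 2, n_trials_per_design = 3, seed = 50)
  one <- replicate_study(cfg, 1, function(data, config) {
    tibble::tibble(mean_y = mean(as_contrasts(data)$y))
  })
  manual_cfg <- cfg
  manual_cfg$seed <- 50 + 1000000L
  manual <- mean(as_contrasts(simulate_network(manual_cfg))$y)
  expect_equal(one$mean_y, manual)
  expect_equal(one$seed, 50 + 1000000L)

  mixed <- replicate_study(cfg, 3, function(data, config) {
    if (config$seed == 50 + 2000000L) stop("boom")
    tibble::tibble(ok = TRUE)
  })
  expect_equal(nrow(mixed), 3)
  expect_equal(sum(!is.na(mixed$error)), 1)
  expect_match(mixed$error[2], "boom")
})

test_that("multi-arm designs produce correlated contrasts with one baseline", {
  cfg <- sim_config(treatments = c("PLA", "SMR", "NSA"),
                    designs = list(c("PLA", "SMR", "NSA")),
                    true_d = c(0, 0.3, 0.6), tau = 0.3,
                    n_trials_per_design = 400, n_per_arm = 1e5, seed = 478)
  ctr <- simulate_contrasts(cfg)
  wide <- tidyr::pivot_wider(ctr[, c("study_id", "treat1", "y")],
                             names_from = "treat1", values_from = "y")
  expect_equal(stats::cor(wide$SMR, wide$NSA), 0.5, tolerance = 0.12)
  expect_equal(unique(ctr$treat2), "PLA")
})
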