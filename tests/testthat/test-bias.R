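test_that("funnel points are centered per comparison", {
  cfg <- sim_config(n_treatments = 3, n_trials_per_design = 8,
                    n_range = c(20, 200), seed = 461)
  ctr <- as_contrasts(simulate_network(cfg))
  fun <- comparison_adjusted_funnel(ctr, "PLA")
  pw <- pairwise_all(ctr, "PLA")
  centered <- fun$points |>
    dplyr::left_join(pw[, c("treat1", "treat2", "tau2")],
                     by = c("treat1", "treat2")) |>
    dplyr::group_by(.data$treat1, .data$treat2) |>
    dplyr::summarise(wm = sum(.data$x / (.data$se^2 + .data$tau2)),
                     .groups = "drop")
  expect_true(all(abs(centered$wm) < 1e-9))
  expect_false(fun$egger$suppressed)
})

test_that("the Egger test is suppressed below 3 points", {
  ctr <- tibble::tibble(study_id = c("s1", "s2"), treat1 = "SMR",
                        treat2 = "PLA", y = c(0.2, 0.4), v = c(0.04, 0.09))
  fun <- comparison_adjusted_funnel(ctr, "PLA")
  expect_true(fun$egger$suppressed)
  expect_equal(nrow(fun$points), 2)
})

test_that("a single-comparison network reduces to the classic funnel", {
  set.seed(462)
  ctr <- tibble::tibble(study_id = paste0("s", 1:10), treat1 = "SMR",
                        treat2 = "PLA", y = rnorm(10, 0.4, 0.2),
                        v = runif(10, 0.01, 0.1))
  fun <- comparison_adjusted_funnel(ctr, "PLA")
  pooled <- pool_random_effects(ctr)$pooled
  expect_equal(fun$points$x, ctr$y - pooled)
})

test_that("Egger rejection is near nominal without bias and high with it", {
  base <- sim_config(n_treatments = 3, tau = 0.1, n_trials_per_design = 10,
                     n_range = c(10, 200), seed = 463)
  calib <- replicate_study(base, 100, function(ctr, cfg) {
    fun <- comparison_adjusted_funnel(ctr, "PLA")
    tibble::tibble(p = fun$egger$p_value)
  }, generator = simulate_contrasts)
  expect_true(all(is.na(calib$error)))
  rate <- mean(calib$p < 0.05)
  expect_lt(rate, 0.13)  # binomial-noise bound around the nominal 5%

  # power: all comparisons against placebo so the injected asymmetry has
  # one coherent direction after orientation (in a closed loop the
  # off-reference comparison flips sign and the asymmetry cancels)
  biased <- sim_config(treatments = c("PLA", "SMR", "NSA"),
                       true_d = c(0, 0.3, 0.6), tau = 0.1,
                       designs = list(c("PLA", "SMR"), c("PLA", "NSA")),
                       n_trials_per_design = 15, n_range = c(10, 200),
                       small_study_bias = 3, seed = 464)
  power <- replicate_study(biased, 40, function(ctr, cfg) {
    fun <- comparison_adjusted_funnel(ctr, "PLA")
    tibble::tibble(p = fun$egger$p_value, b = fun$egger$intercept)
  }, generator = simulate_contrasts)
  expect_gte(mean(power$p < 0.05 & power$b > 0), 0.8)
})

test_that("a two-treatment network draws 100% from its only comparison", {
  ctr <- tibble::tibble(study_id = c("s1", "s2"), treat1 = "SMR",
                        treat2 = "PLA", y = c(0.2, 0.4), v = 0.04)
  cm <- contribution_matrix(ctr, "PLA")
  expect_equal(dim(cm), c(1L, 1L))
  expect_equal(unname(cm[1, 1]), 100)
})

test_that("the symmetric triangle gives the closed-form 66.7/16.7/16.7 split", {
  ctr <- tibble::tibble(study_id = c("s1", "s2", "s3"),
                        treat1 = c("A", "A", "B"), treat2 = c("B", "C", "C"),
                        y = c(0.5, 0.3, 0.2), v = 0.01)
  cm <- contribution_matrix(ctr, reference = "A")
  own <- diag(unclass(cm)[paste(c("B", "C", "B"), "vs", c("A", "A", "C")),
                          paste(c("B", "C", "B"), "vs", c("A", "A", "C"))])
  expect_equal(unname(own), rep(200 / 3, 3), tolerance = 1e-6)
  expect_equal(unname(colSums(cm)), rep(100, 3), tolerance = 0.1)
})

test_that("contribution columns always sum to 100 and survive relabeling", {
  cfg <- sim_config(n_treatments = 4, n_trials_per_design = 4, seed = 464)
  ctr <- simulate_contrasts(cfg)
  cm <- contribution_matrix(ctr, "PLA")
  expect_true(all(abs(colSums(cm) - 100) < 0.1))
  expect_true(all(cm >= 0))
  # relabel treatments and expect identical percentages
  map <- c(PLA = "Z1", SMR = "Z2", NSA = "Z3", OPI = "Z4")
  ctr2 <- ctr
  ctr2$treat1 <- unname(map[ctr$treat1])
  ctr2$treat2 <- unname(map[ctr$treat2])
  cm2 <- contribution_matrix(ctr2, "Z1")
  expect_equal(sort(as.vector(unclass(cm2))), sort(as.vector(unclass(cm))),
               tolerance = 1e-9)
})

test_that("sensitivity refit is a no-op when nothing is excluded", {
  cfg <- sim_config(n_treatments = 3, n_trials_per_design = 4, seed = 465)
  data <- simulate_network(cfg)
  mc <- nma_mcmc(n_chains = 2, n_iter = 1000, n_burnin = 400, seed = 12)
  sens <- sensitivity_refit(data, exclude = character(0), mcmc = mc)
  expect_equal(sens$max_abs_shift, 0, tolerance = 1e-12)
  expect_false(any(sens$comparison$conclusion_change))
})

test_that("excluding an edge's studies widens that comparison", {
  cfg <- sim_config(n_treatments = 3, true_d = c(0, 0.3, 0.6), tau = 0.05,
                    n_trials_per_design = 6, n_per_arm = 80, seed = 466)
  data <- simulate_network(cfg)
  info <- study_info(data)
  # drop every SMR-PLA study: that comparison becomes purely indirect
  smr_pla <- data |>
    dplyr::group_by(.data$study_id) |>
    dplyr::summarise(is_edge = setequal(.data$treatment, c("SMR", "PLA")))
  mc <- nma_mcmc(n_chains = 2, n_iter = 1500, n_burnin = 600, seed = 13)
  sens <- sensitivity_refit(data,
                            exclude = smr_pla$study_id[smr_pla$is_edge],
                            mcmc = mc)
  width <- function(fit) {
    lt <- league_table(fit)
    row <- lt[lt$treat1 == "SMR" & lt$treat2 == "PLA", ]
    row$ci_high - row$ci_low
  }
  expect_gt(width(sens$fit_reduced), width(sens$fit_full))
})

test_that("excluding a planted outlier pulls the estimate back to truth", {
  cfg <- sim_config(n_treatments = 2, true_d = c(0, 0.3), tau = 0,
                    n_trials_per_design = 10, n_per_arm = 100, seed = 467)
  data <- simulate_network(cfg)
  outlier <- dplyr::bind_rows(
    make_arm("out1", "PLA", 100, 0, 1, rob = "high"),
    make_arm("out1", "SMR", 100, 3, 1, rob = "high")
  )
  mc <- nma_mcmc(n_chains = 2, n_iter = 1500, n_burnin = 600, seed = 14)
  sens <- sensitivity_refit(dplyr::bind_rows(data, outlier), mcmc = mc)
  expect_equal(sens$excluded, "out1")
  est <- sens$comparison[sens$comparison$treat1 == "SMR", ]
  expect_lt(abs(est$median_reduced - 0.3), abs(est$median_full - 0.3))
})

test_that("exclusions that break the network are refused", {
  cfg <- sim_config(n_treatments = 3, n_trials_per_design = 2, seed = 468)
  data <- simulate_network(cfg)
  non_pla <- study_info(data)$study_id[
    !purrr::map_lgl(study_info(data)$study_id, function(s) {
      "PLA" %in% data$treatment[data$study_id == s]
    })]
  all_pla <- setdiff(unique(data$study_id), non_pla)
  expect_error(sensitivity_refit(data, exclude = all_pla,
                                 mcmc = nma_mcmc(n_iter = 1000,
                                                 n_burnin = 100, seed = 1)),
               "reference|disconnect")
})

test_that("grade_combine takes the higher rating over all 16 pairs", {
  levels <- c("very-low", "low", "moderate", "high")
  for (a in levels) {
    for (b in levels) {
      expected <- levels[max(match(a, levels), match(b, levels))]
      expect_equal(grade_combine(a, b), expected)
      expect_equal(grade_combine(b, a), expected)  # commutative
    }
    expect_equal(grade_combine(a, a), a)           # idempotent
    expect_equal(grade_combine(a, NA), a)          # pass-through
    expect_equal(grade_combine(NA, a), a)
  }
  expect_error(grade_combine(NA, NA), "both ratings missing")
  expect_error(grade_combine("medium", "low"), "must be one of")
})
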